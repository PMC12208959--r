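# Synthetic reference bundle: a toy chromosome with planted miRNA hairpins,
# tRNA genes, rRNAs and Y RNAs, plus an off-genome rDNA database with
# taxonomy headers.  Stands in for a genome + annotation stack so the whole
# pipeline is exercisable with known ground truth.

.rrna_catalog <- data.frame(
  name = c("18S", "5.8S", "28S", "5S", "mt-rRNA"),
  len  = c(350L, 130L, 450L, 110L, 200L),
  stringsAsFactors = FALSE
)

.default_bundle_params <- function() {
  list(
    genome_size = 100000L,
    n_mir = 20L, n_trna = 10L, n_rrna = 5L, n_yrna = 4L, n_yrna_partial = 2L,
    n_rdna = 30L, n_rdna_families = 5L,
    ssu_len = 300L, lsu_len = 400L,
    rdna_divergence = 0.02,   # per-base substitution rate vs family consensus
    max_retries = 2000L
  )
}

.random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

.mutate_seq <- function(seq, rate) {
  b <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  paste(b, collapse = "")
}

# greedy non-overlapping placement with a small buffer between features
.place_intervals <- function(lens, genome_size, max_retries, buffer = 10L) {
  placed <- matrix(integer(0), ncol = 2L)
  for (len in lens) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      s <- sample.int(genome_size - len, 1L) - 1L   # 0-based start
      e <- s + len
      if (nrow(placed) == 0L ||
          all(e + buffer <= placed[, 1L] | s >= placed[, 2L] + buffer)) {
        placed <- rbind(placed, c(s, e))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("generation error: could not place a feature of length ", len,
                  " after ", max_retries, " retries", call. = FALSE)
  }
  placed
}

#' Build a deterministic synthetic reference bundle
#'
#' Generates a random toy chromosome and plants non-overlapping miRNA
#' hairpins (each with 5p and 3p mature arms), tRNA genes (mature space is
#' the gene plus a non-templated 3' CCA), rRNA loci, full-length Y RNAs and
#' partial Y RNA copies.  Separately generates an rDNA database of SSU and
#' LSU sequences for a configurable number of organisms grouped into
#' families; organisms within a family are small mutations of a shared
#' consensus, and every rDNA sequence is rejection-sampled so that it is not
#' a substring of the genome (either strand).
#'
#' @param seed Integer seed; the bundle is byte-identical for a fixed seed.
#' @param params Optional list overriding the defaults: \code{genome_size}
#'   (100 kb), \code{n_mir} (20), \code{n_trna} (10), \code{n_rrna} (5),
#'   \code{n_yrna} (4), \code{n_yrna_partial} (2), \code{n_rdna} (30),
#'   \code{n_rdna_families} (5), \code{ssu_len}/\code{lsu_len},
#'   \code{rdna_divergence}, \code{max_retries}.
#' @return An object of class \code{snc_bundle}: genome string, locus
#'   tables (0-based half-open), Y RNA sequence set, and the rDNA database
#'   with semicolon-delimited taxonomy strings of at least five levels.
#' @export
build_reference_bundle <- function(seed, params = list()) {
  p <- utils::modifyList(.default_bundle_params(), params)
  with_seed(seed, {
    rrna <- .rrna_catalog[seq_len(min(p$n_rrna, nrow(.rrna_catalog))), ]
    hp_lens   <- sample(70:90, p$n_mir, replace = TRUE)
    trna_lens <- sample(70:75, p$n_trna, replace = TRUE)
    yrna_lens <- sample(95:110, p$n_yrna, replace = TRUE)
    part_lens <- sample(40:60, p$n_yrna_partial, replace = TRUE)
    all_lens <- c(hp_lens, trna_lens, rrna$len, yrna_lens, part_lens)
    iv <- .place_intervals(all_lens, p$genome_size, p$max_retries)
    genome <- strsplit(.random_seq(p$genome_size), "")[[1]]

    k <- 0L
    take <- function(n) {
      idx <- (k + 1L):(k + n); k <<- k + n
      iv[idx, , drop = FALSE]
    }
    mir_iv  <- take(p$n_mir)
    trna_iv <- take(p$n_trna)
    rrna_iv <- take(nrow(rrna))
    yrna_iv <- take(p$n_yrna)
    part_iv <- take(p$n_yrna_partial)

    mir_loci <- data.frame(
      name = sprintf("mir-%d", seq_len(p$n_mir)),
      hp_start = mir_iv[, 1L], hp_end = mir_iv[, 2L],
      stringsAsFactors = FALSE
    )
    mir_loci$m5p_start <- mir_loci$hp_start
    mir_loci$m5p_end   <- mir_loci$hp_start + 22L
    mir_loci$m3p_start <- mir_loci$hp_end - 22L
    mir_loci$m3p_end   <- mir_loci$hp_end

    aa <- c("Gly", "Glu", "Lys", "His", "Met", "Val", "Asp", "Leu", "Ser", "Arg")
    anticodons <- vapply(seq_len(p$n_trna),
                         function(i) .random_seq(3L), character(1))
    trna_loci <- data.frame(
      name = sprintf("tRNA-%s%s-%d", rep_len(aa, p$n_trna), anticodons,
                     seq_len(p$n_trna)),
      start = trna_iv[, 1L], end = trna_iv[, 2L],
      stringsAsFactors = FALSE
    )
    rrna_loci <- data.frame(name = rrna$name, start = rrna_iv[, 1L],
                            end = rrna_iv[, 2L], stringsAsFactors = FALSE)
    yrna_names <- sprintf("RNY%d", c(1L, 3L, 4L, 5L, seq_len(max(0L, p$n_yrna - 4L)) + 5L))[seq_len(p$n_yrna)]
    yrna_loci <- data.frame(
      name = yrna_names, start = yrna_iv[, 1L], end = yrna_iv[, 2L],
      full = TRUE, source = yrna_names, stringsAsFactors = FALSE
    )

    # partial Y RNA copies: copy an internal window of a full Y RNA into a
    # separate genomic location (pseudogene-like)
    part_rows <- list()
    for (j in seq_len(p$n_yrna_partial)) {
      src <- sample.int(p$n_yrna, 1L)
      plen <- part_iv[j, 2L] - part_iv[j, 1L]
      src_span <- yrna_iv[src, 2L] - yrna_iv[src, 1L]
      off <- sample.int(src_span - plen, 1L) - 1L
      frag <- genome[(yrna_iv[src, 1L] + off + 1L):(yrna_iv[src, 1L] + off + plen)]
      genome[(part_iv[j, 1L] + 1L):part_iv[j, 2L]] <- frag
      part_rows[[j]] <- data.frame(
        name = sprintf("%s-partial-%d", yrna_names[src], j),
        start = part_iv[j, 1L], end = part_iv[j, 2L],
        full = FALSE, source = yrna_names[src], stringsAsFactors = FALSE
      )
    }
    yrna_loci <- rbind(yrna_loci, do.call(rbind, part_rows))
    genome <- paste(genome, collapse = "")

    yrna_seqs <- vapply(seq_len(nrow(yrna_loci)), function(i) {
      seq_interval(genome, yrna_loci$start[i], yrna_loci$end[i])
    }, character(1))
    names(yrna_seqs) <- yrna_loci$name

    # rDNA database grouped into families sharing a consensus
    fam_of <- sort(rep_len(seq_len(p$n_rdna_families), p$n_rdna))
    doms <- rep_len(c("Bacteria", "Bacteria", "Bacteria", "Eukaryota", "Archaea"),
                    p$n_rdna_families)
    fam_tax <- vapply(seq_len(p$n_rdna_families), function(f) {
      paste(c(doms[f], sprintf("Phylum%d", (f - 1L) %/% 2L + 1L),
              sprintf("Class%d", f), sprintf("Order%d", f),
              sprintf("Family%d", f)), collapse = ";")
    }, character(1))
    fam_ssu <- vapply(seq_len(p$n_rdna_families),
                      function(f) .random_seq(p$ssu_len), character(1))
    fam_lsu <- vapply(seq_len(p$n_rdna_families),
                      function(f) .random_seq(p$lsu_len), character(1))
    rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    fresh <- function(base) {
      for (try in seq_len(p$max_retries)) {
        s <- .mutate_seq(base, p$rdna_divergence)
        if (!grepl(s, genome, fixed = TRUE) && !grepl(rc(s), genome, fixed = TRUE)) {
          return(s)
        }
      }
      stop("generation error: rDNA sequence collides with the genome", call. = FALSE)
    }
    rdna <- do.call(rbind, lapply(seq_len(p$n_rdna), function(i) {
      f <- fam_of[i]
      org <- sprintf("ORG%03d", i)
      data.frame(
        id = org,
        organism = sprintf("%s_sp%d", sub(";.*", "", fam_tax[f]), i),
        subunit = c("SSU", "LSU"),
        taxonomy = paste0(fam_tax[f], ";", org),
        seq = c(fresh(fam_ssu[f]), fresh(fam_lsu[f])),
        stringsAsFactors = FALSE
      )
    }))

    structure(list(
      genome = genome, mir_loci = mir_loci, trna_loci = trna_loci,
      rrna_loci = rrna_loci, yrna_loci = yrna_loci, yrna_seqs = yrna_seqs,
      rdna = rdna, params = p, seed = seed
    ), class = "snc_bundle")
  })
}

#' @export
print.snc_bundle <- function(x, ...) {
  cat("snc_bundle:", nchar(x$genome), "bp genome;",
      nrow(x$mir_loci), "miRNA hairpins,", nrow(x$trna_loci), "tRNAs,",
      nrow(x$rrna_loci), "rRNAs,", sum(x$yrna_loci$full), "Y RNAs (+",
      sum(!x$yrna_loci$full), "partial),",
      length(unique(x$rdna$id)), "rDNA organisms\n")
  invisible(x)
}

#' Annotated genome intervals of a bundle
#'
#' @param bundle An \code{snc_bundle}.
#' @return data.frame(class, name, start, end), 0-based half-open.
#' @export
bundle_annotations <- function(bundle) {
  rbind(
    data.frame(class = "miRNA-hairpin", name = bundle$mir_loci$name,
               start = bundle$mir_loci$hp_start, end = bundle$mir_loci$hp_end,
               stringsAsFactors = FALSE),
    data.frame(class = "tRNA", name = bundle$trna_loci$name,
               start = bundle$trna_loci$start, end = bundle$trna_loci$end,
               stringsAsFactors = FALSE),
    data.frame(class = "rRNA", name = bundle$rrna_loci$name,
               start = bundle$rrna_loci$start, end = bundle$rrna_loci$end,
               stringsAsFactors = FALSE),
    data.frame(class = "yRNA", name = bundle$yrna_loci$name,
               start = bundle$yrna_loci$start, end = bundle$yrna_loci$end,
               stringsAsFactors = FALSE)
  )
}

#' Mature sequence spaces of a bundle
#'
#' Mature miRNA arms, hairpins, tRNA mature space (gene + CCA), rRNA and
#' Y RNA sequences, extracted from the genome.
#'
#' @param bundle An \code{snc_bundle}.
#' @return A list of named character vectors: \code{mature5p},
#'   \code{mature3p}, \code{hairpin}, \code{trna_space}, \code{rrna},
#'   \code{yrna}.
#' @export
bundle_sequences <- function(bundle) {
  g <- bundle$genome
  ml <- bundle$mir_loci
  out <- list(
    mature5p = stats::setNames(
      vapply(seq_len(nrow(ml)), function(i)
        seq_interval(g, ml$m5p_start[i], ml$m5p_end[i]), character(1)),
      paste0("miR-", sub("^mir-", "", ml$name), "-5p")),
    mature3p = stats::setNames(
      vapply(seq_len(nrow(ml)), function(i)
        seq_interval(g, ml$m3p_start[i], ml$m3p_end[i]), character(1)),
      paste0("miR-", sub("^mir-", "", ml$name), "-3p")),
    hairpin = stats::setNames(
      vapply(seq_len(nrow(ml)), function(i)
        seq_interval(g, ml$hp_start[i], ml$hp_end[i]), character(1)),
      ml$name),
    trna_space = stats::setNames(
      vapply(seq_len(nrow(bundle$trna_loci)), function(i)
        paste0(seq_interval(g, bundle$trna_loci$start[i],
                            bundle$trna_loci$end[i]), "CCA"), character(1)),
      bundle$trna_loci$name),
    rrna = stats::setNames(
      vapply(seq_len(nrow(bundle$rrna_loci)), function(i)
        seq_interval(g, bundle$rrna_loci$start[i], bundle$rrna_loci$end[i]),
        character(1)),
      bundle$rrna_loci$name),
    yrna = bundle$yrna_seqs
  )
  out
}

#' Write / read a bundle as plain-text files
#'
#' Emits \code{genome.fasta}, \code{annotations.bed} (0-based half-open,
#' + strand, name = "class|name"), \code{yrna.fasta},
#' \code{rdna_ssu.fasta} / \code{rdna_lsu.fasta} with SILVA-style headers
#' ("id taxonomy;...;levels"), and \code{bundle.json} with the locus tables.
#'
#' @param bundle An \code{snc_bundle}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(c(chr1 = bundle$genome), file.path(dir, "genome.fasta"))
  ann <- bundle_annotations(bundle)
  write_bed(data.frame(chrom = "chr1", start = ann$start, end = ann$end,
                       name = paste(ann$class, ann$name, sep = "|"),
                       stringsAsFactors = FALSE),
            file.path(dir, "annotations.bed"))
  write_fasta(bundle$yrna_seqs, file.path(dir, "yrna.fasta"))
  for (su in c("SSU", "LSU")) {
    d <- bundle$rdna[bundle$rdna$subunit == su, ]
    write_fasta(stats::setNames(d$seq, paste(d$id, d$taxonomy)),
                file.path(dir, paste0("rdna_", tolower(su), ".fasta")))
  }
  meta <- bundle[c("mir_loci", "trna_loci", "rrna_loci", "yrna_loci",
                   "params", "seed")]
  jsonlite::write_json(meta, file.path(dir, "bundle.json"), digits = NA)
  invisible(dir)
}
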