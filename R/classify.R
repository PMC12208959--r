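# Sequence classification: isomiR / tRF / rRF / yRF callers, not-itr
# grouping (exact genome match, one-edit match, no match), plate labeling,
# and per-sample composition accounting.

#' Default classification windows
#'
#' isomiR calling accepts 5' offsets in [-3, 3], 3' offsets in [-5, 5] and
#' up to 3 nt of non-templated 3' additions; tRNA-half typing uses an
#' anticodon-loop window at mature positions 30-36.
#' @return List of window parameters.
#' @export
default_classify_config <- function() {
  list(max_offset5 = 3L, max_offset3 = 5L, max_nta = 3L,
       loop_window = c(30L, 36L))
}

.fmt_offset <- function(x) {
  if (x > 0) paste0("+", x) else as.character(x)
}

#' Precompute a classification index for a bundle
#'
#' Caches the genome as DNAString objects (both strands), the mature
#' sequence spaces and the annotation table, so classifying many sequences
#' does not rebuild them.
#'
#' @param bundle An \code{snc_bundle}.
#' @return A list used by the \code{call_*} and \code{classify_*}
#'   functions.
#' @export
bundle_index <- function(bundle) {
  g <- Biostrings::DNAString(bundle$genome)
  list(
    bundle = bundle,
    genome_fwd = g,
    genome_rev = Biostrings::reverseComplement(g),
    genome_len = nchar(bundle$genome),
    seqs = bundle_sequences(bundle),
    ann = bundle_annotations(bundle)
  )
}

.as_index <- function(x) {
  if (inherits(x, "snc_bundle")) bundle_index(x) else x
}

#' Call isomiRs for one sequence
#'
#' A call fires for each mature arm whose hairpin contains a templated
#' prefix of the sequence starting within the 5' offset window of the
#' annotated mature 5' end; any untemplated 3' remainder (at most
#' \code{max_nta} nt) becomes the non-templated addition.  Offsets are
#' signed with positive = the read's end is longer than the annotated
#' mature end.
#'
#' @param seq A single A/C/G/T sequence, length >= 15.
#' @param index An \code{snc_bundle} or \code{\link{bundle_index}}.
#' @param config See \code{\link{default_classify_config}}.
#' @return data.frame(arm, offset5, offset3, nta, category, label); zero
#'   rows when no call.
#' @export
call_isomir <- function(seq, index, config = default_classify_config()) {
  ix <- .as_index(index)
  ml <- ix$bundle$mir_loci
  L <- nchar(seq)
  rows <- list()
  d5_order <- order(abs(-config$max_offset5:config$max_offset5),
                    -(-config$max_offset5:config$max_offset5))
  d5_cands <- (-config$max_offset5:config$max_offset5)[d5_order]
  for (i in seq_len(nrow(ml))) {
    H <- ix$seqs$hairpin[[i]]
    hp_start <- ml$hp_start[i]
    for (arm in c("5p", "3p")) {
      m_start <- ml[[paste0("m", arm, "_start")]][i] - hp_start  # 0-based in H
      m_end   <- ml[[paste0("m", arm, "_end")]][i] - hp_start
      arm_name <- sprintf("miR-%s-%s", sub("^mir-", "", ml$name[i]), arm)
      for (d5 in d5_cands) {
        g0 <- m_start - d5          # 0-based start in hairpin; +d5 = longer 5'
        if (g0 < 0L || g0 >= nchar(H)) next
        # maximal templated prefix of seq at g0
        k <- 0L
        while (k < L && g0 + k < nchar(H) &&
               substr(seq, k + 1L, k + 1L) ==
               substr(H, g0 + k + 1L, g0 + k + 1L)) {
          k <- k + 1L
        }
        if (k < L - config$max_nta || k < 15L - config$max_nta) next
        nta <- if (k < L) substr(seq, k + 1L, L) else ""
        offset3 <- (g0 + k) - m_end
        if (abs(offset3) > config$max_offset3) next
        category <- if (nzchar(nta)) "non-templated"
                    else if (d5 == 0L && offset3 == 0L) "canonical"
                    else "non-canonical"
        rows[[length(rows) + 1L]] <- data.frame(
          arm = arm_name, offset5 = d5, offset3 = offset3, nta = nta,
          category = category,
          label = sprintf("%s|%s|%s|", arm_name, .fmt_offset(d5),
                          .fmt_offset(offset3)),
          stringsAsFactors = FALSE
        )
        break                       # one call per arm: nearest 5' offset
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(arm = character(0), offset5 = integer(0),
                  offset3 = integer(0), nta = character(0),
                  category = character(0), label = character(0),
                  stringsAsFactors = FALSE)
}

.genome_hits <- function(seq, ix, max_edits = 0L) {
  # forward + reverse-strand occurrences as 0-based half-open forward coords
  hits <- list()
  f <- Biostrings::matchPattern(seq, ix$genome_fwd, max.mismatch = max_edits,
                                with.indels = max_edits > 0L)
  if (length(f)) {
    hits[[1L]] <- data.frame(start = BiocGenerics::start(f) - 1L,
                             end = BiocGenerics::end(f), strand = "+")
  }
  r <- Biostrings::matchPattern(seq, ix$genome_rev, max.mismatch = max_edits,
                                with.indels = max_edits > 0L)
  if (length(r)) {
    L <- ix$genome_len
    hits[[2L]] <- data.frame(start = L - BiocGenerics::end(r),
                             end = L - BiocGenerics::start(r) + 1L,
                             strand = "-")
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(start = integer(0), end = integer(0), strand = character(0))
}

#' Call tRNA fragments for one sequence
#'
#' A call fires for each tRNA whose mature space (gene + non-templated 3'
#' CCA) contains the sequence exactly.  Types: fragments starting at mature
#' position 1 are 5'-tRFs, or 5'-halves when their 3' terminus falls in the
#' anticodon-loop window; fragments ending at the gene 3' end or inside the
#' CCA are 3'-tRFs, or 3'-halves when their 5' terminus falls in the loop
#' window; everything else is an i-tRF.  The exclusivity flag records
#' whether the sequence is absent from the genome outside tRNA gene
#' intervals (both strands).
#'
#' @inheritParams call_isomir
#' @return data.frame(trna, start, end, type, exclusive); zero rows when no
#'   call.  \code{start}/\code{end} are 1-based inclusive mature-space
#'   positions.
#' @export
call_trf <- function(seq, index, config = default_classify_config()) {
  ix <- .as_index(index)
  spaces <- ix$seqs$trna_space
  lw <- config$loop_window
  rows <- list()
  for (nm in names(spaces)) {
    sp <- spaces[[nm]]
    pos <- as.integer(gregexpr(seq, sp, fixed = TRUE)[[1L]])
    if (pos[1L] == -1L) next
    gene_len <- nchar(sp) - 3L
    for (s in pos) {
      e <- s + nchar(seq) - 1L
      type <- if (s == 1L) {
        if (e >= lw[1L] && e <= lw[2L]) "5'-half" else "5'-tRF"
      } else if (e >= gene_len) {
        if (s >= lw[1L] && s <= lw[2L]) "3'-half" else "3'-tRF"
      } else "i-tRF"
      rows[[length(rows) + 1L]] <- data.frame(
        trna = nm, start = s, end = e, type = type, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(trna = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      exclusive = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  gh <- .genome_hits(seq, ix, 0L)
  tr <- ix$bundle$trna_loci
  inside <- if (nrow(gh)) {
    vapply(seq_len(nrow(gh)), function(i) {
      any(gh$start[i] >= tr$start & gh$end[i] <= tr$end)
    }, logical(1))
  } else logical(0)
  out$exclusive <- nrow(gh) == 0L || all(inside)
  out
}

#' Call rRNA- and Y RNA-derived fragments (exact substring search)
#'
#' @inheritParams call_isomir
#' @return Character vector of source reference names (possibly empty).
#' @export
call_rrf <- function(seq, index) {
  ix <- .as_index(index)
  refs <- ix$seqs$rrna
  names(refs)[vapply(refs, function(r) grepl(seq, r, fixed = TRUE), logical(1))]
}

#' @rdname call_rrf
#' @export
call_yrf <- function(seq, index) {
  ix <- .as_index(index)
  refs <- ix$seqs$yrna
  names(refs)[vapply(refs, function(r) grepl(seq, r, fixed = TRUE), logical(1))]
}

.neighbor_class_map <- c(`miRNA-hairpin` = "isomiR", tRNA = "tRF",
                         rRNA = "rRF", yRNA = "yRF")

#' Classify one sequence into classes or not-itr groups
#'
#' Runs the four class callers; a sequence with no class call becomes a
#' not-itr: Group 1 when it matches the genome exactly (either strand),
#' Group 2 when it matches within edit distance 1 (one replacement,
#' insertion or deletion), recording which annotated class the edited match
#' falls in, and Group 3 otherwise.  Every sequence receives one plate
#' label per applicable prefix ("na-" for not-itrs).
#'
#' @inheritParams call_isomir
#' @return A one-row data.frame: sequence, flags, \code{notitr_group} (0
#'   for classified sequences), \code{group2_neighbors},
#'   \code{unambiguous}, \code{plates} (comma-joined), per-caller
#'   annotations as attribute \code{"calls"}.
#' @export
classify_read <- function(seq, index, config = default_classify_config()) {
  if (nchar(seq) < 15L) stop("invalid-input: sequence shorter than 15 nt",
                             call. = FALSE)
  .check_acgt(seq)
  ix <- .as_index(index)
  iso <- call_isomir(seq, ix, config)
  trf <- call_trf(seq, ix, config)
  rrf <- call_rrf(seq, ix)
  yrf <- call_yrf(seq, ix)
  flags <- c(is_isomir = nrow(iso) > 0L, is_trf = nrow(trf) > 0L,
             is_rrf = length(rrf) > 0L, is_yrf = length(yrf) > 0L)
  group <- 0L
  neighbors <- ""
  if (!any(flags)) {
    if (nrow(.genome_hits(seq, ix, 0L))) {
      group <- 1L
    } else {
      gh1 <- .genome_hits(seq, ix, 1L)
      if (nrow(gh1)) {
        group <- 2L
        ann <- ix$ann
        ncl <- character(0)
        for (i in seq_len(nrow(gh1))) {
          ov <- ann$class[gh1$start[i] < ann$end & gh1$end[i] > ann$start]
          ncl <- c(ncl, if (length(ov)) .neighbor_class_map[ov] else "other")
        }
        neighbors <- paste(sort(unique(ncl)), collapse = ",")
      } else {
        group <- 3L
      }
    }
  }
  prefixes <- c("iso", "tRF", "rRF", "yRF")[flags]
  if (!length(prefixes)) prefixes <- "na"
  plates <- plate_encode(rep(seq, length(prefixes)), prefixes)
  out <- data.frame(
    seq = seq, is_isomir = flags[[1]], is_trf = flags[[2]],
    is_rrf = flags[[3]], is_yrf = flags[[4]], notitr_group = group,
    group2_neighbors = neighbors, unambiguous = sum(flags) == 1L,
    plates = paste(plates, collapse = ","),
    isomir_labels = paste(iso$label, collapse = ","),
    trf_types = paste(unique(trf$type), collapse = ","),
    rrf_sources = paste(rrf, collapse = ","),
    yrf_sources = paste(yrf, collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "calls") <- list(isomir = iso, trf = trf, rrf = rrf, yrf = yrf)
  out
}

#' Classify many sequences
#'
#' @param seqs Character vector of sequences (each >= 15 nt).
#' @inheritParams call_isomir
#' @return data.frame with one row per sequence (see
#'   \code{\link{classify_read}}).
#' @export
classify_reads <- function(seqs, index, config = default_classify_config()) {
  ix <- .as_index(index)
  out <- do.call(rbind, lapply(seqs, classify_read, index = ix,
                               config = config))
  attr(out, "calls") <- NULL
  rownames(out) <- NULL
  out
}

#' Per-sample class composition of retained reads
#'
#' Fractions of total retained reads attributed to unambiguous isomiRs,
#' unambiguous tRFs, rRFs, yRFs and not-itrs; reads whose sequence carries
#' more than one class flag are counted in no class fraction (so fractions
#' need not reach 1).
#'
#' @param counts Named integer vector (sequence -> count) or matrix with
#'   sequences as rownames and samples as columns.
#' @param assignments data.frame from \code{\link{classify_reads}} covering
#'   all counted sequences.
#' @return data.frame with one row per sample and columns isomiR, tRF, rRF,
#'   yRF, notitr, ambiguous.
#' @export
composition_summary <- function(counts, assignments) {
  if (is.null(dim(counts))) counts <- cbind(sample = counts)
  if (is.null(rownames(counts))) stop("counts must carry sequence names",
                                      call. = FALSE)
  a <- assignments[match(rownames(counts), assignments$seq), ]
  if (anyNA(a$seq)) stop("assignments do not cover all counted sequences",
                         call. = FALSE)
  cls <- ifelse(a$notitr_group > 0L, "notitr",
         ifelse(!a$unambiguous, "ambiguous",
         ifelse(a$is_isomir, "isomiR",
         ifelse(a$is_trf, "tRF",
         ifelse(a$is_rrf, "rRF", "yRF")))))
  out <- t(apply(counts, 2L, function(col) {
    tot <- sum(col)
    if (tot == 0) stop("undefined-fraction: sample with zero total reads",
                       call. = FALSE)
    vapply(c("isomiR", "tRF", "rRF", "yRF", "notitr", "ambiguous"),
           function(k) sum(col[cls == k]) / tot, numeric(1))
  }))
  data.frame(sample = colnames(counts), out, stringsAsFactors = FALSE,
             row.names = NULL, check.names = FALSE)
}
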