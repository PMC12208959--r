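# Readers/writers for the plain-text formats the pipeline exchanges.
# Coordinates are 0-based half-open everywhere (BED convention).

#' Evaluate code with a temporarily fixed RNG state
#'
#' Saves and restores \code{.Random.seed} so seeded generators do not
#' disturb the caller's RNG stream; the RNG kind is pinned so results are
#' reproducible across sessions.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Read/write FASTA as a named character vector
#' @param path File path.
#' @return \code{read_fasta}: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read/write FASTQ as a data.frame of (id, seq, qual)
#' @param path File path (gzip transparent).
#' @return \code{read_fastq}: data.frame with columns id, seq, qual.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' @rdname read_fastq
#' @param records data.frame with columns id, seq, qual.
#' @export
write_fastq <- function(records, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(records)),
            all(nchar(records$seq) == nchar(records$qual)))
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(records$qual))
  invisible(path)
}

#' Read/write BED intervals (0-based, half-open)
#' @param path File path.
#' @return \code{read_bed}: data.frame with columns chrom, start, end, name,
#'   score, strand.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"))
  if (any(df$end <= df$start)) {
    bad <- which(df$end <= df$start)[1]
    stop("malformed BED interval at line ", bad, call. = FALSE)
  }
  df
}

#' @rdname read_bed
#' @param intervals data.frame with columns chrom, start, end, name, and
#'   optionally score and strand.
#' @export
write_bed <- function(intervals, path) {
  if (is.null(intervals$score)) intervals$score <- 0L
  if (is.null(intervals$strand)) intervals$strand <- "+"
  utils::write.table(intervals[, c("chrom", "start", "end", "name", "score",
                                   "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a raw count matrix (features x samples, integer TSV)
#' @param path File path.
#' @return \code{read_counts}: integer matrix with feature rownames and
#'   sample colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m) || any(m != round(m)) || any(m < 0)) {
    stop("schema error: raw counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts Integer matrix, features as rows.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a generic TSV with header
#' @param path File path.
#' @return \code{read_tsv}: data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_tsv
#' @param df data.frame to write.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a 0-based half-open interval from a sequence
#' @param seq Character scalar sequence.
#' @param start,end 0-based half-open interval.
#' @return The substring of length \code{end - start}.
#' @keywords internal
seq_interval <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}
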