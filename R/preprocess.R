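# Read preprocessing: 3' quality trimming, semi-global adapter location,
# UMI extraction, and directional UMI deduplication.

#' Trim low-quality 3' bases (Phred+33)
#'
#' Standard 3' quality-trimming: walking in from the 3' end, cut at the
#' position minimizing the running sum of (cutoff - quality); bases after
#' that point are removed.
#'
#' @param seq,qual Read sequence and Sanger quality string.
#' @param cutoff Phred cutoff (default 15).
#' @return List with trimmed \code{seq} and \code{qual}.
#' @export
quality_trim3 <- function(seq, qual, cutoff = 15L) {
  q <- utf8ToInt(qual) - 33L
  n <- length(q)
  if (n == 0L) return(list(seq = seq, qual = qual))
  s <- cumsum(rev(cutoff - q))        # running sum from the 3' end
  best <- which.max(s)
  if (s[best] <= 0) return(list(seq = seq, qual = qual))
  keep <- n - best
  list(seq = substr(seq, 1L, keep), qual = substr(qual, 1L, keep))
}

# Semi-global adapter alignment (unit-cost edits).  The adapter may occur
# in full anywhere in the read or as a prefix overhanging the read's 3'
# end.  Returns the best occurrence: maximal aligned adapter length net of
# twice the edit count, then fewest edits, then leftmost start; NULL when
# no occurrence satisfies edits <= floor(error_rate * aligned_length).
.find_adapter <- function(read, adapter, error_rate, min_overlap = 3L) {
  n <- nchar(read); m <- nchar(adapter)
  if (n == 0L) return(NULL)
  # fast path: exact full occurrence
  hit <- regexpr(adapter, read, fixed = TRUE)
  if (hit > 0L) return(list(start = as.integer(hit), alen = m, edits = 0L))
  r <- strsplit(read, "")[[1]]
  a <- strsplit(adapter, "")[[1]]
  # D[i+1, j+1] = min edits aligning adapter[1..i] ending at read position j,
  # with free start (D[1, ] = 0); S tracks the start position of the
  # alignment so ties can be broken deterministically.
  INF <- n + m + 1L
  Dprev <- rep(0L, n + 1L)
  Sprev <- c(1L, seq_len(n) + 1L)     # start = j+1 for empty alignment at j
  best <- NULL
  consider <- function(start, alen, edits) {
    if (alen < min_overlap || edits > floor(error_rate * alen)) return()
    score <- alen - 2L * edits
    if (is.null(best) || score > best$score ||
        (score == best$score && (edits < best$edits ||
         (edits == best$edits && start < best$start)))) {
      best <<- list(start = start, alen = alen, edits = edits, score = score)
    }
  }
  for (i in seq_len(m)) {
    Dcur <- rep(INF, n + 1L); Scur <- rep(NA_integer_, n + 1L)
    Dcur[1L] <- i; Scur[1L] <- 1L     # adapter prefix consumed before read start
    for (j in seq_len(n)) {
      sub <- Dprev[j] + (a[i] != r[j])
      del <- Dprev[j + 1L] + 1L       # skip adapter base
      ins <- Dcur[j] + 1L             # skip read base
      v <- min(sub, del, ins)
      Dcur[j + 1L] <- v
      Scur[j + 1L] <- if (v == sub) Sprev[j]
                      else if (v == del) Sprev[j + 1L]
                      else Scur[j]
    }
    # partial occurrence: adapter prefix of length i reaching the read end
    consider(Scur[n + 1L], i, Dcur[n + 1L])
    if (i == m) {
      for (j in seq_len(n + 1L)) consider(Scur[j], m, Dcur[j])
    }
    Dprev <- Dcur; Sprev <- Scur
  }
  if (is.null(best)) NULL else best[c("start", "alen", "edits")]
}

#' Locate and remove the 3' adapter from one read
#'
#' Quality-trims the 3' end, then locates the best adapter occurrence by
#' semi-global alignment allowing mismatches and indels up to
#' \code{floor(error_rate * aligned_length)}.  The bases 5' of the adapter
#' are the insert.  In UMI mode a read without an adapter hit is rejected;
#' otherwise it is kept whole.  Inserts shorter than \code{min_length} are
#' rejected.
#'
#' @param seq,qual Read and quality strings.
#' @param adapter 3' adapter sequence.
#' @param error_rate Allowed edit fraction (default 0.12).
#' @param quality_cutoff Phred cutoff for 3' quality trimming (default 15).
#' @param min_length Minimum insert length (default 15).
#' @param umi_mode Reject adapter-less reads when TRUE.
#' @param min_overlap Minimum aligned adapter length (default 3).
#' @return List: \code{insert} (or NA), \code{status} one of "ok",
#'   "no-adapter", "too-short".
#' @export
trim_adapter <- function(seq, qual = NULL, adapter, error_rate = 0.12,
                         quality_cutoff = 15L, min_length = 15L,
                         umi_mode = FALSE, min_overlap = 3L) {
  stopifnot(nzchar(adapter), error_rate >= 0, error_rate < 0.5)
  if (!is.null(qual) && quality_cutoff > 0L) {
    tr <- quality_trim3(seq, qual, quality_cutoff)
    seq <- tr$seq
  }
  hit <- .find_adapter(seq, adapter, error_rate, min_overlap)
  if (is.null(hit)) {
    if (umi_mode) return(list(insert = NA_character_, status = "no-adapter"))
    insert <- seq
  } else {
    insert <- substr(seq, 1L, hit$start - 1L)
  }
  if (nchar(insert) < min_length) {
    return(list(insert = NA_character_, status = "too-short"))
  }
  list(insert = insert, status = "ok")
}

#' Extract insert and UMI from one read
#'
#' The library layout places the UMI between the insert and the 3' adapter,
#' so after adapter removal the last \code{umi_len} bases are the UMI and
#' the rest is the insert.  Rejects reads without an adapter or with a
#' truncated UMI.
#'
#' @inheritParams trim_adapter
#' @param umi_len UMI length (> 0; use \code{trim_adapter} for UMI-less
#'   libraries).
#' @return List: \code{insert}, \code{umi}, \code{status} one of "ok",
#'   "no-adapter", "umi-truncated", "too-short".
#' @export
extract_umi <- function(seq, qual = NULL, adapter, umi_len = 12L,
                        error_rate = 0.12, quality_cutoff = 15L,
                        min_length = 15L) {
  if (umi_len <= 0L) stop("invalid use: umi_len must be > 0; call trim_adapter",
                          call. = FALSE)
  tr <- trim_adapter(seq, qual, adapter, error_rate, quality_cutoff,
                     min_length = 0L, umi_mode = TRUE)
  if (tr$status == "no-adapter") {
    return(list(insert = NA_character_, umi = NA_character_,
                status = "no-adapter"))
  }
  trimmed <- tr$insert
  if (nchar(trimmed) < umi_len) {
    return(list(insert = NA_character_, umi = NA_character_,
                status = "umi-truncated"))
  }
  insert <- substr(trimmed, 1L, nchar(trimmed) - umi_len)
  umi <- substr(trimmed, nchar(trimmed) - umi_len + 1L, nchar(trimmed))
  if (nchar(insert) < min_length) {
    return(list(insert = NA_character_, umi = umi, status = "too-short"))
  }
  list(insert = insert, umi = umi, status = "ok")
}

.hamming1 <- function(a, b) {
  # both same length; TRUE iff Hamming distance is exactly 1
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  sum(av != bv) == 1L
}

#' Deduplicate UMIs by directional adjacency
#'
#' Within each insert, UMIs are clustered with the directional rule: an
#' edge connects u -> v when their Hamming distance is 1 and
#' count(u) >= 2 * count(v) - 1; the deduplicated count of the insert is
#' the number of connected clusters grown from the highest-count UMIs.
#'
#' @param inserts Character vector of insert sequences (one per read).
#' @param umis Character vector of UMIs, parallel to \code{inserts}.
#' @return Named integer vector: insert -> deduplicated count.
#' @export
dedup_umis <- function(inserts, umis) {
  stopifnot(length(inserts) == length(umis))
  if (length(unique(nchar(umis))) > 1L) {
    stop("invalid-input: mixed UMI lengths within a sample", call. = FALSE)
  }
  out <- integer(0)
  for (ins in unique(inserts)) {
    tab <- sort(table(umis[inserts == ins]), decreasing = TRUE)
    us <- names(tab); cnt <- as.integer(tab)
    k <- length(us)
    assigned <- rep(FALSE, k)
    nclust <- 0L
    for (i in seq_len(k)) {        # highest counts first (ties: name order)
      if (assigned[i]) next
      nclust <- nclust + 1L
      queue <- i; assigned[i] <- TRUE
      while (length(queue)) {
        cur <- queue[1L]; queue <- queue[-1L]
        for (j in seq_len(k)) {
          if (!assigned[j] && cnt[cur] >= 2L * cnt[j] - 1L &&
              .hamming1(us[cur], us[j])) {
            assigned[j] <- TRUE
            queue <- c(queue, j)
          }
        }
      }
    }
    out[ins] <- nclust
  }
  out
}

#' Preprocess one sample's reads to deduplicated insert counts
#'
#' Runs adapter trimming (and UMI extraction + directional deduplication
#' when \code{umi_len > 0}) over a set of FASTQ records and returns insert
#' counts plus QC counters.
#'
#' @param records data.frame(id, seq, qual) as from \code{\link{read_fastq}}
#'   or \code{\link{simulate_reads}}.
#' @param adapter 3' adapter sequence.
#' @param umi_len UMI length; 0 for UMI-less (serum-style) libraries.
#' @param error_rate,quality_cutoff,min_length As in
#'   \code{\link{trim_adapter}}.
#' @return List: \code{counts} (named integer vector, insert -> count,
#'   deduplicated when UMIs are used), \code{qc} (raw, adapter_found,
#'   retained, deduplicated, retained_fraction).
#' @export
preprocess_sample <- function(records, adapter, umi_len = 0L,
                              error_rate = 0.12, quality_cutoff = 15L,
                              min_length = 15L) {
  n <- nrow(records)
  inserts <- character(n); umis <- character(n); status <- character(n)
  for (i in seq_len(n)) {
    if (umi_len > 0L) {
      r <- extract_umi(records$seq[i], records$qual[i], adapter, umi_len,
                       error_rate, quality_cutoff, min_length)
      umis[i] <- if (is.na(r$umi)) "" else r$umi
    } else {
      r <- trim_adapter(records$seq[i], records$qual[i], adapter, error_rate,
                        quality_cutoff, min_length, umi_mode = FALSE)
    }
    inserts[i] <- if (is.na(r$insert)) "" else r$insert
    status[i] <- r$status
  }
  ok <- status == "ok"
  counts <- if (umi_len > 0L) {
    if (any(ok)) dedup_umis(inserts[ok], umis[ok]) else integer(0)
  } else {
    if (any(ok)) {
      tab <- table(inserts[ok])
      stats::setNames(as.integer(tab), names(tab))
    } else integer(0)
  }
  qc <- list(
    raw = n,
    adapter_found = sum(status != "no-adapter"),
    retained = sum(ok),
    deduplicated = sum(counts),
    retained_fraction = if (n > 0L) sum(ok) / n else NA_real_
  )
  list(counts = counts, qc = qc)
}
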