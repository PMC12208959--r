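# Taxonomic attribution of genome-unmappable not-itrs: recurrence
# filtering, exact substring search against the rDNA database (SSU and LSU
# separately), and collapsing of consecutively ranked organisms that share
# their first five taxonomy levels.

#' Filter Group-3 not-itrs by recurrence
#'
#' Keeps features supported by at least \code{min_reads} raw reads in at
#' least \code{ceiling(min_frac * n_samples)} samples.
#'
#' @param counts Raw integer matrix, features x samples.
#' @param group3_features Character vector of Group-3 feature ids (rows of
#'   \code{counts}).
#' @param min_reads Per-sample read support threshold (default 10).
#' @param min_frac Minimum fraction of samples (default 0.20).
#' @return Character vector of recurrent feature ids.
#' @export
filter_recurrent_notitrs <- function(counts, group3_features, min_reads = 10,
                                     min_frac = 0.20) {
  if (ncol(counts) == 0L) stop("invalid-input: empty sample set", call. = FALSE)
  feats <- intersect(group3_features, rownames(counts))
  need <- ceiling(min_frac * ncol(counts))
  sup <- rowSums(counts[feats, , drop = FALSE] >= min_reads)
  feats[sup >= need]
}

#' Count distinct not-itr hits per rDNA organism (exact matching)
#'
#' A feature hits an organism when its sequence is an exact substring of
#' that organism's subunit sequence; SSU and LSU are searched separately.
#'
#' @param feature_seqs Named character vector: feature id -> sequence.
#' @param rdna data.frame with columns id, taxonomy, subunit, seq (as in an
#'   \code{snc_bundle}).
#' @param subunit "SSU" or "LSU".
#' @return data.frame: organism, taxonomy, hits (distinct features),
#'   restricted to organisms with at least one hit.
#' @export
match_rdna <- function(feature_seqs, rdna, subunit = c("SSU", "LSU")) {
  subunit <- match.arg(subunit)
  if (any(!nzchar(rdna$taxonomy)) || any(is.na(rdna$taxonomy))) {
    stop("parse error: malformed taxonomy header for record ",
         rdna$id[which(!nzchar(rdna$taxonomy) | is.na(rdna$taxonomy))[1L]],
         call. = FALSE)
  }
  db <- rdna[rdna$subunit == subunit, , drop = FALSE]
  hits <- vapply(seq_len(nrow(db)), function(i) {
    sum(vapply(feature_seqs, function(s) grepl(s, db$seq[i], fixed = TRUE),
               logical(1)))
  }, integer(1))
  out <- data.frame(organism = db$id, taxonomy = db$taxonomy, hits = hits,
                    stringsAsFactors = FALSE)
  out[out$hits > 0L, , drop = FALSE]
}

.tax_levels <- function(taxonomy, n = 5L) {
  parts <- strsplit(taxonomy, ";", fixed = TRUE)
  t(vapply(parts, function(p) {
    if (length(p) < n) {
      warning("taxonomy with fewer than ", n, " levels; padded")
      p <- c(p, rep("unclassified", n - length(p)))
    }
    p[seq_len(n)]
  }, character(n)))
}

#' Collapse consecutively ranked organisms into taxonomy groups
#'
#' Organisms are ranked by decreasing distinct-hit count (ties broken
#' lexicographically by organism id for determinism); adjacent organisms in
#' the ranking that agree on their first \code{levels} taxonomy labels are
#' merged into one group.  The group's representative is its
#' highest-support member; by construction group supports are
#' non-increasing down the ranked list.
#'
#' @param org_counts data.frame from \code{\link{match_rdna}}.
#' @param levels Number of leading taxonomy levels compared (default 5).
#' @return data.frame: rank, n_organisms, level1..level5, representative,
#'   support, members (comma-joined).
#' @export
group_taxa <- function(org_counts, levels = 5L) {
  if (!nrow(org_counts)) {
    return(data.frame(rank = integer(0), n_organisms = integer(0)))
  }
  stopifnot(all(org_counts$hits > 0L))
  ord <- order(-org_counts$hits, org_counts$organism)
  oc <- org_counts[ord, , drop = FALSE]
  lv <- .tax_levels(oc$taxonomy, levels)
  key <- apply(lv, 1L, paste, collapse = ";")
  grp <- cumsum(c(TRUE, key[-1L] != key[-length(key)]))
  out <- do.call(rbind, lapply(split(seq_along(grp), grp), function(idx) {
    rep_i <- idx[1L]     # ranked first = maximal support (ties: id order)
    data.frame(
      n_organisms = length(idx),
      level1 = lv[rep_i, 1L], level2 = lv[rep_i, 2L], level3 = lv[rep_i, 3L],
      level4 = lv[rep_i, 4L], level5 = lv[rep_i, 5L],
      representative = oc$organism[rep_i], support = oc$hits[rep_i],
      members = paste(oc$organism[idx], collapse = ","),
      stringsAsFactors = FALSE)
  }))
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
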