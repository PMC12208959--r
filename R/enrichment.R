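# Presence/absence enrichment between cohorts via the two-sided Fisher
# exact test on per-feature 2x2 presence tables.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The p-value is the sum of hypergeometric probabilities (margins fixed)
#' of all tables at most as probable as the observed one, within relative
#' tolerance 1e-7.  The odds ratio is the cross-product \eqn{ad/bc}; 0.5 is
#' added to every cell only when some cell is zero (Haldane-Anscombe), so
#' extreme tables still report a finite odds ratio.
#'
#' @param a,b,c,d Non-negative integers: (group1-present, group1-absent,
#'   group2-present, group2-absent).
#' @return List with \code{odds_ratio} and \code{p}.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("invalid-input: cells must be non-negative integers", call. = FALSE)
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0L || r2 == 0L || c1 == 0L || c2 == 0L) {
    stop("degenerate-table: a margin is zero", call. = FALSE)
  }
  xs <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  obs <- stats::dhyper(a, r1, r2, c1)
  p <- min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  or <- if (any(cells == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  list(odds_ratio = or, p = p)
}

#' Presence/absence enrichment screen between two groups
#'
#' A feature is "present" in a sample when its raw count is above zero.
#' Features whose mean raw count across all compared samples is below
#' \code{min_mean_raw} are excluded before testing; the rest get a
#' two-sided Fisher test on the (present, absent) x (group1, group2)
#' table, BH adjustment within each class, and a kept flag at
#' \code{fdr_max}.  Tables with a zero margin (e.g. a feature present in
#' every sample) are uninformative and report p = 1 with the
#' Haldane-Anscombe odds ratio.
#'
#' @param counts Raw integer matrix, features x samples.
#' @param groups Two-level factor/character over samples (reference level
#'   first; "enriched_in" names the group with the higher presence odds).
#' @param min_mean_raw Inclusion threshold on the raw mean (default 1).
#' @param fdr_max FDR threshold for the kept flag (default 1e-9).
#' @param classes Optional per-feature classes for per-class BH.
#' @return data.frame: feature, class, a, b, c, d, odds_ratio, p, fdr,
#'   enriched_in, kept.
#' @export
presence_enrichment <- function(counts, groups, min_mean_raw = 1,
                                fdr_max = 1e-9, classes = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L || any(table(groups) == 0L)) {
    stop("invalid-design: need two non-empty groups", call. = FALSE)
  }
  if (is.null(classes)) classes <- rep("all", nrow(counts))
  keep <- rowMeans(counts) >= min_mean_raw
  counts <- counts[keep, , drop = FALSE]
  cls <- classes[keep]
  g1 <- groups == levels(groups)[1L]
  pres <- counts > 0
  a <- rowSums(pres[, g1, drop = FALSE])
  b <- sum(g1) - a
  cc <- rowSums(pres[, !g1, drop = FALSE])
  dd <- sum(!g1) - cc
  res <- lapply(seq_along(a), function(i) {
    if ((a[i] + cc[i]) == 0L || (b[i] + dd[i]) == 0L) {
      or <- ((a[i] + 0.5) * (dd[i] + 0.5)) / ((b[i] + 0.5) * (cc[i] + 0.5))
      list(odds_ratio = or, p = 1)
    } else {
      fisher_exact_2x2(a[i], b[i], cc[i], dd[i])
    }
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  or <- vapply(res, `[[`, numeric(1), "odds_ratio")
  fdr <- stats::ave(p, cls, FUN = function(x) stats::p.adjust(x, "BH"))
  # odds of presence: OR < 1 means higher presence odds in group2
  data.frame(
    feature = rownames(counts), class = cls,
    a = a, b = b, c = cc, d = dd, odds_ratio = or, p = p, fdr = fdr,
    enriched_in = ifelse(or < 1, levels(groups)[2L], levels(groups)[1L]),
    kept = fdr <= fdr_max,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
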