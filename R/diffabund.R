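# Differential abundance: median-of-ratios size factors, a per-feature
# negative-binomial Wald test (method-of-moments dispersion), and the
# filter ledger (|log2FC| >= 0.4, FDR <= 0.05, normalized mean >= 5).

#' Median-of-ratios size factors
#'
#' For each sample j, \eqn{s_j} is the median over features (restricted to
#' features with nonzero counts in every sample) of the ratio of the count
#' to the feature's geometric mean across samples.
#'
#' @param counts Integer matrix, features x samples.
#' @return Numeric vector of positive per-sample size factors.
#' @export
size_factors <- function(counts) {
  if (ncol(counts) < 2L) stop("invalid-input: need >= 2 samples", call. = FALSE)
  ok <- rowSums(counts == 0) == 0L
  if (!any(ok)) stop("normalization-failure: no feature is nonzero in all samples",
                     call. = FALSE)
  lg <- log(counts[ok, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2L, stats::median)
  stats::setNames(sf, colnames(counts))
}

#' Normalize counts by size factors
#' @param counts Integer matrix, features x samples.
#' @param sf Size factors (default: computed from \code{counts}).
#' @return Numeric matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  sweep(counts, 2L, sf, "/")
}

#' Normalize each class as its own dataset
#'
#' Computes median-of-ratios size factors from each class's features alone
#' and normalizes that class's rows with them.  Sample-level shifts in
#' class composition (an isomiR-rich sample versus a not-itr-rich one) are
#' absorbed into the per-class factors instead of contaminating per-feature
#' abundance.  Classes without an all-samples-nonzero feature fall back to
#' total-count factors.
#'
#' @param counts Integer matrix, features x samples.
#' @param classes Per-feature class labels.
#' @return Numeric matrix of normalized counts.
#' @export
normalize_per_class <- function(counts, classes) {
  stopifnot(length(classes) == nrow(counts))
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (cl in unique(classes)) {
    sel <- classes == cl
    sub <- counts[sel, , drop = FALSE]
    sf <- tryCatch(size_factors(sub), error = function(e) {
      tot <- colSums(sub)
      tot / exp(mean(log(tot)))
    })
    out[sel, ] <- sweep(sub, 2L, sf, "/")
  }
  out
}

#' Per-feature negative-binomial Wald test between two groups
#'
#' Features failing the raw-median prefilter (median raw count below
#' \code{min_median} in both groups) are dropped before testing.  For the
#' rest, group means are fitted on the normalized scale; the per-feature NB
#' dispersion is estimated by method of moments (floored at 1e-8) and the
#' per-group variance of the log mean follows by the delta method, using
#' each group's own empirical variance (floored at the Poisson variance) so
#' unequal group variability is respected.  The Wald statistic is
#' log2FC / se with a two-sided normal reference; BH adjustment is applied
#' within each class.
#'
#' @param counts Integer matrix, features x samples.
#' @param groups Two-level factor/character vector over samples; log2FC is
#'   the second level versus the first.
#' @param sf Size factors (default: computed from \code{counts}).
#' @param min_median Raw-median prefilter threshold (default 5).
#' @param classes Optional per-feature class labels for per-class BH; a
#'   single class when NULL.
#' @param per_class_sf Analyze each class as its own dataset, with size
#'   factors computed from that class's features alone (default when
#'   \code{classes} is given).  Mirrors running the DE analysis separately
#'   per class and makes the test robust to sample-level shifts in class
#'   composition, which would otherwise masquerade as fold changes across
#'   a whole class.
#' @return data.frame: feature, class, base_mean, log2fc, se, wald_stat, p,
#'   fdr, median_ref, median_alt, dispersion.
#' @export
nb_wald_test <- function(counts, groups, sf = NULL,
                         min_median = 5, classes = NULL,
                         per_class_sf = !is.null(classes)) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("invalid-design: need exactly two groups",
                                  call. = FALSE)
  if (any(table(groups) < 2L)) stop("invalid-design: a group has < 2 samples",
                                    call. = FALSE)
  if (is.null(classes)) classes <- rep("all", nrow(counts))
  if (per_class_sf && length(unique(classes)) > 1L) {
    out <- do.call(rbind, lapply(unique(classes), function(cl) {
      sel <- classes == cl
      nb_wald_test(counts[sel, , drop = FALSE], groups, sf = NULL,
                   min_median = min_median, classes = classes[sel],
                   per_class_sf = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }
  if (is.null(sf)) {
    sf <- tryCatch(size_factors(counts), error = function(e) {
      # degenerate class (no all-nonzero feature): fall back to totals
      tot <- colSums(counts)
      tot / exp(mean(log(tot)))
    })
  }
  g1 <- groups == levels(groups)[1L]
  g2 <- !g1
  med1 <- apply(counts[, g1, drop = FALSE], 1L, stats::median)
  med2 <- apply(counts[, g2, drop = FALSE], 1L, stats::median)
  keep <- med1 >= min_median | med2 >= min_median
  if (!any(keep)) {
    return(data.frame(feature = character(0), class = character(0),
                      base_mean = numeric(0), log2fc = numeric(0),
                      se = numeric(0), wald_stat = numeric(0), p = numeric(0),
                      fdr = numeric(0), median_ref = numeric(0),
                      median_alt = numeric(0), dispersion = numeric(0)))
  }
  y <- normalize_counts(counts, sf)[keep, , drop = FALSE]
  cls <- classes[keep]
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(y[, g1, drop = FALSE]); v1 <- apply(y[, g1, drop = FALSE], 1L, stats::var)
  m2 <- rowMeans(y[, g2, drop = FALSE]); v2 <- apply(y[, g2, drop = FALSE], 1L, stats::var)
  base_mean <- rowMeans(y)
  # method-of-moments dispersion (pooled within-group), floored
  vw <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  disp <- pmax((vw - base_mean) / base_mean^2, 1e-8)
  c0 <- 0.1                     # small stabilizer against zero group means
  log2fc <- log2((m2 + c0) / (m1 + c0))
  v1e <- pmax(v1, m1 + 1e-8); v2e <- pmax(v2, m2 + 1e-8)
  var_ln <- v1e / (n1 * (m1 + c0)^2) + v2e / (n2 * (m2 + c0)^2)
  se <- sqrt(var_ln) / log(2)
  z <- log2fc / se
  p <- 2 * stats::pnorm(-abs(z))
  fdr <- stats::ave(p, cls, FUN = function(x) stats::p.adjust(x, "BH"))
  data.frame(
    feature = rownames(counts)[keep], class = cls, base_mean = base_mean,
    log2fc = log2fc, se = se, wald_stat = z, p = p, fdr = fdr,
    median_ref = med1[keep], median_alt = med2[keep], dispersion = disp,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Apply the differential-abundance filter ledger
#'
#' Keeps results with |log2FC| at or above \code{lfc_min}, FDR at or below
#' \code{fdr_max}, and a normalized base mean of at least \code{mean_min};
#' the direction of change is retained as "up"/"down".
#'
#' @param results data.frame from \code{\link{nb_wald_test}}.
#' @param lfc_min,fdr_max,mean_min Filter thresholds (defaults 0.4, 0.05, 5).
#' @return The filtered data.frame with an added \code{direction} column.
#' @export
apply_de_filters <- function(results, lfc_min = 0.4, fdr_max = 0.05,
                             mean_min = 5) {
  keep <- abs(results$log2fc) >= lfc_min & results$fdr <= fdr_max &
    results$base_mean >= mean_min
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}
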