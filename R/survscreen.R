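# Survival screening: Kaplan-Meier product-limit curves with a two-group
# log-rank test, a Cox proportional-hazards fitter (Efron tie handling,
# damped Newton on the partial likelihood), and the per-feature screen over
# endpoints, Riluzole strata and covariate sets.

#' Kaplan-Meier estimate and two-group log-rank test
#'
#' Product-limit survival curves per group; when exactly two groups are
#' given, the standard log-rank chi-square (1 df) is computed.  If no
#' events occur the log-rank statistic is undefined and flagged.
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @param group Group labels (1 or 2 levels).
#' @return List: \code{curves} data.frame(group, time, n_risk, n_event,
#'   surv), \code{logrank_stat}, \code{logrank_p}, \code{all_censored}.
#' @export
km_estimate <- function(times, events, group = rep("all", length(times))) {
  stopifnot(length(times) == length(events), length(group) == length(times))
  if (any(times <= 0)) stop("invalid-input: times must be > 0", call. = FALSE)
  group <- as.factor(group)
  if (any(table(group) == 0L) || nlevels(group) < 1L) {
    stop("invalid-split: empty group", call. = FALSE)
  }
  curves <- do.call(rbind, lapply(levels(group), function(gl) {
    t <- times[group == gl]; e <- events[group == gl]
    ut <- sort(unique(t[e == 1]))
    if (!length(ut)) {
      return(data.frame(group = character(0), time = numeric(0),
                        n_risk = integer(0), n_event = integer(0),
                        surv = numeric(0)))
    }
    n_risk <- vapply(ut, function(u) sum(t >= u), integer(1))
    n_event <- vapply(ut, function(u) sum(t == u & e == 1), integer(1))
    data.frame(group = gl, time = ut, n_risk = n_risk, n_event = n_event,
               surv = cumprod(1 - n_event / n_risk),
               stringsAsFactors = FALSE)
  }))
  all_cens <- sum(events) == 0L
  lr_stat <- NA_real_; lr_p <- NA_real_
  if (!all_cens && nlevels(group) == 2L) {
    ut <- sort(unique(times[events == 1]))
    g1 <- group == levels(group)[1L]
    OmE <- 0; V <- 0
    for (u in ut) {
      at <- times >= u
      n <- sum(at); n1 <- sum(at & g1)
      d <- sum(times == u & events == 1)
      d1 <- sum(times == u & events == 1 & g1)
      OmE <- OmE + d1 - d * n1 / n
      if (n > 1L) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    if (V > 0) {
      lr_stat <- OmE^2 / V
      lr_p <- stats::pchisq(lr_stat, df = 1L, lower.tail = FALSE)
    }
  }
  list(curves = curves, logrank_stat = lr_stat, logrank_p = lr_p,
       all_censored = all_cens)
}

# Efron-corrected partial log-likelihood, gradient and information at beta
.cox_efron <- function(X, times, events, beta) {
  n <- nrow(X); p <- ncol(X)
  ord <- order(times)
  X <- X[ord, , drop = FALSE]; times <- times[ord]; events <- events[ord]
  eta <- drop(X %*% beta)
  w <- exp(eta)
  # reverse cumulative sums give risk-set aggregates at each index
  S0 <- rev(cumsum(rev(w)))
  S1 <- apply(X * w, 2L, function(col) rev(cumsum(rev(col))))
  S1 <- matrix(S1, nrow = n)
  S2 <- array(0, dim = c(n, p, p))
  for (a in seq_len(p)) for (b in a:p) {
    v <- rev(cumsum(rev(w * X[, a] * X[, b])))
    S2[, a, b] <- v; S2[, b, a] <- v
  }
  ll <- 0; grad <- numeric(p); info <- matrix(0, p, p)
  ev_times <- unique(times[events == 1])
  for (u in ev_times) {
    first <- match(TRUE, times >= u)        # risk-set anchor
    D <- which(times == u & events == 1)
    d <- length(D)
    s0D <- sum(w[D])
    s1D <- colSums(X[D, , drop = FALSE] * w[D])
    s2D <- matrix(0, p, p)
    for (i in D) s2D <- s2D + w[i] * tcrossprod(X[i, ])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1L) {
      f <- l / d
      phi0 <- S0[first] - f * s0D
      phi1 <- S1[first, ] - f * s1D
      phi2 <- S2[first, , ] - f * s2D
      m <- phi1 / phi0
      ll <- ll - log(phi0)
      grad <- grad - m
      info <- info + phi2 / phi0 - tcrossprod(m)
    }
    grad <- grad + colSums(X[D, , drop = FALSE])
  }
  list(ll = ll, grad = grad, info = info)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Efron-tie-corrected partial likelihood by damped Newton
#' iterations to gradient norm below 1e-8.  Reports per-coefficient Wald
#' p-values, the global likelihood-ratio and Wald tests against the null
#' model, and the score test at the null (which, for a single binary
#' covariate without ties, equals the log-rank statistic).
#'
#' @param X Numeric covariate matrix (n x p), no constant column.
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @param max_iter Newton iteration cap (default 100).
#' @return List: coef, se, hr, p_coef, loglik, loglik_null, lrt_stat,
#'   p_lrt, wald_global, p_wald_global, score_stat, p_score, iterations,
#'   converged, unstable.
#' @export
cox_fit <- function(X, times, events, max_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n != length(times) || n != length(events)) {
    stop("invalid-input: dimension mismatch", call. = FALSE)
  }
  if (n <= p) stop("invalid-input: need n > number of covariates", call. = FALSE)
  if (any(apply(X, 2L, function(col) stats::sd(col) == 0))) {
    stop("invalid-input: constant covariate", call. = FALSE)
  }
  if (sum(events) == 0L) stop("invalid-input: no events", call. = FALSE)
  beta <- numeric(p)
  e0 <- .cox_efron(X, times, events, beta)
  ll_null <- e0$ll
  score_stat <- drop(t(e0$grad) %*% solve(e0$info, e0$grad))
  cur <- e0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (sqrt(sum(cur$grad^2)) < 1e-8) { converged <- TRUE; break }
    step <- solve(cur$info, cur$grad)
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      nxt <- .cox_efron(X, times, events, cand)
      if (nxt$ll >= cur$ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- cand; cur <- nxt
  }
  if (!converged && sqrt(sum(cur$grad^2)) >= 1e-6) {
    stop("convergence error: Newton iterations did not converge", call. = FALSE)
  }
  V <- solve(cur$info)
  se <- sqrt(diag(V))
  z <- beta / se
  lrt <- 2 * (cur$ll - ll_null)
  wald_g <- drop(t(beta) %*% cur$info %*% beta)
  list(
    coef = beta, se = se, hr = exp(beta),
    p_coef = 2 * stats::pnorm(-abs(z)),
    loglik = cur$ll, loglik_null = ll_null,
    lrt_stat = lrt, p_lrt = stats::pchisq(lrt, p, lower.tail = FALSE),
    wald_global = wald_g,
    p_wald_global = stats::pchisq(wald_g, p, lower.tail = FALSE),
    score_stat = score_stat,
    p_score = stats::pchisq(score_stat, p, lower.tail = FALSE),
    iterations = iter, converged = converged,
    unstable = any(abs(beta) > 15)
  )
}

.screen_required_cols <- c("sample_id", "patient_id", "group", "riluzole",
                           "sex", "age_at_onset", "age_at_enrollment",
                           "rD50", "ALSFRS", "onset_type",
                           "time_to_death_from_enrollment",
                           "time_to_death_from_onset", "event", "timepoint")

#' Screen features for association with survival
#'
#' For each feature passing the abundance prefilters (raw median and
#' normalized mean as in the differential-abundance stage), and for each
#' endpoint x Riluzole stratum x covariate set, fits a Cox model with the
#' feature's abundance coded as log2(normalized count + 1) plus the
#' covariate set ("univariate" none; "demographics" adds age at onset, age
#' at enrollment, sex; "demographics+disease" further adds rD50, ALSFRS,
#' onset type), and a mean-split Kaplan-Meier log-rank test.  Only
#' patients' first samples are used (one per patient).  A feature is kept
#' when the abundance coefficient's p-value and either the global LRT or
#' global Wald p-value are at or below \code{p_max}.
#'
#' @param counts Raw integer matrix, features x samples.
#' @param meta Sample metadata with the cohort schema columns.
#' @param settings Optional list: endpoints, strata, covariate_sets,
#'   min_median (5), mean_min (5), p_max (0.05).
#' @param classes Optional per-feature class labels; abundance is then
#'   normalized per class (see \code{\link{normalize_per_class}}) so
#'   sample-level composition shifts do not correlate whole classes with
#'   survival.
#' @return data.frame with one row per feature x endpoint x stratum x
#'   covariate set; strata that cannot be analyzed are skipped with a
#'   warning.
#' @export
survival_screen <- function(counts, meta, settings = list(), classes = NULL) {
  s <- utils::modifyList(list(
    endpoints = c("from-enrollment", "from-onset"),
    strata = c("both", "+", "-"),
    covariate_sets = c("univariate", "demographics", "demographics+disease"),
    min_median = 5, mean_min = 5, p_max = 0.05
  ), settings)
  missing_cols <- setdiff(.screen_required_cols, names(meta))
  if (length(missing_cols)) {
    stop("schema error: missing metadata columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  first <- meta$group == "ALS" & meta$timepoint %in% c("T1", "none") &
    !duplicated(meta$patient_id)
  meta <- meta[first, , drop = FALSE]
  counts <- counts[, meta$sample_id, drop = FALSE]
  y <- if (is.null(classes)) normalize_counts(counts, size_factors(counts))
       else normalize_per_class(counts, classes)
  med <- apply(counts, 1L, stats::median)
  keep <- med >= s$min_median & rowMeans(y) >= s$mean_min
  feats <- rownames(counts)[keep]
  endpoint_col <- c(`from-enrollment` = "time_to_death_from_enrollment",
                    `from-onset` = "time_to_death_from_onset")
  rows <- list()
  for (st in s$strata) {
    in_st <- if (st == "both") rep(TRUE, nrow(meta)) else meta$riluzole == st
    if (sum(in_st) < 5L || sum(meta$event[in_st], na.rm = TRUE) < 2L) {
      warning("stratum '", st, "' has too few patients or events; skipped")
      next
    }
    m_st <- meta[in_st, , drop = FALSE]
    demo <- cbind(age_at_onset = m_st$age_at_onset,
                  age_at_enrollment = m_st$age_at_enrollment,
                  sex = as.numeric(m_st$sex == "M"))
    disease <- cbind(rD50 = m_st$rD50, ALSFRS = m_st$ALSFRS,
                     onset = as.numeric(m_st$onset_type == "bulbar"))
    for (ep in s$endpoints) {
      tt <- m_st[[endpoint_col[[ep]]]]
      ev <- m_st$event
      for (f in feats) {
        ab <- log2(y[f, m_st$sample_id] + 1)
        split_hi <- ab > mean(ab)
        km_p <- if (length(unique(split_hi)) == 2L) {
          km_estimate(tt, ev, ifelse(split_hi, "high", "low"))$logrank_p
        } else NA_real_
        for (cs in s$covariate_sets) {
          Xc <- switch(cs,
            univariate = cbind(abundance = ab),
            demographics = cbind(abundance = ab, demo),
            `demographics+disease` = cbind(abundance = ab, demo, disease))
          fit <- tryCatch(cox_fit(Xc, tt, ev), error = function(e) NULL)
          if (is.null(fit)) {
            rows[[length(rows) + 1L]] <- data.frame(
              feature = f, endpoint = ep, stratum = st, covariate_set = cs,
              coef = NA_real_, hr = NA_real_, se = NA_real_,
              p_coef = NA_real_, p_lrt = NA_real_, p_wald = NA_real_,
              km_logrank_p = km_p, kept = FALSE, stringsAsFactors = FALSE)
            next
          }
          kept <- fit$p_coef[1L] <= s$p_max &&
            (fit$p_lrt <= s$p_max || fit$p_wald_global <= s$p_max)
          rows[[length(rows) + 1L]] <- data.frame(
            feature = f, endpoint = ep, stratum = st, covariate_set = cs,
            coef = fit$coef[1L], hr = fit$hr[1L], se = fit$se[1L],
            p_coef = fit$p_coef[1L], p_lrt = fit$p_lrt,
            p_wald = fit$p_wald_global, km_logrank_p = km_p, kept = kept,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(out) <- NULL
  out
}
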