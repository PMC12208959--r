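# Longitudinal analysis: per-feature T1 -> T4 direction calls by majority
# vote across patients, and Fisher sign-concordance against the
# differential-abundance and survival-screen result sets.

#' Per-feature T1 vs T4 direction calls
#'
#' For each feature, compares the T4 and T1 normalized abundance per
#' longitudinal patient.  Patients where the feature is zero at both
#' timepoints are not considered; equal values count as ties and never
#' toward the majority.  The call is "up" when more considered patients
#' increased than decreased, "down" in the opposite case, and "none" on a
#' tie or when no patient is considered.
#'
#' @param norm_counts Normalized count matrix, features x samples.
#' @param meta Sample metadata with patient_id and timepoint columns; every
#'   longitudinal patient must have both a T1 and a T4 sample.
#' @return data.frame: feature, n_up, n_down, n_tie, call.
#' @export
direction_calls <- function(norm_counts, meta) {
  t1 <- meta[meta$timepoint == "T1", ]
  t4 <- meta[meta$timepoint == "T4", ]
  pats <- intersect(t1$patient_id, t4$patient_id)
  if (!length(pats)) stop("pairing error: no patients with both T1 and T4",
                          call. = FALSE)
  if (length(setdiff(union(t1$patient_id, t4$patient_id), pats))) {
    stop("pairing error: unpaired longitudinal patient", call. = FALSE)
  }
  s1 <- t1$sample_id[match(pats, t1$patient_id)]
  s4 <- t4$sample_id[match(pats, t4$patient_id)]
  a1 <- norm_counts[, s1, drop = FALSE]
  a4 <- norm_counts[, s4, drop = FALSE]
  considered <- a1 > 0 | a4 > 0
  up <- rowSums((a4 > a1) & considered)
  down <- rowSums((a4 < a1) & considered)
  tie <- rowSums((a4 == a1) & considered)
  data.frame(
    feature = rownames(norm_counts), n_up = up, n_down = down, n_tie = tie,
    call = ifelse(up > down, "up", ifelse(down > up, "down", "none")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.concordance_fisher <- function(a, b, c, d) {
  if ((a + b) == 0L || (c + d) == 0L || (a + c) == 0L || (b + d) == 0L) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    list(odds_ratio = or, p = 1)
  } else {
    fisher_exact_2x2(a, b, c, d)
  }
}

#' Sign-concordance tables between longitudinal calls and result sets
#'
#' Differential-abundance mode (\code{de} given): over features that are
#' significant in the DE set and have a longitudinal call of up or down,
#' cross-tabulates the DE direction against the longitudinal call; an odds
#' ratio above 1 means the signs agree more often than chance.  Survival
#' mode (\code{kept_features} given): cross-tabulates survival-set
#' membership against whether the feature changed (call up-or-down vs
#' none).  Both modes are computed pooled and per class.
#'
#' @param calls data.frame from \code{\link{direction_calls}}.
#' @param de Optional filtered DE results (needs feature, direction).
#' @param kept_features Optional character vector of survival-kept feature
#'   ids.
#' @param classes Named character vector feature -> class (for per-class
#'   scope).
#' @return data.frame: mode, scope, class, a, b, c, d, odds_ratio, p.
#' @export
concordance_tables <- function(calls, de = NULL, kept_features = NULL,
                               classes = NULL) {
  if (is.null(classes)) {
    classes <- stats::setNames(rep("all", nrow(calls)), calls$feature)
  }
  scopes <- c("pooled", unique(unname(classes[calls$feature])))
  rows <- list()
  add_row <- function(mode, scope, cls, a, b, c, d) {
    f <- .concordance_fisher(a, b, c, d)
    rows[[length(rows) + 1L]] <<- data.frame(
      mode = mode, scope = scope, class = cls, a = a, b = b, c = c, d = d,
      odds_ratio = f$odds_ratio, p = f$p, stringsAsFactors = FALSE)
  }
  if (!is.null(de)) {
    m <- merge(calls, de[, c("feature", "direction")], by = "feature")
    m <- m[m$call != "none", ]
    if (!nrow(m)) warning("empty-result: no DE features with a direction call")
    m$class <- unname(classes[m$feature])
    for (sc in scopes) {
      d0 <- if (sc == "pooled") m else m[m$class == sc, ]
      add_row("de-sign", if (sc == "pooled") "pooled" else "per-class",
              sc,
              sum(d0$direction == "up" & d0$call == "up"),
              sum(d0$direction == "up" & d0$call == "down"),
              sum(d0$direction == "down" & d0$call == "up"),
              sum(d0$direction == "down" & d0$call == "down"))
    }
  }
  if (!is.null(kept_features)) {
    calls$kept <- calls$feature %in% kept_features
    calls$changed <- calls$call != "none"
    calls$class <- unname(classes[calls$feature])
    for (sc in scopes) {
      d0 <- if (sc == "pooled") calls else calls[calls$class == sc, ]
      add_row("survival-membership",
              if (sc == "pooled") "pooled" else "per-class", sc,
              sum(d0$kept & d0$changed), sum(d0$kept & !d0$changed),
              sum(!d0$kept & d0$changed), sum(!d0$kept & !d0$changed))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
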