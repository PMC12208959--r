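# Cohort simulator with planted truth: negative-binomial counts with a
# per-sample composition dichotomy (isomiR-rich vs not-itr-rich), planted
# group fold changes, presence/absence enrichment, survival hazards tied to
# a latent disease-aggressiveness factor, and longitudinal drift.

#' Default cohort design
#'
#' The defaults define the study conditions every downstream stage is
#' exercised under: 30 controls + 30 patients, 2000 features, 10% planted
#' differential-abundance features at |log2FC| = 1, NB dispersion 0.1,
#' 8 longitudinal patients with four timepoints, 30 hazard-linked features.
#'
#' @return A list of design parameters; override any subset via the
#'   \code{design} argument of \code{\link{simulate_cohort}}.
#' @export
default_cohort_design <- function() {
  list(
    n_control = 30L, n_patient = 30L, n_features = 2000L,
    n_longitudinal = 8L,
    class_probs = c(isomiR = 0.35, tRF = 0.10, rRF = 0.15, yRF = 0.05,
                    notitr = 0.35),
    # composition regimes: relative class weights per regime; per-sample
    # weights are Dirichlet-jittered around the regime's weights
    regime_weights = list(
      `isomiR-rich` = c(isomiR = 0.45, tRF = 0.12, rRF = 0.12, yRF = 0.06,
                        notitr = 0.25),
      `notitr-rich` = c(isomiR = 0.18, tRF = 0.12, rRF = 0.12, yRF = 0.06,
                        notitr = 0.52)),
    regime_conc = 300,          # Dirichlet concentration (higher = less noise)
    p_isomir_rich = 0.5,
    mean_log = log(40), mean_sdlog = 1.0,   # lognormal base means
    libsize_sdlog = 0.25,
    dispersion = 0.1,           # NB: var = mu + dispersion * mu^2
    frac_de = 0.10, lfc_de = 1.0,
    n_enriched = 10L, enrich_presence = c(control = 0.05, patient = 0.95),
    n_hazard = 30L, hazard_link = 0.7, hazard_strength = 0.9,
    base_median_survival = 30,  # months
    censor_time = 60,           # administrative cutoff, months
    drift_mode = "concordant",  # "concordant", "independent", "none"
    drift_frac_de = 0.8, drift_lfc = 1.0, n_drift_background = 100L,
    with_sequences = FALSE, notitr_g3_frac = 0.3
  )
}

.rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

.draw_class_sequence <- function(class, bundle, used) {
  seqs <- bundle_sequences(bundle)
  g <- bundle$genome
  repeat {
    s <- switch(class,
      isomiR = {
        i <- sample.int(length(seqs$mature5p), 1L)
        arm <- sample(c("mature5p", "mature3p"), 1L)
        m <- seqs[[arm]][[i]]
        d3 <- sample(-3:0, 1L)
        substr(m, 1L, nchar(m) + d3)
      },
      tRF = {
        sp <- seqs$trna_space[[sample.int(length(seqs$trna_space), 1L)]]
        len <- sample(16:30, 1L)
        if (stats::runif(1) < 0.5) substr(sp, 1L, len)
        else substr(sp, nchar(sp) - len + 1L, nchar(sp))
      },
      rRF = {
        r <- seqs$rrna[[sample.int(length(seqs$rrna), 1L)]]
        len <- sample(16:30, 1L); st <- sample.int(nchar(r) - len, 1L)
        substr(r, st, st + len - 1L)
      },
      yRF = {
        y <- seqs$yrna[[sample.int(length(seqs$yrna), 1L)]]
        len <- sample(16:30, 1L); st <- sample.int(nchar(y) - len, 1L)
        substr(y, st, st + len - 1L)
      },
      notitr = {
        len <- sample(16:30, 1L); st <- sample.int(nchar(g) - len, 1L)
        substr(g, st, st + len - 1L)
      })
    if (!(s %in% used) && nchar(s) >= 15L) return(s)
  }
}

#' Simulate a two-group cohort with planted truth
#'
#' Draws per-feature negative-binomial counts (variance
#' \eqn{\mu + \alpha\mu^2}) under a per-sample composition regime
#' (isomiR-rich or not-itr-rich Dirichlet class weights), plants group
#' log2 fold changes on a fraction of features, presence/absence enrichment
#' on a few, survival hazards through a patient-level latent
#' disease-aggressiveness factor that both shifts the abundance of
#' hazard-linked features and scales an exponential death hazard
#' (administratively censored), and monotone longitudinal drift across four
#' timepoints for a patient subset.
#'
#' @param bundle Optional \code{snc_bundle}; required only when
#'   \code{design$with_sequences} is TRUE (features then carry real
#'   sequences and plate ids drawn from the bundle).
#' @param design List overriding \code{\link{default_cohort_design}}.
#' @param seed Integer seed.
#' @return A list with \code{counts} (integer matrix, features x samples),
#'   \code{meta} (per-sample clinical table), and \code{truth} (per-feature
#'   planted effects and the per-sample regime).
#' @export
simulate_cohort <- function(bundle = NULL, design = list(), seed = 1L) {
  d <- utils::modifyList(default_cohort_design(), design)
  if (d$n_longitudinal > d$n_patient) {
    stop("invalid-design: n_longitudinal exceeds n_patient", call. = FALSE)
  }
  with_seed(seed, {
    nf <- d$n_features
    classes <- sample(names(d$class_probs), nf, replace = TRUE,
                      prob = d$class_probs)
    if (isTRUE(d$with_sequences)) {
      if (is.null(bundle)) stop("invalid-design: with_sequences needs a bundle",
                                call. = FALSE)
      used <- character(0)
      seqs <- character(nf)
      for (i in seq_len(nf)) {
        seqs[i] <- if (classes[i] == "notitr" &&
                       stats::runif(1) < d$notitr_g3_frac) {
          # non-host rDNA fragment: a Group-3 not-itr by construction
          repeat {
            s <- .draw_rdna_fragments_impl(bundle, 1L)
            if (!(s %in% used)) break
          }
          s
        } else {
          .draw_class_sequence(classes[i], bundle, used)
        }
        used <- c(used, seqs[i])
      }
      prefix <- c(isomiR = "iso", tRF = "tRF", rRF = "rRF", yRF = "yRF",
                  notitr = "na")[classes]
      ids <- plate_encode(seqs, unname(prefix))
    } else {
      seqs <- rep(NA_character_, nf)
      ids <- sprintf("%s_%04d", classes, seq_len(nf))
    }

    base_mean <- pmin(stats::rlnorm(nf, d$mean_log, d$mean_sdlog), 2e4)
    de_idx <- sort(sample.int(nf, round(d$frac_de * nf)))
    lfc <- numeric(nf)
    lfc[de_idx] <- sample(c(-1, 1), length(de_idx), TRUE) * d$lfc_de
    enr_pool <- setdiff(seq_len(nf), de_idx)
    enr_idx <- sort(sample(enr_pool, min(d$n_enriched, length(enr_pool))))
    hz_pool <- setdiff(which(base_mean >= 20), c(enr_idx))
    hz_idx <- sort(sample(hz_pool, min(d$n_hazard, length(hz_pool))))
    hz_sign <- numeric(nf)
    hz_sign[hz_idx] <- sample(c(-1, 1), length(hz_idx), TRUE)

    drift_sign <- numeric(nf)
    if (d$drift_mode == "concordant") {
      cand <- de_idx[stats::runif(length(de_idx)) < d$drift_frac_de]
      drift_sign[cand] <- sign(lfc[cand])
      bg <- sample(setdiff(seq_len(nf), de_idx),
                   min(d$n_drift_background, nf - length(de_idx)))
      drift_sign[bg] <- sample(c(-1, 1), length(bg), TRUE)
    } else if (d$drift_mode == "independent") {
      n_dr <- round(d$frac_de * nf) + d$n_drift_background
      dr <- sample.int(nf, min(n_dr, nf))
      drift_sign[dr] <- sample(c(-1, 1), length(dr), TRUE)
    }

    # samples: controls, patients (first samples), longitudinal extras
    ctrl_ids <- sprintf("C%03d", seq_len(d$n_control))
    pat_ids <- sprintf("P%03d", seq_len(d$n_patient))
    long_pat <- pat_ids[seq_len(d$n_longitudinal)]
    extra <- if (d$n_longitudinal > 0L) {
      as.vector(t(outer(long_pat, c("T2", "T3", "T4"), paste, sep = "_")))
    } else character(0)
    sample_ids <- c(ctrl_ids, pat_ids, extra)
    ns <- length(sample_ids)
    patient_of <- c(ctrl_ids, pat_ids, rep(long_pat, each = 3L))
    group <- ifelse(grepl("^C", patient_of), "control", "ALS")
    timepoint <- c(rep("none", d$n_control),
                   ifelse(pat_ids %in% long_pat, "T1", "none"),
                   rep(c("T2", "T3", "T4"), times = d$n_longitudinal))
    tp_num <- match(timepoint, c("T1", "T2", "T3", "T4"))  # NA for "none"
    tp_num[is.na(tp_num) & group == "ALS"] <- 1L           # non-longitudinal = first
    tp_num[is.na(tp_num)] <- 1L

    regime <- sample(c("isomiR-rich", "notitr-rich"), ns, replace = TRUE,
                     prob = c(d$p_isomir_rich, 1 - d$p_isomir_rich))
    w_ref <- (d$regime_weights[[1]] + d$regime_weights[[2]]) / 2
    libsize <- stats::rlnorm(ns, 0, d$libsize_sdlog)

    # latent disease aggressiveness per patient (0 for controls)
    u_pat <- stats::setNames(stats::rnorm(d$n_patient), pat_ids)
    u <- ifelse(group == "ALS", u_pat[patient_of], 0)

    counts <- matrix(0L, nrow = nf, ncol = ns,
                     dimnames = list(ids, sample_ids))
    size <- 1 / d$dispersion
    cls_idx <- split(seq_len(nf), classes)
    for (j in seq_len(ns)) {
      w <- .rdirichlet1(d$regime_conc * d$regime_weights[[regime[j]]])
      names(w) <- names(w_ref)
      mult <- (w / w_ref)[classes]
      mu <- base_mean * mult * libsize[j]
      if (group[j] == "ALS") {
        mu <- mu * 2^lfc
        mu <- mu * 2^(d$hazard_link * hz_sign * u[j])
        mu <- mu * 2^(d$drift_lfc * drift_sign * (tp_num[j] - 1) / 3)
      }
      # presence/absence features override the NB mean
      pres <- stats::runif(nf) < ifelse(group[j] == "ALS",
                                        d$enrich_presence[["patient"]],
                                        d$enrich_presence[["control"]])
      mu[enr_idx] <- ifelse(pres[enr_idx], pmax(base_mean[enr_idx], 10), 0)
      counts[, j] <- stats::rnbinom(nf, mu = mu, size = size)
    }

    # clinical metadata (survival on patients only, one row per sample)
    age_onset <- stats::setNames(round(stats::rnorm(d$n_patient, 58, 9), 1), pat_ids)
    age_enroll <- age_onset + stats::setNames(round(stats::runif(d$n_patient, 0.5, 2.5), 1), pat_ids)
    sex_pat <- stats::setNames(sample(c("M", "F"), d$n_patient, TRUE), pat_ids)
    ril_pat <- stats::setNames(sample(c("+", "-"), d$n_patient, TRUE, c(0.6, 0.4)), pat_ids)
    onset_pat <- stats::setNames(sample(c("bulbar", "limb"), d$n_patient, TRUE,
                                        c(0.3, 0.7)), pat_ids)
    rd50 <- stats::setNames(round(stats::plogis(-0.6 * u_pat +
                                                stats::rnorm(d$n_patient, 0, 0.5)) * 0.5 + 0.2, 3),
                            pat_ids)
    alsfrs <- stats::setNames(round(pmin(48, 40 - 2 * u_pat +
                                         stats::rnorm(d$n_patient, 0, 3))), pat_ids)

    rate0 <- log(2) / d$base_median_survival
    lp <- d$hazard_strength * u_pat +
      0.02 * (age_onset - 58) + 0.1 * (sex_pat == "M")
    t_death <- stats::rexp(d$n_patient, rate = rate0 * exp(lp))
    event <- as.integer(t_death <= d$censor_time)
    t_obs <- stats::setNames(round(pmin(t_death, d$censor_time), 2), pat_ids)
    names(event) <- pat_ids

    is_pat <- group == "ALS"
    meta <- data.frame(
      sample_id = sample_ids, patient_id = patient_of, group = group,
      riluzole = ifelse(is_pat, ril_pat[patient_of], "unknown"),
      sex = ifelse(is_pat, sex_pat[patient_of],
                   sample(c("M", "F"), ns, TRUE)),
      age_at_onset = ifelse(is_pat, age_onset[patient_of], NA_real_),
      age_at_enrollment = ifelse(is_pat, age_enroll[patient_of], NA_real_),
      rD50 = ifelse(is_pat, rd50[patient_of], NA_real_),
      ALSFRS = ifelse(is_pat, alsfrs[patient_of], NA_real_),
      onset_type = ifelse(is_pat, onset_pat[patient_of], NA_character_),
      time_to_death_from_enrollment = ifelse(is_pat, t_obs[patient_of], NA_real_),
      time_to_death_from_onset = ifelse(
        is_pat,
        t_obs[patient_of] + 12 * (age_enroll[patient_of] - age_onset[patient_of]),
        NA_real_),
      event = ifelse(is_pat, event[patient_of], NA_integer_),
      timepoint = timepoint,
      stringsAsFactors = FALSE
    )

    truth <- list(
      features = data.frame(
        feature = ids, class = classes, seq = seqs,
        de = seq_len(nf) %in% de_idx, lfc = lfc,
        enriched = seq_len(nf) %in% enr_idx,
        hazard_linked = seq_len(nf) %in% hz_idx, hazard_sign = hz_sign,
        drift_sign = drift_sign,
        base_mean = base_mean, stringsAsFactors = FALSE
      ),
      regime = stats::setNames(regime, sample_ids),
      latent_u = u_pat,
      design = d
    )
    list(counts = counts, meta = meta, truth = truth)
  })
}

.draw_rdna_fragments_impl <- function(bundle, n, family = NULL,
                                      len_range = c(18L, 30L)) {
  db <- bundle$rdna
  if (!is.null(family)) {
    db <- db[grepl(family, db$taxonomy, fixed = TRUE), ]
    if (!nrow(db)) stop("invalid-argument: no organisms match family '",
                        family, "'", call. = FALSE)
  }
  g <- Biostrings::DNAString(bundle$genome)
  grc <- Biostrings::reverseComplement(g)
  out <- character(0)
  while (length(out) < n) {
    row <- db[sample.int(nrow(db), 1L), ]
    len <- sample(len_range[1L]:len_range[2L], 1L)
    st <- sample.int(nchar(row$seq) - len, 1L)
    s <- substr(row$seq, st, st + len - 1L)
    hit1 <- Biostrings::matchPattern(s, g, max.mismatch = 1, with.indels = TRUE)
    hit2 <- Biostrings::matchPattern(s, grc, max.mismatch = 1, with.indels = TRUE)
    if (length(hit1) == 0L && length(hit2) == 0L && !(s %in% out)) {
      out <- c(out, s)
    }
  }
  out
}

#' Draw non-host rDNA fragments from a bundle's database
#'
#' Samples short fragments from the rDNA database (optionally restricted to
#' one family), rejection-checked so no fragment matches the host genome
#' within edit distance 1 on either strand; such fragments classify as
#' Group-3 not-itrs by construction.
#'
#' @param bundle An \code{snc_bundle}.
#' @param n Number of distinct fragments.
#' @param family Optional taxonomy substring (e.g. "Family2") restricting
#'   the source organisms.
#' @param len_range Fragment length range (default 18-30 nt).
#' @param seed Integer seed.
#' @return Character vector of fragment sequences.
#' @export
draw_rdna_fragments <- function(bundle, n, family = NULL,
                                len_range = c(18L, 30L), seed = 1L) {
  with_seed(seed, .draw_rdna_fragments_impl(bundle, n, family, len_range))
}

#' Simulate small-RNA FASTQ records for one library
#'
#' Each molecule yields one or more PCR copies of the read
#' \code{insert [+ UMI] + 3' adapter}, truncated to the read length; PCR
#' duplicates share insert and UMI.  A configured fraction of inserts are
#' drawn from the bundle's rDNA database (non-host reads), rejection-sampled
#' so they do not match the host genome within edit distance 1.  Uniform
#' substitution errors and Sanger Phred qualities are applied.
#'
#' @param bundle \code{snc_bundle} (used for non-host inserts; may be NULL
#'   when \code{nonhost_frac = 0}).
#' @param profile List: \code{molecules} (named integer vector,
#'   insert sequence -> molecule count), \code{adapter},
#'   \code{umi_len} (0 = no UMI, serum-style), \code{dup_rate} (mean PCR
#'   copies per molecule; 0 or 1 = no duplication), \code{error_rate}
#'   (per-base substitution), \code{adapter_dropout} (fraction of reads
#'   emitted without adapter), \code{nonhost_frac}, \code{nonhost_family}
#'   (restrict non-host inserts to one family's organisms),
#'   \code{read_len}.
#' @param seed Integer seed.
#' @return A list: \code{records} data.frame(id, seq, qual) and
#'   \code{molecules} the realized molecule table (including non-host
#'   additions).
#' @export
simulate_reads <- function(bundle = NULL, profile = list(), seed = 1L) {
  p <- utils::modifyList(list(
    molecules = NULL, adapter = "TGGAATTCTCGGGTGCCAAGG", umi_len = 12L,
    dup_rate = 1, error_rate = 0, adapter_dropout = 0,
    nonhost_frac = 0, nonhost_family = NULL, read_len = 75L
  ), profile)
  if (p$umi_len < 0L) stop("invalid-argument: umi_len < 0", call. = FALSE)
  if (is.null(p$molecules)) stop("invalid-argument: profile$molecules required",
                                 call. = FALSE)
  with_seed(seed, {
    mols <- p$molecules
    if (p$nonhost_frac > 0) {
      n_host <- sum(mols)
      n_nh <- max(1L, round(p$nonhost_frac / (1 - p$nonhost_frac) * n_host))
      n_species <- max(1L, min(n_nh %/% 12L + 1L, 40L))
      nh_seqs <- .draw_rdna_fragments_impl(bundle, n_species,
                                           family = p$nonhost_family)
      nh_counts <- stats::rmultinom(1L, n_nh, rep(1, n_species))[, 1L]
      add <- stats::setNames(as.integer(nh_counts), nh_seqs)
      add <- add[add > 0L]
      mols <- c(mols, add)
    }

    nucs <- c("A", "C", "G", "T")
    recs <- list(); rid <- 0L
    for (k in seq_along(mols)) {
      insert <- names(mols)[k]
      for (m in seq_len(mols[[k]])) {
        umi <- if (p$umi_len > 0L) {
          paste(sample(nucs, p$umi_len, TRUE), collapse = "")
        } else ""
        ncopies <- if (p$dup_rate > 1) 1L + stats::rpois(1L, p$dup_rate - 1) else 1L
        for (cp in seq_len(ncopies)) {
          body <- if (stats::runif(1) < p$adapter_dropout) {
            paste0(insert, umi)
          } else {
            paste0(insert, umi, p$adapter)
          }
          body <- substr(body, 1L, p$read_len)
          if (p$error_rate > 0) {
            b <- strsplit(body, "")[[1]]
            hit <- which(stats::runif(length(b)) < p$error_rate)
            for (i in hit) b[i] <- sample(setdiff(nucs, b[i]), 1L)
            body <- paste(b, collapse = "")
          }
          rid <- rid + 1L
          q <- paste(rawToChar(as.raw(33L + sample(35:40, nchar(body), TRUE))),
                     collapse = "")
          recs[[rid]] <- c(sprintf("read%06d", rid), body, q)
        }
      }
    }
    records <- as.data.frame(do.call(rbind, recs), stringsAsFactors = FALSE)
    names(records) <- c("id", "seq", "qual")
    list(records = records, molecules = mols)
  })
}
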