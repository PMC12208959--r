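# End-to-end orchestration: simulate (or load) a cohort, classify features,
# and run the downstream statistical stages with the standard thresholds,
# writing per-stage TSVs, QC JSON, and a summary report.

#' Default pipeline configuration
#'
#' Thresholds default to the standard analysis values: adapter error rate
#' 0.12, quality cutoff 15, minimum insert 15 nt; differential abundance
#' median >= 5 raw, |log2FC| >= 0.4, FDR <= 0.05, normalized mean >= 5;
#' enrichment raw mean >= 1, FDR <= 1e-9; survival p <= 0.05; taxonomy
#' recurrence >= 10 reads in >= 20% of samples.
#'
#' @return A list; override any subset via the \code{config} argument of
#'   \code{\link{run_pipeline}}.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    stages = c("simulate", "classify", "diffabund", "enrichment", "survival",
               "longitudinal", "taxsearch"),
    counts_tsv = NULL, meta_tsv = NULL,
    bundle_params = list(genome_size = 30000L),
    design = list(n_features = 400L, with_sequences = TRUE),
    thresholds = list(
      adapter_error = 0.12, quality_cutoff = 15L, min_length = 15L,
      de_min_median = 5, de_lfc = 0.4, de_fdr = 0.05, de_mean = 5,
      enrich_mean_raw = 1, enrich_fdr = 1e-9,
      surv_p = 0.05,
      tax_min_reads = 10, tax_min_frac = 0.20
    )
  )
}

.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("config error: YAML config needs the yaml package", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("config error: config must be a list or a path",
                             call. = FALSE)
  config
}

#' Run the pipeline end-to-end
#'
#' Executes the enabled stages in dependency order on a simulated (or
#' loaded) cohort: classification of every feature sequence, per-class
#' differential abundance with the filter ledger, presence/absence
#' enrichment, survival screening, longitudinal direction calls with
#' sign-concordance tables, and rDNA taxonomic attribution of recurrent
#' Group-3 not-itrs.  All stage outputs are written as TSV under
#' \code{config$outdir} together with \code{qc.json}, \code{summary.tsv}
#' and the resolved \code{config.json}; runs are byte-identical for a
#' fixed seed.
#'
#' @param config A list (see \code{\link{default_pipeline_config}}) or a
#'   path to a JSON/YAML file of overrides; \code{outdir} is required.
#' @return Invisibly, a run report: per-stage output paths and counters.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(default_pipeline_config(), .read_config(config))
  if (is.null(cfg$outdir)) stop("config error: outdir is required", call. = FALSE)
  if (!all(cfg$stages %in% default_pipeline_config()$stages)) {
    stop("config error: unknown stage ",
         paste(setdiff(cfg$stages, default_pipeline_config()$stages),
               collapse = ", "), call. = FALSE)
  }
  th <- cfg$thresholds
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(outputs = character(0), counters = list())
  emit <- function(df, name) {
    path <- file.path(cfg$outdir, name)
    write_tsv(df, path)
    report$outputs <<- c(report$outputs, path)
  }

  bundle <- build_reference_bundle(cfg$seed, cfg$bundle_params)
  if ("simulate" %in% cfg$stages) {
    sim <- simulate_cohort(bundle, cfg$design, seed = cfg$seed + 1L)
    counts <- sim$counts; meta <- sim$meta
    truth <- sim$truth
    emit(data.frame(feature = rownames(counts), counts, check.names = FALSE),
         "counts.tsv")
    emit(meta, "meta.tsv")
  } else {
    if (is.null(cfg$counts_tsv) || is.null(cfg$meta_tsv)) {
      stop("dependency error: stage needs counts_tsv and meta_tsv when ",
           "simulate is disabled", call. = FALSE)
    }
    counts <- read_counts(cfg$counts_tsv)
    meta <- read_tsv(cfg$meta_tsv)
    truth <- NULL
  }
  report$counters$samples <- ncol(counts)
  report$counters$features <- nrow(counts)

  classes <- NULL
  assignments <- NULL
  if ("classify" %in% cfg$stages) {
    plates <- rownames(counts)
    seqs <- tryCatch(plate_decode(plates), error = function(e) {
      stop("dependency error: classify needs plate feature ids", call. = FALSE)
    })
    ix <- bundle_index(bundle)
    assignments <- classify_reads(seqs, ix)
    assignments$feature <- plates
    emit(assignments, "assignments.tsv")
    classes <- ifelse(assignments$notitr_group > 0L, "notitr",
               ifelse(assignments$is_isomir, "isomiR",
               ifelse(assignments$is_trf, "tRF",
               ifelse(assignments$is_rrf, "rRF", "yRF"))))
    comp_counts <- counts
    rownames(comp_counts) <- seqs
    emit(composition_summary(comp_counts, assignments), "composition.tsv")
    report$counters$notitr_group3 <- sum(assignments$notitr_group == 3L)
  } else if (!is.null(truth)) {
    classes <- truth$features$class
  }

  first <- !duplicated(meta$patient_id) & meta$timepoint %in% c("T1", "none")
  meta_first <- meta[first, , drop = FALSE]
  counts_first <- counts[, meta_first$sample_id, drop = FALSE]
  groups <- factor(meta_first$group, levels = c("control", "ALS"))
  two_groups <- all(table(groups) >= 2L)

  de_filtered <- NULL
  if ("diffabund" %in% cfg$stages && two_groups) {
    de <- nb_wald_test(counts_first, groups, min_median = th$de_min_median,
                       classes = classes)
    de_filtered <- apply_de_filters(de, th$de_lfc, th$de_fdr, th$de_mean)
    emit(de, "de_results.tsv")
    emit(de_filtered, "de_filtered.tsv")
    report$counters$de_tested <- nrow(de)
    report$counters$de_significant <- nrow(de_filtered)
  }

  if ("enrichment" %in% cfg$stages && two_groups) {
    enr <- presence_enrichment(counts_first, groups, th$enrich_mean_raw,
                               th$enrich_fdr, classes = classes)
    emit(enr, "enrichment.tsv")
    report$counters$enriched <- sum(enr$kept)
  }

  surv <- NULL
  if ("survival" %in% cfg$stages) {
    if (!any(meta$group == "ALS") || !"event" %in% names(meta)) {
      stop("dependency error: survival stage needs patient survival metadata",
           call. = FALSE)
    }
    surv <- survival_screen(counts, meta, settings = list(
      strata = "both", covariate_sets = "univariate",
      min_median = th$de_min_median, mean_min = th$de_mean,
      p_max = th$surv_p), classes = classes)
    emit(surv, "survival.tsv")
    report$counters$survival_kept <- length(unique(surv$feature[surv$kept]))
  }

  if ("longitudinal" %in% cfg$stages && any(meta$timepoint == "T4")) {
    y <- if (!is.null(classes)) normalize_per_class(counts, classes)
         else normalize_counts(counts)
    calls <- direction_calls(y, meta)
    emit(calls, "longitudinal_calls.tsv")
    cls_vec <- if (!is.null(classes)) {
      stats::setNames(classes, rownames(counts))
    } else NULL
    conc <- concordance_tables(
      calls,
      de = de_filtered,
      kept_features = if (!is.null(surv)) unique(surv$feature[surv$kept]),
      classes = cls_vec)
    if (!is.null(conc)) emit(conc, "concordance.tsv")
  }

  if ("taxsearch" %in% cfg$stages) {
    if (is.null(assignments)) {
      stop("dependency error: taxsearch needs the classify stage", call. = FALSE)
    }
    g3 <- assignments$feature[assignments$notitr_group == 3L]
    rec <- filter_recurrent_notitrs(counts, g3, th$tax_min_reads,
                                    th$tax_min_frac)
    feature_seqs <- stats::setNames(plate_decode(rec), rec)
    for (su in c("SSU", "LSU")) {
      oc <- match_rdna(feature_seqs, bundle$rdna, su)
      emit(group_taxa(oc), paste0("taxsearch_", tolower(su), ".tsv"))
    }
    report$counters$recurrent_group3 <- length(rec)
  }

  jsonlite::write_json(report$counters, file.path(cfg$outdir, "qc.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(cfg, file.path(cfg$outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  summary_df <- data.frame(counter = names(report$counters),
                           value = unlist(report$counters, use.names = FALSE))
  emit(summary_df, "summary.tsv")
  invisible(report)
}
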