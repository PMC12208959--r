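# Reference-bundle and cohort generator: determinism, structural
# invariants, and recoverability of planted effects.

test_that("bundle is deterministic and structurally sound", {
  b <- test_bundle()
  b2 <- build_reference_bundle(101, list(genome_size = 20000L))
  expect_identical(b, b2)
  expect_equal(nrow(b$mir_loci), 20L)
  expect_true(all(b$mir_loci$m5p_start >= b$mir_loci$hp_start &
                  b$mir_loci$m5p_end <= b$mir_loci$hp_end))
  expect_true(all(b$mir_loci$m3p_start >= b$mir_loci$hp_start &
                  b$mir_loci$m3p_end <= b$mir_loci$hp_end))
  ann <- bundle_annotations(b)
  expect_true(all(ann$start >= 0 & ann$end <= nchar(b$genome)))
  # tRNA mature space carries the non-templated CCA
  sp <- bundle_sequences(b)$trna_space
  expect_true(all(substr(sp, nchar(sp) - 2L, nchar(sp)) == "CCA"))
  # taxonomy strings have at least five levels
  expect_true(all(lengths(strsplit(b$rdna$taxonomy, ";")) >= 5L))
})

test_that("bundle files are byte-identical under a fixed seed", {
  d1 <- file.path(tempdir(), "bun1"); d2 <- file.path(tempdir(), "bun2")
  b <- build_reference_bundle(7, list(genome_size = 8000L, n_rdna = 6L))
  write_bundle(b, d1)
  write_bundle(build_reference_bundle(7, list(genome_size = 8000L, n_rdna = 6L)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("no rDNA sequence is a substring of the genome (brute force)", {
  b <- test_bundle()
  hits <- vapply(b$rdna$seq, function(s) genome_contains(b, s), logical(1))
  expect_false(any(hits))
})

test_that("cohort design is validated and degenerate designs work", {
  expect_error(simulate_cohort(design = list(n_longitudinal = 40L,
                                             n_patient = 10L), seed = 1),
               "invalid-design")
  # patient-only cohort for survival screening
  sim <- simulate_cohort(design = list(n_control = 0L, n_patient = 12L,
                                       n_features = 50L, n_longitudinal = 0L),
                         seed = 2)
  expect_equal(sum(sim$meta$group == "control"), 0L)
  expect_true(all(!is.na(sim$meta$time_to_death_from_enrollment)))
  expect_true(all(sim$meta$time_to_death_from_onset >=
                  sim$meta$time_to_death_from_enrollment))
})

test_that("planted log2 fold changes are recovered on average", {
  sim <- simulate_cohort(design = list(n_features = 1000L, frac_de = 0.05,
                                       n_longitudinal = 0L), seed = 3)
  tr <- sim$truth$features
  meta <- sim$meta
  cf <- sim$counts[, meta$sample_id]
  de <- nb_wald_test(cf, factor(meta$group, levels = c("control", "ALS")),
                     classes = tr$class)
  m <- merge(de, tr[tr$de, c("feature", "lfc")], by = "feature")
  expect_gt(nrow(m), 20)
  # signed mean of estimates vs planted |log2FC| = 1
  expect_lt(abs(mean(m$log2fc * sign(m$lfc)) - 1), 0.2)
})

test_that("composition regimes anticorrelate isomiR and not-itr fractions", {
  sim <- simulate_cohort(design = list(n_features = 600L,
                                       n_longitudinal = 0L), seed = 4)
  cls <- sim$truth$features$class
  frac <- apply(sim$counts, 2L, function(col) {
    c(iso = sum(col[cls == "isomiR"]), ni = sum(col[cls == "notitr"])) / sum(col)
  })
  expect_lt(cor(frac["iso", ], frac["ni", ], method = "spearman"), -0.5)
})

test_that("simulated reads honour duplication, UMIs, and adapter dropout", {
  b <- test_bundle()
  sq <- bundle_sequences(b)
  mols <- stats::setNames(c(25L, 15L, 8L),
                          c(sq$mature5p[[2]],
                            substr(sq$trna_space[[2]], 1, 20),
                            substr(sq$rrna[[1]], 5, 26)))
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  r0 <- simulate_reads(b, list(molecules = mols, dup_rate = 0, umi_len = 12L),
                       seed = 5)
  expect_equal(nrow(r0$records), sum(mols))
  p0 <- preprocess_sample(r0$records, adapter, umi_len = 12L)
  expect_equal(p0$counts[names(mols)], mols)
  # 3x duplication: raw reads inflate, deduplicated counts recover molecules
  r3 <- simulate_reads(b, list(molecules = mols, dup_rate = 3, umi_len = 12L),
                       seed = 6)
  expect_gt(nrow(r3$records), 1.8 * sum(mols))
  p3 <- preprocess_sample(r3$records, adapter, umi_len = 12L)
  expect_equal(p3$counts[names(mols)], mols)
  # adapter dropout: affected reads are discarded in UMI mode
  rd <- simulate_reads(b, list(molecules = mols, dup_rate = 0, umi_len = 12L,
                               adapter_dropout = 1), seed = 7)
  pd <- preprocess_sample(rd$records, adapter, umi_len = 12L)
  expect_equal(pd$qc$retained, 0L)
  expect_error(simulate_reads(b, list(molecules = mols, umi_len = -1L)),
               "invalid-argument")
})

test_that("non-host fragments never match the genome within one edit", {
  b <- test_bundle()
  frags <- draw_rdna_fragments(b, 6L, family = "Family1", seed = 8)
  for (f in frags) {
    nb <- edit1_neighborhood(f)
    expect_false(any(vapply(nb, function(s) genome_contains(b, s), logical(1))),
                 info = f)
  }
})
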