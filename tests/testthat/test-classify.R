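# isomiR / tRF / rRF / yRF callers and not-itr grouping, checked against
# brute-force sequence oracles on a small bundle.

test_that("canonical and offset isomiRs are called with the label dialect", {
  ix <- test_index()
  b <- test_bundle()
  sq <- bundle_sequences(b)
  m <- sq$mature5p[[3]]
  iso <- call_isomir(m, ix)
  expect_equal(nrow(iso), 1L)
  expect_equal(iso$category, "canonical")
  expect_match(iso$label, "\\|0\\|0\\|$")
  # one extra templated 3' nucleotide -> |0|+1|, non-canonical
  hp <- sq$hairpin[[3]]
  pos3 <- (b$mir_loci$m5p_end[3] - b$mir_loci$hp_start[3])  # 0-based next base
  ext <- paste0(m, substr(hp, pos3 + 1L, pos3 + 1L))
  iso1 <- call_isomir(ext, ix)
  expect_equal(iso1$offset3, 1L)
  expect_equal(iso1$offset5, 0L)
  expect_equal(iso1$category, "non-canonical")
  expect_match(iso1$label, "\\|0\\|\\+1\\|$")
})

test_that("non-templated 3' additions are split from the templated prefix", {
  ix <- test_index()
  b <- test_bundle()
  sq <- bundle_sequences(b)
  # shorten the mature 3' end by 2 and append a dinucleotide that does NOT
  # match the hairpin at those positions (brute-force construction)
  for (i in seq_len(nrow(b$mir_loci))) {
    m <- sq$mature5p[[i]]
    hp <- sq$hairpin[[i]]
    core <- substr(m, 1, nchar(m) - 2L)
    templated_next <- substr(hp, nchar(core) + 1L, nchar(core) + 2L)
    nta <- if (templated_next == "AA") "CC" else "AA"
    if (substr(nta, 1, 1) == substr(templated_next, 1, 1)) next
    iso <- call_isomir(paste0(core, nta), ix)
    expect_equal(iso$offset3, -2L)
    expect_equal(iso$nta, nta)
    expect_equal(iso$category, "non-templated")
    expect_match(iso$label, "\\|0\\|-2\\|$")
    break
  }
})

test_that("tRF types follow start/end coordinates in gene+CCA space", {
  ix <- test_index()
  sq <- bundle_sequences(test_bundle())
  sp <- sq$trna_space[[4]]
  # 18-nt suffix touches the CCA: 3'-tRF
  t3 <- call_trf(substr(sp, nchar(sp) - 17L, nchar(sp)), ix)
  expect_true("3'-tRF" %in% t3$type[t3$trna == names(sq$trna_space)[4]])
  # 34-nt prefix ends at position 34, inside the anticodon-loop window: 5'-half
  t5 <- call_trf(substr(sp, 1L, 34L), ix)
  expect_true("5'-half" %in% t5$type[t5$trna == names(sq$trna_space)[4]])
  # 20-mer internal fragment touching neither terminus: i-tRF
  ti <- call_trf(substr(sp, 5L, 24L), ix)
  expect_true("i-tRF" %in% ti$type[ti$trna == names(sq$trna_space)[4]])
  # 5'-tRF: prefix ending past the loop window
  tp <- call_trf(substr(sp, 1L, 40L), ix)
  expect_true("5'-tRF" %in% tp$type[tp$trna == names(sq$trna_space)[4]])
})

test_that("rRF and yRF calls are exact substring hits", {
  ix <- test_index()
  sq <- bundle_sequences(test_bundle())
  r <- substr(sq$rrna[["5S"]], 20, 35)        # 16-mer from 5S
  expect_true("5S" %in% call_rrf(r, ix))
  y <- sq$yrna[["RNY4"]]
  frag <- substr(y, nchar(y) - 26L, nchar(y))  # 27-mer from the 3' region
  expect_true("RNY4" %in% call_yrf(frag, ix))
  set.seed(11)
  repeat {                                    # random 20-mer absent everywhere
    s <- random_acgt(1, 20)
    if (!genome_contains(test_bundle(), s)) break
  }
  expect_length(call_rrf(s, ix), 0L)
  expect_length(call_yrf(s, ix), 0L)
})

test_that("not-itr groups follow the exact / one-edit / no-match ladder", {
  ix <- test_index()
  b <- test_bundle()
  ann <- bundle_annotations(b)
  # Group 1: an exact genome 20-mer from an unannotated region
  set.seed(12)
  repeat {
    st <- sample.int(nchar(b$genome) - 20L, 1L)
    if (!any(st < ann$end & (st + 20L) > ann$start)) break
  }
  s1 <- substr(b$genome, st + 1L, st + 20L)
  c1 <- classify_read(s1, ix)
  expect_equal(c1$notitr_group, 1L)
  expect_false(any(c(c1$is_isomir, c1$is_trf, c1$is_rrf, c1$is_yrf)))
  # Group 2: an rRF with one substitution, verified against the exhaustive
  # one-edit neighbourhood oracle
  sq <- bundle_sequences(b)
  r <- substr(sq$rrna[["18S"]], 100, 121)
  mut <- r
  substr(mut, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                 substr(r, 11, 11))[1]
  stopifnot(!genome_contains(b, mut))
  expect_true(any(vapply(edit1_neighborhood(mut),
                         function(s) genome_contains(b, s), logical(1))))
  c2 <- classify_read(mut, ix)
  expect_equal(c2$notitr_group, 2L)
  expect_match(c2$group2_neighbors, "rRF")
  # Group 3: a non-host rDNA fragment
  s3 <- draw_rdna_fragments(b, 1L, seed = 13)
  c3 <- classify_read(s3, ix)
  expect_equal(c3$notitr_group, 3L)
  expect_match(c3$plates, "^na-")
  expect_error(classify_read("ACGTACGTACGTephemeral", ix), "invalid")
  expect_error(classify_read("ACGTACGTACG", ix), "invalid-input")
})

test_that("every sequence gets exactly one of: class flags or a group", {
  ix <- test_index()
  b <- test_bundle()
  sq <- bundle_sequences(b)
  set.seed(14)
  pool <- c(
    sq$mature3p[1:3],
    substr(sq$trna_space[[1]], 3, 22),
    substr(sq$rrna[["28S"]], 50, 70),
    substr(sq$yrna[[2]], 10, 33),
    random_acgt(3, 20),
    vapply(1:3, function(i) {
      st <- sample.int(nchar(b$genome) - 22L, 1L)
      substr(b$genome, st + 1L, st + 22L)
    }, character(1))
  )
  asn <- classify_reads(unname(pool), ix)
  has_flag <- asn$is_isomir | asn$is_trf | asn$is_rrf | asn$is_yrf
  expect_true(all(xor(has_flag, asn$notitr_group > 0L)))
  # every emitted plate decodes back to its sequence
  for (i in seq_len(nrow(asn))) {
    plates <- strsplit(asn$plates[i], ",")[[1]]
    expect_true(all(plate_decode(plates) == asn$seq[i]))
  }
  # classification agrees with the brute-force genome scanner for not-itrs
  for (i in which(asn$notitr_group > 0L)) {
    exact <- genome_contains(b, asn$seq[i])
    expect_equal(asn$notitr_group[i] == 1L, exact)
    if (!exact) {
      one_edit <- any(vapply(edit1_neighborhood(asn$seq[i]),
                             function(s) genome_contains(b, s), logical(1)))
      expect_equal(asn$notitr_group[i] == 2L, one_edit)
    }
  }
})

test_that("composition fractions exclude ambiguous reads and sum sanely", {
  ix <- test_index()
  sq <- bundle_sequences(test_bundle())
  seqs <- c(sq$mature5p[[1]], sq$mature5p[[2]],
            substr(sq$trna_space[[1]], 1, 20))
  asn <- classify_reads(seqs, ix)
  counts <- matrix(c(6L, 3L, 1L), ncol = 1,
                   dimnames = list(seqs, "S1"))
  comp <- composition_summary(counts, asn)
  expect_equal(comp$isomiR + comp$tRF + comp$rRF + comp$yRF + comp$notitr +
               comp$ambiguous, 1)
  expect_equal(comp$isomiR, 0.9)
  expect_equal(comp$tRF, 0.1)
  expect_error(composition_summary(matrix(0L, 1, 1,
                                          dimnames = list(seqs[1], "S")),
                                   asn),
               "undefined-fraction")
})

test_that("isomiR-rich and notitr-rich samples anticorrelate in composition", {
  sim <- simulate_cohort(design = list(n_features = 400L,
                                       n_longitudinal = 0L), seed = 15)
  cls <- sim$truth$features$class
  asn <- data.frame(
    seq = sim$truth$features$feature,
    is_isomir = cls == "isomiR", is_trf = cls == "tRF",
    is_rrf = cls == "rRF", is_yrf = cls == "yRF",
    notitr_group = ifelse(cls == "notitr", 1L, 0L),
    unambiguous = cls != "notitr",
    stringsAsFactors = FALSE
  )
  comp <- composition_summary(sim$counts, asn)
  expect_lt(cor(comp$isomiR, comp$notitr, method = "spearman"), -0.5)
})
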