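# Adapter trimming, UMI extraction, and directional deduplication.

ADPT <- "TGGAATTCTCGGGTGCCAAGG"
q40 <- function(s) strrep("I", nchar(s))

test_that("exact adapter occurrences yield the 5' insert", {
  insert <- strrep("ACGT", 5)
  read <- paste0(insert, ADPT)
  r <- trim_adapter(read, q40(read), ADPT)
  expect_equal(r$insert, insert)
  expect_equal(r$status, "ok")
  # adapter prefix overhanging the read 3' end is still found
  read2 <- paste0(insert, substr(ADPT, 1, 8))
  r2 <- trim_adapter(read2, q40(read2), ADPT)
  expect_equal(r2$insert, insert)
})

test_that("mismatched adapters are tolerated up to the error budget", {
  insert <- strrep("GATC", 5)
  mut <- ADPT
  substr(mut, 3, 3) <- "A"; substr(mut, 11, 11) <- "C"   # 2 edits, <= floor(0.12*21)
  read <- paste0(insert, mut)
  expect_equal(trim_adapter(read, q40(read), ADPT)$insert, insert)
  mut3 <- mut; substr(mut3, 17, 17) <- "A"               # 3 edits: over budget
  read3 <- paste0(insert, mut3)
  expect_equal(trim_adapter(read3, q40(read3), ADPT, umi_mode = TRUE)$status,
               "no-adapter")
})

test_that("adapter-less reads are rejected in UMI mode, kept whole otherwise", {
  read <- strrep("ACGT", 10)
  expect_equal(trim_adapter(read, q40(read), ADPT, umi_mode = TRUE)$status,
               "no-adapter")
  r <- trim_adapter(read, q40(read), ADPT, umi_mode = FALSE)
  expect_equal(r$insert, read)
})

test_that("short inserts are rejected at the 15-nt floor", {
  insert14 <- strrep("AC", 7)
  read <- paste0(insert14, ADPT)
  expect_equal(trim_adapter(read, q40(read), ADPT)$status, "too-short")
  insert15 <- paste0(insert14, "G")
  expect_equal(trim_adapter(paste0(insert15, ADPT),
                            q40(paste0(insert15, ADPT)), ADPT)$status, "ok")
})

test_that("low-quality 3' tails are trimmed before adapter search", {
  insert <- strrep("TGCA", 5)
  read <- paste0(insert, ADPT, "AAAA")
  qual <- paste0(q40(paste0(insert, ADPT)), strrep("#", 4))   # Q2 tail
  r <- trim_adapter(read, qual, ADPT)
  expect_equal(r$insert, insert)
  tr <- quality_trim3(read, qual)
  expect_equal(tr$seq, paste0(insert, ADPT))
})

test_that("UMI extraction returns insert and tag, rejecting truncations", {
  insert <- strrep("CAGT", 5)
  umi <- strrep("T", 12)
  read <- paste0(insert, umi, ADPT)
  r <- extract_umi(read, q40(read), ADPT, umi_len = 12L)
  expect_equal(r$insert, insert)
  expect_equal(r$umi, umi)
  # two reads differing only in UMI share the insert
  umi2 <- paste0(strrep("T", 11), "A")
  r2 <- extract_umi(paste0(insert, umi2, ADPT),
                    q40(paste0(insert, umi2, ADPT)), ADPT, umi_len = 12L)
  expect_equal(r2$insert, insert)
  expect_false(identical(r$umi, r2$umi))
  # truncated UMI: only 8 of 12 nt before the read end, no adapter
  read3 <- paste0(insert, strrep("T", 8))
  expect_equal(extract_umi(read3, q40(read3), ADPT, umi_len = 12L)$status,
               "no-adapter")
  # adapter present but too few bases for a full UMI
  read4 <- paste0("ACGTACGT", ADPT)
  expect_equal(extract_umi(read4, q40(read4), ADPT, umi_len = 12L)$status,
               "umi-truncated")
  expect_error(extract_umi(read, q40(read), ADPT, umi_len = 0L), "invalid use")
})

test_that("directional UMI clustering follows the 2n-1 rule", {
  # 10x AAAA absorbs 1x AAAT (Hamming 1, 10 >= 2*1-1)
  expect_equal(unname(dedup_umis(rep("ACGTACGTACGTACG", 11),
                                 c(rep("AAAA", 10), "AAAT"))), 1L)
  # equal counts at Hamming distance 1 are NOT absorbed (5 < 2*5-1)
  expect_equal(unname(dedup_umis(rep("ACGTACGTACGTACG", 10),
                                 c(rep("AAAA", 5), rep("AAAT", 5)))), 2L)
  # Hamming distance 4: never connected
  expect_equal(unname(dedup_umis(rep("ACGTACGTACGTACG", 10),
                                 c(rep("AAAA", 5), rep("TTTT", 5)))), 2L)
  # three inserts, all distinct UMIs
  out <- dedup_umis(c("A15AAAAAAAAAAAA", "C15CCCCCCCCCCCC", "G15GGGGGGGGGGGG"),
                    c("AAAA", "CCCC", "GGGG"))
  expect_equal(unname(out), c(1L, 1L, 1L))
  expect_error(dedup_umis(c("X", "X"), c("AAAA", "AAA")), "invalid-input")
})

test_that("deduplicated counts never exceed raw counts", {
  set.seed(42)
  for (rep_i in 1:5) {
    n <- 50L
    inserts <- sample(random_acgt(5, 20), n, replace = TRUE)
    umis <- sample(random_acgt(8, 6), n, replace = TRUE)
    ded <- dedup_umis(inserts, umis)
    raw <- table(inserts)
    expect_true(all(ded[names(raw)] <= as.integer(raw)))
    # pairwise non-adjacent UMIs (all distinct at Hamming > 1) keep all
    umis2 <- random_acgt(n, 8)
    if (!anyDuplicated(umis2)) {
      ham1 <- any(vapply(seq_len(n - 1), function(i) {
        any(vapply((i + 1):n, function(j) {
          sum(utf8ToInt(umis2[i]) != utf8ToInt(umis2[j])) <= 1
        }, logical(1)))
      }, logical(1)))
      if (!ham1) {
        ded2 <- dedup_umis(inserts, umis2)
        expect_equal(sum(ded2), n)
      }
    }
  }
})

test_that("retained fraction is consistent QC accounting", {
  insert <- strrep("ACGT", 5)
  recs <- data.frame(
    id = c("a", "b", "c"),
    seq = c(paste0(insert, ADPT), strrep("ACGT", 10), paste0("ACGTAC", ADPT)),
    qual = c(q40(paste0(insert, ADPT)), q40(strrep("ACGT", 10)),
             q40(paste0("ACGTAC", ADPT))),
    stringsAsFactors = FALSE
  )
  # non-UMI mode: read b is kept whole, read c is too short
  p <- preprocess_sample(recs, ADPT, umi_len = 0L)
  expect_equal(p$qc$raw, 3L)
  expect_equal(p$qc$retained, 2L)
  expect_equal(p$qc$retained_fraction, 2 / 3)
  expect_true(p$qc$retained_fraction >= 0 && p$qc$retained_fraction <= 1)
})
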