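# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

test_bundle <- function() {
  if (is.null(.fixtures$bundle)) {
    .fixtures$bundle <- build_reference_bundle(101, list(genome_size = 20000L))
  }
  .fixtures$bundle
}

test_index <- function() {
  if (is.null(.fixtures$index)) {
    .fixtures$index <- bundle_index(test_bundle())
  }
  .fixtures$index
}

random_acgt <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# brute-force oracle: all sequences within edit distance exactly <= 1
edit1_neighborhood <- function(seq) {
  nucs <- c("A", "C", "G", "T")
  b <- strsplit(seq, "")[[1]]
  out <- seq
  for (i in seq_along(b)) {
    for (nu in nucs) {
      sub <- b; sub[i] <- nu
      out <- c(out, paste(sub, collapse = ""))
    }
    out <- c(out, paste(b[-i], collapse = ""))            # deletion
  }
  for (i in 0:length(b)) {
    for (nu in nucs) {
      out <- c(out, paste(c(b[seq_len(i)], nu, b[seq_len(length(b) - i) + i]),
                          collapse = ""))                 # insertion
    }
  }
  unique(out)
}

# brute-force genome scan (either strand) used as classification oracle
genome_contains <- function(bundle, seq) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  grepl(seq, bundle$genome, fixed = TRUE) ||
    grepl(rc, bundle$genome, fixed = TRUE)
}

# brute-force two-sided Fisher p via explicit binomial coefficients
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(N, c1)
  obs <- choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}
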