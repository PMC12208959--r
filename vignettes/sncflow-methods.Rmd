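---
title: "Methods and design of the sncflow pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the sncflow pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sncflow classifies short RNA-sequencing reads from blood biofluids into
isomiRs, tRNA-derived fragments (tRFs), rRNA-derived fragments (rRFs),
Y RNA-derived fragments (yRFs), and unannotated "not-itrs", labels every
molecule with a reversible base-32 "license plate", and screens the
resulting count matrices for diagnostic (differential abundance,
presence/absence enrichment), prognostic (Cox / Kaplan-Meier survival), and
longitudinal (sign-concordance) associations, finishing with exact-match
taxonomic attribution of reads that cannot derive from the host genome.
This vignette records the models, the parameters that matter, and the
design decisions that were genuinely open.

## The license-plate codec

A plate renders as `<prefix>-<length>-<payload>`: the prefix names the
molecule class (`iso`, `tRF`, `rRF`, `yRF`, or `na` for not-itrs), the
middle field is the sequence length in nucleotides, and the payload is a
base-32 spelling of the sequence itself.  Because the payload encodes the
sequence bijectively, plates are unique, conflict-free and independent of
any genome assembly.

The sequence is chunked 5' to 3' into 5-mers with a trailing remainder.  A
5-mer maps to the big-endian base-4 value $v = \sum_{i=1}^{5} d_i\,4^{5-i}$
with A=0, C=1, G=2, T=3, written as two symbols
$\alpha[v \,\mathrm{div}\, 32]\,\alpha[v \,\mathrm{mod}\, 32]$ over the
32-symbol alphabet (digits and capital letters minus A/C/G/T).  Remainders
of 1-2 nt cost one symbol, 3-4 nt cost two, so a sequence of length $L$
has a payload of $2\lfloor L/5\rfloor$ plus 0/1/2 characters.

Two aspects of the codec are not derivable from first principles and were
fixed from the two published sequence-label pairs that anchor it:

* **Alphabet order.** The symbol set is stated in prose but not its order.
  The two published pairs pin eleven positional constraints
  ($\alpha[10]=K$, $\alpha[12]=L$, ..., $\alpha[30]=Y$); the simple
  interleaving `BD0EF1HI2JK3LM4NO5PQ6RS7UV8WX9YZ` (two letters, one digit,
  repeating; letters alphabetical, digits numeric) satisfies all eleven and
  is adopted.
* **Short-chunk codes.** The two published 4-mer codes (`GAGC`→`H9`,
  `CTGC`→`HM`) provably cannot come from the positional rule under any
  nucleotide ordering.  The codec therefore applies the positional rule at
  lengths 1-4 and then swaps the chunk pairs GAGC↔TCTC and CTGC↔TATC, an
  involution that honours both published codes while preserving
  bijectivity.  Unpinned 1-4-mer codes beyond those two are this package's
  own convention.

One published label (`rRF-43-...`, 17 payload characters where the length
rule demands 18) contradicts every other published label and is treated as
a typographical omission; it is excluded from the golden tests.

## Synthetic data: what it emulates and what it does not

`build_reference_bundle()` plants non-overlapping miRNA hairpins (two
mature arms each), tRNA genes (mature space = gene + non-templated 3'
CCA), rRNA loci, and full-length plus partial Y RNA copies on a random toy
chromosome (100 kb by default; tests use 15-30 kb), and generates an
off-genome rDNA database of SSU/LSU sequences for 30 organisms in 5
families.  Organisms within a family diverge from a shared consensus by
2% substitutions, so a fragment of one organism usually also hits its
relatives -- the structure the taxonomy-grouping stage exists to collapse.
Every rDNA sequence is rejection-sampled against the genome, and fragments
drawn for simulation are additionally rejected if they match the genome
within edit distance 1, making them Group-3 not-itrs by construction.

`simulate_cohort()` draws negative-binomial counts with variance
$\mu + \alpha\mu^2$ ($\alpha = 0.1$).  Its defaults are the study
conditions of the test suite: 30 controls + 30 patients, 2000 features,
10% planted differential-abundance features at $|\log_2 FC| = 1$, 8
longitudinal patients with four timepoints, 10 presence/absence-enriched
features (5% vs 95% presence), and 30 hazard-linked features.  Three
design choices deserve comment:

* **Composition dichotomy.** Each sample is assigned an `isomiR-rich` or
  `notitr-rich` regime; per-sample class weights are Dirichlet-jittered
  around the regime's weights (concentration 300).  This reproduces the
  qualitative anticorrelation between isomiR and not-itr fractions seen
  across real biofluid libraries.  The regime magnitudes are free knobs --
  no quantitative model of the dichotomy exists -- chosen so both regimes
  remain realistic libraries rather than caricatures.
* **Survival coupling.** Hazard-linked features and survival are coupled
  through a patient-level latent aggressiveness factor $u \sim N(0,1)$:
  the features' abundance shifts by $2^{0.7\,s_f u}$ (sign $s_f$ per
  feature) and the death hazard is exponential with log-hazard
  $0.9u + 0.02(\text{age}-58) + 0.1\,[\text{male}]$, administratively
  censored at 60 months.  This keeps proportional hazards exact while
  making each feature a noisy marginal predictor, which is how abundance
  biomarkers behave; it also lets the rD50 aggressiveness score correlate
  with survival, as observed.
* **Longitudinal drift.** In `concordant` mode, 80% of planted DE features
  drift monotonically across T1..T4 with the DE sign (plus 100 background
  drifters of random sign); `independent` and `none` modes exist for
  calibration experiments.

The generator does **not** emulate realistic genome composition, splicing,
strand-ambiguous features, sequence-dependent PCR bias, or quality-error
models beyond uniform substitution.  Passing tests therefore demonstrate
correctness of the statistical machinery under its stated model, not
robustness to artefacts real libraries can contain.

## Preprocessing

Reads are 3'-quality-trimmed (Phred+33, cutoff 15, the standard
running-sum rule), then the 3' adapter is located by semi-global alignment
with unit-cost edits, allowing up to $\lfloor 0.12\,\ell\rfloor$ edits for
an aligned adapter length $\ell$ and a minimum overlap of 3 nt.  The best
occurrence maximizes aligned length net of twice the edit count, then
fewest edits, then leftmost start -- a deterministic tie-break.  In UMI
libraries the 12-nt UMI sits between the insert and the adapter;
adapter-less or UMI-truncated reads are discarded, and inserts below 15 nt
are always discarded.  UMIs are deduplicated per insert with the
directional rule: $u$ absorbs $v$ when their Hamming distance is 1 and
$\mathrm{count}(u) \ge 2\,\mathrm{count}(v) - 1$; the deduplicated count
is the number of clusters.  Clustering is per insert rather than per
alignment position because no alignment exists at this stage.

## Classification

isomiR calling accepts 5' offsets in $[-3, 3]$, 3' offsets in $[-5, 5]$
and up to 3 nt of non-templated 3' additions (NTA); the templated prefix
is matched inside the hairpin and the NTA is whatever maximal-match logic
leaves over.  Offsets are signed with positive = longer than the annotated
mature end, rendered in the backward-compatible label dialect
`name|offset5|offset3|`.  tRF calling searches the mature space (gene +
CCA) exactly; fragments starting at position 1 are 5'-tRFs (5'-halves when
they end in the anticodon-loop window, mature positions 30-36), fragments
reaching the gene 3' end or the CCA are 3'-tRFs (3'-halves when they start
in the loop window), and the rest are i-tRFs.  rRF and yRF calls are exact
substring hits.  Multi-labels are retained -- no precedence suppresses a
call -- and `unambiguous` means exactly one class flag.

Sequences with no class call become not-itrs: Group 1 when they match the
genome exactly on either strand, Group 2 when they match within edit
distance 1 (one replacement, insertion or deletion; the annotated class of
the edited match is recorded), Group 3 otherwise.  Genome matching uses
Biostrings pattern matching; the test suite cross-checks it against an
exhaustive one-edit-neighbourhood scan on small genomes.

## Differential abundance

Size factors are median-of-ratios over features nonzero in every sample.
Each class is analyzed as its own dataset -- its size factors are computed
from its own features.  This mirrors running the DE analysis separately
per class and is load-bearing: with a composition dichotomy, a chance
imbalance of regimes between groups shifts whole classes coherently, and a
single normalization would convert that shift into hundreds of correlated
false positives.  Per-class normalization absorbs it.

The test itself is deliberately simple: per-group means on the normalized
scale, method-of-moments NB dispersion (floored at $10^{-8}$), per-group
empirical variances (floored at the Poisson variance) feeding a
delta-method standard error of the log2 fold change, a normal reference
for the Wald statistic, and BH adjustment within class.  A small
stabilizer (0.1) in the fold-change ratio guards zero group means; there
is no shrinkage and no dispersion-trend fitting, since numerical agreement
with external DE tools is a non-goal -- the accuracy claims are parameter
recovery and error-rate control on synthetic data (recall $\ge 0.95$,
empirical FDR $\le 0.05$, null $p<0.05$ fraction $\approx 0.054$ under the
default conditions).  The filter ledger keeps $|\log_2 FC| \ge 0.4$ (read
as magnitude, since both directions are reported), FDR $\le 0.05$, and
normalized mean $\ge 5$, after a raw-median $\ge 5$ prefilter in at least
one group.

## Enrichment, survival, longitudinal, taxonomy

**Enrichment.** Presence means raw count > 0; features with raw mean < 1
across compared samples are excluded.  The two-sided Fisher p-value sums
hypergeometric probabilities of tables at most as probable as the observed
one (relative tolerance $10^{-7}$), validated exhaustively against
binomial-coefficient enumeration for all tables with total $\le 40$.  The
odds ratio is the cross-product, with Haldane-Anscombe 0.5 added to every
cell only when a cell is zero so extreme tables stay reportable.  The FDR
gate is $10^{-9}$.

**Survival.** The Cox fitter maximizes the Efron-tie-corrected partial
likelihood by damped Newton iterations to gradient norm $< 10^{-8}$ (cap
100); it matches `survival::coxph` to seven decimals in the cross-check
tests, and its score test at the null equals the log-rank statistic
without ties.  Abundance enters as $\log_2(\text{normalized count} + 1)$,
continuous -- scale-stable, and the mean-split is reserved for the
Kaplan-Meier view as described.  Covariate sets: none (univariate); age at
onset, age at enrollment, sex; plus rD50, ALSFRS, onset type (binary
bulbar/limb).  Riluzole is handled by stratified reruns (`+`, `-`) or
ignored (`both`); strata with too few patients or events are skipped with
a warning.  A feature is kept when the abundance coefficient has
$p \le 0.05$ and either the global LRT or global Wald test has
$p \le 0.05$.

**Longitudinal.** A feature's T1→T4 call is the majority direction across
longitudinal patients, considering only patients where the feature is
nonzero at either timepoint; exact ties count separately and never toward
the majority (the tie rule is this package's choice).  Concordance is a
Fisher test on DE-direction × call (sign mode) and on kept × changed
(survival-membership mode); both constructions are emitted because the
single published construction is ambiguous, and both are computed pooled
and per class.

**Taxonomy.** Group-3 not-itrs recurrent at $\ge 10$ reads in
$\ge 20\%$ of samples are searched by exact substring against the SSU and
LSU databases separately.  Organisms are ranked by distinct-hit count with
lexicographic tie-break (the published "consecutively ranked" is otherwise
nondeterministic), and consecutive organisms agreeing on their first five
semicolon-delimited taxonomy levels merge into one group whose
representative is its best-supported member; group supports are
non-increasing by construction.  Taxonomies shorter than five levels are
padded with `unclassified` and flagged.

## Numerical choices and degenerate inputs

Zero group means in fold changes (stabilizer 0.1); all-censored survival
flagged rather than tested; constant covariates rejected; monotone
partial likelihoods flagged unstable at $|\beta| > 15$; degenerate Fisher
margins are an error at the operation level but reported as $p = 1$ in the
screen (a feature present everywhere is uninformative, not broken);
classes lacking an all-nonzero feature fall back to total-count size
factors.  All generators take explicit seeds, pin the RNG kind, and
restore the caller's RNG state.

## Problem sizes in the shipped tests

The suite runs the default 30+30 x 2000-feature cohort for the DE checks,
120-150 patients x 250-400 features for survival screening, 200 replicates
at n = 400 for Cox coverage, exhaustive Fisher enumeration to table total
40, and 15-30 kb bundles for classification oracles -- sizes chosen so the
whole suite completes in about two minutes while every statistical claim
is still tested at meaningful power.

## Known limitations

The NB test's normal reference is slightly anti-conservative at very small
n; the isomiR caller reports one call per arm (the nearest 5' offset)
rather than all windows; tRNA-half typing uses a fixed loop window rather
than per-tRNA structure; the adapter aligner is exact DP with no
heuristics, so very long reads would be slow; and the taxonomy stage
counts a not-itr toward every organism it hits, which double-counts
fragments conserved across families -- the grouping step exists precisely
to make that interpretable.
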