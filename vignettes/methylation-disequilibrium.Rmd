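---
title: "Methylation disequilibrium, MD blocks and methylecomtype association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation disequilibrium, MD blocks and methylecomtype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdewas)
```

## The model

Array- and sequencing-based methylation assays summarise each CpG locus per
sample as a β-value in [0, 1] (methylated signal over total signal, with a
stabilising offset in the denominator). Neighbouring CpGs are co-regulated:
their methylation states are associated over a range on the order of 1–10 kb.
`mdewas` treats this *methylation disequilibrium* (MD) exactly as population
genetics treats linkage disequilibrium, with one crucial simplification:
because a β-value is a per-sample summary, the multi-locus level combination
of a sample — its *methylecomtype* — is observed directly. No phasing, EM
estimation of haplotype frequencies, or transmission information is needed;
everything reduces to counting.

### Binarization

Each β is thresholded at `T` (default 0.5) into a high (H, `β ≥ T`) or low
(L) methylation level. The tie `β = T` codes as H: "high" is treated as the
closed upper category, and the rule only needs to be uniform and documented.
Binarization discards quantitative information by design — it is what makes
the combination types countable — and `T` is exposed everywhere
(`binarize()`, `ewas()`, the CLI `--threshold`) for sensitivity analysis.

### The MD coefficients

For loci M1, M2 with level frequencies $p_{H_1}, p_{L_1}, p_{H_2}, p_{L_2}$
and joint frequency $p_{H_1H_2}$ (all estimated by direct counting over
samples with a non-missing level at both loci), independence means
$p_{H_1H_2} = p_{H_1}p_{H_2}$, and the raw MD coefficient is the deviation

$$gd = p_{H_1H_2} - p_{H_1}\,p_{H_2}.$$

Since $|gd|$ is bounded by the marginals, it is standardized in the two ways
classical LD analysis standardizes $D$:

$$gD' = \frac{|gd|}{gd_{max}},\qquad
  gd_{max} = \begin{cases}
    \min(p_{H_1}p_{L_2},\, p_{L_1}p_{H_2}) & gd > 0\\
    \min(p_{H_1}p_{H_2},\, p_{L_1}p_{L_2}) & gd < 0
  \end{cases}$$

with $gD' \equiv 0$ at $gd = 0$ (the 0/0 case), and

$$gr^2 = \frac{gd^2}{p_{H_1}p_{L_1}p_{H_2}p_{L_2}}.$$

Both lie in [0, 1]; floating-point overshoot is clamped. When a locus is
monomorphic in the pairwise-complete samples the coefficients are undefined
and the pair is reported uninformative ($gd = 0$, standardized values `NA`).
When both marginals equal 0.5, $gr^2 = gD'^2$ exactly — a useful closed-form
check that the test suite exercises.

### Confidence bounds and the Gabriel block rule

Block finding needs a *classification* of each pair, not a point estimate:
with a handful of samples, $\hat{gD'} = 1$ is weak evidence. Following the
construction that the Gabriel criterion presumes, we place a 101-point grid
$d' \in \{0, 0.01, \dots, 1\}$, evaluate the multinomial log-likelihood of
the observed 2×2 counts under cell probabilities implied by the observed
marginals and $|gd| = d' \cdot gd_{max}$ (with the sign of the observed
$gd$), normalize the exponentiated likelihoods to a discrete distribution
over the grid, and read off one-sided bounds: `ci_low` is the smallest grid
value accumulating 5% of the mass, `ci_high` the smallest accumulating 95%.
The grid step is configurable (`step`); 0.01 matches the conventional
resolution. A pair is

* **strong MD** if `ci_low ≥ 0.70` and `ci_high ≥ 0.98`,
* **strong recombination** (historical LD terminology for clear
  independence) if `ci_high < 0.90`,
* **uninformative** otherwise,

the standard Gabriel/Haploview thresholds, all exposed as arguments. Two
further guards mark pairs uninformative: fewer than two pairwise-complete
samples, and a minor-level frequency below `f_min` (default 0.05, 0
disables) — the analogue of a minor-allele-frequency filter, since
near-monomorphic loci produce unstable classifications.

An *MD block* is a run of contiguous sorted loci whose outermost pair is
strong MD and in which at least `strong_fraction` (default 0.95) of the
informative pairs are strong MD.

### The elastic sliding window

Testing every pair on a chromosome is quadratic and pointless — MD decays
within kilobases — so the genome is scanned with a window of `window` loci
(default 20, the point at which block counts stabilise on real 450K data).
Within a window, candidate regions (strong outermost pair + the 95% rule)
are resolved longest-first, ties to the leftmost start, kept disjoint, and
committed; the scan resumes after the last committed block, or one locus on.

A fixed window would truncate blocks that straddle its border. When a
detected block reaches the window's last locus the window is therefore
re-run once at `elastic_factor × window` loci (default 2×, "doubling"). One
subtlety matters for correctness: the doubled window is anchored at the
*block's first locus*, not at the old window start. A block is committed
while still touching the (extended) window end only when it already starts
at the anchor — i.e. after the doubling has been granted — otherwise it is
deferred and the scan re-anchors at its start. Anchoring at the old window
start instead would truncate even an isolated 30-locus block at whatever
offset it happened to occupy in the window, defeating the extension's
purpose; with re-anchoring, blocks up to exactly `2 × window` loci are
recovered with exact boundaries, and longer blocks are split at the 2×
limit. Windows never span chromosome boundaries. No maximum base-pair gap
is enforced by default (the 1–10 kb decay is an empirical expectation, not
a rule); `max_gap` enables one.

With `elastic_factor = 1` the extension machinery is disabled entirely and
the scan degrades to a fixed-window Gabriel partition.

### Methylecomtype frequencies and association

For each block, every sample with a complete level at all member loci
contributes exactly one pattern (H/L string in locus order); patterns are
reported by descending count, ties lexicographic (H before L). Samples with
a missing level in the block are dropped from that block's table only.
Unknown-status samples (status −1) **do** enter MD estimation and block
finding — disequilibrium is a population property — but never the
association tables.

Each pattern with overall frequency ≥ `min_comtype_freq` (default 0.01, a
floor against vacuous tables) is tested pattern-vs-rest in a 2×2 table
against case/control status: Pearson χ² without continuity correction
(1 df; χ² = 0 reports p = 1), odds ratio $ad/bc$, and the Wald 95% CI
$\exp(\log OR \pm 1.96\sqrt{\sum 1/\text{cell}})$, with the
Haldane–Anscombe +0.5 applied to all four cells whenever any cell is zero.
Raw p-values are the primary output, as is conventional for this scan;
`adjust = "bonferroni"` or `"BH"` appends an adjusted column. A k×2
whole-block test is deliberately not offered — the unit of interpretation
here is the individual methylecomtype.

### Per-locus t test

Independently of the block machinery, `locus_ttest()` performs the familiar
per-CpG two-sample comparison on the *raw* β-values. Welch's unequal-variance
form is the default (group variances of β-values routinely differ;
`var_equal = TRUE` restores the pooled test). It is computed genewise with
vectorised moment formulas and is verified locus-by-locus against
`stats::t.test` in the test suite. Degenerate loci follow documented
conventions: both variances zero with equal means gives t = 0, p = 1; with
unequal means an infinite t and a p floored at the smallest positive double.

## The input dialect and intermediate file

The input is one plain-text matrix: first row, per-sample status codes
(1/0/−1); each further row a locus (name, chromosome, position, one β per
sample). Fields are single-space-, tab- or comma-separated; `NA` (or an
empty CSV field) is a missing β. Loci are sorted by chromosome rank
(numeric ascending, then X, Y, MT, then other labels lexicographically —
`chr` prefixes are ignored for ranking but preserved) and position; the
sort is stable. The sorted data are saved as `out_sort.txt` with one extra
trailing column per row — the binarized level string, `?` for missing — so
the intermediate remains parseable by `read_betas()` (the reader detects
and drops the level column) while supporting downstream custom analyses.
Positions are used exactly as supplied (1-based); BED export converts to
0-based half-open coordinates.

## The synthetic-data generator

`simulate_methylation()` exists so that every stage of the pipeline can be
validated against known truth. It emulates the structure of a 450K
case/control cohort:

* defaults of 354 cases and 335 controls (a typical large EWAS cohort
  composition) and 2 kb locus spacing, inside the 1–10 kb MD-decay range;
* planted blocks: each sample draws a latent pattern from `pattern_freqs`
  and keeps it with probability `within_dprime`, otherwise redraws each
  block locus independently from its group's marginal — for balanced
  two-pattern blocks this makes `within_dprime` the exact pairwise D′, which
  the consistency tests exploit at n = 10⁴;
* planted effects: in cases the odds of each risk pattern are multiplied by
  its `odds_ratio`, so the population case/control odds ratio of carrying
  the pattern equals the planted value;
* β emission: truncated normals on [0, 1] centred at 0.80 (H) and 0.20 (L)
  with sd 0.10 — levels well separated across T = 0.5 but with realistic
  spread. Any emission separating the levels across the threshold would do;
  the parameters (`mu_high`, `mu_low`, `beta_noise_sd`) are exposed.
* non-block loci are independent Bernoulli(0.5) levels.

What the generator does **not** emulate: probe-specific β distributions and
annotations, batch and position effects, cell-composition confounding, and
covariate structure. Passing the planted-recovery suites therefore
demonstrates algorithmic correctness — counting, classification, boundary
logic, effect estimation — not robustness to the artefacts of real arrays,
which the tool (by design) expects to have been handled upstream.

## Numerical and degenerate-input choices

* Likelihood grid: log-probabilities floored at 1e−12 before `log`;
  row-wise normalization by the maximum before exponentiation; cumulative
  masses compared with a 1e−12 slack so grid endpoints are never lost to
  rounding.
* `gD'`/`gr²` clamped to [0, 1]; `gD' = 0` defined at `gd = 0`.
* Candidate ties in a window: longest block, then leftmost.
* Comtype ties: lexicographic with H < L, locale-independent (radix sort).
* Zero-locus files, chromosomes with < 2 polymorphic loci, blocks with no
  complete sample, and all-unknown status inputs all degrade to empty
  results (with messages/warnings), never to errors; genuinely malformed
  input (status outside {1, 0, −1}, β outside [0, 1], ragged rows) errors
  with the offending line or value named.

## Problem sizes used in the validation suites

The shipped suites run planted-block recovery on a 180-locus two-chromosome
genome (blocks of 3–30 loci at 200 samples), association calibration on
5,000 permutation tests at n = 400 with ~50 expected per cell, odds-ratio
recovery over 100 replicates at 500 + 500 samples, and one full-pipeline
run at 689 samples × 20,000 loci (4 chromosomes, file round-trip included),
sizes chosen to exercise every code path — including the elastic extension
beyond the window size — while keeping a complete run of the suite in the
low minutes on a single core.

## Known limitations

* Binarization loses within-level quantitative variation; loci with
  intermediate β distributions straddling `T` will appear noisy.
* The Gabriel thresholds were tuned for SNP LD; they transfer in form, and
  our calibration shows correct null behaviour of the downstream tests, but
  the block definition itself has no significance guarantee.
* No covariate adjustment or logistic modelling; confounded designs need
  upstream correction of the β matrix.
* The association test treats methylecomtypes pattern-vs-rest; rare-pattern
  inference relies on the Haldane correction and is conservative.
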