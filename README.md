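# mdewas

Case/control epigenome-wide association analysis on **combinations** of
DNA-methylation levels, rather than one CpG at a time.

Neighbouring CpG loci are not independent: their methylation levels show
non-random association — *methylation disequilibrium* (MD), the epigenetic
analogue of linkage disequilibrium between SNPs. `mdewas` carries the classic
haplotype-block association framework over to 450K-style β-value matrices:

1. β-values (β ∈ [0, 1]) are binarized at a threshold *T* (default 0.5) into
   high (H) and low (L) methylation levels;
2. for two loci with level frequencies *p*<sub>H1</sub>, *p*<sub>H2</sub> and
   joint frequency *p*<sub>H1H2</sub>, the MD coefficient is
   *gd* = *p*<sub>H1H2</sub> − *p*<sub>H1</sub>·*p*<sub>H2</sub>, standardized
   as *gD′* = |*gd*| / *gd*<sub>max</sub> (with
   *gd*<sub>max</sub> = min(*p*<sub>H1</sub>*p*<sub>L2</sub>, *p*<sub>L1</sub>*p*<sub>H2</sub>)
   for *gd* > 0 and min(*p*<sub>H1</sub>*p*<sub>H2</sub>, *p*<sub>L1</sub>*p*<sub>L2</sub>)
   for *gd* < 0) and
   *gr²* = *gd*² / (*p*<sub>H1</sub>*p*<sub>L1</sub>*p*<sub>H2</sub>*p*<sub>L2</sub>),
   both in [0, 1];
3. chromosomes are partitioned into **MD blocks** with the Gabriel
   confidence-interval rule (strong-MD pairs: one-sided 95% bounds on *gD′*
   with CI<sub>low</sub> ≥ 0.70 and CI<sub>high</sub> ≥ 0.98; a block needs a
   strong outermost pair and ≥ 95% strong pairs among its informative pairs),
   applied through an elastic sliding window (default 20 loci, doubled once
   when a block reaches the window border);
4. within each block, every sample's ordered H/L combination — its
   **methylecomtype** (with *k* loci there are at most 2^*k*; e.g. 2³ = 8 for
   three loci) — is counted, and each methylecomtype is tested for
   case/control association with a Pearson χ² (1 df), odds ratio and 95% CI
   (Haldane–Anscombe +0.5 on tables with empty cells).

A per-locus Welch *t* test on the raw β-values, a synthetic-data generator
with planted blocks and planted effects, and a command-line interface are
included.

## Worked example

Simulate 200 cases and 200 controls with a planted 6-locus block whose
all-high methylecomtype carries an odds ratio of 3, then run the full scan:

```r
library(mdewas)

spec <- synth_spec(
  n_case = 200, n_control = 200,
  chromosomes = list(list(label = "1", n_loci = 100,
                          start_pos = 1e6, spacing_bp = 2000)),
  blocks = list(list(chrom = "1", first_locus = 40, n_loci = 6,
                     within_dprime = 1,
                     pattern_freqs = c(HHHHHH = 0.3, LLLLLL = 0.7))),
  effects = list(list(block = 1, risk_pattern = "HHHHHH", odds_ratio = 3)),
  seed = 42)
sim <- simulate_methylation(spec)
fit <- ewas(sim$data)
fit
#> Methylecomtype association scan
#>   samples: 400 (200 case / 200 control / 0 unknown)
#>   loci: 100; threshold T = 0.5; window = 20 (elastic x2)
#>   MD blocks: 1
#>   methylecomtype tests: 2
#>   strongest associations:
#>       block pattern  chi2  p_value   OR
#> 1 block_1_1  HHHHHH 28.47 9.53e-08 3.01
#> 2 block_1_1  LLLLLL 28.35 1.01e-07 0.33
```

The scan recovered the planted block exactly and found its all-high pattern
in 57.5% of cases vs 31% of controls (χ² = 28.5, OR = 3.01 with 95% CI
[2.00, 4.54] — bracketing the planted odds ratio of 3); the complementary
all-low pattern is correspondingly protective (OR = 0.33). `summary(fit)`
shows the full association rows and `plot(fit)` draws −log₁₀(p) per block.

Running from a file instead: `ewas("betas.txt", out_prefix = "run/out")`
reads the plain-text input dialect (first row: per-sample status codes
1/0/−1 for case/control/unknown; then one row per locus: name, chromosome,
position, and one β per sample), and writes `out_sort.txt` (the sorted,
binarized intermediate), `out_blocks.tsv` and `out_assoc.tsv`.

### Command line

```sh
Rscript exec/ewas.R ewas        --input betas.txt --out-prefix run/out
Rscript exec/ewas.R coefficient --input betas.txt --out-prefix run/out   # pairwise gD'/gr2
Rscript exec/ewas.R block       --input betas.txt --out-prefix run/out   # blocks only
Rscript exec/ewas.R ttest       --input betas.txt --out-prefix run/out   # per-locus Welch t
```

(`-ewas` etc. are accepted as aliases; see `--help`-style usage on error.
Setting every status to −1 in the input likewise yields block-only output.)

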