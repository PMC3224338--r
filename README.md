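# estsurvey

Diagnostic analyses for de novo EST survey sequencing — the statistics a
transcriptome project runs when there is no reference genome to lean on.

When a species' transcriptome is surveyed by long-read EST sequencing
(454/Roche GS20 or GS FLX libraries from several tissues, some of them
normalized by duplex-specific nuclease), the assembly into unigenes is
only the start. The questions that determine whether the resource is any
good are statistical: Was sequencing deep enough to tag essentially every
expressed gene? How much of the striking unigene redundancy is allelic or
paralogous variation, and how much is sequencing error? Did normalization
deliver more genes, and did it destroy quantitative information? Did an
aggressive second assembly pass create chimeras? Which functional
categories does each library over-represent? This package implements the
full set of analyses for researchers running or evaluating such surveys,
plus a ground-truthed synthetic 454-style library generator used to
validate every stage.

## What's inside

| Stage | Functions | Method |
|---|---|---|
| Read clean-up | `clip_masked()`, `filter_library()` | longest clear segment of masked reads, >= 50 nt filter |
| Gene tagging | `read_hits()`, `assign_best_hit()`, `build_profile()` | best BLAST-style hit, e <= 1e-4, max bit score |
| Coverage summaries | `proteome_coverage()`, `terminal_window_bias()` | interval union per subject; 5'/3' 100-residue windows |
| Rarefaction | `build_curves()`, `expected_detections()` | subsampling without replacement + exact hypergeometric oracle |
| Saturation | `fit_hyperbola()`, `slope_at()` | Levenberg-Marquardt fit of y = ax/(b+x) |
| Redundancy | `pileup_columns()`, `classify_positions()` | per-column variant/error classification from SAM |
| Normalization | `spearman_profiles()`, `compare_matrix()` | Spearman of count profiles, union gene universe |
| Chimera proxy | `annotation_retention()` | annotation loss across assembly passes |
| Enrichment | `enrich_categories()`, `enrichment_matrix()` | Fisher's exact, BH FDR, signed z matrix |
| Simulation | `sim_config()`, `generate_reads()`, ... | Zipf expression, gamma-flattening, homopolymer errors |

The core quantitative model is the saturation hyperbola for gene
discovery. With `y` the number of reference genes tagged at least `k`
times by a random subsample of `x` reads,

    y = a x / (b + x),        dy/dx at x_f = a b / (b + x_f)^2

where `a` is the asymptotic number of detectable genes, `b` the
half-saturation read count, and the derivative at the library's final
read count `x_f` — genes gained per additional read — is the
completeness verdict. The redundancy classifier works per alignment
column: a shared variant (>= 25 identical point mutations, or >= 4
identical in-frame indels) is a putative allele or paralog; anything
below threshold, or any out-of-frame indel, is a putative sequencing
error.

## Worked example

Simulate a normalized library, profile it, rarefy, and fit:

```r
library(estsurvey)

cfg <- sim_config(n_genes = 500, n_reads = 20000, seed = 7)
tx  <- build_transcriptome(cfg)
w   <- draw_weights(tx, cfg)
lib <- generate_reads(tx, setNames(w$norm_weight, w$gene_id), cfg,
                      library = "LVN.1")

prof <- build_profile(lib$truth$reads, "LVN.1")
head(prof, 3)
#>   library gene_id count
#> 1   LVN.1   g0384   958
#> 2   LVN.1   g0440   610
#> 3   LVN.1   g0036   431

pool <- read_pool(prof)
curves <- build_curves(pool, thresholds = c(1, 5), reps = 5, seed = 7)
fit_hyperbola(curves[curves$k == 1, ])
#> saturation fit y = ax/(b+x): a = 597 genes, b = 599 reads
#>   R^2 = 0.9922; slope at final read count (20000) = 0.0008 genes/read

expected_detections(pool, c(1000, 10000, 20000), k = 1)
#> [1] 377.8299 551.8789 552.0000
```

Reading: the pool holds 552 distinct genes (the transcriptome also
carries paralog copies); the fitted asymptote of ~597 estimates what
unlimited sequencing of this library could tag; the final slope of
0.0008 genes/read says this library is sequenced nearly to exhaustion —
a thousand more reads would find less than one new gene. The last line
is the exact expectation behind the Monte-Carlo curve.

The numbered scripts under `analysis/` run the complete workflow on a
four-library simulated survey (three normalized, one not, two
platforms): `01_simulate_libraries.R` through `06_compare_enrich.R`,
writing tables under `results/`. They reproduce the survey's qualitative
findings on synthetic data: the non-normalized library's detection
asymptote falls well short of the normalized ones', rank correlations
between normalized and non-normalized profiles land around 0.7, and
abundance-linked categories show the non-normalized library
over-representing abundant transcripts.

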