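---
title: "Diagnostics for de novo EST surveys: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostics for de novo EST surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estsurvey)
```

# The problem

A de novo transcriptome survey of a species without a reference genome —
classically a 454/Roche EST project — produces hundreds of thousands of
reads, an assembly into "unigenes" (contigs plus singletons), and a set of
nagging questions that the sequence data alone cannot answer directly:

* **Completeness.** Did sequencing tag essentially every transcript
  expressed in the sampled tissues, or would more reads keep finding new
  genes?
* **Redundancy.** Why do some reference genes attract hundreds or
  thousands of distinct unigenes? How much of that redundancy is biology
  (alleles, recently duplicated paralogs) and how much is sequencing
  error that defeated the assembler?
* **Normalization.** Did duplex-specific-nuclease normalization of the
  cDNA achieve its goal (more genes tagged at equal depth), and did it
  destroy the quantitative signal, or only flatten it?
* **Assembly quality.** Did a more aggressive second assembly pass merge
  redundant unigenes, or did it fuse unrelated transcripts into chimeras?
* **Representation.** Which functional categories does each tissue
  library over- or under-represent?

This package implements the statistical machinery for all five questions,
together with a fully ground-truthed generator of synthetic 454-style
libraries used to validate every stage end to end. The numbered scripts
under `analysis/` run the whole workflow on simulated libraries and write
their tables under `results/`.

# Gene discovery: rarefaction and the hyperbolic saturation model

The completeness question is answered by rarefaction: from the pool of all
reads assigned to reference genes, draw random subsets of increasing size
$n$ and record $y(n)$, the number of genes tagged at least $k$ times
($k \in \{1, 5, 10, 100\}$). Sampling is without replacement — the pool is
a finite, existing read set, not an infinite population.

Two independent routes to the same curve are implemented:

* `subsample_detections()` draws actual subsamples (default 10 replicates
  per grid point, 20 geometrically spaced sizes ending at the full pool);
* `expected_detections()` computes the exact expectation
  $E[y(n)] = \sum_g P(X_g \ge k)$ with
  $X_g \sim \mathrm{Hypergeometric}(N, c_g, n)$, where $c_g$ is gene $g$'s
  read count.

The Monte-Carlo route is what a practitioner plots; the closed form is the
oracle the test suite holds it to (agreement within 3 standard errors at
every grid point, with a small absolute floor of 0.1 detections for grid
points where the subsample is nearly deterministic and the replicate SE
estimate collapses).

Detection curves are summarized by the two-parameter hyperbola

$$y = \frac{a\,x}{b + x},$$

where $a$ is the asymptote (genes detectable at unlimited depth) and $b$
the half-saturation read count. Completeness of a library with final read
count $x_f$ is read off the analytic slope

$$\left.\frac{dy}{dx}\right|_{x_f} = \frac{a\,b}{(b + x_f)^2}
\quad\text{(genes per additional read):}$$

a slope near zero means further sequencing of that library would find
almost nothing new. `slope_at()` is this derivative; the test suite checks
it against finite differences and against a published completeness table
whose printed slope column it reproduces to all four printed decimals for
all thirteen rows (`pea_saturation_fits()`).

**Fitting.** `fit_hyperbola()` uses Levenberg–Marquardt least squares
(minpack.lm) with starts $a_0 = 1.2\,\max y$ and $b_0$ the linearly
interpolated $x$ at which the curve crosses $a_0/2$ (median $x$ if it
never does). Convergence: relative tolerances of $10^{-10}$ on parameters
within 500 iterations; $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ about the
mean. Replicated curves are averaged per sample size before fitting —
single-draw curves are also accepted. On data the model cannot describe
(for example a $k \ge 5$ curve from a shallowly sequenced flattened
library, which is still convex over the observed range) the fit returns
`converged = FALSE` with absent parameters rather than a misleading
number. Parameter recovery was verified on binomially noised curves at
survey-like depths: median relative error on $(a, b)$ below 5% over 50
simulations, median $R^2 > 0.99$.

The `final_x` convention matters: the slope column of a completeness
table is reproduced exactly when $x_f$ is the library's total read count
entering the analysis, and that convention is fixed here.

# Redundancy: classifying alignment columns

When the unigenes matching one reference cDNA are aligned back to it
(SAM input, e.g. from BWA-SW), every covered reference position is
classified:

* **identical** — covered, and no variant event at all;
* **putative biological variant** — some substitution allele (same base
  at the same position) shared by at least 25 unigenes, or some identical
  in-frame indel (length divisible by 3) shared by at least 4. Wide
  sharing of the identical change is implausible under independent
  sequencing error, and in-frame indels are what selection tolerates in
  coding sequence;
* **putative sequencing error** — any substitution allele observed but
  below the support threshold, or any out-of-frame indel.

The variant and error flags can co-occur at one position (different
alleles at the same column), so the percentage columns of a per-reference
report may legitimately sum above 100. Thresholds (25 substitutions,
4 in-frame indels, modulus 3) live in `classifier_thresholds()`. Two
conventions were genuinely open and are documented toggles:

* "identical" means *all covering unigenes carry the reference base*
  (references are same-species Sanger cDNAs, so agreement with the
  reference is the natural baseline), not merely "unigenes agree with
  each other";
* an in-frame indel *below* its support threshold contributes to
  neither class by default — the error rule names only out-of-frame
  indels — with `inframe_below_threshold_as_error = TRUE` to count it as
  error instead;
* "identical variants" groups events at allele level: substitutions by
  (position, base), insertions by (anchor position, inserted sequence),
  deletions by (position, length), with every deleted position receiving
  its deletion event and insertions anchored to the reference position
  immediately 5' of the inserted bases.

`pileup_columns()` walks CIGAR strings itself because the classifier
needs insertion events keyed by their inserted sequence, which standard
pileup engines do not expose. It is held, in the tests, to a brute-force
oracle that materializes the full query-by-position alignment matrix on
randomized toy alignments, and to an end-to-end recovery check: on
simulated mixtures of two haplotypes (60 near-full-length unigenes, 0.5%
random error), all planted variant positions are flagged as variants and
the flagged error positions are planted errors, across 20 seeds. For such
mixtures the substitution support floor is scaled to the mixture's depth
(10 at ~35x coverage), preserving the published threshold's intent — "too
widely shared to be error" — at a depth where 25 would exceed the number
of haplotype-2 unigenes covering a column.

# Normalization assessment and the chimera proxy

Whether normalized libraries retain expression information is measured by
the Spearman rank correlation between per-gene read counts of library
pairs (`spearman_profiles()`). The gene universe is the union of genes
detected in either library, absent genes entering as zero — the only
choice that penalizes detection dropout, which is precisely what
normalization is supposed to cause for abundant genes' competitors. An
intersection policy is available; ties take average ranks.

The chimera proxy (`annotation_retention()`) needs no alignment of
assemblies to each other: if an assembly pass creates chimeric contigs,
distinct reference-gene annotations disappear. Retention of a pass is the
fraction of the genes tagged at read level that the pass's unigenes still
tag; genes a pass gains that the reads never tagged do not count.

# Category enrichment

`enrich_categories()` tests each functional category (MapMan-bincode-like
dotted hierarchical codes, propagated so membership in `29.5.3` implies
`29.5` and `29`) by Fisher's exact test on the 2x2 table of test-set
versus background-set membership, with the background supplied explicitly
(the union of gene sets relevant to the comparison). Two-sided p-values
use the point-probability convention (sum of all tables no more probable
than the observed one) — the convention of `stats::fisher.test` and of
the tools this analysis style descends from; the tests verify it against
exhaustive hypergeometric enumeration for backgrounds up to 60 genes.
Benjamini–Hochberg correction is applied per library column (one matrix
column = one family), with an uncorrected variant (`fdr = FALSE`) for
exploratory views. For heatmap rendering, p-values become signed z-scores
$z = \pm\Phi^{-1}(1 - p/2)$ (positive = over-represented), so $p = 0.05$
maps to $\pm 1.96$; $|z|$ is capped at 10 to keep vanishing p-values
plottable.

# The synthetic library generator

`sim_config()` / `build_transcriptome()` / `draw_weights()` /
`generate_reads()` emulate the data-generating process every downstream
stage assumes, with complete ground truth (per-read source gene,
haplotype, coordinates, planted errors; per-gene weights and realized
counts). What it models, and why:

* **Transcriptome.** 2000 genes of 500–3000 nt (uniform), i.i.d. random
  sequence. With probability 0.3 a gene carries a second haplotype at
  0.5% divergence (allelic variation in an outbred seed lot); with
  probability 0.1 a diverged duplicate (3%) is emitted as a separate gene
  sharing a paralog group.
* **Expression.** Zipf (discrete power law) over a random permutation of
  the genes: a handful of genes dominating a leaf library is exactly the
  few-genes-dominate pattern such surveys report. A log-normal
  alternative is available.
* **Normalization.** Weight exponentiation $w \mapsto w^\gamma$,
  renormalized; $\gamma = 1$ is no normalization, $\gamma = 0$ complete
  flattening. No mechanistic model of duplex-specific-nuclease kinetics
  is attempted.
* **Reads.** Lengths Gaussian per platform (GS20: 100 +/- 10 nt;
  GS FLX: 230 +/- 20 nt), truncated to the transcript. Start positions
  decay geometrically from the 3'-most feasible start (rate
  `three_prime_lambda`, default 0.005 — a mild bias, matching poly-dT
  priming with little observed 5' depletion); 0 gives uniform starts,
  verified by chi-square goodness of fit. Substitutions are planted per
  base (0.008); each homopolymer run of length $L \ge 2$ gains or loses
  one unit with probability $0.02\,(L-1)$, concentrating indels in
  homopolymers as pyrosequencing does and contributing roughly 0.002
  events per base, for a total error rate of about 1%. Reads are emitted
  on the sense strand (the libraries being modelled were oriented).
* **Contamination.** Optionally a lowercase 20-nt primer prefix on a
  configurable fraction of reads, exercising the masked-read clean-up.

**Calibration.** The published tables constrain the generator only
indirectly, through two reproduction targets: the Spearman correlation
between normalized and non-normalized profiles of one tissue
(printed range 0.697–0.762) and the detection shortfall of the
non-normalized library (asymptote ratio roughly 0.75, realized detection
ratio roughly 0.64). A Zipf exponent of 1.0 turned out to be too flat to
produce any meaningful dropout at feasible simulated depths, making the
second target unreachable; the defaults were therefore set jointly —
exponent 1.5, $\gamma = 0.45$, assessed at 80 000 reads per library over
2000 genes (a ~1/8-scale version of a 200 000-read library over a
17 000-gene universe) — and then frozen. Under these conditions the
acceptance tests find the normalized/non-normalized correlation inside
[0.65, 0.80], bracketing the printed range, and a strictly higher fitted
$k = 1$ asymptote for the normalized library. These defaults reproduce
the published statistical structure; they are not a claim about pea
biology.

**Determinism.** One master seed; every stage derives fixed substreams
(`seed + 1` for weights, `seed + 2` for reads, per-library offsets in the
orchestrated run). Identical configuration gives byte-identical FASTA and
truth files, which the test suite asserts.

# Read clean-up conventions

`clip_masked()` keeps the longest contiguous clear segment of a read
(uppercase `ACGT`; lowercase, `X`, and by default `N` count as masked)
and discards the read if that segment is shorter than 50 nt. Keeping the
longest segment — rather than splitting at internal masks or keeping the
first segment — maximizes usable sequence; the choice only matters for
reads with internal masked blocks, and it is documented here because the
original procedure did not specify it. Quality arrays, when present, are
sliced to exactly the retained window and never re-scored. Clean-up is
idempotent, and ties between equally long segments go to the 5'-most.

# Best-hit tagging conventions

`assign_best_hit()` keeps, per query, the hit with e-value at most 1e-4
and the highest bit score; ties break by lower e-value, then
lexicographically smallest subject id, making output order-independent.
Subject ids of the form `GENE.n` are collapsed to the locus by default
(detection is counted per gene, not per splice form) with a toggle.
Tabular input follows the 12-column BLAST convention (1-based inclusive
coordinates, minus-strand subject intervals given end-first and
normalized on read); internal intervals are handled by IRanges.
`proteome_coverage()` unions subject intervals per reference protein;
`terminal_window_bias()` counts queries overlapping the first/last 100
residues, the diagnostic for 3'-biased coverage.

# What the simulation does and does not show

Passing tests on simulated libraries demonstrate that every stage
computes what it claims on data with known truth: exact profile recovery,
oracle-level agreement of rarefaction and classification, fitted
asymptotes that track true detectable-gene counts, correlation structure
matching the calibration targets. They do not demonstrate that real pea
libraries satisfy the generator's assumptions: real transcriptomes have
correlated base composition, expression is not exactly Zipf, real
normalization is sequence-dependent rather than a clean power transform,
chimeric reads and structural error modes are absent (flowgrams, quality
scores, and chimera simulation are out of scope), and paralog families
here have at most two members. Conclusions about real data should lean on
the per-stage contracts, not on the simulator's resemblance to any
particular organism.

# Known limitations

* The hyperbola is the only saturation model offered; richness
  estimators (Chao) and sigmoid alternatives are out of scope, and for
  pre-inflection curves the hyperbola is declared non-converged rather
  than approximated.
* The pileup reader handles the SAM operations an EST-to-cDNA aligner
  emits (M/I/D/S/H/N/=/X, one reference at a time); it is not a general
  BAM engine and ignores base qualities.
* Fisher enrichment on flat term lists only: graph-aware decorrelation
  of hierarchical ontologies (topGO-style weighting) is deliberately not
  reimplemented; propagated dotted codes are tested as plain categories.
* `spearman_profiles()` refuses universes smaller than 3 genes and flags
  constant profiles as undefined rather than returning a number.
* Recovering absolute expression from normalized counts is not
  attempted anywhere; the package only measures what normalization
  preserved.

# Problem sizes used in the checks

The shipped tests and the analysis scripts run at deliberately modest
scale, chosen as the smallest sizes at which each property is stable:
oracle comparisons on pools of tens of genes and toy alignments up to 20
bp; parameter recovery on 18-point curves at depths to 250 000; the
normalization properties on one 2000-gene transcriptome sampled at
80 000 reads per library; haplotype-mixture recovery on 60–80 unigenes
over 600–900 nt references, 20 seeds. The same functions run unchanged at
full survey scale.
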