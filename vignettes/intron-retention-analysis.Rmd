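---
title: "Intron-retention marker discovery: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intron-retention marker discovery: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irmarker)
```

`irmarker` treats intron retention (IR) as a quantitative, testable signal:
each retained-intron event in each sample yields an inclusion junction count
$I$ and a skipping junction count $S$, and the analysis asks whether the
underlying intron ratio differs between subject groups, recovers under
treatment, and marks out genes that wire into functional pathways. This
vignette explains the models behind each stage, the defaults and why they
are what they are, what the synthetic generators do and do not emulate, and
the numerical choices a maintainer should know about.

## The intron ratio and its filter

The intron ratio of an event is the length-adjusted inclusion fraction

$$\psi = \frac{I / L_I}{I / L_I + S / L_S},$$

where $L_I$ and $L_S$ are the effective lengths of the read forms that can
generate inclusion and skipping reads. The length adjustment matters
because an intron-containing form offers more alignable positions than the
skipped junction; with $L_I = L_S$ the ratio reduces to $I/(I+S)$, which is
also what the simulators produce (they draw counts directly at the
read-form level, so unit lengths are the internally consistent choice).

A cell (event × sample) enters any analysis only when $I + S > 10$, the
strict coverage rule (`coverage_min = 10`, per cell). The per-cell
interpretation was chosen over a mean-coverage interpretation because it is
the only one that guarantees every ψ that reaches a test is individually
well-measured; it is configurable. An event enters a two-group test only
when at least two samples pass per group — the minimum for any
replicate-aware test.

Ordination (PCA by SVD of the column-centered ψ matrix; classical MDS on
Euclidean distances, which is its exact dual on a complete matrix) drops
events with any missing ψ rather than imputing. Imputation would have to
invent a model for exactly the cells the coverage filter flagged as
unreliable, and would leak that model into the group-separation claims the
ordination is meant to support.

## The differential-IR test

Counts are modelled beta-binomially: given total $n$, the inclusion count
is $I \sim \mathrm{BetaBin}(n, \theta, \rho)$ with mean $\theta$ and
intra-class correlation $\rho$, parameterized as
$\alpha = \theta(1-\rho)/\rho$, $\beta = (1-\theta)(1-\rho)/\rho$ — the
standard ICC form, so $\rho \to 0$ is the pure binomial and $\rho$ is
directly the excess-variance fraction. The null model fits one $\theta$ and
one $\rho$ to both groups; the alternative fits group-specific $\theta$
with a shared $\rho$. Both are maximized by bounded quasi-Newton iteration
on logit-transformed parameters from two starts (a moment start and a
near-binomial start), with $\rho$ floored at $10^{-6}$ to avoid the
boundary. The test statistic is $2(\ell_1 - \ell_0)$; a grid-search oracle
in the test suite confirms the optimizer reaches the same maxima to
$10^{-3}$.

**Reference distribution.** The statistic's asymptotic reference is
$\chi^2_1$, but at the replicate counts this design targets (6–8 subjects
per group) that reference is measurably liberal: on null simulations at the
design conditions (2 × 8 samples, depth 50, $\rho = 0.01$) the empirical
p < 0.05 rate sits near 0.07 rather than 0.05. The default reference is
therefore $F(1, m-2)$ with $m$ the total number of samples — the same style
of small-sample denominator correction that quasi-likelihood F-tests apply
in count regression — which brings the rate to ≈ 0.045 while costing little
power. `reference = "chisq"` restores the asymptotic p-value.

**Calling rule.** An event is significant when
(p < 0.05 **or** FDR < 0.1) **and** $|\Delta\psi| > 0.05$, with
$\Delta\psi$ the difference of group means of per-sample ψ (second group
minus first). The effect gate is applied post hoc to a point-null test; a
composite-null test of $|\Delta\psi| > 0.05$ would be a different (and
stricter) statistic, and is out of scope. The FDR procedure is
Benjamini–Hochberg. Output ordering is deterministic: p ascending, ties by
$|\Delta\psi|$ descending, then event id.

Gene-level roll-up: only-IncIR genes are IncIR, only-DecIR genes DecIR,
and genes carrying both directions are `Mixed`; non-significant events are
ignored. Both event-level and gene-level tables are exposed, since
published counts are sometimes by locus and sometimes by gene.

## Differential expression

TMM scaling factors follow the trimmed-mean construction: reference = the
sample whose upper quartile is closest to the mean upper quartile; genes
zero in either sample removed; M (log2 ratio) doubly trimmed at 30% with A
(mean log2 abundance) trimmed at 5%; precision-weighted mean of the
surviving M values; factors rescaled to geometric mean 1. Ratios are taken
on raw counts, so the factors absorb sequencing depth as well as
composition — a library sequenced twice as deep recovers a factor of 2 —
and the expression offset is therefore the log factor (put on a mean
library scale), not depth × factor, which would count depth twice. On
equal-depth data this convention coincides with edgeR's composition-only
factors, which the test suite uses as an independent cross-check.

The per-gene test is a negative-binomial likelihood-ratio test with a
single common dispersion estimated across genes by adjusted-profile-
likelihood maximization; the fit is delegated to edgeR
(`estimateGLMCommonDisp`, `glmFit`, `glmLRT`). Common rather than tagwise
dispersion is the minimal defensible model here and keeps the test
desk-verifiable; empirical-Bayes shrinkage is deliberately not layered on.
Genes with counts-per-million ≤ 1 in more samples than the smaller group
size are filtered before testing (configurable, logged). DEGs are called
by (p < 0.05 or FDR < 0.1) and FC > 1.2, strict inequality — FC exactly
1.2 is not called, and on the log2 scale the gate is 0.263.

## Recovery across three groups

In a control → pre-treatment → post-treatment design, the two legs
(control vs pre, pre vs post) are run with identical thresholds, and each
common event is classified by Venn intersection: IncIR-then-DecIR is a
reverse-V (the ratio rose with the condition and fell back under
treatment), DecIR-then-IncIR a V, everything else `none`. Recovery is
defined at the locus level; gene roll-up is available separately. Each
recovered locus additionally gets a one-way fixed-effects ANOVA on
per-sample ψ across the three groups, with Tukey HSD pairwise comparisons
attached when the omnibus p < 0.05 (standard gatekeeping). Per-sample ψ —
rather than pooled-count ratios — was chosen so the ANOVA sees the same
replicate structure the primary test does.

## Network link enrichment

The interactome is an undirected, score-weighted edge list filtered at
confidence ≥ 0.7 (inclusive at the cutoff; scores on a 0–1000 dialect are
auto-rescaled when any score exceeds 1), deduplicated to the best score
per pair, self-loops removed. The statistic is the total number of
distinct links from a query set (e.g. IR genes) to a target functional set,
and its null is built from K equal-size gene sets drawn uniformly without
replacement from the network nodes outside the target set (the query and
target panels are laid out disjointly in this analysis; the universe is
configurable). The empirical p-value is the add-one estimate
$(\#\{T_{null} \ge T_{obs}\} + 1)/(K + 1)$, so it is never zero and is
exactly $1/(K+1)$ when the observation beats every null draw.

K defaults to 999. The study design this generalizes used only 5 random
sets yet quoted a p-value below $1/6$, so its test must have been
parametric and is not reproducible from the text; this package makes the
permutation p primary and additionally reports a normal-approximation
z-test (observed vs null mean/sd) when K ≥ 30. Neither claims to
reproduce the original figure's p-value.

## Overlap statistics

Fold enrichment of two gene sets over a background of $N$ genes is
$k N / (n_A n_B)$ — observed overlap over its expectation under
independent uniform draws. The background must be stated by the caller
(4,546 annotated IR-capable loci for IR comparisons, 22,000 genes for
expression comparisons, both overrideable): fold enrichment is meaningless
without it, which is why the argument has no silent default. The p-value
is the upper-tail hypergeometric by default (the enrichment question is
one-sided); Fisher's two-sided p is available. Matching is by exact,
case-sensitive symbol; alias resolution is a documented non-goal, so
cross-study comparisons should pre-harmonize symbols.

## The synthetic generators

`simulate_ir_counts()` draws, per cell, a total depth
$n \sim \mathrm{NB}(\mu = 50, \text{dispersion} = 0.3)$ and an inclusion
count $I \sim \mathrm{BetaBin}(n, \psi_g, \rho)$; baseline ψ is
Beta(2, 6) (mean 0.25, the moderate ratios typical of retained introns
passing a coverage filter), planted events shift by ±Δψ in the second
group with clamping to [0.01, 0.99], and a third group reverts planted
events to baseline — the reverse-V/V trajectory — for a configurable
fraction (default all). Group sizes default to 6 control + 8 case (+ 8
post-treatment paired with case); an optional per-subject logit-normal
random effect (default sd 0) is shared between the paired groups. The
within-group overdispersion of real cohorts is not published for this
design; ρ = 0.01 is our default and is exposed in the scenario. The
generator matches the test's assumed model *by construction* — so
calibration results validate the inference machinery, not the model's fit
to real junction counts, where trans effects, correlated events within a
gene, and mapping artifacts all exist and are not emulated. No read-level
or sequence-level structure is simulated.

`simulate_expression()` uses log-normal baseline means (mean 100),
NB(dispersion 0.1) counts, library-size multipliers, and an even up/down
split of planted log2 fold changes. `simulate_interactome()` is an
Erdős–Rényi background with independent extra query–target edges and
scores uniform on [0.7, 1]; `build_sets_with_overlap()` constructs gene
sets hitting exact Venn-region counts, used to reconstruct printed
cross-study overlaps.

## Problem sizes and determinism

The shipped calibration and power analyses use 2,000 null events × 3
seeds, 400 events for power (8 vs 6 at depth 100), 500 events for recovery
(50 planted), 50 replicate null graphs (+20 under excess connectivity;
n = 300, edge probability 0.01), and 2,000 genes for the expression
checks — sizes at which every Monte-Carlo band in the test suite is
narrow relative to its acceptance interval while the whole suite stays
interactive. All generators take an explicit seed and are byte-identical
under it; the demo driver (`ir_demo()`) derives all stage seeds from one
master seed with a fixed linear rule.

## Known limitations

- The beta-binomial test assumes a shared ρ across groups and events'
  independence; genes with several correlated events will look more
  significant at the gene level than they should.
- The |Δψ| gate is post hoc, not a composite-null test, so very deep data
  can call effects barely above 0.05 with near-zero p.
- TMM's depth-absorbing convention differs from edgeR's; factors from the
  two are comparable only after removing the depth component.
- Overlap arithmetic trusts the caller's background size and symbol
  harmonization.
- The permutation null draws query sets uniformly, ignoring degree
  structure; a degree-matched null would be stricter for hub-heavy query
  sets.
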