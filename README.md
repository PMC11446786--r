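# irmarker

Intron retention (IR) — an intron left in a mature transcript — is not just
splicing noise: the set of genes whose IR shifts under stress behaves like a
panel of physiological sensors, and shifts in IR have been proposed as
blood-based markers of depressive states that out-perform ordinary
differential expression. `irmarker` implements that marker-discovery
analysis as a tested, reusable R pipeline operating on junction read
counts, for transcriptomics researchers who want to quantify IR, test it
between subject groups, track its recovery under treatment, and ask whether
IR genes preferentially wire into functional gene sets.

The pipeline covers six connected analyses:

1. **IR quantification** — the length-adjusted intron ratio
   ψ = (I/L_I) / (I/L_I + S/L_S) from inclusion (I) and skipping (S)
   junction reads, with a per-cell coverage filter (keep I + S > 10) and
   PCA/MDS sample ordination on the ψ matrix.
2. **Differential IR** — a replicate-aware beta-binomial likelihood-ratio
   test per intron event (group-specific ψ, shared intra-class correlation
   ρ), Benjamini–Hochberg FDR, and the dual calling rule
   (p < 0.05 **or** FDR < 0.1) **and** |Δψ| > 0.05, giving IncIR/DecIR
   events and IncIR/DecIR/Mixed genes.
3. **Differential expression** — TMM scaling factors and a
   negative-binomial likelihood-ratio test (common dispersion, via edgeR)
   under the rule (p < 0.05 or FDR < 0.1) and FC > 1.2
   (equivalently |log2FC| > 0.263).
4. **Recovery classification** — in a control → pre-treatment →
   post-treatment design, loci that rise then fall (reverse-V) or fall then
   rise (V) across the two differential-IR legs, plus per-locus one-way
   ANOVA with Tukey HSD.
5. **Network link enrichment** — distinct-neighbor link counts between a
   query gene set and a functional target set on a score-filtered (≥ 0.7)
   protein–protein interaction network, ranked hub tables, and an
   equal-size random-set permutation null with the add-one empirical
   p-value (#{null ≥ observed} + 1) / (K + 1).
6. **Overlap statistics** — fold enrichment
   FE = k·N / (n_A·n_B) of two gene sets over a stated background N,
   upper-tail hypergeometric / Fisher p-values, and exact three-set Venn
   partitions.

A synthetic-data module generates every input the pipeline consumes —
beta-binomially overdispersed junction counts with planted Δψ effects,
negative-binomial expression with library-size structure, interactomes with
planted excess connectivity, and gene sets with exact Venn-region counts —
with ground truth attached, so calibration and power of each stage are
measurable without any sequencing data.

## Worked example

Simulate a 6-control vs 8-case study with 10% of 500 intron events planted
in each direction (Δψ = 0.3), then test:

```r
library(irmarker)

scenario <- ir_scenario(
  n_events = 500, groups = c(CON = 6, BMT = 8),
  frac_inc = 0.1, frac_dec = 0.1, delta_psi = 0.3,
  depth_mean = 80, seed = 101)
sim <- simulate_ir_counts(scenario)

fit <- diff_ir(sim$counts, "CON", "BMT")
fit
#> Differential intron retention: BMT vs CON
#>   500 events tested, 57 IncIR, 54 DecIR (0 skipped)

head(tidy(fit), 4)
#> # A tibble: 4 × 10
#>   event_id gene   psi_mean_a psi_mean_b delta_psi  stat   p_value q_value
#> 1 ev00049  g00049     0.500     0.850       0.350  40.7 0.0000349 0.00240
#> 2 ev00069  g00069     0.241     0.00376    -0.237  40.2 0.0000372 0.00240
#> 3 ev00054  g00054     0.277     0.0112     -0.266  38.8 0.0000438 0.00240
#> 4 ev00022  g00022     0.0836    0.386       0.302  38.2 0.0000472 0.00240
```

Of the 100 planted events, 111 calls are made (57 IncIR, 54 DecIR; the
extras are borderline nulls at depth 80): `delta_psi` is the case-minus-
control difference in mean intron ratio, `p_value` the beta-binomial LRT
p, and `call` the thresholded direction. `classify_genes(fit)` rolls the
calls up to genes (`Mixed` = a gene carrying both directions).

The printed cross-study comparison is one call: two IR gene lists of 497
and 346 genes sharing 94, judged against a 4,546-locus background,

```r
sets <- build_sets_with_overlap(4546, c(a_only = 403, b_only = 252, ab = 94))
overlap_test(sets$sets$A, sets$sets$B, 4546)
#>     n_a   n_b     k background_n expected fold_enrichment fisher_p
#> 1   497   346    94         4546     37.8            2.48 9.79e-19
```

a 2.5-fold enrichment over the 37.8 overlapping genes expected by chance —
IR gene sets from independent depression cohorts overlap far more than
random.

Each result type has `tidy()`/`glance()` methods and an `autoplot()`
(ordination scatter, Δψ volcano, expression volcano, permutation-null
histogram, recovery trajectories). `ir_demo(dir, seed)` runs the whole
synthetic pipeline end to end and writes self-describing TSV outputs.

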