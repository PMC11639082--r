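# mavemap

Scoring, quality filtering, and clinical calibration of multiplexed
variant effect maps from tile sequencing.

Deep mutational scans couple a selection assay (for example, a human
disease gene complementing a deletion phenotype in yeast under genotoxic
stress) with high-depth sequencing of short tiles spanning a mutagenized
ORF, before and after selection. The hard part is downstream: turning
noisy per-codon counts into a variant effect map a clinical lab can use.
`mavemap` is for analysts building or auditing such maps. It covers the
full path from marginal counts to ACMG/AMP evidence strengths, and ships
a synthetic-data generator with known ground truth so every stage is
testable without any raw sequencing data.

## The model

For codon change *v*, replicate *r*, with marginal counts *k* over
effective depths *d* (frequencies φ = k/d), the wild-type-corrected
enrichment log ratio is

    log φ_vr = log[ (φ_post − φ_wt) / (φ_pre − φ_wt) ]

with a floor of half a pseudo-read on the corrected post frequency, then
rescaled per replicate so the synonymous median maps to 1 and the
nonsense median to 0:

    s_vr = (log φ_vr − median_nonsense) / (median_syn − median_nonsense)

Quality filters flag variants with <10 pre-selection reads, variants not
significantly above the wild-type control error rate (one-sided exact
Poisson test), and replicates diverging beyond 3× their Poisson
delta-method SD. Between-replicate variance is regularized toward a
monotone read-support prior (Baldi–Long, ν₀ = 3), calibration-anchor
uncertainty is bootstrap-propagated, and codon changes encoding the same
amino-acid change are combined by inverse-variance weighting. A
high-confidence (HiQ) subset removes scores whose ±SE interval spans 0.5
and hyper-complementing scores above 1 + 2×median SE. Scores are
calibrated to base-10 log-likelihood ratios of pathogenicity by
Gaussian-KDE density ratios regularized against a uniform, thresholded
on the log10 odds ladder (0.32 / 0.64 / 1.3 / 2.5) into PS3/BS3 evidence
strengths, and evaluated by balanced precision–recall (AUBPRC, R90BP).

See `vignettes/variant-effect-scoring.Rmd` for the full account.

## Worked example

```r
library(mavemap)

cfg <- sim_config(n_positions = 200, depth = 1e5, seed = 7)
exp <- simulate_experiment(cfg)   # counts + ground truth
fit <- variant_scores(exp$counts) # the fitted map
summary(fit)
#> Map composition
#>   missense: 1146  nonsense: 59  synonymous: 195
#>   70.4% of missense above 0.50; 22.5% below 0.20
#>   coverage: 30.2% of all possible substitutions

hiq <- hiq_filter(fit)            # hyper cut 1.207; 1278 variants kept

# calibrate against a labeled reference set (here drawn from the truth)
ref <- data.frame(score = c(0.01, 0.03, 0.05, 0.95, 1.00, 1.05),
                  label = c("P", "P", "P", "B", "B", "B"))
cal <- llr_calibrate(ref)
predict(cal, c(0.05, 0.5, 1.0))
#>   score       llr        evidence
#> 1  0.05  3.197853 PS3_very_strong
#> 2  0.50  0.000000   indeterminate
#> 3  1.00 -2.861258  BS3_supporting
```

The map `fit$scores` holds one row per amino-acid change (`hgvs_pro`,
`score`, `se`, `df`, `flags`): a score of 1 means wild-type-like rescue,
0 means nonsense-like loss of function, and the LLR/evidence columns say
how strongly a score argues for pathogenicity (PS3) or benignity (BS3)
under ACMG/AMP rules. Map-level analyses are provided by
`positional_median()`, `stratified_comparison()` (conservation and
solvent accessibility), `moving_window_correlation()` (functional score
vs predicted ΔΔG), `chk2_hotspots()` with `group_compare()`, and
`contingency_odds()` for case–control odds ratios.

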