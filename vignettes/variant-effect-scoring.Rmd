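---
title: "Scoring and clinically calibrating a variant effect map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and clinically calibrating a variant effect map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mavemap)
```

# The problem

Multiplexed assays of variant effect (MAVEs) measure the functional
consequence of thousands of protein variants at once: a mutagenized open
reading frame is expressed in a selectable system (here the motivating
design is a yeast complementation assay, in which a human kinase rescues
a DNA-damage-sensitive deletion strain under genotoxic stress), and
variant frequencies are read out by deep "tile" sequencing before and
after selection. `mavemap` implements the downstream computational
machinery: turning per-tile variant counts into calibrated functional
scores with errors and quality filters, distilling a high-confidence
subset, converting scores into clinical evidence strengths, and running
the map-level statistical analyses such maps are interrogated with.

# The scoring model

For each codon change $v$, condition $c \in \{\text{pre}, \text{post},
\text{wt}\}$ and replicate $r$, the input is a *marginal count* $k_{vcr}$
(reads carrying the alternate codon, irrespective of co-occurring
variants) and an *effective depth* $d_{vcr}$ (reads in which the call at
that codon was decidable), giving frequencies
$\varphi_{vcr} = k_{vcr}/d_{vcr}$. The wild-type control library measures
the sequencing miscall rate at each codon, and the error-corrected
enrichment log ratio is

$$\log \phi_{vr} = \log\frac{\varphi^{\text{post}}_{vr} -
\varphi^{\text{wt}}_{vr}}{\varphi^{\text{pre}}_{vr} -
\varphi^{\text{wt}}_{vr}}.$$

A non-positive corrected post-selection frequency is floored at half a
pseudo-read over the effective depth, so fully depleted variants obtain a
finite, strongly negative ratio — necessary because genuinely
lower-than-nonsense scores occur (dominant-negative-like behaviour) and
must be representable. A non-positive corrected *pre*-selection
frequency means the variant cannot be distinguished from sequencing
error; it is filtered, not floored.

Log ratios are then rescaled per replicate (and per mutagenesis region,
when a `region` column is present) so that the median of synonymous
variants maps to 1 and the median of nonsense variants maps to 0:

$$s_{vr} = \frac{\log\phi_{vr} - \tilde m_{\text{non}}}
{\tilde m_{\text{syn}} - \tilde m_{\text{non}}}.$$

Because this is affine, the log base cancels exactly; we use the natural
log and test invariance to the base at $10^{-12}$. Nonsense variants
beyond a configurable C-terminal cutoff (position 489 in the CHK2 map,
where truncations retain function in the assay) are excluded from the
nonsense anchor and flagged `c_terminal_nonsense`, but still scored.

One description of this rescaling anchors the *mode* rather than the
median of each calibration class; we implement the median (it is the
anchoring actually prescribed by the procedure's methods, and is robust
at the class sizes involved). The mode reading is noted here as the
alternative.

## Quality filters

Three filters, applied independently (so their order cannot matter):

* `low_pre_reads` — pre-selection marginal count below 10 reads;
* `wt_indistinguishable` — the pre-selection count is not significantly
  above the wild-type-control rate scaled to the pre-library depth, by a
  one-sided exact Poisson test at $\alpha = 0.05$ (the criterion is
  stated qualitatively in the motivating procedure; the exact test is our
  choice and both $\alpha$ and the test are configurable), or the
  corrected pre-selection frequency is non-positive;
* `replicate_divergent` — two replicates' log ratios differ by more than
  3 times their Poisson delta-method standard deviation
  $\sqrt{\sum 1/k}$ over the pre and post counts involved.

Flagged records are excluded from the released map but retained in the
audit table with their flag strings.

## Error model

Between-replicate variance at low read support is a noisy estimate with
1 degree of freedom, so it is regularized in the Baldi–Long fashion:

$$\sigma^2_{\text{reg}} = \frac{\nu_0\,\sigma_0^2(\text{support}) +
(n-1)\,s^2}{\nu_0 + n - 1},$$

with $\nu_0 = 3$ pseudo-observations by default. The prior
$\sigma_0^2(\cdot)$ is fitted across all variants by a
monotone-decreasing isotonic regression of raw variances on log10 read
support — assumption-free, monotone by construction, and stable where a
parametric fit would be sensitive to the tail of poorly measured
variants. The variance of a variant's mean score is
$\sigma^2_{\text{reg}}/n$ plus a bootstrap-propagated component for the
uncertainty of the calibration medians themselves: the synonymous and
nonsense sets are resampled $B = 1000$ times (seeded, recorded in the
configuration) and every score is re-rescaled under each draw.
Propagating anchor uncertainty can be disabled
(`bootstrap_calibration = FALSE`), since whether the original pipeline
includes it is not documented. Codon changes encoding the same
amino-acid change are finally combined by inverse-variance weighting.

## The HiQ subset

For clinical use, scores whose $\pm 1$ SE interval contains the
synonymous/nonsense midpoint 0.5 are removed (inclusive at the interval
endpoints, the conservative reading), as are hyper-complementing scores
above $1 + 2\times\text{median SE}$ — apparent better-than-wild-type
rescue, which phylogenetic evidence suggests is deleterious in the native
context rather than advantageous. The threshold is computed over **all**
variants' standard errors by default (missense, synonymous and
nonsense); whether C-terminal nonsense variants should be excluded from
that median first is not specified, so `hyper_threshold()` simply takes
whatever SE vector it is given.

# Clinical calibration

Given reference sets of pathogenic and benign variants with map scores,
`llr_calibrate()` fits one Gaussian kernel density per class, with a
biased-cross-validation bandwidth and a Silverman fallback below 10
points, and evaluates the base-10 log-likelihood ratio of pathogenicity

$$\mathrm{LLR}(s) = \log_{10}\frac{(1-\varepsilon) f_P(s) +
\varepsilon u(s)}{(1-\varepsilon) f_B(s) + \varepsilon u(s)},$$

where $u$ is uniform on the score support extended by one bandwidth and
$\varepsilon = 0.01$ (the regularization weight is not published; 0.01
is small enough to leave well-covered regions untouched while bounding
ratios in the tails). The base is 10 because the evidence-strength
thresholds 0.32 / 0.64 / 1.3 / 2.5 are, to printed precision, log10 of
the Tavtigian-style odds-of-pathogenicity ladder (2.08, 4.33, 18.7,
350) — a consistency check kept in the test suite. LLR values map to
ACMG/AMP categories PS3_very_strong down to BS3_supporting;
boundary values leave the indeterminate gap (0.32 is already
supporting), 2.5 itself is strong ("above 2.5" is very strong), and
values below −1.32 clamp to BS3_supporting, the strongest benign level
the scheme assigns.

Classification performance is evaluated with balanced precision
$\text{sens}/(\text{sens} + 1 - \text{spec})$ — precision as it would be
at a 50% prior of pathogenicity, removing dependence on the reference
set's composition (on an exactly balanced set it equals raw precision,
an identity the tests assert). The curve's area over recall (AUBPRC) and
the maximal recall at 90% balanced precision (R90BP) summarize it;
R90BP is 0 when no threshold reaches 90%.

# What the simulator emulates

`simulate_experiment()` generates the complete experiment with known
truth, because raw MAVE sequencing data are rarely deposited and every
pipeline stage must still be testable. It emulates the assay's stated
conditions: ~540 codons mutagenized, mean amino-acid mutation load 0.3
per clone (Poisson, implying 3.7% multi-mutant clones, under the 5%
design limit), pools of $10^6$ clones (so each variant is carried by
more than 50 independent clones), two replicates, and 2M reads per tile.
Variants are the nine single-nucleotide codon neighbours of every codon;
latent fitness is 1 for synonymous, 0 for nonsense, and for missense a
mixture of 60% wild-type-like $\mathcal N(1, 0.05)$, 25% loss-of-function
$\mathcal N(0, 0.05)$, 10% intermediate $\mathcal U(0.2, 0.8)$ and 5%
hyper-complementing $\mathcal N(1.7, 0.1)$ — weights chosen to resemble
the observed map composition (roughly two-thirds synonymous-like,
a quarter nonsense-like, and an appreciable hyper-complementing tail).
Selection multiplies each clone's frequency by
$\exp(g(f - 1))$ with $g = 3$ (a multi-mutant clone takes the minimum
fitness of its variants); the exponential form makes the rescaled score
approximately linear in latent fitness, and $g = 3$ gives nonsense
variants a ~20-fold depletion, comfortably above the counting noise at
the default depth without driving every damaging variant to the floor.
Counts are Poisson draws around depth × frequency plus depth × error
rate. The wild-type-control miscall rate defaults to a total of $10^{-4}$
per codon call spread uniformly over the 63 alternate codons (the true
rate of the motivating assay is unpublished; this figure is a documented
placeholder, not a claim — and it must sit well below the per-variant
library frequency of ~$6\times10^{-5} \times 63$ or the assay itself
would not have produced a clean map).

Random number streams are split per (condition, replicate, tile), so
adding a third replicate cannot perturb the first two — a property the
tests pin down bitwise.

The generator does **not** emulate: read-level errors and alignment
(call-level posteriors are an input, and the 0.9 posterior threshold is
applied to synthetic call records), PCR jackpots and chimeras,
position-dependent coverage within a tile, batch effects between
sequencing runs, or C-terminal-truncation tolerance (simulated nonsense
fitness is 0 everywhere; the C-terminal anchor exclusion is exercised by
configuration instead). Passing recovery tests on simulated data
therefore demonstrates correctness of the estimator under the stated
generative model, not robustness to every artifact of real libraries.

## Problem sizes used in the tests

Most tests run 40–60-position experiments at depths of 2–5 × 10^4 with
5 × 10^4 clones; the end-to-end recovery checks use the full default
conditions (543 positions, 2M reads/tile), which score in a few seconds,
and a scaled-down 200-position, 5 × 10^4-read configuration whose
root-mean-square recovery error tolerance (0.25) was frozen from a pilot
run of that exact configuration. At the default depth the recovered map
correlates with latent truth at $r \approx 0.98$; at the scaled-down
depth $r \approx 0.92$, dominated by Poisson noise at pre-selection
counts near the 10-read filter boundary.

# Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_positions = 200, depth = 1e5, seed = 7)
exp <- simulate_experiment(cfg)
fit <- variant_scores(exp$counts)
summary(fit)

hiq <- hiq_filter(fit)
ref <- data.frame(score = c(hiq$hiq$score[hiq$hiq$score < 0.2][1:12],
                            hiq$hiq$score[hiq$hiq$score > 0.8][1:24]),
                  label = rep(c("P", "B"), c(12, 24)))
cal <- llr_calibrate(ref)
predict(cal, c(0.05, 0.5, 1.0))
balanced_pr(ref$score, ref$label)
```

# Numerical choices and degenerate inputs

* Posterior filter at call level: strict `> 0.9` ("exceeding"); a
  decidable call failing the threshold is demoted to a wild-type
  sentinel so that it still contributes depth — effective depth counts
  all decidable reads, which is one reading of an under-specified point
  and is documented rather than guessed silently.
* Zero effective depth excludes the record with a warning, never a
  division error; an empty calibration class, coincident anchors, or a
  missing wild-type control are hard errors.
* The bootstrap SE of a two-replicate mean is corrected by
  $\sqrt{n/(n-1)}$ for the small-sample bias of the plug-in bootstrap.
* Wilcoxon comparisons are exact when both groups have ≤ 25 values and
  no ties, otherwise normal approximation with continuity and tie
  correction; Fisher tests use the two-sided hypergeometric sum; odds
  ratios take a Haldane 0.5 correction (flagged) on zero cells.
* Writers are deterministic: fixed column order, position-sorted rows,
  six significant digits, missing SE as an empty field.

# Known limitations

* Read alignment and the posterior model behind call records are out of
  scope; counts or call records are the entry point.
* Region-to-region normalization beyond per-region rescaling is not
  attempted.
* The calibration assumes reference variants are correctly labeled and
  that their scores are exchangeable with the map's; with a dozen
  positives, KDE bandwidth choice is the dominant uncertainty, which is
  why both the BCV selector and its small-n fallback are pinned by
  tests.
* Phylogenetic analysis of hyper-complementing variants (model
  comparison across species) is out of scope; the HiQ filter simply
  removes scores above the hyper-complementation threshold.
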