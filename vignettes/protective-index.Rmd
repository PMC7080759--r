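---
title: "The composite Protective Index: model, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The composite Protective Index: model, simulation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protindex)
```

## The protection problem

Heritable bacterial symbionts such as *Spiroplasma* can defend their insect
host against parasitoid wasps: in *Drosophila melanogaster* attacked by
*Leptopilina heterotoma*, the symbiont kills the developing wasp inside the
larva. Whether the *fly* is thereby rescued is a different question — many
"protected" larvae still die before eclosion, and survivors can be partly
sterilised by the attack. A survival proportion alone therefore overstates
the fitness benefit of carrying the symbiont.

The Protective Index (PI) folds survival and reproduction into one
composite measure. For symbiont-positive (S+) flies,

$$
\mathrm{PI} \;=\;
\frac{s_e \, f_e \, m_e}{s_u \, f_u \, m_u},
$$

where $s$ is larva-to-adult survival, $f$ the proportion of adult females
that are fertile, $m$ the mean number of daughters produced by fertile
females over assay days 2–5, and the subscripts denote wasp-**e**xposed and
**u**nexposed S+ groups. PI is dimensionless; 1 means attack is costless,
0 means attack annihilates fitness. The metric presumes that without the
symbiont essentially no attacked fly survives (observed S− survival is
below 1%), so unprotected fitness after attack is ~0 and PI measures the
symbiont's rescue. PI is deliberately *not* defined for S− flies; the
package records their survival only as a diagnostic.

`compute_pi()` is the plug-in ratio of the six group summaries. The point
estimate is the plug-in value, not a posterior mean — this reproduces the
published 21% / 9% / 7% / 12% figures exactly from the printed per-cell
summaries (`published_components()`).

When an assay yields too few survivors to measure fertility (the Lh14 wasp
strain), `pi_survival_bound()` reports an upper bound instead of an
estimate. Its default is the survival ratio $s_e / s_u$; a `"product"`
convention ($s_e \cdot s_u$) is available behind an argument because the
published Lh14 bounds are numerically the product, while the accompanying
text says only that protection is "less than the survival value". We do
not assert either convention as correct; the object always labels itself a
bound.

## Uncertainty by posterior simulation

Counts behind each component give conjugate posteriors:

* each proportion (two survivals, two fertility proportions) gets a
  Beta$(\alpha_0 + k,\; \beta_0 + n - k)$ posterior; the default prior is
  the uniform Beta(1, 1), with Jeffreys Beta(½, ½) one argument away. The
  published analysis names the beta family but not hyperparameters, so the
  least-informative conventional choice is the default.
* each fecundity mean gets a Normal(mean, se) posterior truncated at zero.
  Truncation (by inverse-CDF sampling, so it is exact and vectorised)
  prevents negative PI draws; at the observed means and standard errors
  the truncated mass is negligible.

`pi_posterior()` draws all six components independently (the published
simulation does the same; no correlation model is attempted), forms PI per
draw, and reports the equal-tailed 95% interval from the 2.5th and 97.5th
percentiles of `n_draws` draws. The default `n_draws = 1e5` puts the Monte
Carlo standard error of the percentile bounds below 0.002 on the PI scale;
the same seed reproduces draws bit-for-bit. Percentile (not HPD) intervals
match the quantile-of-draws definition of the published intervals.

The published table prints proportions, not raw counts, so
`reconstruct_components()` rebuilds approximate counts from the stated
design — ~450 pooled larvae per survival cell, ~45 assayed females (37 for
the one control cell) — and documents itself as an approximation. With the
default priors this reproduces intervals within a few hundredths of the
printed ones, e.g. (0.13, 0.33) against the printed (0.12, 0.33) for Lh-Fr
without ethanol; exact reproduction is impossible because the original
sample sizes and priors are unpublished.

Strain comparisons use the same draws: `posterior_ordering()` computes
$P(\mathrm{PI}_a > \mathrm{PI}_b)$ by pairwise comparison with ties
split evenly, so $p(a,b) + p(b,a) = 1$ holds exactly.

## What the synthetic experiment emulates

`default_params()` encodes one row per wasp-strain block × symbiont ×
ethanol × exposure cell. Its defaults *are* the study conditions:

* **Survival** (`p_fly`): the published per-cell point estimates for S+
  cells; for attacked S− cells the precise percentages in the survival
  analysis (0.89% / 0.45% / 0.33% without ethanol; 3.33% / 0.22% / 1.33%
  with). Unexposed S− cells reuse the block's unexposed S+ value, since no
  symbiont or ethanol effect on unattacked survival was detected.
* **Wasp emergence** (`p_wasp`): zero in every S+ cell — the symbiont
  killed every wasp in every assay — and applies among attacked larvae
  that did not survive. The S− baseline is not printed numerically
  anywhere, so it is set once at 0.6 (0.7 for Lh14, the strain most lethal
  to its host) and reduced under ethanol by the reported strain-specific
  40/21/60%.
* **Pupation** (`p_pupate`): a marginal probability, constrained
  `p_fly ≤ p_pupate`. Attacked non-survivors mostly die in the pupal case
  (60% residual pupation), unattacked non-survivors mostly as larvae (10%);
  these two fractions are structural choices, as the raw dead-pupa counts
  are not published.
* **Fertility and fecundity**: Bernoulli(`p_fertile`) fertility; fertile
  females draw a daughter total from Normal(`fecundity_mu`,
  `fecundity_sd`) truncated so rounding yields ≥ 1, split over the four
  assay days by a symmetric multinomial. `fecundity_sd` is back-calculated
  from printed standard errors as $\mathrm{se}\sqrt{n}$ with
  $n = \mathrm{round}(45\,p_{\text{fertile}})$. Cells never assayed (all
  S− cells; the Lh14 block) carry `NA` and generate no records —
  downstream analysis is forced into bound mode exactly as the real data
  force it.
* **Wings**: areas Normal(`wing_mu`, 0.07) mm², rendered as unit-area
  hexagons scaled, rotated and translated in pixel coordinates at 200
  px/mm, so the landmark pipeline (shoelace area, mm² conversion, Box-Cox,
  linear model) runs end-to-end. Cell means are the published
  attacked/unattacked means with a ±0.01 mm² ethanol offset matching the
  reported ~0.02 mm² ethanol effect.
* **Oviposition**: Poisson with mean 1.4 eggs per dissected larva — inside
  the reported "greater than 1, less than 2" band for every strain ×
  symbiont combination.
* **Replication** (`experiment_design()`): 12 vials × 30 larvae per
  treatment (the reported range is 10–15), 45 females per fertility cell,
  50 wings per cell, 5 larvae × 5 vials for oviposition.

The generator is per-vial binomial by default (`icc = 0`), because the
published models are plain GLMs; a beta-binomial intra-class correlation
is available for robustness experiments only. One run seed derives fixed
substreams per table, so regenerating any one table is reproducible.

What it does **not** emulate: within-host dynamics (symbiont titre, wasp
development), sex (S+ broods are effectively all-female through
male-killing, and no analysis here uses sex), day-of-emergence structure,
or vial-level environmental drift. Passing parameter-recovery tests on
this generator therefore demonstrates the *statistical* machinery, not
fidelity to unmodelled biology.

`recover_params()` closes the loop: it re-estimates each cell's survival,
fertility and fecundity from generated tables and flags estimates more
than 3 standard errors from truth. The fecundity truth is the exact mean
of the rounded truncated normal (computed by summation), not the nominal
`fecundity_mu`, so the check is unbiased even where truncation matters.

## The inferential layer

Fly survival, fertility and oviposition are factorial GLMs (binomial,
binomial, Poisson) fitted at vial level — `cbind(successes, failures)`
per vial is likelihood-identical to per-larva rows for fixed effects.
`term_tests()` produces Type II likelihood-ratio χ² tests (F for gaussian
responses): each term is compared against the model containing all other
terms except those that include it, so marginality is respected by
construction. `stepwise_simplify()` removes the least-significant
removable term above `alpha` (default 0.05), highest interaction order
first, alphabetical on ties — a deterministic path to the minimum adequate
model, with every removal's statistic reported.

Wasp emergence data are *completely separated*: every S+ vial has zero
emerging wasps, so the binomial MLE for the symbiont coefficient is
infinite and IRLS walks it outward until the iteration cap.
`fit_penalized_logistic()` is a maximum a-posteriori logistic regression
with independent Cauchy priors — scale 2.5 on coefficients, 10 on the
intercept, after centring binary predictors and rescaling continuous ones
to SD 0.5 — optimised by BFGS with analytic gradients. The mode is finite
under separation and start-independent to 10⁻⁶; away from the boundary at
large n the prior washes out and the fit agrees with the MLE to within
2%. Symbiont interaction terms are excluded from the wasp-success model
configuration, since all-zero cells make them unidentifiable. Estimates
are reported back on the original predictor scale.

Wing areas are Box-Cox transformed before the linear model;
`boxcox_lambda()` profiles the likelihood on the fixed grid −2…2 in steps
of 0.01, which makes λ deterministic and testable (the identity and log
limits are recovered on normal and log-normal samples).

## Numerical and design choices

* Clopper–Pearson bounds use the beta-quantile closed form with the k = 0
  and k = n boundary cases handled explicitly; Wilson is optional.
* Degenerate inputs fail loudly: zero-trial summaries, zero denominators
  in PI, non-integer counts in data files and inverted count orderings are
  errors naming the offending component or row, never silent repairs. One
  deliberate exception: stored `fertile`/`daughters_total` columns are
  recomputed from daily counts and only warned about, because derived
  fields must not be trusted from disk.
* Landmarks are taken in boundary order as supplied; the shoelace area is
  orientation-independent, and collapsing to fewer than three distinct
  points yields area zero with a warning rather than an error (mirroring
  the practice of excluding unclear wings upstream).
* The test suite runs its heaviest simulations at reduced but adequate
  sizes chosen once: 150 replicates for recovery coverage, 60 for
  interaction power, 200 for type-I calibration, 10⁵ draws for interval
  checks.

## Known limitations

* Credible-interval reproduction is approximate by construction (counts
  reconstructed from the stated design, priors unpublished).
* The posterior treats the six components as independent; any real
  correlation between survival and fertility of the same cohort is
  ignored, exactly as in the published simulation.
* At the published effect sizes and the 12-vial design, the 2-df
  symbiont × strain interaction test has limited replicate power: the
  suite's own simulation detects it in roughly 70% of runs, so a
  single-experiment significance (as observed) is expected, but
  near-certain detection is not attainable at this scale.
* The survival-only bound's convention (ratio vs product) is genuinely
  ambiguous in the source material; both are implemented, neither is
  asserted.
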