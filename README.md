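# protindex

Composite **Protective Index (PI)** analysis for defensive-symbiosis
experiments: how much fitness does a heritable symbiont rescue when its
insect host is attacked by a parasitoid?

In *Drosophila melanogaster*, the endosymbiont *Spiroplasma* (strain MSRO)
kills the larvae of the parasitoid wasp *Leptopilina heterotoma* inside
attacked fly larvae. Killing the wasp does not always save the fly, and
survivors of attack are often partly sterilised — so survival alone
overstates protection. The PI combines survival and reproduction of
symbiont-carrying (S+) flies into one dimensionless measure:

```
PI = (s_e × f_e × m_e) / (s_u × f_u × m_u)
```

where `s` = larva-to-adult survival, `f` = proportion of females fertile,
`m` = mean daughters of fertile females, for wasp-**e**xposed vs
**u**nexposed S+ groups. The package provides:

* the plug-in PI point estimate, a survival-only upper bound for assays
  with too few survivors, and simulation-based 95% credible intervals
  (beta posteriors for proportions, truncated-normal for fecundity means);
* posterior probabilities that protection differs between attacking wasp
  strains, read off the same draws;
* exact (Clopper–Pearson) binomial group summaries;
* the factorial GLM layer: Type II likelihood-ratio term tests, stepwise
  simplification to the minimum adequate model, and a Cauchy-prior MAP
  logistic regression that stays finite under the complete separation
  created by zero wasp emergence in every S+ vial;
* wing-landmark morphometrics (shoelace polygon area, mm² conversion,
  Box-Cox transformed linear models) as a body-size stress proxy;
* a synthetic-data generator reproducing the full host × symbiont ×
  wasp-strain × ethanol factorial assay, used for parameter-recovery and
  calibration tests;
* `run_pipeline()`, tying simulation/loading, protection reports, GLM
  reports, ordering probabilities and provenance into one seeded run.

## Worked example

The published per-cell summaries ship with the package
(`published_summaries()`), so the headline numbers are reproducible at the
prompt:

```r
library(protindex)

# plug-in PI from the printed group summaries
for (cs in list(c("LH_FR","0%"), c("LH_MAD","0%"),
                c("LH_FR","6%"), c("LH_MAD","6%")))
  cat(cs[1], cs[2], "PI =",
      round(100 * compute_pi(published_components(cs[1], cs[2]))), "%\n")
#> LH_FR 0% PI = 21 %
#> LH_MAD 0% PI = 9 %
#> LH_FR 6% PI = 7 %
#> LH_MAD 6% PI = 12 %
```

Without ethanol, *Spiroplasma* preserves ~21% of fly fitness under Lh-Fr
attack but only ~9% under Lh-Mad; ethanol reverses the ranking. Credible
intervals come from posterior simulation on counts reconstructed from the
stated design (~450 larvae, ~45 females per cell):

```r
post_fr  <- pi_posterior(reconstruct_components("LH_FR", "0%"),
                         n_draws = 1e5, seed = 7)
post_mad <- pi_posterior(reconstruct_components("LH_MAD", "0%"),
                         n_draws = 1e5, seed = 8)
post_fr
#> Protective Index: 0.207 (95% CrI 0.125-0.327; 100000 draws)
post_mad
#> Protective Index: 0.090 (95% CrI 0.037-0.168; 100000 draws)
posterior_ordering(post_fr, post_mad)$p_greater
#> [1] 0.97923
```

So the posterior probability that protection against Lh-Fr exceeds that
against Lh-Mad (no ethanol) is ≈0.98. A full synthetic run and recovery
check:

```r
tables <- simulate_experiment(experiment_design(seed = 42))
rec <- recover_params(tables, default_params())
subset(rec, quantity == "p_fly" & exposure == "exposed" &
            spiroplasma == "S+" & ethanol == "0%")[
  , c("wasp_strain", "estimate", "truth", "se", "flagged")]
#>   wasp_strain estimate truth     se flagged
#> 1 LH_FR         0.444   0.42 0.0260 FALSE
#> 2 LH14          0.0528  0.05 0.0115 FALSE
#> 3 LH_MAD        0.419   0.40 0.0258 FALSE
```

Every estimate sits within sampling error of its generative truth at the
12-vial design scale.

See `vignettes/protective-index.Rmd` for the model, the generator's
assumptions, and the numerical choices.

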