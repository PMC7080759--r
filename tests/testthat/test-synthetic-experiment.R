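test_that("default parameters reproduce the published cell summaries", {
  p <- default_params()
  cell <- function(strain, spiro, etoh, expo) {
    p[p$wasp_strain == strain & p$spiroplasma == spiro &
        p$ethanol == etoh & p$exposure == expo, ]
  }
  fr <- cell("LH_FR", "S+", "0%", "exposed")
  expect_equal(fr$p_fly, 0.42)
  expect_equal(fr$p_fertile, 0.56)
  expect_equal(fr$fecundity_mu, 10.9)
  mad <- cell("LH_MAD", "S+", "6%", "unexposed")
  expect_equal(mad$p_fly, 0.80)
  expect_equal(mad$p_fertile, 0.95)
  expect_equal(mad$fecundity_mu, 14.2)
  # symbiont presence blocks wasp emergence in every cell
  expect_true(all(p$p_wasp[p$spiroplasma == "S+"] == 0))
  expect_true(all(p$p_fly <= p$p_pupate))
})

test_that("degenerate probabilities produce deterministic vials", {
  d <- experiment_design(n_vials_per_treatment = 5, seed = 3)
  p <- default_params()
  p$p_fly <- 1
  p$p_pupate <- 1
  p$p_wasp <- 0
  v <- generate_vials(d, p)
  expect_true(all(v$n_flies == 30))
  expect_true(all(v$n_wasps == 0))
})

test_that("pooled fly proportion converges at the binomial rate", {
  d <- experiment_design(n_vials_per_treatment = 400, seed = 5)
  p <- default_params()
  v <- generate_vials(d, p)
  cell <- v[v$wasp_strain == "LH_FR" & v$spiroplasma == "S+" &
              v$ethanol == "0%", ]
  n <- sum(cell$n_larvae)
  se <- sqrt(0.42 * 0.58 / n)
  expect_lt(abs(sum(cell$n_flies) / n - 0.42), 3 * se)
})

test_that("intra-vial correlation inflates between-vial variance as the
           beta-binomial formula predicts", {
  d <- experiment_design(n_vials_per_treatment = 2000, seed = 9)
  base <- default_params()[1, ]
  base$p_fly <- 0.42
  base$p_pupate <- 0.8
  draw_var <- function(icc) {
    base$icc <- icc
    v <- generate_vials(d, base, seed = 17)
    var(v$n_flies)
  }
  v0 <- draw_var(0)
  v2 <- draw_var(0.2)
  expected0 <- 30 * 0.42 * 0.58
  expected2 <- expected0 * (1 + 29 * 0.2)
  expect_lt(abs(v0 / expected0 - 1), 0.15)
  expect_lt(abs(v2 / expected2 - 1), 0.15)
  expect_gt(v2, v0 * 2)
})

test_that("fertility generation matches its configured law", {
  d <- experiment_design(n_females_fertility = 4000, seed = 21)
  p <- default_params()
  p <- p[!is.na(p$p_fertile) & p$wasp_strain == "LH_FR" &
           p$ethanol == "0%", ]
  f <- generate_fertility(d, p)
  for (expo in c("exposed", "unexposed")) {
    cell <- p[p$exposure == expo, ]
    rows <- f[f$exposure == expo, ]
    se <- sqrt(cell$p_fertile * (1 - cell$p_fertile) / nrow(rows))
    expect_lt(abs(mean(rows$fertile) - cell$p_fertile), 3 * se)
    mom <- protindex:::fecundity_moments(cell$fecundity_mu,
                                         cell$fecundity_sd)
    d_obs <- rows$daughters_total[rows$fertile]
    expect_lt(abs(mean(d_obs) - mom$mean), 3 * mom$sd / sqrt(length(d_obs)))
    # daily counts always sum to the total; infertile females all-zero
    expect_true(all(rows$day2 + rows$day3 + rows$day4 + rows$day5 ==
                      rows$daughters_total))
    expect_true(all(rows$fertile == (rows$daughters_total > 0)))
  }
  p$p_fertile <- 0
  f0 <- generate_fertility(experiment_design(n_females_fertility = 50), p)
  expect_true(all(f0$daughters_total == 0))
})

test_that("oviposition counts are Poisson with mean between 1 and 2", {
  ov <- generate_oviposition(1e5, lambda = 1.4, seed = 2)
  m <- mean(ov$n_eggs_larvae)
  expect_gt(m, 1)
  expect_lt(m, 2)
  expect_lt(abs(m - 1.4), 3 * sqrt(1.4 / 1e5))
  expect_true(all(generate_oviposition(100, lambda = 1e-9,
                                       seed = 3)$n_eggs_larvae == 0))
})

test_that("a fixed seed reproduces every table exactly", {
  d <- experiment_design(n_vials_per_treatment = 4,
                         n_females_fertility = 8,
                         n_wings_per_cell = 3, seed = 42)
  t1 <- simulate_experiment(d)
  t2 <- simulate_experiment(d)
  for (nm in names(t1)) expect_identical(t1[[nm]], t2[[nm]], label = nm)
  t3 <- simulate_experiment(d, seed = 43)
  expect_false(identical(t1$vials$n_flies, t3$vials$n_flies))
})

test_that("generated tables satisfy the data-model invariants", {
  tables <- simulate_experiment(experiment_design(
    n_vials_per_treatment = 6, n_females_fertility = 10,
    n_wings_per_cell = 4, seed = 7))
  expect_silent(validate_vials(tables$vials))
  splus_attacked <- tables$vials$spiroplasma == "S+" &
    tables$vials$wasp_strain != "NONE"
  expect_true(all(tables$vials$n_wasps[splus_attacked] == 0))
  expect_true(all(tables$wings$scale_px_per_mm > 0))
})

test_that("parameter recovery is exact for degenerate truth and accurate
           at large n", {
  p <- default_params()
  p$p_fly[p$wasp_strain == "LH14" & p$spiroplasma == "S-" &
            p$exposure == "exposed"] <- 0
  d_big <- experiment_design(n_vials_per_treatment = 350,
                             n_females_fertility = 400, seed = 31)
  tables <- list(vials = generate_vials(d_big, p),
                 fertility = generate_fertility(d_big, p))
  rep <- recover_params(tables, p)
  surv <- rep[rep$quantity == "p_fly", ]
  expect_true(all(surv$abs_error[surv$truth == 0] == 0))
  expect_true(all(surv$abs_error < 0.01))
  expect_lt(mean(rep$flagged, na.rm = TRUE), 0.05)
})
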