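test_that("Clopper-Pearson bounds match the beta-quantile form and
           binom.test across the (k, n) sweep", {
  for (n in c(1:40, 45, 100, 250, 500)) {
    k <- 0:n
    s <- lapply(k, summarize_proportion, n_total = n)
    lo <- vapply(s, `[[`, numeric(1), "ci_low")
    hi <- vapply(s, `[[`, numeric(1), "ci_high")
    lo_oracle <- ifelse(k == 0, 0, qbeta(0.025, k, n - k + 1))
    hi_oracle <- ifelse(k == n, 1, qbeta(0.975, k + 1, n - k))
    expect_lt(max(abs(lo - lo_oracle)), 1e-10)
    expect_lt(max(abs(hi - hi_oracle)), 1e-10)
  }
  set.seed(1)
  for (i in 1:50) {
    n <- sample(500, 1)
    k <- sample(0:n, 1)
    bt <- binom.test(k, n)$conf.int
    s <- summarize_proportion(k, n)
    expect_equal(s$ci_low, bt[1], tolerance = 1e-8)
    expect_equal(s$ci_high, bt[2], tolerance = 1e-8)
  }
})

test_that("group summaries honour boundaries and reject undefined input", {
  expect_equal(summarize_proportion(0, 20)$ci_low, 0)
  expect_equal(summarize_proportion(0, 20)$proportion, 0)
  expect_equal(summarize_proportion(20, 20)$ci_high, 1)
  w <- summarize_proportion(25, 45, method = "wilson")
  expect_true(w$ci_low <= w$proportion && w$proportion <= w$ci_high)
  expect_error(summarize_proportion(1, 0), "undefined")
  expect_error(summarize_proportion(5, 4))
})

make_components <- function(s_e, f_e, m_e, s_u, f_u, m_u,
                            n_larvae = 1000, n_fem = 100, se = 0.5) {
  protection_components(
    exposed_survival = summarize_proportion(round(s_e * n_larvae), n_larvae),
    unexposed_survival = summarize_proportion(round(s_u * n_larvae),
                                              n_larvae),
    exposed_fertile = summarize_proportion(round(f_e * n_fem), n_fem),
    unexposed_fertile = summarize_proportion(round(f_u * n_fem), n_fem),
    exposed_fecundity = fecundity_summary(m_e, se),
    unexposed_fecundity = fecundity_summary(m_u, se)
  )
}

test_that("compute_pi is an identity at equal components, scale-invariant in
           fecundity, and monotone in each component", {
  comp <- make_components(0.5, 0.6, 12, 0.5, 0.6, 12)
  expect_equal(compute_pi(comp), 1.0)
  set.seed(4)
  for (i in 1:25) {
    v <- runif(4, 0.05, 0.95)
    m <- runif(2, 2, 20)
    base <- make_components(v[1], v[2], m[1], v[3], v[4], m[2])
    pi0 <- compute_pi(base)
    scaled <- make_components(v[1], v[2], m[1] * 3.7, v[3], v[4], m[2] * 3.7)
    expect_equal(compute_pi(scaled), pi0, tolerance = 1e-12)
    up <- make_components(min(v[1] * 1.1, 0.99), v[2], m[1], v[3], v[4], m[2])
    expect_gt(compute_pi(up), pi0)
    dn <- make_components(v[1], v[2], m[1], min(v[3] * 1.1, 0.99), v[4], m[2])
    expect_lt(compute_pi(dn), pi0)
  }
  zero_denom <- make_components(0.5, 0.6, 12, 0.0, 0.6, 12)
  expect_error(compute_pi(zero_denom), "survival")
})

test_that("the survival-only bound follows the documented conventions", {
  comp <- protection_components(
    exposed_survival = summarize_proportion(5, 100),
    unexposed_survival = summarize_proportion(72, 100)
  )
  expect_error(compute_pi(comp), "pi_survival_bound")
  expect_equal(pi_survival_bound(comp)$bound, 0.05 / 0.72)
  expect_equal(pi_survival_bound(comp, "product")$bound, 0.05 * 0.72)
  zero <- protection_components(
    exposed_survival = summarize_proportion(0, 100),
    unexposed_survival = summarize_proportion(72, 100)
  )
  expect_equal(pi_survival_bound(zero)$bound, 0)
  eq <- protection_components(
    exposed_survival = summarize_proportion(50, 100),
    unexposed_survival = summarize_proportion(50, 100)
  )
  expect_equal(pi_survival_bound(eq)$bound, 1)
})

test_that("percent_change reproduces relative reductions", {
  expect_equal(percent_change(17.5, 10.6), 100 * (1 - 10.6 / 17.5))
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "undefined")
})

test_that("the PI posterior collapses onto the plug-in point as information
           grows, and is seed-reproducible", {
  big <- make_components(0.42, 0.56, 10.9, 0.81, 0.97, 15.6,
                         n_larvae = 5e7, n_fem = 2e7, se = 1e-5)
  post <- pi_posterior(big, n_draws = 5000, seed = 1)
  expect_lt(post$ci_high - post$ci_low, 1e-3)
  expect_lt(abs(post$point - (0.42 * 0.56 * 10.9) / (0.81 * 0.97 * 15.6)),
            1e-3)
  p1 <- pi_posterior(big, n_draws = 2000, seed = 99)
  p2 <- pi_posterior(big, n_draws = 2000, seed = 99)
  expect_identical(p1$draws, p2$draws)
  expect_warning(pi_posterior(big, n_draws = 500, seed = 1), "unstable")
  printed <- published_components("LH_FR", "0%")
  expect_error(pi_posterior(printed), "reconstruct_components")
})

test_that("posterior interval width agrees with the log-scale delta method
           at large counts", {
  n_l <- 45000
  n_f <- 10000
  comp <- make_components(0.42, 0.56, 10.9, 0.81, 0.97, 15.6,
                          n_larvae = n_l, n_fem = n_f, se = 0.2)
  post <- pi_posterior(comp, n_draws = 5e4, seed = 12)
  var_log <- (1 - 0.42) / (n_l * 0.42) + (1 - 0.81) / (n_l * 0.81) +
    (1 - 0.56) / (n_f * 0.56) + (1 - 0.97) / (n_f * 0.97) +
    (0.2 / 10.9)^2 + (0.2 / 15.6)^2
  point <- (0.42 * 0.56 * 10.9) / (0.81 * 0.97 * 15.6)
  delta <- exp(log(point) + c(-1, 1) * 1.96 * sqrt(var_log))
  width_sim <- post$ci_high - post$ci_low
  width_delta <- delta[2] - delta[1]
  expect_lt(abs(width_sim / width_delta - 1), 0.2)
})

test_that("posterior ordering respects the tie convention and the normal
           closed form", {
  x <- c(1, 2, 3)
  expect_equal(posterior_ordering(x, x)$p_greater, 0.5)
  expect_equal(posterior_ordering(c(4, 5, 6), x)$p_greater, 1.0)
  expect_error(posterior_ordering(1:3, 1:4), "equal length")
  set.seed(8)
  a <- rnorm(2e5, 1.0, 0.1)
  b <- rnorm(2e5, 0.8, 0.1)
  p <- posterior_ordering(a, b)$p_greater
  expect_lt(abs(p - pnorm(0.2 / sqrt(0.02))), 0.005)
  # complementarity is exact
  expect_equal(posterior_ordering(a, b)$p_greater +
                 posterior_ordering(b, a)$p_greater, 1.0)
})

test_that("build_components pools larvae, summarises fertility, and matches
           generator truth on synthetic data", {
  single <- make_vials(12, n_larvae = 30)
  ctrl <- make_vials(rep(25, 3), exposed = FALSE)
  fert <- NULL
  comp <- build_components(rbind(single, ctrl), NULL, "LH_FR", "0%")
  expect_equal(comp$exposed_survival$proportion, 0.40)
  expect_null(comp$exposed_fertile)

  d <- experiment_design(n_vials_per_treatment = 150,
                         n_females_fertility = 400, seed = 13)
  p <- default_params()
  tables <- list(vials = generate_vials(d, p),
                 fertility = generate_fertility(d, p))
  comp <- build_components(tables$vials, tables$fertility, "LH_FR", "0%")
  n <- comp$exposed_survival$n_total
  expect_lt(abs(comp$exposed_survival$proportion - 0.42),
            3 * sqrt(0.42 * 0.58 / n))
  expect_lt(abs(comp$exposed_fertile$proportion - 0.56),
            3 * sqrt(0.56 * 0.44 / comp$exposed_fertile$n_total))
  mom <- protindex:::fecundity_moments(10.9, 1.83 * sqrt(25))
  expect_lt(abs(comp$exposed_fecundity$mean - mom$mean),
            3 * mom$sd / sqrt(comp$exposed_fecundity$n))
  expect_error(build_components(single, NULL, "LH_FR", "0%"), "control")
})
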