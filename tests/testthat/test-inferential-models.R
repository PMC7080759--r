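test_that("a null group effect yields a near-zero coefficient", {
  df <- data.frame(k = c(20, 22, 21, 19), n = 50,
                   grp = factor(c("a", "a", "b", "b")))
  fit <- fit_glm(df, model_spec(c("k", "n"), "binomial", "grp"))
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[["grpb"]]), 0.1)
})

test_that("the binomial LRT on a 2x2 table equals the closed-form
           G statistic and the saturated deviance is zero", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(50:200, 2)
    k <- c(rbinom(1, n[1], 0.3), rbinom(1, n[2], 0.6))
    df <- data.frame(k = k, n = n, grp = factor(c("a", "b")))
    spec <- model_spec(c("k", "n"), "binomial", "grp")
    fit <- fit_glm(df, spec)
    expect_lt(fit$deviance, 1e-8)  # saturated
    tt <- term_tests(df, spec)
    expect_equal(tt$statistic, g_statistic(k, n), tolerance = 1e-6)
    expect_equal(tt$df, 1L)
  }
})

test_that("single-factor gaussian F equals the squared equal-variance t", {
  set.seed(3)
  df <- data.frame(y = c(rnorm(20, 0), rnorm(20, 0.7)),
                   grp = factor(rep(c("a", "b"), each = 20)))
  tt <- term_tests(df, model_spec("y", "gaussian", "grp"))
  t2 <- t.test(y ~ grp, data = df, var.equal = TRUE)$statistic^2
  expect_equal(tt$statistic, unname(t2), tolerance = 1e-8)
  expect_equal(tt$statistic_kind, "F")
})

test_that("Poisson term tests hold their nominal size under the null", {
  set.seed(5)
  pvals <- replicate(200, {
    df <- data.frame(eggs = rpois(60, 1.4),
                     strain = factor(rep(c("a", "b", "c"), each = 20)))
    term_tests(df, model_spec("eggs", "poisson", "strain"))$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("term tests respect marginality: the main-effect comparison
           excludes its interaction", {
  set.seed(6)
  df <- expand.grid(a = factor(c("x", "y")), b = factor(c("u", "v")),
                    rep = 1:10)
  df$k <- rbinom(nrow(df), 30, ifelse(df$a == "x", 0.3, 0.6))
  df$n <- 30
  spec <- model_spec(c("k", "n"), "binomial", c("a", "b"))
  tt <- term_tests(df, spec)
  # manual Type II comparison for 'a': (b) vs (a + b), interaction excluded
  f0 <- glm(cbind(k, n - k) ~ b, binomial, df)
  f1 <- glm(cbind(k, n - k) ~ a + b, binomial, df)
  expect_equal(tt$statistic[tt$term == "a"],
               deviance(f0) - deviance(f1), tolerance = 1e-8)
})

test_that("stepwise simplification drops null interactions, keeps true main
           effects, and never violates marginality", {
  set.seed(7)
  df <- expand.grid(a = factor(c("x", "y")), b = factor(c("u", "v")),
                    rep = 1:30)
  p <- ifelse(df$a == "x", 0.25, 0.65)  # main effect of a only
  df$k <- rbinom(nrow(df), 30, p)
  df$n <- 30
  spec <- model_spec(c("k", "n"), "binomial", c("a", "b"))
  out <- stepwise_simplify(df, spec)
  expect_true("a:b" %in% out$dropped$term)
  expect_true("a" %in% out$spec$factors)
  # strong three-way interaction: nothing can be dropped
  df3 <- expand.grid(a = factor(c("x", "y")), b = factor(c("u", "v")),
                     c = factor(c("s", "t")), rep = 1:40)
  p3 <- with(df3, 0.2 + 0.55 * (a == "y" & b == "v" & c == "t"))
  df3$k <- rbinom(nrow(df3), 30, p3)
  df3$n <- 30
  out3 <- stepwise_simplify(df3, model_spec(c("k", "n"), "binomial",
                                            c("a", "b", "c")))
  expect_equal(nrow(out3$dropped), 0)
  expect_equal(length(out3$spec$interactions), 4)
})

test_that("all-null data simplify towards the intercept-only model", {
  set.seed(11)
  reduced <- replicate(40, {
    df <- expand.grid(a = factor(c("x", "y")), b = factor(c("u", "v")),
                      rep = 1:12)
    df$k <- rbinom(nrow(df), 30, 0.4)
    df$n <- 30
    out <- stepwise_simplify(df, model_spec(c("k", "n"), "binomial",
                                            c("a", "b")))
    length(out$spec$factors) + length(out$spec$interactions)
  })
  expect_gt(mean(reduced == 0), 0.5)
})

sep_data <- function(n_vials = 10, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    spiro = factor(rep(c("Splus", "Sminus"), each = n_vials)),
    n = 30L
  )
  df$wasps <- ifelse(df$spiro == "Splus", 0L, rbinom(n_vials, 30, 0.55))
  df
}

test_that("complete separation: ML diverges, the Cauchy-penalized fit stays
           finite and start-independent", {
  df <- sep_data()
  spec <- model_spec(c("wasps", "n"), "binomial", "spiro")
  ml25 <- suppressWarnings(fit_glm(df, spec, maxit = 25))
  ml100 <- suppressWarnings(fit_glm(df, spec, maxit = 100))
  expect_gt(abs(ml100$coefficients[["spiroSplus"]]),
            abs(ml25$coefficients[["spiroSplus"]]) - 1e-6)
  expect_gt(abs(ml100$coefficients[["spiroSplus"]]), 15)

  pen <- fit_penalized_logistic(df, spec)
  expect_true(pen$converged)
  expect_true(pen$penalized)
  expect_true(is.finite(pen$coefficients[["spiroSplus"]]))
  expect_lt(abs(pen$coefficients[["spiroSplus"]]), 15)
  for (s in list(c(2, 2), c(-3, 1), c(0.5, -4))) {
    alt <- fit_penalized_logistic(df, spec, start = s)
    expect_lt(max(abs(alt$coefficients - pen$coefficients)), 1e-6)
  }
})

test_that("the penalized posterior mode matches a grid oracle and shrinks
           toward zero", {
  df <- sep_data(n_vials = 6, seed = 4)
  spec <- model_spec(c("wasps", "n"), "binomial", "spiro")
  pen <- fit_penalized_logistic(df, spec)
  # oracle: direct 2-D grid maximization of the Cauchy log-posterior on the
  # standardized design, refined twice
  X <- cbind(1, ifelse(df$spiro == "Splus", 1, 0))
  z <- X[, 2] - mean(X[, 2])
  lp <- function(b0, b1) {
    eta <- b0 + b1 * z
    sum(df$wasps * eta - df$n * log1p(exp(eta))) -
      log1p((b0 / 10)^2) - log1p((b1 / 2.5)^2)
  }
  centre <- c(0, 0); half <- 20
  for (r in 1:4) {
    g0 <- seq(centre[1] - half, centre[1] + half, length.out = 61)
    g1 <- seq(centre[2] - half, centre[2] + half, length.out = 61)
    val <- outer(g0, g1, Vectorize(lp))
    ix <- which(val == max(val), arr.ind = TRUE)[1, ]
    centre <- c(g0[ix[1]], g1[ix[2]])
    half <- half / 15
  }
  std <- pen$model$standardized
  expect_lt(abs(std[1] - centre[1]), 0.01)
  expect_lt(abs(std[2] - centre[2]), 0.01)

  # shrinkage on null balanced data
  set.seed(9)
  dfn <- data.frame(spiro = factor(rep(c("a", "b"), each = 8)), n = 30L)
  dfn$wasps <- rbinom(16, 30, 0.5)
  mle <- fit_glm(dfn, model_spec(c("wasps", "n"), "binomial", "spiro"))
  penn <- fit_penalized_logistic(dfn, model_spec(c("wasps", "n"),
                                                 "binomial", "spiro"))
  expect_lte(abs(penn$coefficients[["spirob"]]),
             abs(mle$coefficients[["spirob"]]) + 1e-8)

  # the prior washes out at large n away from the boundary
  set.seed(10)
  dfb <- data.frame(spiro = factor(rep(c("a", "b"), each = 200)), n = 200L)
  dfb$wasps <- rbinom(400, 200, ifelse(dfb$spiro == "a", 0.35, 0.6))
  mleb <- fit_glm(dfb, model_spec(c("wasps", "n"), "binomial", "spiro"))
  penb <- fit_penalized_logistic(dfb, model_spec(c("wasps", "n"),
                                                 "binomial", "spiro"))
  expect_lt(abs(penb$coefficients[["spirob"]] /
                  mleb$coefficients[["spirob"]] - 1), 0.02)
})

test_that("Box-Cox lambda lands on the identity and log limits", {
  set.seed(12)
  x <- rnorm(1e4, 50, 2)
  expect_lt(abs(boxcox_lambda(x)$lambda - 1), 0.15)
  y <- exp(rnorm(1e4, 1, 0.5))
  expect_lt(abs(boxcox_lambda(y)$lambda - 0), 0.1)
  bc <- boxcox_lambda(c(1.5, 2, 4), grid = 1)
  expect_equal(bc$transformed, c(1.5, 2, 4) - 1)
  expect_error(boxcox_lambda(c(1, -2)), "positive")
})
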