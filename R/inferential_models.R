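# Inferential layer: factorial GLMs with likelihood-ratio term tests and
# stepwise simplification to a minimum adequate model, a Cauchy-prior MAP
# logistic regression for separated data, and Box-Cox transformed linear
# models.

#' Specify a factorial model
#'
#' @param response For `family = "binomial"`, a length-2 character vector
#'   naming the successes and totals columns; for `"poisson"` or
#'   `"gaussian"`, the response column name.
#' @param family `"binomial"`, `"poisson"` or `"gaussian"`.
#' @param factors Character vector of categorical predictor columns.
#' @param interactions List of character vectors, each an interaction among
#'   declared factors (default: all interactions up to the full cross,
#'   i.e. `A * B * ...`).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(response, family = c("binomial", "poisson", "gaussian"),
                       factors, interactions = NULL) {
  family <- match.arg(family)
  if (family == "binomial" && length(response) != 2) {
    stop("binomial responses are (successes, totals) column names",
         call. = FALSE)
  }
  if (is.null(interactions) && length(factors) > 1) {
    interactions <- unlist(lapply(2:length(factors), function(k) {
      utils::combn(sort(factors), k, simplify = FALSE)
    }), recursive = FALSE)
  }
  for (ia in interactions) {
    if (!all(ia %in% factors)) {
      stop("interaction terms must be among declared factors: ",
           paste(ia, collapse = ":"), call. = FALSE)
    }
  }
  structure(
    list(response = response, family = family, factors = factors,
         interactions = interactions %||% list()),
    class = "model_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

spec_terms <- function(spec) {
  c(sort(spec$factors),
    vapply(spec$interactions, function(ia) paste(sort(ia), collapse = ":"),
           character(1)))
}

spec_formula <- function(spec) {
  lhs <- if (spec$family == "binomial") {
    sprintf("cbind(%s, %s - %s)", spec$response[1], spec$response[2],
            spec$response[1])
  } else {
    spec$response[1]
  }
  rhs <- paste(spec_terms(spec), collapse = " + ")
  if (rhs == "") rhs <- "1"
  stats::as.formula(paste(lhs, "~", rhs))
}

#' Fit a generalized linear model from a model spec
#'
#' Maximum-likelihood fit via IRLS (`stats::glm`). Binomial responses are
#' modelled at vial level as (successes, totals); the likelihood is
#' identical to per-individual rows for fixed effects.
#'
#' @param data A data frame holding response and factor columns.
#' @param spec A [model_spec()].
#' @param maxit IRLS iteration cap (default 25).
#' @return A list of class `fit_result`: `coefficients`, `deviance`,
#'   `df_residual`, `converged`, `penalized`, and the underlying `model`.
#' @export
fit_glm <- function(data, spec, maxit = 25) {
  stopifnot(inherits(spec, "model_spec"))
  fit <- stats::glm(spec_formula(spec), family = spec$family, data = data,
                    control = stats::glm.control(maxit = maxit))
  structure(
    list(coefficients = stats::coef(fit), deviance = stats::deviance(fit),
         df_residual = stats::df.residual(fit), converged = fit$converged,
         penalized = FALSE, model = fit, spec = spec),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s %s fit: deviance %.4g on %d df%s%s\n",
              if (x$penalized) "penalized" else "ML",
              x$spec$family %||% "logistic", x$deviance, x$df_residual,
              if (x$converged) "" else " [NOT CONVERGED]",
              if (x$penalized) " (Cauchy prior MAP)" else ""))
  print(x$coefficients)
  invisible(x)
}

#' Marginality-respecting term tests
#'
#' Type II analysis of deviance: each term is tested by likelihood ratio
#' against a model holding all other terms except those containing it
#' (chi-square for binomial/Poisson, F for gaussian). No main effect is
#' tested while its interaction is retained in the comparison. Aliased
#' terms are reported untestable (`NA` statistic).
#'
#' @param data A data frame.
#' @param spec A [model_spec()].
#' @return A tibble: `term`, `statistic_kind`, `statistic`, `df`, `df2`
#'   (residual df, F only), `p_value`.
#' @export
term_tests <- function(data, spec) {
  fit <- fit_glm(data, spec)$model
  kind <- if (spec$family == "gaussian") "F" else "chi_square"
  an <- tryCatch(
    car::Anova(fit, type = 2,
               test.statistic = if (kind == "F") "F" else "LR"),
    error = function(e) NULL
  )
  if (is.null(an)) {
    return(tibble::tibble(term = spec_terms(spec), statistic_kind = kind,
                          statistic = NA_real_, df = NA_integer_,
                          df2 = NA_integer_, p_value = NA_real_))
  }
  rows <- rownames(an)
  keep <- !rows %in% c("Residuals", "(Intercept)")
  stat_col <- if (kind == "F") grep("^F", colnames(an), value = TRUE)[1]
              else "LR Chisq"
  p_col <- grep("^Pr\\(", colnames(an), value = TRUE)[1]
  tibble::tibble(
    term = rows[keep],
    statistic_kind = kind,
    statistic = as.numeric(an[[stat_col]][keep]),
    df = as.integer(an$Df[keep]),
    df2 = if (kind == "F") rep(as.integer(stats::df.residual(fit)),
                               sum(keep))
          else NA_integer_,
    p_value = as.numeric(an[[p_col]][keep])
  )
}

#' Stepwise simplification to the minimum adequate model
#'
#' Starting from the full model, repeatedly removes the removable term
#' (highest order first, respecting marginality) with the largest p-value
#' above `alpha`, refitting after each removal, until every remaining
#' removable term is significant. Ties break alphabetically, so the path is
#' deterministic. Dropped-term tests are the model-comparison statistics at
#' the step of removal.
#'
#' @param data A data frame.
#' @param spec The full [model_spec()].
#' @param alpha Retention threshold (default 0.05).
#' @return A list: `spec` (minimum adequate model), `dropped` (tibble of
#'   removal tests in order), `retained` (term tests of the final model).
#' @export
stepwise_simplify <- function(data, spec, alpha = 0.05) {
  stopifnot(inherits(spec, "model_spec"))
  current <- spec
  dropped <- list()
  repeat {
    fit <- fit_glm(data, current)$model
    kind <- if (current$family == "gaussian") "F" else "chi_square"
    d1 <- tryCatch(
      stats::drop1(fit, test = if (kind == "F") "F" else "Chisq"),
      error = function(e) NULL
    )
    if (is.null(d1)) break
    terms_d1 <- rownames(d1)[-1]
    if (length(terms_d1) == 0) break
    ord <- vapply(strsplit(terms_d1, ":"), length, integer(1))
    stat <- if (kind == "F") d1$`F value`[-1] else d1$LRT[-1]
    pval <- d1[[grep("^Pr\\(", colnames(d1), value = TRUE)[1]]][-1]
    cand <- data.frame(term = terms_d1, order = ord, statistic = stat,
                       df = d1$Df[-1], p_value = pval,
                       stringsAsFactors = FALSE)
    cand <- cand[cand$p_value > alpha & !is.na(cand$p_value), ]
    if (nrow(cand) == 0) break
    # drop from the highest interaction order present among candidates;
    # least significant first, alphabetical on ties
    cand <- cand[cand$order == max(cand$order), ]
    cand <- cand[order(-cand$p_value, cand$term), ]
    victim <- cand[1, ]
    dropped[[length(dropped) + 1]] <- tibble::tibble(
      term = victim$term, statistic_kind = kind,
      statistic = victim$statistic, df = as.integer(victim$df),
      p_value = victim$p_value
    )
    current <- remove_term(current, victim$term)
  }
  list(
    spec = current,
    dropped = if (length(dropped)) dplyr::bind_rows(dropped)
              else tibble::tibble(term = character(),
                                  statistic_kind = character(),
                                  statistic = numeric(), df = integer(),
                                  p_value = numeric()),
    retained = if (length(spec_terms(current)) > 0) term_tests(data, current)
               else tibble::tibble(term = character())
  )
}

remove_term <- function(spec, term) {
  parts <- sort(strsplit(term, ":")[[1]])
  if (length(parts) == 1) {
    spec$factors <- setdiff(spec$factors, parts)
  } else {
    keep <- vapply(spec$interactions, function(ia) {
      !identical(sort(ia), parts)
    }, logical(1))
    spec$interactions <- spec$interactions[keep]
  }
  spec
}

# --- separation-robust logistic regression -----------------------------------

#' Cauchy-prior MAP logistic regression
#'
#' Penalized logistic regression for separated data: independent Cauchy
#' priors with scale `prior_scale` (default 2.5) on coefficients and 10 on
#' the intercept, applied after centering binary predictor columns and
#' rescaling continuous ones to standard deviation 0.5. The posterior mode
#' is found by BFGS with analytic gradients; estimates remain finite under
#' complete separation, where the unpenalized maximum-likelihood estimates
#' diverge.
#'
#' @param data A data frame.
#' @param spec A binomial [model_spec()].
#' @param prior_scale Cauchy scale for coefficients (default 2.5).
#' @param intercept_scale Cauchy scale for the intercept (default 10).
#' @param start Optional numeric start vector (standardized scale), for
#'   checking start-independence.
#' @return A `fit_result` with `penalized = TRUE`; coefficients are
#'   reported on the original predictor scale.
#' @export
fit_penalized_logistic <- function(data, spec, prior_scale = 2.5,
                                   intercept_scale = 10, start = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "binomial") {
    stop("penalized logistic regression needs a binomial spec",
         call. = FALSE)
  }
  mf <- stats::model.frame(spec_formula(spec), data)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  resp <- stats::model.response(mf)
  if (is.matrix(resp)) {
    k <- resp[, 1]
    n <- resp[, 1] + resp[, 2]
  } else {
    k <- as.numeric(resp)
    n <- rep(1, length(k))
  }
  # arm-style standardization: center all non-constant columns; rescale
  # columns with >2 distinct values to sd 0.5
  p <- ncol(X)
  centre <- rep(0, p)
  scale_ <- rep(1, p)
  for (j in seq_len(p)[-1]) {
    xj <- X[, j]
    centre[j] <- mean(xj)
    if (length(unique(xj)) > 2) {
      s <- sd(xj)
      if (s > 0) scale_[j] <- s / 0.5
    }
  }
  Z <- sweep(sweep(X, 2, centre, "-"), 2, scale_, "/")
  Z[, 1] <- 1
  scales <- c(intercept_scale, rep(prior_scale, p - 1))

  neg_post <- function(beta) {
    eta <- drop(Z %*% beta)
    ll <- sum(k * eta - n * log1p(exp(eta)))
    lp <- -sum(log1p((beta / scales)^2))
    -(ll + lp)
  }
  neg_grad <- function(beta) {
    eta <- drop(Z %*% beta)
    mu <- 1 / (1 + exp(-eta))
    gll <- drop(crossprod(Z, k - n * mu))
    glp <- -2 * beta / (scales^2 + beta^2)
    -(gll + glp)
  }
  beta0 <- start %||% rep(0, p)
  opt <- stats::optim(beta0, neg_post, neg_grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  beta_z <- opt$par
  # back-transform to the original predictor scale
  beta <- beta_z / scale_
  beta[1] <- beta_z[1] - sum(beta_z[-1] * centre[-1] / scale_[-1])
  names(beta) <- colnames(X)
  eta <- drop(X %*% beta)
  dev <- -2 * sum(k * eta - n * log1p(exp(eta))) +
    2 * sum(ifelse(k > 0, k * log(k / n), 0) +
              ifelse(n - k > 0, (n - k) * log(1 - k / n), 0))
  structure(
    list(coefficients = beta, deviance = dev,
         df_residual = length(k) - p, converged = opt$convergence == 0,
         penalized = TRUE, prior_scale = prior_scale,
         model = list(optim = opt, standardized = beta_z),
         spec = spec),
    class = "fit_result"
  )
}

# --- Box-Cox -----------------------------------------------------------------

#' Box-Cox power transform with profile-likelihood lambda
#'
#' Estimates lambda on a fixed grid (default -2..2 in steps of 0.01) by
#' profile likelihood (via `MASS::boxcox`) and applies
#' `y = (x^lambda - 1) / lambda` (natural log at lambda = 0).
#'
#' @param x Positive numeric values.
#' @param grid Candidate lambda grid.
#' @return A list: `lambda`, `transformed`, `grid`, `profile`
#'   (log-likelihood at each grid point).
#' @export
boxcox_lambda <- function(x, grid = seq(-2, 2, by = 0.01)) {
  if (any(x <= 0)) {
    stop("Box-Cox requires strictly positive values", call. = FALSE)
  }
  prof <- MASS::boxcox(x ~ 1, data = data.frame(x = x), lambda = grid,
                       plotit = FALSE)
  lambda <- prof$x[which.max(prof$y)]
  transformed <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  list(lambda = lambda, transformed = transformed, grid = prof$x,
       profile = prof$y)
}
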