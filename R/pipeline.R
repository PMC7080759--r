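# End-to-end pipeline: configuration, simulation or loading, protection
# report, GLM term tests, ordering probabilities, outcome proportions, and a
# provenance log. All outputs are plain CSV / YAML so runs are diff-able.

#' Run configuration
#'
#' Either paths to the four assay CSVs or a request to simulate them. All
#' stochastic stages derive their substreams from the single `seed`.
#'
#' @param inputs Named list of paths (`vials`, `fertility`, `wings`,
#'   `oviposition`; any may be NULL), or NULL to simulate.
#' @param simulate If TRUE (default when no inputs), generate tables with
#'   [simulate_experiment()].
#' @param design An [experiment_design()] for simulation.
#' @param seed Run seed.
#' @param n_draws Posterior draws for PI intervals.
#' @param prior A [prior_spec()].
#' @param ci_method Binomial CI method.
#' @param alpha Stepwise retention threshold.
#' @param output_dir Directory for report files.
#' @return A list of class `run_config`.
#' @export
run_config <- function(inputs = NULL, simulate = is.null(inputs),
                       design = experiment_design(), seed = design$seed,
                       n_draws = 1e5, prior = prior_spec(),
                       ci_method = "clopper_pearson", alpha = 0.05,
                       output_dir = tempfile("protindex_run_")) {
  structure(
    list(inputs = inputs, simulate = simulate, design = design,
         seed = as.integer(seed), n_draws = n_draws, prior = prior,
         ci_method = ci_method, alpha = alpha, output_dir = output_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Recognised keys mirror the [run_config()] arguments; `design` is a
#' mapping of [experiment_design()] arguments, `prior` a mapping with
#' `alpha0` / `beta0`.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- do.call(experiment_design, y$design %||% list())
  prior <- do.call(prior_spec, y$prior %||% list())
  run_config(
    inputs = y$inputs, simulate = y$simulate %||% is.null(y$inputs),
    design = design, seed = y$seed %||% design$seed,
    n_draws = y$n_draws %||% 1e5, prior = prior,
    ci_method = y$ci_method %||% "clopper_pearson",
    alpha = y$alpha %||% 0.05,
    output_dir = y$output_dir %||% tempfile("protindex_run_")
  )
}

load_or_simulate <- function(config) {
  if (config$simulate) {
    return(simulate_experiment(config$design, default_params(), config$seed))
  }
  inp <- config$inputs
  list(
    vials = if (!is.null(inp$vials)) read_vial_table(inp$vials) else
      stop("config must provide a vials table or request simulation",
           call. = FALSE),
    fertility = if (!is.null(inp$fertility))
      read_fertility_table(inp$fertility) else NULL,
    wings = if (!is.null(inp$wings)) read_wing_table(inp$wings) else NULL,
    oviposition = if (!is.null(inp$oviposition))
      read_oviposition_table(inp$oviposition) else NULL
  )
}

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = digits, format = "g"))
}

protection_report <- function(tables, config) {
  strains <- intersect(WASP_STRAINS[-1], unique(as.character(
    tables$vials$wasp_strain[tables$vials$wasp_strain != "NONE"])))
  rows <- list()
  posteriors <- list()
  for (strain in strains) {
    for (etoh in ETHANOL_LEVELS) {
      comp <- tryCatch(
        build_components(tables$vials, tables$fertility, strain, etoh,
                         config$ci_method),
        error = function(e) NULL
      )
      if (is.null(comp)) next
      bound_mode <- !has_fertility(comp)
      if (bound_mode) {
        pi_point <- NA_real_
        bnd <- pi_survival_bound(comp)
        ci <- c(NA_real_, NA_real_)
      } else {
        post <- pi_posterior(comp, config$prior, config$n_draws,
                             seed = substream(config$seed, 90L +
                                                10L * match(strain,
                                                            WASP_STRAINS) +
                                                match(etoh, ETHANOL_LEVELS)))
        posteriors[[paste(strain, etoh)]] <- post
        pi_point <- post$point
        ci <- c(post$ci_low, post$ci_high)
        bnd <- NULL
      }
      side_row <- function(side) {
        s <- comp[[paste0(side, "_survival")]]
        f <- comp[[paste0(side, "_fertile")]]
        m <- comp[[paste0(side, "_fecundity")]]
        tibble::tibble(
          wasp_strain = strain, ethanol = etoh, group = side,
          survival = s$proportion, surv_lo = s$ci_low, surv_hi = s$ci_high,
          fertile = if (is.null(f)) NA_real_ else f$proportion,
          fert_lo = if (is.null(f)) NA_real_ else f$ci_low,
          fert_hi = if (is.null(f)) NA_real_ else f$ci_high,
          fecundity = if (is.null(m)) NA_real_ else m$mean,
          fecundity_se = if (is.null(m)) NA_real_ else m$se,
          pi = pi_point, pi_lo = ci[1], pi_hi = ci[2],
          pi_bound = if (bound_mode) bnd$bound else NA_real_,
          bound_mode = bound_mode
        )
      }
      rows[[paste(strain, etoh)]] <- dplyr::bind_rows(side_row("exposed"),
                                                      side_row("unexposed"))
    }
  }
  list(table = dplyr::bind_rows(rows), posteriors = posteriors)
}

ordering_report <- function(posteriors) {
  keys <- names(posteriors)
  if (length(keys) < 2) {
    return(tibble::tibble(a = character(), b = character(),
                          p_greater = numeric()))
  }
  pairs <- utils::combn(keys, 2, simplify = FALSE)
  dplyr::bind_rows(lapply(pairs, function(pr) {
    cmp <- posterior_ordering(posteriors[[pr[1]]], posteriors[[pr[2]]])
    tibble::tibble(a = pr[1], b = pr[2], p_greater = cmp$p_greater)
  }))
}

outcome_proportions <- function(vials) {
  grp <- dplyr::group_by(vials, .data$wasp_strain, .data$spiroplasma,
                         .data$ethanol)
  out <- dplyr::summarise(
    grp,
    total_larvae = sum(.data$n_larvae),
    total_pupae = sum(.data$n_pupae),
    total_flies = sum(.data$n_flies),
    total_wasps = sum(.data$n_wasps),
    .groups = "drop"
  )
  tibble::tibble(
    out[c("wasp_strain", "spiroplasma", "ethanol")],
    n_larvae = out$total_larvae,
    prop_fly = out$total_flies / out$total_larvae,
    prop_wasp = out$total_wasps / out$total_larvae,
    prop_dead_pupa = (out$total_pupae - out$total_flies - out$total_wasps) /
      out$total_larvae,
    prop_dead_larva = (out$total_larvae - out$total_pupae) /
      out$total_larvae
  )
}

glm_reports <- function(tables, config) {
  out <- list()
  v <- tables$vials
  attacked <- v[v$wasp_strain != "NONE", ]
  if (nrow(attacked) > 0 && length(unique(attacked$wasp_strain)) > 1) {
    df <- data.frame(
      flies = attacked$n_flies, larvae = attacked$n_larvae,
      spiroplasma = factor(as.character(attacked$spiroplasma)),
      strain = factor(as.character(attacked$wasp_strain)),
      ethanol = factor(as.character(attacked$ethanol))
    )
    spec <- model_spec(c("flies", "larvae"), "binomial",
                       c("spiroplasma", "strain", "ethanol"))
    simp <- stepwise_simplify(df, spec, config$alpha)
    out$fly_survival <- list(dropped = simp$dropped,
                             retained = simp$retained)
    # wasp success: penalized fit, symbiont interactions excluded because
    # symbiont-positive cells are completely separated (zero wasp emergence)
    df$wasps <- attacked$n_wasps
    wspec <- model_spec(c("wasps", "larvae"), "binomial",
                        c("spiroplasma", "strain", "ethanol"),
                        interactions = list(c("ethanol", "strain")))
    out$wasp_success <- fit_penalized_logistic(df, wspec)
  }
  if (!is.null(tables$fertility) && nrow(tables$fertility) > 0) {
    fert <- tables$fertility
    for (strain in intersect(c("LH_FR", "LH_MAD"),
                             unique(as.character(fert$wasp_strain)))) {
      fdf <- fert[fert$wasp_strain == strain, ]
      if (length(unique(fdf$exposure)) < 2) next
      df <- data.frame(
        fertile = as.integer(fdf$fertile), one = 1L,
        exposure = factor(as.character(fdf$exposure)),
        ethanol = factor(as.character(fdf$ethanol))
      )
      spec <- model_spec(c("fertile", "one"), "binomial",
                         c("exposure", "ethanol"))
      simp <- stepwise_simplify(df, spec, config$alpha)
      out[[paste0("fertility_", strain)]] <- list(dropped = simp$dropped,
                                                  retained = simp$retained)
    }
  }
  if (!is.null(tables$oviposition) && nrow(tables$oviposition) > 0) {
    ov <- tables$oviposition
    df <- data.frame(
      eggs = ov$n_eggs_larvae,
      strain = factor(as.character(ov$wasp_strain)),
      spiroplasma = factor(as.character(ov$spiroplasma))
    )
    if (length(unique(df$strain)) > 1 && length(unique(df$spiroplasma)) > 1) {
      spec <- model_spec("eggs", "poisson", c("spiroplasma", "strain"))
      simp <- stepwise_simplify(df, spec, config$alpha)
      out$oviposition <- list(dropped = simp$dropped,
                              retained = simp$retained)
    }
  }
  if (!is.null(tables$wings) && nrow(tables$wings) > 0) {
    aw <- wing_areas(tables$wings)
    for (strain in intersect(c("LH_FR", "LH_MAD"),
                             unique(as.character(aw$wasp_strain)))) {
      adf <- aw[aw$wasp_strain == strain & aw$spiroplasma == "S+", ]
      if (length(unique(adf$exposure)) < 2) next
      bc <- boxcox_lambda(adf$area_mm2)
      df <- data.frame(
        area_bc = bc$transformed,
        exposure = factor(as.character(adf$exposure)),
        ethanol = factor(as.character(adf$ethanol))
      )
      spec <- model_spec("area_bc", "gaussian", c("exposure", "ethanol"))
      simp <- stepwise_simplify(df, spec, config$alpha)
      out[[paste0("wing_", strain)]] <- list(
        lambda = bc$lambda, dropped = simp$dropped,
        retained = simp$retained,
        summary = summarize_wings(adf)
      )
    }
  }
  out
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) the four assay tables, then produces: a
#' protection report shaped like the published summary table (per-group
#' survival / fertility / fecundity summaries with PI and its credible
#' interval, or the survival-only bound where fertility is missing); GLM
#' term-test and dropped-term reports per response; the matrix of posterior
#' ordering probabilities between strain x ethanol PI posteriors;
#' stacked outcome proportions per treatment; and a provenance log
#' recording the seed, substreams, reconstruction sizes and package
#' version. All outputs are written as CSV/YAML under
#' `config$output_dir` and returned invisibly.
#'
#' @param config A [run_config()] (or path to a YAML config, which is read
#'   with [read_run_config()]).
#' @return Invisibly, a list with `tables`, `protection`, `ordering`,
#'   `outcomes`, `glm`, `paths`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- load_or_simulate(config)

  prot <- protection_report(tables, config)
  ordering <- ordering_report(prot$posteriors)
  outcomes <- outcome_proportions(tables$vials)
  glm_out <- glm_reports(tables, config)

  paths <- list(
    protection = file.path(config$output_dir, "protection_report.csv"),
    ordering = file.path(config$output_dir, "ordering_probabilities.csv"),
    outcomes = file.path(config$output_dir, "outcome_proportions.csv"),
    provenance = file.path(config$output_dir, "provenance.yaml")
  )
  readr::write_csv(prot$table, paths$protection, progress = FALSE)
  readr::write_csv(ordering, paths$ordering, progress = FALSE)
  readr::write_csv(outcomes, paths$outcomes, progress = FALSE)
  for (nm in names(glm_out)) {
    item <- glm_out[[nm]]
    if (inherits(item, "fit_result")) {
      readr::write_csv(
        tibble::tibble(term = names(item$coefficients),
                       estimate = unname(item$coefficients),
                       penalized = item$penalized,
                       converged = item$converged),
        file.path(config$output_dir, paste0("glm_", nm, ".csv")),
        progress = FALSE)
    } else if (!is.null(item$retained)) {
      readr::write_csv(item$retained,
                       file.path(config$output_dir,
                                 paste0("glm_", nm, "_terms.csv")),
                       progress = FALSE)
      readr::write_csv(item$dropped,
                       file.path(config$output_dir,
                                 paste0("glm_", nm, "_dropped.csv")),
                       progress = FALSE)
    }
  }
  yaml::write_yaml(
    list(
      seed = config$seed,
      n_draws = config$n_draws,
      prior = list(alpha0 = config$prior$alpha0,
                   beta0 = config$prior$beta0),
      ci_method = config$ci_method,
      alpha = config$alpha,
      simulated = config$simulate,
      design = if (config$simulate) unclass(config$design) else NULL,
      package_version = as.character(utils::packageVersion("protindex"))
    ),
    paths$provenance
  )
  invisible(list(tables = tables, protection = prot$table,
                 ordering = ordering, outcomes = outcomes, glm = glm_out,
                 paths = paths))
}
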