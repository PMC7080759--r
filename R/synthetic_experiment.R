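# Synthetic factorial assay generator.
#
# Emulates the statistical structure of the host x symbiont x wasp-strain x
# ethanol protection experiment: per-vial binomial (optionally beta-binomial)
# larva-to-adult survival, wasp emergence among attacked non-surviving larvae,
# Bernoulli fertility with rounded truncated-normal daughter counts split over
# four assay days, normal wing areas rendered as landmark hexagons, and
# Poisson oviposition counts.

#' Experiment design parameters
#'
#' Replication structure of one full factorial run. Defaults follow the
#' reported design: 30 first-instar larvae per vial, 10-15 (default 12)
#' replicate vials per treatment, ~45 females per fertility cell, and five
#' dissected larvae from each of five replicate vials for oviposition.
#'
#' @param n_vials_per_treatment Vials per treatment cell (default 12).
#' @param larvae_per_vial Larvae placed per vial (default 30).
#' @param n_females_fertility Females assayed per fertility cell (default 45).
#' @param n_wings_per_cell Wings measured per cell (default 50).
#' @param n_larvae_dissected Larvae dissected per oviposition cell
#'   (default 25 = 5 larvae x 5 vials).
#' @param seed Integer seed; every generator derives its substream from it.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_vials_per_treatment = 12,
                              larvae_per_vial = 30,
                              n_females_fertility = 45,
                              n_wings_per_cell = 50,
                              n_larvae_dissected = 25,
                              seed = 1L) {
  counts <- c(n_vials_per_treatment, larvae_per_vial, n_females_fertility,
              n_wings_per_cell, n_larvae_dissected)
  if (any(counts < 1 | counts != floor(counts))) {
    stop("design counts must be positive integers", call. = FALSE)
  }
  structure(
    list(
      n_vials_per_treatment = as.integer(n_vials_per_treatment),
      larvae_per_vial = as.integer(larvae_per_vial),
      n_females_fertility = as.integer(n_females_fertility),
      n_wings_per_cell = as.integer(n_wings_per_cell),
      n_larvae_dissected = as.integer(n_larvae_dissected),
      seed = as.integer(seed)
    ),
    class = "experiment_design"
  )
}

# Deterministic substream seeds below 2^31 so one run seed reproduces every
# table independently of generation order.
substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k * 7919) %% 2147483647)
}

#' Default generative parameters for every treatment cell
#'
#' One row per wasp-strain block x symbiont status x ethanol x exposure cell.
#' Point estimates for survival, proportion fertile and fecundity of the
#' symbiont-positive cells are the published per-cell summaries of the
#' Lh-Fr / Lh14 / Lh-Mad protection assay; survival of symbiont-negative
#' attacked cells uses the precise percentages reported in the survival
#' analysis (e.g. 0.89% for Lh-Fr without ethanol). Unexposed
#' symbiont-negative survival equals the block's unexposed symbiont-positive
#' value, reflecting the absence of a detectable symbiont effect without
#' wasps. Wasp emergence is zero in every symbiont-positive cell; baseline
#' emergence among non-surviving attacked symbiont-negative larvae is 0.6
#' (0.7 for Lh14), reduced under ethanol by the reported strain-specific
#' percentages (40/21/60% for Lh-Fr/Lh14/Lh-Mad).
#'
#' Fecundity standard deviations are back-calculated from the published
#' standard errors as `se * sqrt(round(p_fertile * 45))`. Fertility and
#' fecundity are `NA` for cells that were not assayed (all S- cells and the
#' Lh14 block, which had too few survivors).
#'
#' @return A tibble with columns `wasp_strain`, `spiroplasma`, `ethanol`,
#'   `exposure`, `p_fly`, `p_pupate`, `p_wasp`, `p_fertile`, `fecundity_mu`,
#'   `fecundity_sd`, `wing_mu`, `wing_sd`, `oviposition_lambda`, `icc`.
#' @export
#' @examples
#' p <- default_params()
#' subset(p, wasp_strain == "LH_FR" & ethanol == "0%")
default_params <- function() {
  g <- expand.grid(
    wasp_strain = WASP_STRAINS[-1],
    spiroplasma = SPIRO_LEVELS,
    ethanol     = ETHANOL_LEVELS,
    exposure    = EXPOSURE_LEVELS,
    stringsAsFactors = TRUE
  )
  g <- tibble::as_tibble(g)
  key <- paste(g$wasp_strain, g$spiroplasma, g$ethanol, g$exposure)

  lookup <- function(map, default = NA_real_) {
    out <- rep(default, nrow(g))
    hit <- key %in% names(map)
    out[hit] <- unlist(map)[key[hit]]
    out
  }

  # survival: Table-1 point estimates (S+), reported percentages (S- exposed),
  # block control value (unexposed)
  unexp_s <- c(`LH_FR 0%` = 0.81, `LH_FR 6%` = 0.80,
               `LH14 0%` = 0.72, `LH14 6%` = 0.69,
               `LH_MAD 0%` = 0.75, `LH_MAD 6%` = 0.80)
  p_fly <- numeric(nrow(g))
  exp_splus  <- c(`LH_FR 0%` = 0.42, `LH_FR 6%` = 0.33,
                  `LH14 0%` = 0.05, `LH14 6%` = 0.01,
                  `LH_MAD 0%` = 0.40, `LH_MAD 6%` = 0.33)
  exp_sminus <- c(`LH_FR 0%` = 0.0089, `LH_FR 6%` = 0.0333,
                  `LH14 0%` = 0.0045, `LH14 6%` = 0.0022,
                  `LH_MAD 0%` = 0.0033, `LH_MAD 6%` = 0.0133)
  blocketh <- paste(g$wasp_strain, g$ethanol)
  p_fly[g$exposure == "unexposed"] <- unexp_s[blocketh[g$exposure == "unexposed"]]
  sel <- g$exposure == "exposed" & g$spiroplasma == "S+"
  p_fly[sel] <- exp_splus[blocketh[sel]]
  sel <- g$exposure == "exposed" & g$spiroplasma == "S-"
  p_fly[sel] <- exp_sminus[blocketh[sel]]

  # wasp emergence among attacked non-surviving larvae; zero whenever the
  # symbiont is present, zero without wasps
  base_wasp <- c(LH_FR = 0.60, LH14 = 0.70, LH_MAD = 0.60)
  etoh_red  <- c(LH_FR = 0.40, LH14 = 0.21, LH_MAD = 0.60)
  p_wasp <- rep(0, nrow(g))
  sel <- g$exposure == "exposed" & g$spiroplasma == "S-"
  p_wasp[sel] <- base_wasp[as.character(g$wasp_strain[sel])] *
    ifelse(g$ethanol[sel] == "6%",
           1 - etoh_red[as.character(g$wasp_strain[sel])], 1)

  # marginal pupation: most attacked larvae reach the pupal case even when
  # they fail to eclose; unattacked non-survivors mostly die as larvae
  p_pupate <- ifelse(g$exposure == "exposed",
                     p_fly + 0.6 * (1 - p_fly),
                     p_fly + 0.1 * (1 - p_fly))

  fert_key <- paste(g$wasp_strain, g$spiroplasma, g$ethanol, g$exposure)
  fert <- c(`LH_FR S+ 0% exposed` = 0.56, `LH_FR S+ 0% unexposed` = 0.97,
            `LH_FR S+ 6% exposed` = 0.34, `LH_FR S+ 6% unexposed` = 1.00,
            `LH_MAD S+ 0% exposed` = 0.40, `LH_MAD S+ 0% unexposed` = 0.95,
            `LH_MAD S+ 6% exposed` = 0.60, `LH_MAD S+ 6% unexposed` = 0.95)
  fec_mu <- c(`LH_FR S+ 0% exposed` = 10.9, `LH_FR S+ 0% unexposed` = 15.6,
              `LH_FR S+ 6% exposed` = 9.98, `LH_FR S+ 6% unexposed` = 19.2,
              `LH_MAD S+ 0% exposed` = 5.45, `LH_MAD S+ 0% unexposed` = 13.7,
              `LH_MAD S+ 6% exposed` = 6.38, `LH_MAD S+ 6% unexposed` = 14.2)
  fec_se <- c(`LH_FR S+ 0% exposed` = 1.83, `LH_FR S+ 0% unexposed` = 1.31,
              `LH_FR S+ 6% exposed` = 2.41, `LH_FR S+ 6% unexposed` = 1.38,
              `LH_MAD S+ 0% exposed` = 1.54, `LH_MAD S+ 0% unexposed` = 0.985,
              `LH_MAD S+ 6% exposed` = 1.28, `LH_MAD S+ 6% unexposed` = 0.805)
  p_fertile <- rep(NA_real_, nrow(g))
  fecundity_mu <- rep(NA_real_, nrow(g))
  fecundity_sd <- rep(NA_real_, nrow(g))
  hit <- fert_key %in% names(fert)
  p_fertile[hit] <- fert[fert_key[hit]]
  fecundity_mu[hit] <- fec_mu[fert_key[hit]]
  fecundity_sd[hit] <- fec_se[fert_key[hit]] *
    sqrt(round(fert[fert_key[hit]] * 45))

  # wing area mm^2: measured for S+ cells of the two strains with survivors;
  # published attacked/unattacked means with a +/-0.01 ethanol offset
  wing_base <- c(`LH_FR exposed` = 1.26, `LH_FR unexposed` = 1.30,
                 `LH_MAD exposed` = 1.17, `LH_MAD unexposed` = 1.22)
  wkey <- paste(g$wasp_strain, g$exposure)
  wing_mu <- rep(NA_real_, nrow(g))
  hit <- wkey %in% names(wing_base) & g$spiroplasma == "S+"
  wing_mu[hit] <- wing_base[wkey[hit]] +
    ifelse(g$ethanol[hit] == "0%", 0.01, -0.01)
  wing_sd <- ifelse(is.na(wing_mu), NA_real_, 0.07)

  g$p_fly <- unname(p_fly)
  g$p_pupate <- unname(p_pupate)
  g$p_wasp <- unname(p_wasp)
  g$p_fertile <- unname(p_fertile)
  g$fecundity_mu <- unname(fecundity_mu)
  g$fecundity_sd <- unname(fecundity_sd)
  g$wing_mu <- unname(wing_mu)
  g$wing_sd <- unname(wing_sd)
  g$oviposition_lambda <- 1.4
  g$icc <- 0
  validate_params(g)
}

#' Validate a treatment-parameter table
#'
#' Checks probability ranges, `p_fly <= p_pupate`, zero wasp emergence in
#' symbiont-positive cells, and non-negative dispersion parameters.
#'
#' @param params A tibble shaped like [default_params()].
#' @return The validated tibble.
#' @export
validate_params <- function(params) {
  probs <- c("p_fly", "p_pupate", "p_wasp")
  for (p in probs) {
    if (any(params[[p]] < 0 | params[[p]] > 1, na.rm = TRUE)) {
      stop(p, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (any(params$p_fly > params$p_pupate + 1e-12)) {
    stop("p_fly must not exceed p_pupate", call. = FALSE)
  }
  if (any(params$spiroplasma == "S+" & params$p_wasp > 0)) {
    stop("symbiont-positive cells must have p_wasp = 0", call. = FALSE)
  }
  if (any(params$fecundity_sd < 0, na.rm = TRUE)) {
    stop("fecundity_sd must be non-negative", call. = FALSE)
  }
  if (any(params$icc < 0 | params$icc >= 1, na.rm = TRUE)) {
    stop("icc must lie in [0, 1)", call. = FALSE)
  }
  params
}

param_cell <- function(params, strain, spiro, etoh, expo) {
  row <- params[params$wasp_strain == strain & params$spiroplasma == spiro &
                  params$ethanol == etoh & params$exposure == expo, ]
  if (nrow(row) != 1) {
    stop("no unique parameter row for cell ", strain, "/", spiro, "/", etoh,
         "/", expo, call. = FALSE)
  }
  row
}

# Beta-binomial sampler: icc = 0 degenerates to the plain binomial.
rbetabinom <- function(n_draws, size, prob, icc) {
  if (prob <= 0) return(rep(0L, n_draws))
  if (prob >= 1) return(rep(as.integer(size), n_draws))
  if (icc <= 0) return(rbinom(n_draws, size, prob))
  a <- prob * (1 - icc) / icc
  b <- (1 - prob) * (1 - icc) / icc
  rbinom(n_draws, size, rbeta(n_draws, a, b))
}

#' Generate a per-vial emergence table
#'
#' For each treatment cell, fly survivors per vial are beta-binomial
#' (`p_fly`, intra-vial correlation `icc`; plain binomial at `icc = 0`);
#' wasp emergers are binomial with `p_wasp` among the attacked larvae that
#' did not survive; residual dead pupae fill the gap up to the marginal
#' pupation probability `p_pupate`. Unexposed cells are emitted with
#' `wasp_strain = NONE` and the strain block recorded in `block`.
#'
#' @param design An [experiment_design()].
#' @param params A parameter tibble, e.g. [default_params()].
#' @param seed Integer seed (default: the design's seed).
#' @return A validated vial tibble.
#' @export
generate_vials <- function(design, params = default_params(),
                           seed = design$seed) {
  validate_params(params)
  set.seed(substream(seed, 1L))
  nv <- design$n_vials_per_treatment
  nl <- design$larvae_per_vial
  rows <- lapply(seq_len(nrow(params)), function(i) {
    cell <- params[i, ]
    flies <- rbetabinom(nv, nl, cell$p_fly, cell$icc)
    p_wasp <- if (cell$exposure == "exposed") cell$p_wasp else 0
    wasps <- rbinom(nv, nl - flies, p_wasp)
    # residual pupation among larvae that produced neither fly nor wasp,
    # chosen so the marginal pupation probability is p_pupate
    denom <- (1 - cell$p_fly) * (1 - p_wasp)
    q <- if (denom > 0) {
      max(0, min(1, (cell$p_pupate - cell$p_fly - (1 - cell$p_fly) * p_wasp) /
                   denom))
    } else 0
    dead_pupae <- rbinom(nv, nl - flies - wasps, q)
    tibble::tibble(
      vial_id = sprintf("%s_%s_%s_%s_v%02d", cell$wasp_strain,
                        cell$spiroplasma, sub("%", "", cell$ethanol),
                        substr(cell$exposure, 1, 4), seq_len(nv)),
      wasp_strain = factor(
        if (cell$exposure == "exposed") as.character(cell$wasp_strain)
        else "NONE", WASP_STRAINS),
      spiroplasma = factor(as.character(cell$spiroplasma), SPIRO_LEVELS),
      ethanol = factor(as.character(cell$ethanol), ETHANOL_LEVELS),
      block = factor(as.character(cell$wasp_strain), WASP_STRAINS),
      n_larvae = as.integer(nl),
      n_pupae = as.integer(flies + wasps + dead_pupae),
      n_flies = as.integer(flies),
      n_wasps = as.integer(wasps)
    )
  })
  validate_vials(dplyr::bind_rows(rows))
}

# Exact moments of the generated daughter count among fertile females:
# a normal(mu, sd) draw conditioned on exceeding 0.5, rounded to integer.
fecundity_moments <- function(mu, sd) {
  if (sd <= 0) return(list(mean = round(mu), sd = 0))
  kmax <- max(10, ceiling(mu + 12 * sd))
  k <- seq_len(kmax)
  pk <- pnorm((k + 0.5 - mu) / sd) - pnorm((k - 0.5 - mu) / sd)
  pk <- pk / sum(pk)
  m <- sum(k * pk)
  v <- sum((k - m)^2 * pk)
  list(mean = m, sd = sqrt(v))
}

#' Generate a per-female fertility table
#'
#' Each female in an assayed cell is fertile with probability `p_fertile`;
#' fertile females receive a daughter total drawn from a
#' normal(`fecundity_mu`, `fecundity_sd`) truncated below so that rounding
#' yields at least one daughter, split across the four assay days by a
#' symmetric multinomial. Infertile females have all-zero days. Cells with
#' `NA` fertility parameters are skipped (not assayed).
#'
#' @inheritParams generate_vials
#' @return A fertility tibble (same schema as [read_fertility_table()]).
#' @export
generate_fertility <- function(design, params = default_params(),
                               seed = design$seed) {
  validate_params(params)
  set.seed(substream(seed, 2L))
  nf <- design$n_females_fertility
  cells <- params[!is.na(params$p_fertile), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    fertile <- runif(nf) < cell$p_fertile
    totals <- integer(nf)
    nfert <- sum(fertile)
    if (nfert > 0) {
      if (cell$fecundity_sd > 0) {
        lo <- pnorm((0.5 - cell$fecundity_mu) / cell$fecundity_sd)
        u <- runif(nfert, lo, 1)
        x <- cell$fecundity_mu + cell$fecundity_sd * qnorm(u)
      } else {
        x <- rep(max(1, cell$fecundity_mu), nfert)
      }
      totals[fertile] <- pmax(1L, as.integer(round(x)))
    }
    days <- vapply(totals, function(tt) {
      if (tt == 0) integer(4) else
        as.integer(stats::rmultinom(1, tt, rep(0.25, 4)))
    }, integer(4))
    tibble::tibble(
      female_id = sprintf("%s_%s_%s_%s_f%02d", cell$wasp_strain,
                          cell$spiroplasma, sub("%", "", cell$ethanol),
                          substr(cell$exposure, 1, 4), seq_len(nf)),
      exposure = factor(as.character(cell$exposure), EXPOSURE_LEVELS),
      wasp_strain = factor(as.character(cell$wasp_strain), WASP_STRAINS),
      spiroplasma = factor(as.character(cell$spiroplasma), SPIRO_LEVELS),
      ethanol = factor(as.character(cell$ethanol), ETHANOL_LEVELS),
      day2 = days[1, ], day3 = days[2, ], day4 = days[3, ], day5 = days[4, ],
      daughters_total = totals,
      fertile = totals > 0L
    )
  })
  dplyr::bind_rows(rows)
}

# Regular hexagon with unit area, centred at the origin.
unit_hexagon <- function() {
  ang <- pi / 3 * (0:5)
  r <- sqrt(1 / (1.5 * sqrt(3)))
  cbind(x = r * cos(ang), y = r * sin(ang))
}

#' Generate a wing-landmark table
#'
#' Wing areas are drawn normal(`wing_mu`, `wing_sd`) truncated at zero and
#' rendered as six boundary-ordered landmarks: a unit-area hexagon scaled to
#' the target area, randomly rotated and translated, in pixels at the given
#' image scale. Cells with `NA` wing parameters are skipped.
#'
#' @inheritParams generate_vials
#' @param scale_px_per_mm Image scale in pixels per millimetre (default 200).
#' @return A wing tibble (same schema as [read_wing_table()]).
#' @export
generate_wings <- function(design, params = default_params(),
                           seed = design$seed, scale_px_per_mm = 200) {
  validate_params(params)
  set.seed(substream(seed, 3L))
  nw <- design$n_wings_per_cell
  hex <- unit_hexagon()
  cells <- params[!is.na(params$wing_mu), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    area <- rnorm(nw, cell$wing_mu, cell$wing_sd)
    while (any(area <= 0)) {
      area[area <= 0] <- rnorm(sum(area <= 0), cell$wing_mu, cell$wing_sd)
    }
    theta <- runif(nw, 0, 2 * pi)
    shift_x <- runif(nw, 400, 600)
    shift_y <- runif(nw, 400, 600)
    coords <- t(vapply(seq_len(nw), function(j) {
      rot <- matrix(c(cos(theta[j]), sin(theta[j]),
                      -sin(theta[j]), cos(theta[j])), 2, 2)
      pts <- hex %*% rot * sqrt(area[j]) * scale_px_per_mm
      c(rbind(pts[, 1] + shift_x[j], pts[, 2] + shift_y[j]))
    }, numeric(12)))
    colnames(coords) <- as.vector(rbind(paste0("x", 1:6), paste0("y", 1:6)))
    tibble::as_tibble(cbind(
      tibble::tibble(
        female_id = sprintf("%s_%s_%s_%s_w%02d", cell$wasp_strain,
                            cell$spiroplasma, sub("%", "", cell$ethanol),
                            substr(cell$exposure, 1, 4), seq_len(nw)),
        wasp_strain = factor(as.character(cell$wasp_strain), WASP_STRAINS),
        spiroplasma = factor(as.character(cell$spiroplasma), SPIRO_LEVELS),
        ethanol = factor(as.character(cell$ethanol), ETHANOL_LEVELS),
        exposure = factor(as.character(cell$exposure), EXPOSURE_LEVELS)
      ),
      tibble::as_tibble(coords),
      tibble::tibble(scale_px_per_mm = scale_px_per_mm)
    ))
  })
  dplyr::bind_rows(rows)
}

#' Generate per-larva oviposition counts
#'
#' Counts of wasp eggs/larvae per dissected host larva are Poisson with the
#' given rate; the default rate of 1.4 keeps the long-run mean between 1 and
#' 2 eggs per larva, as observed across all strain x symbiont combinations.
#'
#' @param n_larvae Number of dissected larvae.
#' @param lambda Poisson mean eggs per larva (> 0 unless exactly 0 allowed
#'   as a degenerate rate).
#' @param seed Integer seed.
#' @param wasp_strain,spiroplasma Labels attached to the generated rows.
#' @return An oviposition tibble (same schema as
#'   [read_oviposition_table()]).
#' @export
generate_oviposition <- function(n_larvae, lambda = 1.4, seed = 1L,
                                 wasp_strain = "LH_FR", spiroplasma = "S+") {
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  set.seed(substream(seed, 4L))
  strain <- match.arg(wasp_strain, WASP_STRAINS[-1])
  tibble::tibble(
    larva_id = sprintf("%s_%s_l%03d", strain, spiroplasma, seq_len(n_larvae)),
    wasp_strain = factor(strain, WASP_STRAINS[-1]),
    spiroplasma = factor(match.arg(spiroplasma, SPIRO_LEVELS), SPIRO_LEVELS),
    n_eggs_larvae = as.integer(rpois(n_larvae, lambda))
  )
}

#' Generate all four assay tables for one run
#'
#' Convenience wrapper deriving independent substreams for the vial,
#' fertility, wing and oviposition tables from one run seed. The
#' oviposition assay follows the reported design: attacked cells only,
#' without ethanol, for each strain x symbiont combination.
#'
#' @inheritParams generate_vials
#' @return A named list `vials`, `fertility`, `wings`, `oviposition`.
#' @export
simulate_experiment <- function(design = experiment_design(),
                                params = default_params(),
                                seed = design$seed) {
  ovi_cells <- unique(params[params$exposure == "exposed",
                             c("wasp_strain", "spiroplasma",
                               "oviposition_lambda")])
  ovi <- dplyr::bind_rows(lapply(seq_len(nrow(ovi_cells)), function(i) {
    generate_oviposition(
      design$n_larvae_dissected,
      lambda = ovi_cells$oviposition_lambda[i],
      seed = substream(seed, 40L + i),
      wasp_strain = as.character(ovi_cells$wasp_strain[i]),
      spiroplasma = as.character(ovi_cells$spiroplasma[i])
    )
  }))
  list(
    vials = generate_vials(design, params, seed),
    fertility = generate_fertility(design, params, seed),
    wings = generate_wings(design, params, seed),
    oviposition = ovi
  )
}

#' Parameter-recovery report for synthetic data
#'
#' Re-estimates per-cell survival, fertility and fecundity from generated
#' tables and compares each estimate with its generative truth. Survival and
#' fertility truths are the configured probabilities; the fecundity truth is
#' the exact mean of the rounded truncated-normal daughter distribution.
#' Standard errors are evaluated at the truth, and estimates more than
#' `3 * se` from the truth are flagged. Cells without data are reported as
#' unestimable (`NA` estimate, no flag).
#'
#' @param tables A list with `vials` and `fertility` tibbles.
#' @param params The generative parameter tibble.
#' @return A tibble with one row per cell x quantity: `estimate`, `truth`,
#'   `se`, `abs_error`, `n`, `flagged`.
#' @export
recover_params <- function(tables, params) {
  vial_est <- dplyr::summarise(
    dplyr::group_by(tables$vials, .data$block, .data$spiroplasma,
                    .data$ethanol,
                    exposure = factor(ifelse(.data$wasp_strain == "NONE",
                                             "unexposed", "exposed"),
                                      EXPOSURE_LEVELS)),
    n = sum(.data$n_larvae), k = sum(.data$n_flies),
    n_vials = dplyr::n(), .groups = "drop")
  fert_est <- dplyr::summarise(
    dplyr::group_by(tables$fertility, block = .data$wasp_strain,
                    .data$spiroplasma, .data$ethanol, .data$exposure),
    n = dplyr::n(), k = sum(.data$fertile),
    n_fert = sum(.data$fertile),
    mean_daughters = if (sum(.data$fertile) > 0)
      mean(.data$daughters_total[.data$fertile]) else NA_real_,
    .groups = "drop")

  rows <- lapply(seq_len(nrow(params)), function(i) {
    cell <- params[i, ]
    out <- list()
    ve <- vial_est[as.character(vial_est$block) ==
                     as.character(cell$wasp_strain) &
                     vial_est$spiroplasma == cell$spiroplasma &
                     vial_est$ethanol == cell$ethanol &
                     vial_est$exposure == cell$exposure, ]
    if (nrow(ve) == 1 && ve$n > 0) {
      m <- ve$n / ve$n_vials  # larvae per vial, for the overdispersion factor
      se <- sqrt(cell$p_fly * (1 - cell$p_fly) *
                   (1 + (m - 1) * cell$icc) / ve$n)
      est <- ve$k / ve$n
      out$survival <- tibble::tibble(
        quantity = "p_fly", estimate = est, truth = cell$p_fly, se = se,
        n = ve$n)
    } else {
      out$survival <- tibble::tibble(
        quantity = "p_fly", estimate = NA_real_, truth = cell$p_fly,
        se = NA_real_, n = 0L)
    }
    if (!is.na(cell$p_fertile)) {
      fe <- fert_est[as.character(fert_est$block) ==
                       as.character(cell$wasp_strain) &
                       fert_est$spiroplasma == cell$spiroplasma &
                       fert_est$ethanol == cell$ethanol &
                       fert_est$exposure == cell$exposure, ]
      if (nrow(fe) == 1 && fe$n > 0) {
        se_f <- sqrt(cell$p_fertile * (1 - cell$p_fertile) / fe$n)
        out$fertile <- tibble::tibble(
          quantity = "p_fertile", estimate = fe$k / fe$n,
          truth = cell$p_fertile, se = se_f, n = fe$n)
        mom <- fecundity_moments(cell$fecundity_mu, cell$fecundity_sd)
        if (!is.na(fe$mean_daughters) && fe$n_fert > 0) {
          out$fecundity <- tibble::tibble(
            quantity = "fecundity_mu", estimate = fe$mean_daughters,
            truth = mom$mean, se = mom$sd / sqrt(fe$n_fert), n = fe$n_fert)
        } else {
          out$fecundity <- tibble::tibble(
            quantity = "fecundity_mu", estimate = NA_real_, truth = mom$mean,
            se = NA_real_, n = 0L)
        }
      } else {
        out$fertile <- tibble::tibble(
          quantity = "p_fertile", estimate = NA_real_, truth = cell$p_fertile,
          se = NA_real_, n = 0L)
      }
    }
    res <- dplyr::bind_rows(out)
    res$wasp_strain <- cell$wasp_strain
    res$spiroplasma <- cell$spiroplasma
    res$ethanol <- cell$ethanol
    res$exposure <- cell$exposure
    res
  })
  rep <- dplyr::bind_rows(rows)
  rep$abs_error <- abs(rep$estimate - rep$truth)
  # degenerate cells (se = 0, e.g. truth exactly 0) must match exactly
  rep$flagged <- !is.na(rep$estimate) & !is.na(rep$se) &
    ifelse(rep$se > 0, rep$abs_error > 3 * rep$se, rep$abs_error > 0)
  rep[, c("wasp_strain", "spiroplasma", "ethanol", "exposure", "quantity",
          "estimate", "truth", "se", "abs_error", "n", "flagged")]
}
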