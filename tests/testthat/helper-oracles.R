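# Independent oracles used across the suite.

# Fan triangulation from the first vertex: sum of signed triangle areas.
fan_triangulation_area <- function(coords) {
  p0 <- coords[1, ]
  total <- 0
  for (i in 2:(nrow(coords) - 1)) {
    a <- coords[i, ] - p0
    b <- coords[i + 1, ] - p0
    total <- total + (a[1] * b[2] - a[2] * b[1]) / 2
  }
  abs(total)
}

# Random convex hexagon: six points on a noisy circle, sorted by angle.
random_convex_hexagon <- function() {
  ang <- sort(runif(6, 0, 2 * pi))
  r <- runif(6, 0.5, 2)
  cbind(r * cos(ang), r * sin(ang))
}

# Closed-form G statistic for a 2x2 successes/failures table.
g_statistic <- function(k, n) {
  o <- rbind(k, n - k)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  2 * sum(ifelse(o > 0, o * log(o / e), 0))
}

# Minimal vial tibble for handwritten fixtures.
make_vials <- function(n_flies, n_larvae = 30, strain = "LH_FR",
                       spiro = "S+", etoh = "0%", exposed = TRUE) {
  tibble::tibble(
    vial_id = sprintf("v%d", seq_along(n_flies)),
    wasp_strain = factor(if (exposed) strain else "NONE",
                         protindex::treatment_levels()$wasp_strain),
    spiroplasma = factor(spiro, c("S+", "S-")),
    ethanol = factor(etoh, c("0%", "6%")),
    block = factor(strain, protindex::treatment_levels()$wasp_strain),
    n_larvae = as.integer(n_larvae),
    n_pupae = as.integer(pmin(n_larvae, n_flies + 2L)),
    n_flies = as.integer(n_flies),
    n_wasps = 0L
  )
}
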