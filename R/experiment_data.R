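#' @importFrom rlang .data
#' @importFrom stats quantile rbeta rbinom rnorm rpois runif sd qbeta qnorm
#'   pnorm setNames complete.cases
NULL

# Canonical factor levels for the three crossed treatment factors.
WASP_STRAINS    <- c("NONE", "LH_FR", "LH14", "LH_MAD")
SPIRO_LEVELS    <- c("S+", "S-")
ETHANOL_LEVELS  <- c("0%", "6%")
EXPOSURE_LEVELS <- c("exposed", "unexposed")

#' Treatment factor levels
#'
#' The factorial design crosses parasitoid wasp strain (including the no-wasp
#' control arm `NONE`), host symbiont infection status (`S+` / `S-`), and
#' dietary ethanol (`0%` / `6%`). The cross yields the eight treatments run
#' per wasp strain.
#'
#' @return A named list with character vectors `wasp_strain`, `spiroplasma`,
#'   `ethanol` and `exposure`.
#' @export
#' @examples
#' treatment_levels()$wasp_strain
treatment_levels <- function() {
  list(
    wasp_strain = WASP_STRAINS,
    spiroplasma = SPIRO_LEVELS,
    ethanol     = ETHANOL_LEVELS,
    exposure    = EXPOSURE_LEVELS
  )
}

# --- parsing helpers ---------------------------------------------------------

parse_strain <- function(x) {
  up <- toupper(gsub("[^[:alnum:]]", "_", trimws(x)))
  up[up %in% c("LH_FR", "LHFR", "FR")]            <- "LH_FR"
  up[up %in% c("LH14", "LH_14")]                  <- "LH14"
  up[up %in% c("LH_MAD", "LHMAD", "MAD")]         <- "LH_MAD"
  up[up %in% c("NONE", "NO_WASP", "CONTROL", "")] <- "NONE"
  bad <- !up %in% WASP_STRAINS
  if (any(bad)) {
    stop("unknown wasp strain code(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  factor(up, levels = WASP_STRAINS)
}

parse_spiro <- function(x) {
  raw <- trimws(as.character(x))
  out <- rep(NA_character_, length(raw))
  out[raw %in% c("S+", "Splus", "SPLUS", "plus", "TRUE", "1", "pos")]   <- "S+"
  out[raw %in% c("S-", "Sminus", "SMINUS", "minus", "FALSE", "0", "neg")] <- "S-"
  bad <- is.na(out)
  if (any(bad)) {
    stop("unknown Spiroplasma code(s): ", paste(unique(raw[bad]), collapse = ", "),
         call. = FALSE)
  }
  factor(out, levels = SPIRO_LEVELS)
}

parse_ethanol <- function(x) {
  raw <- trimws(as.character(x))
  out <- rep(NA_character_, length(raw))
  out[raw %in% c("0", "0%", "EtOH0", "ETOH0", "none")] <- "0%"
  out[raw %in% c("6", "6%", "EtOH6", "ETOH6")]         <- "6%"
  bad <- is.na(out)
  if (any(bad)) {
    stop("unknown ethanol code(s): ", paste(unique(raw[bad]), collapse = ", "),
         call. = FALSE)
  }
  factor(out, levels = ETHANOL_LEVELS)
}

parse_exposure <- function(x) {
  raw <- tolower(trimws(as.character(x)))
  bad <- !raw %in% EXPOSURE_LEVELS
  if (any(bad)) {
    stop("unknown exposure code(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  factor(raw, levels = EXPOSURE_LEVELS)
}

# Counts must be whole numbers; decimal values are data-entry errors, not
# rounding candidates.
check_count <- function(x, name, id = NULL) {
  bad <- is.na(x) | x < 0 | x != floor(x)
  if (any(bad)) {
    where <- if (is.null(id)) which(bad)[1] else id[bad][1]
    stop("column '", name, "' must hold non-negative integers; offending row: ",
         where, call. = FALSE)
  }
  as.integer(x)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

read_assay_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# --- vial table --------------------------------------------------------------

#' Read and validate a per-vial emergence table
#'
#' Columns: `vial_id`, `wasp_strain`, `spiroplasma`, `ethanol`, `n_larvae`,
#' `n_pupae`, `n_flies`, `n_wasps`, and optionally `block` (the wasp-strain
#' block an unexposed control vial belongs to). Each vial records the number
#' of first-instar larvae placed (design value 30) and the pupae, adult flies
#' and adult wasps that emerged. Rows must satisfy
#' `n_flies + n_wasps <= n_pupae <= n_larvae`.
#'
#' @param path Path to a UTF-8 comma-delimited file with one header row.
#' @return A tibble with validated, canonically-typed columns.
#' @export
read_vial_table <- function(path) {
  df <- read_assay_csv(path)
  require_columns(df, c("vial_id", "wasp_strain", "spiroplasma", "ethanol",
                        "n_larvae", "n_pupae", "n_flies", "n_wasps"),
                  "vial table")
  if (nrow(df) == 0) return(empty_vial_table())
  out <- tibble::tibble(
    vial_id     = as.character(df$vial_id),
    wasp_strain = parse_strain(df$wasp_strain),
    spiroplasma = parse_spiro(df$spiroplasma),
    ethanol     = parse_ethanol(df$ethanol),
    block       = if ("block" %in% names(df)) parse_strain(df$block)
                  else parse_strain(as.character(df$wasp_strain)),
    n_larvae    = check_count(df$n_larvae, "n_larvae", df$vial_id),
    n_pupae     = check_count(df$n_pupae, "n_pupae", df$vial_id),
    n_flies     = check_count(df$n_flies, "n_flies", df$vial_id),
    n_wasps     = check_count(df$n_wasps, "n_wasps", df$vial_id)
  )
  validate_vials(out)
}

empty_vial_table <- function() {
  tibble::tibble(
    vial_id = character(), wasp_strain = factor(character(), WASP_STRAINS),
    spiroplasma = factor(character(), SPIRO_LEVELS),
    ethanol = factor(character(), ETHANOL_LEVELS),
    block = factor(character(), WASP_STRAINS),
    n_larvae = integer(), n_pupae = integer(),
    n_flies = integer(), n_wasps = integer()
  )
}

#' Validate vial count ordering
#'
#' Enforces `n_flies + n_wasps <= n_pupae <= n_larvae` per vial.
#'
#' @param vials A vial tibble as returned by [read_vial_table()].
#' @return The input, invisibly validated (returned unchanged).
#' @export
validate_vials <- function(vials) {
  bad <- vials$n_flies + vials$n_wasps > vials$n_pupae |
    vials$n_pupae > vials$n_larvae
  if (any(bad)) {
    stop("vial(s) violate count ordering n_flies + n_wasps <= n_pupae <= ",
         "n_larvae: ", paste(vials$vial_id[bad], collapse = ", "),
         call. = FALSE)
  }
  vials
}

# --- fertility table ---------------------------------------------------------

#' Read and validate a per-female fertility table
#'
#' Columns: `female_id`, `exposure` (`exposed` / `unexposed`), `wasp_strain`,
#' `spiroplasma`, `ethanol`, and four daily daughter counts `day2`..`day5`
#' (offspring emerging from eggs laid on assay days 2-5). `daughters_total`
#' and the `fertile` flag (any daughter produced) are always derived from the
#' daily counts; stored copies in the file are ignored with a warning if they
#' disagree.
#'
#' @inheritParams read_vial_table
#' @return A tibble with derived columns `daughters_total` and `fertile`.
#' @export
read_fertility_table <- function(path) {
  df <- read_assay_csv(path)
  day_cols <- c("day2", "day3", "day4", "day5")
  require_columns(df, c("female_id", "exposure", "wasp_strain", "spiroplasma",
                        "ethanol", day_cols), "fertility table")
  if (nrow(df) == 0) return(empty_fertility_table())
  days <- lapply(day_cols, function(cl) check_count(df[[cl]], cl, df$female_id))
  total <- Reduce(`+`, days)
  out <- tibble::tibble(
    female_id   = as.character(df$female_id),
    exposure    = parse_exposure(df$exposure),
    wasp_strain = parse_strain(df$wasp_strain),
    spiroplasma = parse_spiro(df$spiroplasma),
    ethanol     = parse_ethanol(df$ethanol),
    day2 = days[[1]], day3 = days[[2]], day4 = days[[3]], day5 = days[[4]],
    daughters_total = as.integer(total),
    fertile = total > 0L
  )
  for (stored in c("daughters_total", "fertile")) {
    if (stored %in% names(df)) {
      mismatch <- !is.na(df[[stored]]) &
        as.numeric(df[[stored]]) != as.numeric(out[[stored]])
      if (any(mismatch)) {
        warning("stored '", stored, "' disagrees with value derived from ",
                "daily counts for female(s) ",
                paste(out$female_id[mismatch], collapse = ", "),
                "; derived value used", call. = FALSE)
      }
    }
  }
  out
}

empty_fertility_table <- function() {
  tibble::tibble(
    female_id = character(),
    exposure = factor(character(), EXPOSURE_LEVELS),
    wasp_strain = factor(character(), WASP_STRAINS),
    spiroplasma = factor(character(), SPIRO_LEVELS),
    ethanol = factor(character(), ETHANOL_LEVELS),
    day2 = integer(), day3 = integer(), day4 = integer(), day5 = integer(),
    daughters_total = integer(), fertile = logical()
  )
}

# --- wing landmark table -----------------------------------------------------

#' Read and validate a wing-landmark table
#'
#' Columns: `female_id`, `wasp_strain`, `spiroplasma`, `ethanol`, `exposure`,
#' the six landmark coordinates `x1`,`y1`,...,`x6`,`y6` in pixels (landmarks
#' supplied in boundary order around the wing), and `scale_px_per_mm`
#' (pixels per millimetre from a scale slide, positive).
#'
#' @inheritParams read_vial_table
#' @return A validated tibble.
#' @export
read_wing_table <- function(path) {
  df <- read_assay_csv(path)
  coord_cols <- as.vector(rbind(paste0("x", 1:6), paste0("y", 1:6)))
  require_columns(df, c("female_id", "wasp_strain", "spiroplasma", "ethanol",
                        "exposure", coord_cols, "scale_px_per_mm"),
                  "wing table")
  if (nrow(df) == 0) return(empty_wing_table())
  coords <- df[coord_cols]
  if (any(!complete.cases(coords))) {
    stop("wing table has missing landmark coordinates", call. = FALSE)
  }
  if (any(is.na(df$scale_px_per_mm) | df$scale_px_per_mm <= 0)) {
    stop("scale_px_per_mm must be positive for every wing", call. = FALSE)
  }
  tibble::as_tibble(c(
    list(
      female_id   = as.character(df$female_id),
      wasp_strain = parse_strain(df$wasp_strain),
      spiroplasma = parse_spiro(df$spiroplasma),
      ethanol     = parse_ethanol(df$ethanol),
      exposure    = parse_exposure(df$exposure)
    ),
    lapply(coords, as.numeric),
    list(scale_px_per_mm = as.numeric(df$scale_px_per_mm))
  ))
}

empty_wing_table <- function() {
  coord_cols <- as.vector(rbind(paste0("x", 1:6), paste0("y", 1:6)))
  tibble::as_tibble(c(
    list(
      female_id = character(),
      wasp_strain = factor(character(), WASP_STRAINS),
      spiroplasma = factor(character(), SPIRO_LEVELS),
      ethanol = factor(character(), ETHANOL_LEVELS),
      exposure = factor(character(), EXPOSURE_LEVELS)
    ),
    setNames(rep(list(numeric()), 12), coord_cols),
    list(scale_px_per_mm = numeric())
  ))
}

# --- oviposition table -------------------------------------------------------

#' Read and validate a per-larva wasp oviposition table
#'
#' Columns: `larva_id`, `wasp_strain` (a real strain, never `NONE`),
#' `spiroplasma`, `n_eggs_larvae` (wasp eggs plus wasp larvae counted in a
#' dissected host larva; non-negative integer).
#'
#' @inheritParams read_vial_table
#' @return A validated tibble.
#' @export
read_oviposition_table <- function(path) {
  df <- read_assay_csv(path)
  require_columns(df, c("larva_id", "wasp_strain", "spiroplasma",
                        "n_eggs_larvae"), "oviposition table")
  if (nrow(df) == 0) return(empty_oviposition_table())
  strain <- parse_strain(df$wasp_strain)
  if (any(strain == "NONE")) {
    stop("oviposition rows require an attacking wasp strain (not NONE)",
         call. = FALSE)
  }
  tibble::tibble(
    larva_id      = as.character(df$larva_id),
    wasp_strain   = factor(as.character(strain), WASP_STRAINS[-1]),
    spiroplasma   = parse_spiro(df$spiroplasma),
    n_eggs_larvae = check_count(df$n_eggs_larvae, "n_eggs_larvae", df$larva_id)
  )
}

empty_oviposition_table <- function() {
  tibble::tibble(
    larva_id = character(),
    wasp_strain = factor(character(), WASP_STRAINS[-1]),
    spiroplasma = factor(character(), SPIRO_LEVELS),
    n_eggs_larvae = integer()
  )
}

# --- writer ------------------------------------------------------------------

#' Write an assay table to CSV
#'
#' Round-trips losslessly with the corresponding reader: factors are written
#' as their canonical string codes, counts as integers. UTF-8,
#' comma-delimited, one header row.
#'
#' @param records A tibble from one of the readers or generators.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_assay_table <- function(records, path) {
  df <- as.data.frame(records)
  fct <- vapply(df, is.factor, logical(1))
  df[fct] <- lapply(df[fct], as.character)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
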