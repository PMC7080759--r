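# Wing size from six landmark coordinates: interior polygon area by the
# shoelace formula, converted from pixels to mm^2 by the per-image scale.

#' Polygon area of six wing landmarks
#'
#' Absolute shoelace area of the hexagon traced by the landmarks in
#' boundary order, in pixel units and in mm^2 (`area_px2 / scale^2`).
#' Orientation-independent; repeated consecutive points simply collapse an
#' edge. Fewer than three distinct points give zero area with a warning.
#'
#' @param coords A 6x2 numeric matrix (or 12-vector x1,y1,...,x6,y6) of
#'   landmark coordinates in pixels.
#' @param scale Pixels per millimetre (> 0).
#' @param female_id Optional identifier carried into the result.
#' @return A list of class `wing_area`: `female_id`, `area_px2`,
#'   `area_mm2`.
#' @export
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0.5, 1), c(0, 1), c(0, 0.5))
#' polygon_area(sq, scale = 1)$area_mm2  # unit square
polygon_area <- function(coords, scale, female_id = NA_character_) {
  if (is.numeric(coords) && is.null(dim(coords))) {
    coords <- matrix(coords, ncol = 2, byrow = TRUE)
  }
  coords <- as.matrix(coords)
  if (nrow(coords) != 6 || ncol(coords) != 2) {
    stop("six (x, y) landmark pairs are required", call. = FALSE)
  }
  if (length(scale) != 1 || is.na(scale) || scale <= 0) {
    stop("scale must be a positive pixels-per-mm value", call. = FALSE)
  }
  if (nrow(unique(coords)) < 3) {
    warning("fewer than 3 distinct landmarks; area is zero", call. = FALSE)
  }
  x <- coords[, 1]
  y <- coords[, 2]
  j <- c(2:6, 1)
  area_px2 <- abs(sum(x * y[j] - x[j] * y)) / 2
  structure(
    list(female_id = female_id, area_px2 = area_px2,
         area_mm2 = area_px2 / scale^2),
    class = "wing_area"
  )
}

#' Wing areas for a whole landmark table
#'
#' Applies [polygon_area()] to every row of a wing tibble.
#'
#' @param wings A wing tibble from [read_wing_table()] or
#'   [generate_wings()].
#' @return The grouping columns of the input plus `area_px2` and
#'   `area_mm2`.
#' @export
wing_areas <- function(wings) {
  coord_cols <- as.vector(rbind(paste0("x", 1:6), paste0("y", 1:6)))
  areas <- vapply(seq_len(nrow(wings)), function(i) {
    polygon_area(as.numeric(wings[i, coord_cols]),
                 wings$scale_px_per_mm[i])$area_mm2
  }, numeric(1))
  out <- wings[, setdiff(names(wings), c(coord_cols, "scale_px_per_mm"))]
  out$area_mm2 <- areas
  out$area_px2 <- areas * wings$scale_px_per_mm^2
  out
}

#' Group means, SEs, and differences in wing area
#'
#' Per-group mean and standard error of wing area, plus each group's
#' difference from the reference group in mm^2 and as a percent of the
#' reference mean. Groups with a single observation (no SE) or none are
#' excluded with a warning.
#'
#' @param areas A tibble with an `area_mm2` column.
#' @param group Name of the grouping column (default `"exposure"`).
#' @param reference Reference level (default `"unexposed"`).
#' @return A tibble: `group`, `n`, `mean_mm2`, `se_mm2`, `diff_mm2`
#'   (reference minus group), `percent_smaller`.
#' @export
#' @examples
#' df <- tibble::tibble(
#'   exposure = rep(c("unexposed", "exposed"), each = 2),
#'   area_mm2 = c(1.31, 1.29, 1.27, 1.25)
#' )
#' summarize_wings(df)
summarize_wings <- function(areas, group = "exposure",
                            reference = "unexposed") {
  g <- as.character(areas[[group]])
  counts <- table(g)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning("group(s) with fewer than 2 observations excluded: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !g %in% small
    areas <- areas[keep, ]
    g <- g[keep]
  }
  if (!reference %in% g) {
    stop("reference group '", reference, "' not present", call. = FALSE)
  }
  levels_ <- unique(c(reference, sort(unique(g))))
  out <- dplyr::bind_rows(lapply(levels_, function(lv) {
    a <- areas$area_mm2[g == lv]
    tibble::tibble(group = lv, n = length(a), mean_mm2 = mean(a),
                   se_mm2 = sd(a) / sqrt(length(a)))
  }))
  ref_mean <- out$mean_mm2[out$group == reference]
  out$diff_mm2 <- ref_mean - out$mean_mm2
  out$percent_smaller <- percent_change(ref_mean, out$mean_mm2)
  out
}
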