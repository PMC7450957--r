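#' RGB to HSI conversion
#'
#' Standard HSI decomposition used by the colour-plane thresholding strategy:
#' intensity `I = (R + G + B) / 3` (0-255), saturation
#' `S = 1 - min(R,G,B) / I` (0-1, 0 where I = 0), hue from the standard
#' geometric formula in degrees (0-360, 0 where the pixel is achromatic).
#'
#' @param pixels H x W x 3 array of 8-bit RGB values.
#' @return List of matrices `H`, `S`, `I`.
#' @export
rgb_to_hsi <- function(pixels) {
  R <- pixels[, , 1]; G <- pixels[, , 2]; B <- pixels[, , 3]
  I <- (R + G + B) / 3
  mn <- pmin(R, G, B)
  S <- ifelse(I > 0, 1 - mn / I, 0)
  num <- 0.5 * ((R - G) + (R - B))
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  theta <- acos(pmin(pmax(ifelse(den > 0, num / den, 1), -1), 1)) * 180 / pi
  H <- ifelse(B <= G, theta, 360 - theta)
  H[den == 0] <- 0
  list(H = H, S = S, I = I)
}

#' Two-boundary colour-plane threshold rule
#'
#' A rule selects pixels whose value in one colour plane (R, G, B in 0-255,
#' H in degrees, S in 0-1, I in 0-255) lies inside `[lower, upper]` — the
#' two fixed boundaries of the classic thresholding strategy.
#'
#' @param plane One of `"R"`, `"G"`, `"B"`, `"H"`, `"S"`, `"I"`.
#' @param lower,upper Boundaries, `lower <= upper`.
#' @return A `threshold_rule`.
#' @export
threshold_rule <- function(plane = c("R", "G", "B", "H", "S", "I"),
                           lower, upper) {
  plane <- match.arg(plane)
  if (!(is.numeric(lower) && is.numeric(upper)) || lower > upper) {
    abort("`lower` must be <= `upper`.")
  }
  structure(list(plane = plane, lower = lower, upper = upper),
            class = "threshold_rule")
}

plane_values <- function(image, plane) {
  if (plane %in% c("R", "G", "B")) {
    image$pixels[, , match(plane, c("R", "G", "B"))]
  } else {
    rgb_to_hsi(image$pixels)[[plane]]
  }
}

#' Two-stage colour-plane threshold segmentation
#'
#' The classic-panel strategy: stage 1 selects the rosette as the pixels
#' whose `rosette_rule` plane value lies between the rule's two boundaries;
#' stage 2 marks damage inside that selection by `damage_rule`. Pixels
#' outside the stage-1 selection can never be marked damaged.
#'
#' @param image A [scan_image()].
#' @param rosette_rule,damage_rule [threshold_rule()]s.
#' @return Logical damage mask.
#' @export
threshold_classify <- function(image, rosette_rule, damage_rule) {
  stopifnot(inherits(image, "scan_image"),
            inherits(rosette_rule, "threshold_rule"),
            inherits(damage_rule, "threshold_rule"))
  v1 <- plane_values(image, rosette_rule$plane)
  sel <- v1 >= rosette_rule$lower & v1 <= rosette_rule$upper
  v2 <- plane_values(image, damage_rule$plane)
  sel & v2 >= damage_rule$lower & v2 <= damage_rule$upper
}

#' Square-unit grid rule
#'
#' @param unit_size Square side in mm (> 0).
#' @param sensitivity Ordinal sensitivity level 1 (least) to 9 (most).
#' @return A `grid_rule`.
#' @export
grid_rule <- function(unit_size = 0.5, sensitivity = 5) {
  if (unit_size <= 0) abort("`unit_size` must be > 0.")
  if (!sensitivity %in% 1:9) abort("`sensitivity` must be an integer in 1..9.")
  structure(list(unit_size = unit_size, sensitivity = as.integer(sensitivity)),
            class = "grid_rule")
}

# Strictly decreasing cutoff ladder on the green-deficiency score g: higher
# sensitivity -> lower cutoff -> nested, larger detections.
GRID_CUTOFFS <- seq(0.95, 0.55, length.out = 9)

#' Grid-average green-deficiency segmentation
#'
#' The square-unit strategy: the image is tiled into squares of
#' `unit_size` mm (pixels are assigned to the square containing their
#' centre); for every square overlapping the rosette the mean R, G, B over
#' its rosette pixels is computed, and the square is marked damaged when the
#' green-deficiency score `g = mean(meanR, meanB) / max(meanG, 1)` exceeds a
#' cutoff that decreases strictly with the sensitivity level (so detections
#' at level s are nested inside level s + 1). The damage mask is the union of
#' marked squares intersected with the rosette; averaging only rosette pixels
#' makes the result independent of the background colour.
#'
#' @param image A [scan_image()].
#' @param rosette A `rosette_mask` from [segment_rosette()].
#' @param rule A [grid_rule()]; `unit_size` must be at least 2 px at the
#'   image dpi.
#' @return Logical damage mask.
#' @export
grid_classify <- function(image, rosette, rule) {
  stopifnot(inherits(image, "scan_image"), inherits(rosette, "rosette_mask"),
            inherits(rule, "grid_rule"))
  px_mm <- 25.4 / image$dpi
  unit_px <- rule$unit_size / px_mm
  if (unit_px < 2) {
    abort("grid unit smaller than 2 px at this dpi.",
          class = "mitedamage_unit_too_small")
  }
  d <- dim(image)
  cell_r <- floor(((seq_len(d[1]) - 0.5) * px_mm) / rule$unit_size)
  cell_c <- floor(((seq_len(d[2]) - 0.5) * px_mm) / rule$unit_size)
  cell_id <- outer(cell_r, cell_c * (max(cell_r) + 1L), `+`) + 1L
  m <- rosette$mask
  ids <- cell_id[m]
  if (length(ids) == 0L) return(matrix(FALSE, d[1], d[2]))
  mR <- tapply(image$pixels[, , 1][m], ids, mean)
  mG <- tapply(image$pixels[, , 2][m], ids, mean)
  mB <- tapply(image$pixels[, , 3][m], ids, mean)
  g <- ((mR + mB) / 2) / pmax(mG, 1)
  marked <- as.integer(names(g))[g > GRID_CUTOFFS[rule$sensitivity]]
  out <- matrix(cell_id %in% marked, d[1], d[2]) & m
  out
}
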