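#' Emulate the manual grid-counting standard
#'
#' The manual reference method overlays a square grid (classically
#' 0.25 x 0.25 mm) on the image and counts marked squares; the damaged area
#' is the count times the square area. Under the `any-overlap` rule a square
#' is counted as soon as any damaged pixel overlaps it — which is why the
#' manual standard systematically overestimates: every counted square whose
#' area is not fully damaged adds healthy tissue to the estimate. Under the
#' `majority` rule a square is counted only when more than half of its area
#' is damaged.
#'
#' Overlap is computed exactly in physical units: pixel `i` spans
#' `[(i-1) p, i p)` mm (p = pixel pitch), grid cell `I` spans
#' `[I g, (I+1) g)` mm, and the damaged area inside each cell is accumulated
#' through the rectangle-overlap weights of pixels against cells, so
#' fractional pixel/cell alignment is handled without resampling.
#'
#' @param truth_damage Logical matrix of damaged pixels (e.g. a ground-truth
#'   damage mask, standing in for the rater's marks).
#' @param grid_size Grid square side in mm (> 0; default 0.25).
#' @param rule `"any-overlap"` or `"majority"`.
#' @param dpi Resolution calibrating pixel size.
#' @return Estimated damaged area in mm^2 (`count * grid_size^2`).
#' @export
manual_grid_emulate <- function(truth_damage, grid_size = 0.25,
                                rule = c("any-overlap", "majority"), dpi) {
  rule <- match.arg(rule)
  if (grid_size <= 0) abort("`grid_size` must be > 0.")
  stopifnot(is.matrix(truth_damage))
  storage.mode(truth_damage) <- "logical"
  if (!any(truth_damage)) return(0)
  p <- 25.4 / dpi
  Wy <- overlap_weights(nrow(truth_damage), p, grid_size)
  Wx <- overlap_weights(ncol(truth_damage), p, grid_size)
  covered <- Wy %*% truth_damage %*% t(Wx) # damaged area (mm^2) per cell
  eps <- 1e-9 * p^2
  n_cells <- if (rule == "any-overlap") {
    sum(covered > eps)
  } else {
    sum(covered > grid_size^2 / 2)
  }
  n_cells * grid_size^2
}

# Rows = grid cells, cols = pixels; entry = 1-D overlap length (mm) between
# pixel j's span and cell I's span.
overlap_weights <- function(n_px, p, g) {
  n_cells <- ceiling(n_px * p / g)
  lo_px <- (seq_len(n_px) - 1) * p
  hi_px <- lo_px + p
  W <- matrix(0, n_cells, n_px)
  for (I in seq_len(n_cells)) {
    lo <- (I - 1) * g
    hi <- I * g
    ov <- pmin(hi, hi_px) - pmax(lo, lo_px)
    pos <- ov > 0
    W[I, pos] <- ov[pos]
  }
  W
}
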