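#' Segment the rosette from the scanner background
#'
#' Plant pixels are those whose Euclidean RGB distance from the background
#' reference colour (white = (255,255,255), black = (0,0,0), per the image's
#' background tag) exceeds `threshold`. The largest connected component is
#' kept, interior holes are filled, and the total rosette area follows from
#' the pixel count and the dpi calibration.
#'
#' @param image A [scan_image()].
#' @param threshold RGB distance above which a pixel counts as plant
#'   (default 60).
#' @return A `rosette_mask`: list with `mask` (logical matrix), `dpi`,
#'   `area_mm2`.
#' @export
segment_rosette <- function(image, threshold = 60) {
  stopifnot(inherits(image, "scan_image"))
  plant <- plant_mask(image, threshold)
  lab <- label_components(plant, connectivity = 8)
  if (max(lab) == 0L) {
    abort("no plant found in image.", class = "mitedamage_no_plant")
  }
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  mask <- fill_holes(mask)
  rosette_mask(mask, image$dpi)
}

plant_mask <- function(image, threshold = 60) {
  ref <- if (image$background == "white") 255 else 0
  d2 <- (image$pixels[, , 1] - ref)^2 +
    (image$pixels[, , 2] - ref)^2 +
    (image$pixels[, , 3] - ref)^2
  d2 > threshold^2
}

# Fill interior holes: background components (4-connectivity) that do not
# touch the image border are enclosed by the mask and become foreground.
fill_holes <- function(mask) {
  lab <- label_components(!mask, connectivity = 4)
  if (max(lab) == 0L) return(mask)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labs <- border_labs[border_labs > 0L]
  mask | (lab > 0L & !(lab %in% border_labs))
}

rosette_mask <- function(mask, dpi) {
  structure(
    list(mask = mask, dpi = dpi, area_mm2 = sum(mask) * pixel_area_mm2(dpi)),
    class = "rosette_mask"
  )
}

#' @export
print.rosette_mask <- function(x, ...) {
  cat(sprintf(
    "<rosette_mask> %d x %d px, %d plant px, %.1f mm2\n",
    nrow(x$mask), ncol(x$mask), sum(x$mask), x$area_mm2
  ))
  invisible(x)
}

#' Split a multi-rosette scan into individual rosettes
#'
#' Finds every connected plant component above `min_area`, crops each with a
#' margin, and returns the crops ordered top-left to bottom-right (by the
#' top edge, then the left edge, of the component bounding box). Each crop's
#' mask contains only its own component's pixels, so plant pixels are
#' conserved across the split.
#'
#' @param image A [scan_image()] possibly containing several rosettes.
#' @param min_area Minimum component area in mm^2 to count as a rosette.
#' @param threshold RGB background-distance threshold (see
#'   [segment_rosette()]).
#' @param margin_px Crop margin in pixels.
#' @return A list of `list(image = scan_image, mask = rosette_mask)`, possibly
#'   empty.
#' @export
split_rosettes <- function(image, min_area = 10, threshold = 60, margin_px = 8) {
  stopifnot(inherits(image, "scan_image"))
  plant <- plant_mask(image, threshold)
  lab <- label_components(plant, connectivity = 8)
  if (max(lab) == 0L) return(list())
  sizes <- tabulate(lab[lab > 0L])
  pa <- pixel_area_mm2(image$dpi)
  keep <- which(sizes * pa >= min_area)
  if (length(keep) == 0L) return(list())
  boxes <- lapply(keep, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    c(
      r0 = min(idx[, 1]), r1 = max(idx[, 1]),
      c0 = min(idx[, 2]), c1 = max(idx[, 2])
    )
  })
  ord <- order(
    vapply(boxes, `[[`, numeric(1), "r0"),
    vapply(boxes, `[[`, numeric(1), "c0")
  )
  lapply(ord, function(o) {
    k <- keep[o]; b <- boxes[[o]]
    r <- max(1L, b["r0"] - margin_px):min(nrow(lab), b["r1"] + margin_px)
    cc <- max(1L, b["c0"] - margin_px):min(ncol(lab), b["c1"] + margin_px)
    crop <- scan_image(image$pixels[r, cc, , drop = FALSE], image$dpi,
                       image$background)
    m <- lab[r, cc, drop = FALSE] == k
    list(image = crop, mask = rosette_mask(m, image$dpi))
  })
}
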