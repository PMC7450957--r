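#' Construct a calibrated RGB scan image
#'
#' The basic unit every pipeline stage consumes: an 8-bit RGB pixel grid with
#' its physical calibration (dots per inch) and the background the rosette was
#' scanned on. Pixels are stored as an H x W x 3 numeric array of channel
#' values in `[0, 255]`, row-major with the origin at the top-left corner.
#'
#' @param pixels H x W x 3 numeric array, channel values in `[0, 255]`.
#' @param dpi Scan resolution in dots per inch (> 0).
#' @param background Background the plant was scanned on: `"white"` or
#'   `"black"`. The background tag travels with the image because the
#'   segmentation reference colour and the scan-condition contract depend
#'   on it.
#' @return A `scan_image` object.
#' @export
scan_image <- function(pixels, dpi, background = c("white", "black")) {
  background <- match.arg(background)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    abort("`pixels` must be an H x W x 3 array (RGB).", class = "mitedamage_non_rgb")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("channel values must lie in [0, 255] with no missing values.")
  }
  if (!is.numeric(dpi) || length(dpi) != 1L || is.na(dpi) || dpi <= 0) {
    abort("`dpi` must be a single positive number.")
  }
  structure(
    list(pixels = pixels, dpi = as.numeric(dpi), background = background),
    class = "scan_image"
  )
}

#' @export
print.scan_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<scan_image> %d x %d px, %g dpi, %s background (%.1f x %.1f mm)\n",
    d[1], d[2], x$dpi, x$background,
    d[1] * 25.4 / x$dpi, d[2] * 25.4 / x$dpi
  ))
  invisible(x)
}

#' @export
dim.scan_image <- function(x) dim(x$pixels)[1:2]

#' Physical area of one pixel
#'
#' Converts a scan resolution into the area one pixel covers on the scanner
#' bed: a pixel is `25.4 / dpi` mm on a side.
#'
#' @param dpi Dots per inch (> 0).
#' @return Pixel area in mm^2, i.e. `(25.4 / dpi)^2`.
#' @examples
#' pixel_area_mm2(1200) # 4.48028e-4 mm^2
#' @export
pixel_area_mm2 <- function(dpi) {
  if (!is.numeric(dpi) || any(is.na(dpi)) || any(dpi <= 0)) {
    abort("`dpi` must be positive.")
  }
  (25.4 / dpi)^2
}

#' Scanner brightness/contrast conditions
#'
#' A scan condition records the brightness and contrast settings (in scanner
#' units) and the background a set of scans was acquired under. `condition_id`
#' is free text (e.g. `"A1"`, `"W3"`, `"B2"`).
#'
#' `scan_condition_set()` returns the two built-in condition tables used in
#' the damage-estimation stability study (six conditions, `A1`-`A6`, applied
#' on both backgrounds) and the method-performance study (three brightness
#' steps per background, `W1`-`W3` and `B1`-`B3`). Both brightness and
#' contrast are stored explicitly per condition.
#'
#' @param condition_id Free-text identifier, unique within a condition set.
#' @param brightness Scanner brightness units (additive, see
#'   [apply_scan_condition()]).
#' @param contrast Scanner contrast units.
#' @param background `"white"` or `"black"`.
#' @return A one-row tibble (a condition set is a tibble of such rows).
#' @export
scan_condition <- function(condition_id, brightness, contrast,
                           background = c("white", "black")) {
  background <- match.arg(background)
  tibble::tibble(
    condition_id = as.character(condition_id),
    brightness = as.numeric(brightness),
    contrast = as.numeric(contrast),
    background = background
  )
}

#' @rdname scan_condition
#' @param set Which built-in table: `"stability"` (A1-A6, both backgrounds) or
#'   `"performance"` (W1-W3 on white, B1-B3 on black).
#' @export
scan_condition_set <- function(set = c("stability", "performance")) {
  set <- match.arg(set)
  if (set == "stability") {
    base <- tibble::tibble(
      condition_id = paste0("A", 1:6),
      contrast = c(-100, -50, -69, -69, -69, -56),
      brightness = c(90, 25, 40, 30, 20, 1)
    )
    dplyr::bind_rows(
      dplyr::mutate(base, background = "white"),
      dplyr::mutate(base, background = "black")
    )[, c("condition_id", "brightness", "contrast", "background")]
  } else {
    tibble::tibble(
      condition_id = c("W1", "W2", "W3", "B1", "B2", "B3"),
      brightness = c(20, 30, 40, 30, 40, 50),
      contrast = c(-20, -20, -20, -10, -10, -10),
      background = rep(c("white", "black"), each = 3)
    )
  }
}

#' Emulate a scanner brightness/contrast setting
#'
#' Applies the pixel-level transform standing in for flatbed-scanner
#' brightness/contrast controls: brightness is an additive offset in 8-bit
#' counts and contrast a gain about mid-grey 128 following the standard 8-bit
#' contrast curve `gain = 259 (C + 255) / (255 (259 - C))`, so
#'
#' `out = clip_0^255( gain * (in - 128) + 128 + brightness )`
#'
#' The transform is the identity at brightness 0 / contrast 0, and a
#' brightness step of +10 moves every non-saturated pixel by exactly +10
#' counts. The condition's background must match the image's: background is
#' part of the acquisition condition, not a free parameter.
#'
#' @param image A [scan_image()].
#' @param condition A one-row condition tibble (see [scan_condition()]).
#' @return A `scan_image` with transformed pixels.
#' @export
apply_scan_condition <- function(image, condition) {
  stopifnot(inherits(image, "scan_image"))
  if (!is.data.frame(condition) || nrow(condition) != 1L) {
    abort("`condition` must be a one-row condition tibble.")
  }
  if (!identical(condition$background, image$background)) {
    abort(
      sprintf(
        "condition background (%s) does not match image background (%s).",
        condition$background, image$background
      ),
      class = "mitedamage_background_mismatch"
    )
  }
  gain <- contrast_gain(condition$contrast)
  out <- gain * (image$pixels - 128) + 128 + condition$brightness
  out <- pmin(pmax(out, 0), 255)
  scan_image(out, dpi = image$dpi, background = image$background)
}

contrast_gain <- function(contrast) {
  (259 * (contrast + 255)) / (255 * (259 - contrast))
}

#' Read and write calibrated scans
#'
#' `write_scan()` writes a scan as PNG (dpi embedded in the pHYs chunk) or
#' TIFF. The available TIFF writer cannot embed resolution tags, so TIFF
#' output gets a small JSON sidecar `<path>.meta.json` carrying the dpi.
#' `read_scan()` restores pixels and dpi losslessly; it takes dpi from the
#' embedded metadata, then from a sidecar, then from `dpi` given explicitly,
#' and fails if none is available.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param background Background tag to attach on read.
#' @param dpi Optional dpi override used when the file carries no resolution
#'   metadata.
#' @param image A [scan_image()].
#' @return `read_scan()` a `scan_image`; `write_scan()` the path, invisibly.
#' @export
read_scan <- function(path, background = c("white", "black"), dpi = NULL) {
  background <- match.arg(background)
  if (!file.exists(path)) {
    abort(sprintf("scan file not found: %s", path), class = "mitedamage_missing_file")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    file_dpi <- if (!is.null(info$dpi) && all(is.finite(info$dpi))) {
      mean(info$dpi)
    } else {
      NULL
    }
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    xres <- attr(img, "x.resolution")
    unit <- attr(img, "resolution.unit")
    file_dpi <- if (!is.null(xres) && (is.null(unit) || identical(unit, "inch"))) {
      as.numeric(xres)
    } else {
      NULL
    }
  } else {
    abort("only PNG and TIFF scans are supported.")
  }
  sidecar <- paste0(path, ".meta.json")
  if (is.null(file_dpi) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    file_dpi <- as.numeric(meta$dpi)
  }
  if (is.null(file_dpi)) file_dpi <- dpi
  # PNG stores resolution as integer pixels-per-metre; undo the quantisation
  # so integer dpi values survive a round-trip
  if (!is.null(file_dpi) && abs(file_dpi - round(file_dpi)) < 0.05) {
    file_dpi <- round(file_dpi)
  }
  if (is.null(file_dpi)) {
    abort(
      sprintf("%s carries no dpi metadata; pass `dpi` explicitly.", path),
      class = "mitedamage_missing_dpi"
    )
  }
  if (length(dim(img)) != 3L || dim(img)[3] < 3L) {
    abort(
      sprintf("%s is not an RGB image.", path),
      class = "mitedamage_non_rgb"
    )
  }
  px <- round(img[, , 1:3, drop = FALSE] * 255)
  scan_image(px, dpi = file_dpi, background = background)
}

#' @rdname read_scan
#' @export
write_scan <- function(image, path) {
  stopifnot(inherits(image, "scan_image"))
  ext <- tolower(tools::file_ext(path))
  arr <- image$pixels / 255
  if (ext == "png") {
    png::writePNG(arr, target = path, dpi = image$dpi)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(arr, where = path, bits.per.sample = 8L, compression = "none")
    jsonlite::write_json(
      list(dpi = image$dpi, background = image$background),
      paste0(path, ".meta.json"),
      auto_unbox = TRUE
    )
  } else {
    abort("only PNG and TIFF scans are supported.")
  }
  invisible(path)
}
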