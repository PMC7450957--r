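#' Label connected components of a binary mask
#'
#' Breadth-first-search connected-component labelling with selectable
#' connectivity; components are numbered 1..k in scan order of their first
#' pixel, so the labelling is deterministic.
#'
#' @param mask Logical matrix (TRUE = foreground).
#' @param connectivity 4 (edge neighbours) or 8 (edge + diagonal).
#' @return Integer matrix of the same shape; 0 = background.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  storage.mode(mask) <- "logical"
  label_components_cpp(mask, as.integer(connectivity))
}

#' Remove small damage clusters
#'
#' Noise filter of the damage-quantification pipeline: connected components
#' of the damage mask with fewer than `min_size` pixels are discarded;
#' components with `min_size` pixels or more are kept intact (strictly
#' "under the threshold is disregarded": a component of exactly `min_size`
#' pixels survives).
#'
#' @param damage_mask Logical matrix of detected damage pixels.
#' @param min_size Minimum component size in pixels (>= 0; 0 is the
#'   identity).
#' @param connectivity Component connectivity, 4 or 8 (default 8, the more
#'   conservative merging).
#' @return Filtered logical mask, always a subset of the input.
#' @export
cluster_filter <- function(damage_mask, min_size, connectivity = 8) {
  if (min_size < 0) abort("`min_size` must be >= 0.")
  if (min_size == 0) {
    storage.mode(damage_mask) <- "logical"
    return(damage_mask)
  }
  lab <- label_components(damage_mask, connectivity)
  if (max(lab) == 0L) return(lab > 0L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  out <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  out
}

#' Calibrate the cluster-size noise threshold from control rosettes
#'
#' Control rosettes carry no real damage, so every cluster a segmentation
#' method detects on them is a false detection. Pooling the sizes of those
#' clusters across all control masks and taking the mean (rounded to the
#' nearest integer) gives the minimum cluster size below which detections are
#' treated as noise. The pooled size-frequency table is returned alongside so
#' the calibration can be inspected.
#'
#' @param control_masks List of logical damage masks from control rosettes.
#' @param connectivity Component connectivity, 4 or 8.
#' @return A `cluster_calibration`: list with `threshold` (pixels),
#'   `cluster_sizes` (pooled), `freq` (tibble of size, n), `n_masks`.
#' @export
select_cluster_threshold <- function(control_masks, connectivity = 8) {
  if (!is.list(control_masks) || length(control_masks) == 0L) {
    abort("`control_masks` must be a non-empty list of masks.")
  }
  sizes <- unlist(lapply(control_masks, function(m) {
    lab <- label_components(m, connectivity)
    if (max(lab) == 0L) return(integer(0))
    tabulate(lab[lab > 0L])
  }))
  if (length(sizes) == 0L) {
    abort("no clusters detected in any control mask: nothing to calibrate.",
          class = "mitedamage_nothing_to_calibrate")
  }
  freq <- dplyr::count(tibble::tibble(size = as.integer(sizes)), .data$size,
                       name = "n")
  structure(
    list(
      threshold = as.integer(round(mean(sizes))),
      cluster_sizes = as.integer(sizes),
      freq = freq,
      n_masks = length(control_masks)
    ),
    class = "cluster_calibration"
  )
}

#' @export
print.cluster_calibration <- function(x, ...) {
  cat(sprintf(
    "<cluster_calibration> threshold %d px (mean of %d clusters from %d control masks)\n",
    x$threshold, length(x$cluster_sizes), x$n_masks
  ))
  invisible(x)
}

#' @export
tidy.cluster_calibration <- function(x, ...) x$freq

#' @export
glance.cluster_calibration <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    n_clusters = length(x$cluster_sizes),
    mean_size = mean(x$cluster_sizes),
    n_masks = x$n_masks
  )
}
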