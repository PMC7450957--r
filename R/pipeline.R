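#' Reproducible run configuration
#'
#' A run config bundles everything a pipeline run depends on, so a run is
#' fully determined by (config, inputs): the master seed, the imaging
#' parameters, the cohort design, the classifier recipe and the
#' cluster-filter settings. It round-trips through plain-text YAML so the
#' file can be archived next to the outputs.
#'
#' @param seed Master seed.
#' @param dpi Scan resolution.
#' @param background `"white"` or `"black"`.
#' @param specs List of [phenotype_spec()]s.
#' @param n_replicates Replicates per spec per arm.
#' @param n_train Scans used to train the classifier.
#' @param labels_per_class Sparse labels sampled per class per training scan.
#' @param scales Feature scales.
#' @param n_trees Forest size.
#' @param connectivity Cluster connectivity (4 or 8).
#' @param min_cluster Minimum cluster size in pixels, or `"auto"` to
#'   calibrate from the control rosettes via [select_cluster_threshold()].
#' @return A `run_config`.
#' @export
run_config <- function(seed = 1, dpi = 150, background = "white",
                       specs = list(), n_replicates = 8, n_train = 6,
                       labels_per_class = 300, scales = c(1, 2, 4),
                       n_trees = 100, connectivity = 8, min_cluster = "auto") {
  structure(
    list(
      seed = as.integer(seed), dpi = dpi, background = background,
      specs = specs, n_replicates = n_replicates, n_train = n_train,
      labels_per_class = labels_per_class, scales = scales,
      n_trees = n_trees, connectivity = connectivity,
      min_cluster = min_cluster
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$specs <- lapply(cfg$specs, unclass)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$specs <- lapply(cfg$specs, function(s) do.call(phenotype_spec, s))
  do.call(run_config, cfg[setdiff(names(cfg), character(0))])
}

#' Write a simulated cohort to disk
#'
#' Writes each scan as a PNG (dpi embedded), its ground-truth class map as a
#' single-channel PNG label image (pixel value = class code), a JSON sidecar
#' with seed, spec and true areas, and a `manifest.csv` (see
#' [cohort_manifest()]).
#'
#' @param scans Cohort from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(scans, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("cannot create output directory %s", dir))
  for (s in scans) {
    stem <- file.path(dir, s$meta$rosette_id)
    write_scan(s$image, paste0(stem, ".png"))
    png::writePNG(s$truth$class_map / 255, paste0(stem, "_truth.png"))
    jsonlite::write_json(
      list(
        seed = s$seed, spec = unclass(s$spec),
        true_damage_area_mm2 = s$truth$true_damage_area,
        true_rosette_area_mm2 = s$truth$true_rosette_area,
        meta = s$meta
      ),
      paste0(stem, ".json"), auto_unbox = TRUE, digits = NA
    )
  }
  manifest <- cohort_manifest(scans)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Train a classifier on a cohort's training split
#'
#' Emulates the training protocol: `n_train` scans (a mix of infested and
#' control rosettes) are selected deterministically from the seed, sparse
#' labels are sampled from their ground truth (confounders never labelled,
#' see [sample_labels()]), and a random forest is fitted on the pooled
#' labels.
#'
#' @param scans Cohort from [generate_cohort()].
#' @param n_train Number of training scans (>= 2).
#' @param labels_per_class Labels per class per scan.
#' @param seed Selection/sampling/forest seed.
#' @param scales,n_trees See [train_pixel_classifier()].
#' @return A `pixel_classifier`; the indices of the training scans are
#'   attached as attribute `train_idx`.
#' @export
train_cohort_classifier <- function(scans, n_train = 6, labels_per_class = 300,
                                    seed = 1, scales = c(1, 2, 4), n_trees = 100) {
  stopifnot(length(scans) >= n_train, n_train >= 2)
  treatments <- vapply(scans, function(s) s$meta$treatment, character(1))
  idx <- withr::with_seed(as.integer(seed), {
    # guarantee both arms are represented, as in the training protocol
    inf <- sample(which(treatments == "infested"))
    ctl <- sample(which(treatments == "control"))
    n_inf <- min(length(inf), ceiling(n_train / 2))
    c(inf[seq_len(n_inf)], ctl[seq_len(min(length(ctl), n_train - n_inf))])
  })
  labels <- purrr::imap(scans[idx], function(s, k) {
    sample_labels(s, n_per_class = labels_per_class,
                  seed = child_seed(seed, 500000L + k))
  })
  model <- train_pixel_classifier(
    images = purrr::map(scans[idx], "image"), labels = labels,
    seed = seed, n_trees = n_trees, scales = scales
  )
  attr(model, "train_idx") <- idx
  model
}

#' Quantify damage over a cohort of scans
#'
#' Runs the measurement pipeline on every scan: rosette segmentation, damage
#' segmentation by the supplied strategy, cluster-size noise filtering
#' (threshold either fixed or auto-calibrated on the control scans' raw
#' detections), and conversion to mm^2.
#'
#' @param scans Cohort from [generate_cohort()] (or any list of objects with
#'   `$image` and `$meta`).
#' @param strategy A `pixel_classifier`, a
#'   `list(rosette_rule =, damage_rule =)` of [threshold_rule()]s, or a
#'   [grid_rule()].
#' @param min_cluster Minimum cluster size in pixels, or `"auto"`.
#' @param connectivity Cluster connectivity (4 or 8).
#' @param condition_id Condition tag recorded in the measurements.
#' @return Measurement tibble, one row per scan (see [measure()]); the
#'   cluster threshold used is attached as attribute `cluster_threshold`.
#' @export
quantify_cohort <- function(scans, strategy, min_cluster = "auto",
                            connectivity = 8, condition_id = "sim") {
  masks <- purrr::map(scans, function(s) {
    ros <- segment_rosette(s$image)
    dmg <- segment_damage(s$image, ros, strategy) & ros$mask
    list(rosette = ros, damage = dmg)
  })
  treatments <- vapply(scans, function(s) s$meta$treatment, character(1))
  if (identical(min_cluster, "auto")) {
    ctl_masks <- purrr::map(masks[treatments == "control"], "damage")
    cal <- tryCatch(
      select_cluster_threshold(ctl_masks, connectivity = connectivity),
      mitedamage_nothing_to_calibrate = function(e) NULL
    )
    min_cluster <- if (is.null(cal)) 0L else cal$threshold
  }
  out <- purrr::map2_dfr(scans, masks, function(s, m) {
    filtered <- cluster_filter(m$damage, min_cluster, connectivity)
    measure(
      filtered, m$rosette,
      rosette_id = s$meta$rosette_id, genotype = s$meta$genotype,
      treatment = s$meta$treatment, condition_id = condition_id,
      background = s$image$background
    )
  })
  attr(out, "cluster_threshold") <- min_cluster
  out
}

segment_damage <- function(image, rosette, strategy) {
  if (inherits(strategy, "pixel_classifier")) {
    damage_mask(classify_pixels(strategy, image))
  } else if (inherits(strategy, "grid_rule")) {
    grid_classify(image, rosette, strategy)
  } else if (is.list(strategy) &&
             all(c("rosette_rule", "damage_rule") %in% names(strategy))) {
    threshold_classify(image, strategy$rosette_rule, strategy$damage_rule)
  } else {
    abort("`strategy` must be a pixel_classifier, grid_rule, or a list with rosette_rule and damage_rule.",
          class = "mitedamage_missing_model")
  }
}

#' Ground-truth measurements of a synthetic cohort
#'
#' @param scans Cohort from [generate_cohort()].
#' @return Tibble with one row per scan: id, genotype, treatment, true
#'   rosette and damage areas in mm^2.
#' @export
truth_measurements <- function(scans) {
  cohort_manifest(scans)[, c("rosette_id", "genotype", "treatment",
                             "true_rosette_area_mm2", "true_damage_area_mm2")]
}

#' Run the full simulation-to-report pipeline
#'
#' End-to-end orchestration of one study: simulate the cohort, train the
#' pixel classifier on its training split, quantify every scan with
#' auto-calibrated cluster filtering, apply the per-group control
#' correction, and measure each stage against ground truth.
#'
#' @param config A [run_config()].
#' @return List with `scans`, `model`, `measurements` (per-rosette, with
#'   `cluster_threshold` attribute), `corrected`, `truth`, and `comparison`
#'   (corrected vs truth, per rosette).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  scans <- generate_cohort(
    config$specs, n_replicates = config$n_replicates, seed = config$seed,
    dpi = config$dpi, background = config$background
  )
  model <- train_cohort_classifier(
    scans, n_train = config$n_train,
    labels_per_class = config$labels_per_class,
    seed = config$seed, scales = config$scales, n_trees = config$n_trees
  )
  measurements <- quantify_cohort(
    scans, model, min_cluster = config$min_cluster,
    connectivity = config$connectivity
  )
  corrected <- correct_damage(measurements)
  truth <- truth_measurements(scans)
  comparison <- dplyr::left_join(
    corrected,
    truth[, c("rosette_id", "true_damage_area_mm2")],
    by = "rosette_id"
  )
  list(
    scans = scans, model = model, measurements = measurements,
    corrected = corrected, truth = truth, comparison = comparison
  )
}
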