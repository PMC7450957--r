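#' Sparse pixel annotations
#'
#' A label set is the rater's sparse annotation of a scan: a tibble of pixel
#' coordinates (1-based row/col) with a class in `background`, `healthy`,
#' `damaged`. Coordinates must lie inside the image and no pixel may be
#' labelled twice.
#'
#' @param row,col Integer pixel coordinates (1-based).
#' @param class Character vector of classes.
#' @param image Optional [scan_image()] to validate coordinates against.
#' @return A tibble with columns `row`, `col`, `class`.
#' @export
label_set <- function(row, col, class, image = NULL) {
  class <- as.character(class)
  bad <- setdiff(unique(class), TRAIN_CLASSES)
  if (length(bad) > 0) {
    abort(sprintf("unknown classes: %s", paste(bad, collapse = ", ")))
  }
  lab <- tibble::tibble(row = as.integer(row), col = as.integer(col), class = class)
  if (anyDuplicated(lab[, c("row", "col")]) > 0) {
    abort("each pixel may be labelled at most once.")
  }
  if (!is.null(image)) {
    d <- dim(image)
    if (any(lab$row < 1 | lab$row > d[1] | lab$col < 1 | lab$col > d[2])) {
      abort("label coordinates outside the image.")
    }
  }
  lab
}

#' Sample training labels from a synthetic scan's ground truth
#'
#' Emulates the rater's sparse annotation: up to `n_per_class` pixels per
#' training class are sampled from the ground-truth class map. Confounder
#' pixels are never sampled — the rater labels only unambiguous background,
#' healthy tissue and damage, so the classifier has to generalise over
#' confounders (the failure mode the downstream correction absorbs).
#'
#' @param scan A `synthetic_scan`.
#' @param n_per_class Labels per class (classes absent from the scan are
#'   skipped).
#' @param seed Sampling seed.
#' @return A label tibble (see [label_set()]).
#' @export
sample_labels <- function(scan, n_per_class = 300, seed = 1) {
  stopifnot(inherits(scan, "synthetic_scan"))
  cm <- scan$truth$class_map
  codes <- c(background = CLASS_BACKGROUND, healthy = CLASS_HEALTHY,
             damaged = CLASS_DAMAGED)
  withr::with_seed(as.integer(seed), {
    parts <- purrr::imap(codes, function(code, cls) {
      idx <- which(cm == code)
      if (length(idx) == 0L) return(NULL)
      take <- idx[sample.int(length(idx), min(n_per_class, length(idx)))]
      tibble::tibble(
        row = ((take - 1L) %% nrow(cm)) + 1L,
        col = ((take - 1L) %/% nrow(cm)) + 1L,
        class = cls
      )
    })
  })
  dplyr::bind_rows(parts)
}

#' Train the random-forest pixel classifier
#'
#' Fits a probability random forest on the multi-scale features (see
#' [extract_features()]) of the labelled pixels pooled over the training
#' scans. All three classes (`background`, `healthy`, `damaged`) must be
#' present in the pooled labels. Training-pixel resampling happens inside the
#' forest's per-tree bagging; with a fixed `seed` (and single-threaded
#' growing) training and prediction are fully deterministic.
#'
#' @param images List of [scan_image()]s.
#' @param labels List of label tibbles, parallel to `images`.
#' @param seed Forest seed.
#' @param n_trees Number of trees (default 100).
#' @param scales Feature scales, see [extract_features()].
#' @return A `pixel_classifier`.
#' @export
train_pixel_classifier <- function(images, labels, seed = 1, n_trees = 100,
                                   scales = c(1, 2, 4, 8)) {
  stopifnot(length(images) == length(labels), length(images) >= 1L)
  pooled <- dplyr::bind_rows(labels)
  missing_cls <- setdiff(TRAIN_CLASSES, unique(pooled$class))
  if (length(missing_cls) > 0) {
    abort(
      sprintf("no labels for class(es): %s", paste(missing_cls, collapse = ", ")),
      class = "mitedamage_missing_class"
    )
  }
  rows <- purrr::map2(images, labels, function(img, lab) {
    if (is.null(lab) || nrow(lab) == 0L) return(NULL)
    d <- dim(img)
    if (any(lab$row < 1 | lab$row > d[1] | lab$col < 1 | lab$col > d[2])) {
      abort("label coordinates outside the image.")
    }
    f <- extract_features(img, scales)
    idx <- (lab$col - 1L) * d[1] + lab$row
    cbind(as.data.frame(f[idx, , drop = FALSE]), .class = lab$class)
  })
  train <- dplyr::bind_rows(rows)
  y <- factor(train$.class, levels = TRAIN_CLASSES)
  x <- train[, setdiff(names(train), ".class"), drop = FALSE]
  forest <- ranger::ranger(
    x = x, y = y,
    num.trees = n_trees,
    probability = TRUE,
    seed = as.integer(seed),
    num.threads = 1
  )
  structure(
    list(
      forest = forest,
      scales = scales,
      classes = TRAIN_CLASSES,
      seed = as.integer(seed),
      n_trees = as.integer(n_trees)
    ),
    class = "pixel_classifier"
  )
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(
    "<pixel_classifier> %d trees, scales {%s}, classes {%s}, seed %d\n",
    x$n_trees, paste(x$scales, collapse = ", "),
    paste(x$classes, collapse = ", "), x$seed
  ))
  invisible(x)
}

predict_class_probs <- function(model, image) {
  if (!inherits(model, "pixel_classifier")) {
    abort("`model` must be a trained pixel_classifier.",
          class = "mitedamage_untrained")
  }
  f <- extract_features(image, model$scales)
  p <- stats::predict(model$forest, data = as.data.frame(f),
                      num.threads = 1)$predictions
  # ranger's probability columns follow the factor levels used in training
  p[, model$classes, drop = FALSE]
}

#' Classify every pixel of a scan
#'
#' Predicts class probabilities per pixel and takes the arg-max, with ties
#' resolved by the fixed class order background < healthy < damaged.
#'
#' @param model A [train_pixel_classifier()] fit.
#' @param image A [scan_image()].
#' @return A `class_map`: integer matrix (0 background, 1 healthy, 2 damaged)
#'   with a `classes` attribute. Use [damage_mask()] to extract the binary
#'   damage mask.
#' @export
classify_pixels <- function(model, image) {
  p <- predict_class_probs(model, image)
  cls <- max.col(p, ties.method = "first") - 1L # 0-based codes, fixed order
  d <- dim(image)
  out <- matrix(cls, d[1], d[2])
  attr(out, "classes") <- TRAIN_CLASSES
  out
}

#' @rdname classify_pixels
#' @param class_map An integer class map from [classify_pixels()].
#' @export
damage_mask <- function(class_map) {
  class_map == CLASS_DAMAGED
}

#' Per-pixel classification uncertainty
#'
#' `1 - (top probability - runner-up probability)`: 0 where the forest is
#' unanimous, 1 where the two best classes tie. Ranking pixels by this map
#' drives the active-learning loop — new labels are solicited where the
#' classifier is least certain, and retraining on them lowers mean
#' uncertainty.
#'
#' @inheritParams classify_pixels
#' @return Numeric H x W matrix in `[0, 1]`.
#' @export
uncertainty_map <- function(model, image) {
  p <- predict_class_probs(model, image)
  top <- pmax(p[, 1], p[, 2], p[, 3])
  bottom <- pmin(p[, 1], p[, 2], p[, 3])
  second <- rowSums(p) - top - bottom
  d <- dim(image)
  matrix(1 - (top - second), d[1], d[2])
}
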