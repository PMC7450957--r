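test_that("feature stack has the documented layout and degenerate limits", {
  flat <- scan_image(array(77, c(20, 20, 3)), dpi = 300, background = "white")
  f <- extract_features(flat, scales = c(1, 2))
  expect_identical(ncol(f), 3L + 7L * 2L)
  expect_lt(max(abs(f[, grep("gradmag|laplacian|st_eig", colnames(f))])), 1e-9)
  expect_true(all(f[, "R"] == 77))

  # at a scale comparable to the image, smoothing approaches the image mean
  set.seed(1)
  noisy <- scan_image(array(runif(3 * 24 * 24, 0, 255), c(24, 24, 3)),
                      dpi = 300, background = "white")
  g <- extract_features(noisy, scales = 64)
  centre <- 12 * 24 + 12 # an interior pixel, column-major
  expect_lt(abs(g[centre, "sR_s64"] - mean(noisy$pixels[, , 1])) /
              mean(noisy$pixels[, , 1]), 0.01)
  expect_error(extract_features(flat, scales = numeric(0)), "scale")
})

test_that("training reaches near-perfect resubstitution accuracy and is seeded", {
  s <- quick_scan(seed = 51)
  lab <- sample_labels(s, n_per_class = 400, seed = 1)
  model <- train_pixel_classifier(list(s$image), list(lab), seed = 3,
                                  n_trees = 60, scales = c(1, 2))
  cm <- classify_pixels(model, s$image)
  idx <- cbind(lab$row, lab$col)
  acc <- mean(c("background", "healthy", "damaged")[cm[idx] + 1L] == lab$class)
  expect_gte(acc, 0.99)

  model2 <- train_pixel_classifier(list(s$image), list(lab), seed = 3,
                                   n_trees = 60, scales = c(1, 2))
  probe <- quick_scan(seed = 52)
  expect_identical(classify_pixels(model, probe$image),
                   classify_pixels(model2, probe$image))
})

test_that("training without a class fails naming the absent class", {
  s <- quick_scan(seed = 51)
  lab <- sample_labels(s, n_per_class = 50, seed = 1)
  lab <- lab[lab$class != "damaged", ]
  expect_error(
    train_pixel_classifier(list(s$image), list(lab), seed = 1, n_trees = 10),
    "damaged",
    class = "mitedamage_missing_class"
  )
})

test_that("classifier state survives serialisation with identical predictions", {
  s <- quick_scan(seed = 53)
  lab <- sample_labels(s, n_per_class = 150, seed = 2)
  model <- train_pixel_classifier(list(s$image), list(lab), seed = 5,
                                  n_trees = 40, scales = c(1, 2))
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(model, path)
  reloaded <- readRDS(path)
  probe <- quick_scan(seed = 54)
  expect_identical(classify_pixels(model, probe$image),
                   classify_pixels(reloaded, probe$image))
})

test_that("held-out damage segmentation beats the Jaccard benchmark", {
  run <- study_run()
  held_out <- setdiff(seq_along(run$scans), attr(run$model, "train_idx"))
  infested <- held_out[vapply(run$scans[held_out],
                              function(s) s$meta$treatment, "") == "infested"]
  jacs <- vapply(run$scans[infested[1:6]], function(s) {
    pred <- damage_mask(classify_pixels(run$model, s$image))
    truth <- s$truth$class_map == 2L
    sum(pred & truth) / sum(pred | truth)
  }, numeric(1))
  expect_gte(mean(jacs), 0.6)

  probe <- scan_image(array(250, c(24, 24, 3)), dpi = 300, background = "white")
  cm <- classify_pixels(run$model, probe)
  expect_identical(sum(damage_mask(cm)), 0L)
})

test_that("uncertainty has margin semantics and falls after targeted relabelling", {
  run <- study_run()
  model <- run$model
  s <- run$scans[[setdiff(seq_along(run$scans), attr(model, "train_idx"))[1]]]
  u <- uncertainty_map(model, s$image)
  expect_true(all(u >= 0 & u <= 1 + 1e-12))

  # active-learning loop: add labels where the model is least certain
  thr <- stats::quantile(u, 0.9)
  cand <- which(u >= thr & s$truth$class_map != 3L)
  set.seed(1)
  take <- cand[sample.int(length(cand), 400)]
  extra <- tibble::tibble(
    row = ((take - 1L) %% nrow(u)) + 1L,
    col = ((take - 1L) %/% nrow(u)) + 1L,
    class = c("background", "healthy", "damaged")[s$truth$class_map[take] + 1L]
  )
  base_imgs <- purrr::map(run$scans[attr(model, "train_idx")], "image")
  base_labs <- purrr::map(run$scans[attr(model, "train_idx")],
                          sample_labels, n_per_class = 300, seed = 1)
  m1 <- train_pixel_classifier(base_imgs, base_labs, seed = 5, n_trees = 60,
                               scales = c(1, 2, 4))
  m2 <- train_pixel_classifier(c(base_imgs, list(s$image)),
                               c(base_labs, list(extra)),
                               seed = 5, n_trees = 60, scales = c(1, 2, 4))
  expect_lt(mean(uncertainty_map(m2, s$image)),
            mean(uncertainty_map(m1, s$image)))
})

test_that("two-stage thresholding honours its boundary contracts", {
  s <- quick_scan(seed = 61)
  rosr <- threshold_rule("I", 40, 240)
  all_in <- threshold_rule("I", 0, 255)
  v <- mitedamage:::plane_values(s$image, "I")
  stage1 <- v >= 40 & v <= 240
  expect_identical(threshold_classify(s$image, rosr, all_in), stage1)
  none <- threshold_rule("I", 1000, 1000)
  expect_identical(sum(threshold_classify(s$image, rosr, none)), 0L)
  expect_error(threshold_rule("I", 10, 5), "lower")
})

test_that("a tuned threshold rule recovers area but also marks confounders", {
  tune_on <- quick_scan(seed = 71)
  rosr <- threshold_rule("I", 40, 240)
  lowers <- seq(150, 230, by = 5)
  best <- lowers[which.min(vapply(lowers, function(lo) {
    m <- threshold_classify(tune_on$image, rosr, threshold_rule("I", lo, 255))
    abs(sum(m) * pixel_area_mm2(150) - tune_on$truth$true_damage_area)
  }, numeric(1)))]
  rule <- threshold_rule("I", best, 255)
  for (seed in 72:73) {
    s <- quick_scan(seed = seed)
    m <- threshold_classify(s$image, rosr, rule)
    est <- sum(m) * pixel_area_mm2(150)
    expect_lt(abs(est - s$truth$true_damage_area) / s$truth$true_damage_area, 0.3)
    expect_gt(sum(m & s$truth$class_map == 3L), 0) # confounders swept in
  }
})

test_that("threshold and grid masks ignore background-only changes", {
  w <- quick_scan(seed = 75, background = "white")
  b <- quick_scan(seed = 75, background = "black")
  rosr <- threshold_rule("I", 40, 240)
  dmgr <- threshold_rule("I", 180, 255)
  expect_identical(threshold_classify(w$image, rosr, dmgr),
                   threshold_classify(b$image, rosr, dmgr))
  # identical plant pixels, only the background differs: use the shared
  # ground-truth plant mask so the mean-colour squares see the same tissue
  rule <- grid_rule(unit_size = 1, sensitivity = 6)
  rmask <- mitedamage:::rosette_mask(w$truth$class_map != 0L, 150)
  expect_identical(grid_classify(w$image, rmask, rule),
                   grid_classify(b$image, rmask, rule))
})

test_that("grid detection is empty on pure green and nested in sensitivity", {
  n <- 60
  arr <- array(0, c(n, n, 3))
  disc <- outer(1:n, 1:n, function(i, j) (i - 30)^2 + (j - 30)^2 <= 20^2)
  arr[, , 2][disc] <- 140
  img <- scan_image(arr, dpi = 150, background = "black")
  ros <- segment_rosette(img)
  for (s in c(1, 5, 9)) {
    expect_identical(sum(grid_classify(img, ros, grid_rule(1, s))), 0L)
  }

  s <- quick_scan(seed = 81)
  ros <- segment_rosette(s$image)
  prev <- NULL
  areas <- numeric(0)
  for (lev in 1:9) {
    m <- grid_classify(s$image, ros, grid_rule(0.8, lev))
    if (!is.null(prev)) expect_true(all(m[prev])) # nested detections
    prev <- m
    areas <- c(areas, sum(m))
  }
  expect_gte(areas[9], areas[1])
  expect_error(grid_classify(s$image, ros, grid_rule(0.2, 5)),
               class = "mitedamage_unit_too_small")
})

test_that("manual grid emulation matches its brute-force oracle on both rules", {
  set.seed(4)
  for (k in 1:8) {
    m <- random_blob_mask(n = 24, n_blobs = 2)
    for (rule in c("any-overlap", "majority")) {
      expect_equal(
        manual_grid_emulate(m, grid_size = 0.5, rule = rule, dpi = 150),
        oracle_grid_area(m, 0.5, rule, 150)
      )
    }
  }
})

test_that("any-overlap counting never underestimates the exact pixel area", {
  set.seed(9)
  for (k in 1:20) {
    m <- random_blob_mask(n = 40, n_blobs = 3)
    exact <- sum(m) * pixel_area_mm2(300)
    est <- manual_grid_emulate(m, 0.25, "any-overlap", dpi = 300)
    expect_gte(est, exact - 1e-12)
  }
  single <- matrix(FALSE, 10, 10); single[1, 1] <- TRUE
  expect_equal(manual_grid_emulate(single, 0.25, "any-overlap", dpi = 1200),
               0.0625)
  expect_equal(manual_grid_emulate(matrix(FALSE, 5, 5), 0.25, "any-overlap",
                                   dpi = 300), 0)
})
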