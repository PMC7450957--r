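test_that("cluster filter keeps components at or above the size threshold", {
  # four well-separated components of sizes 5, 36, 37, 40
  m2 <- matrix(FALSE, 32, 40)
  m2[1, 1:5] <- TRUE                      # 5
  m2[5:10, 1:6] <- TRUE                   # 36
  m2[14:20, 1:5] <- TRUE; m2[14, 6:7] <- TRUE # 37
  m2[24:28, 10:17] <- TRUE                # 40
  sizes <- sort(tabulate(label_components(m2, 8)[label_components(m2, 8) > 0]))
  expect_identical(sizes, c(5L, 36L, 37L, 40L))
  kept <- cluster_filter(m2, min_size = 37, connectivity = 8)
  expect_identical(sum(kept), 77L)

  expect_identical(cluster_filter(m2, 0), m2)
  # output is a subset, and kept area is non-increasing in min_size
  areas <- vapply(c(0, 5, 20, 37, 50), function(k) {
    f <- cluster_filter(m2, k)
    expect_true(all(m2[f]))
    sum(f)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("cluster filter agrees with the flood-fill oracle on random masks", {
  set.seed(2)
  for (k in 1:25) {
    m <- matrix(runif(20 * 20) < 0.3, 20, 20)
    for (conn in c(4, 8)) {
      min_size <- sample(1:6, 1)
      expect_identical(cluster_filter(m, min_size, conn),
                       oracle_size_filter(m, min_size, conn))
    }
  }
})

test_that("threshold calibration pools control clusters and takes the mean", {
  one <- matrix(FALSE, 20, 20)
  one[1, 1:10] <- TRUE        # 10
  one[5:8, 1:5] <- TRUE       # 20
  one[12:17, 3:7] <- TRUE     # 30
  cal <- select_cluster_threshold(list(one), connectivity = 8)
  expect_identical(cal$threshold, 20L)
  expect_identical(sort(cal$cluster_sizes), c(10L, 20L, 30L))
  expect_identical(sum(cal$freq$n), 3L)

  single <- matrix(FALSE, 10, 10); single[3:5, 3:5] <- TRUE
  expect_identical(select_cluster_threshold(list(single))$threshold, 9L)

  two_a <- matrix(FALSE, 10, 10); two_a[1, 1:4] <- TRUE
  two_b <- matrix(FALSE, 10, 10); two_b[5:6, 5:8] <- TRUE
  expect_identical(select_cluster_threshold(list(two_a, two_b))$threshold,
                   select_cluster_threshold(list(two_b, two_a))$threshold)

  expect_error(select_cluster_threshold(list(matrix(FALSE, 5, 5))),
               class = "mitedamage_nothing_to_calibrate")
})

test_that("measurement converts pixel counts at the dpi calibration", {
  ros <- matrix(TRUE, 50, 40)
  dmg <- matrix(FALSE, 50, 40); dmg[1:25, 1:40] <- TRUE # 1000 px
  row <- measure(dmg, mitedamage:::rosette_mask(ros, 1200))
  expect_equal(row$damage_area_mm2, 1000 * (25.4 / 1200)^2)
  expect_equal(row$damage_area_mm2, 0.4480, tolerance = 1e-4)
  expect_equal(row$total_area_mm2, 2000 * (25.4 / 1200)^2)

  none <- measure(matrix(FALSE, 50, 40), mitedamage:::rosette_mask(ros, 1200))
  expect_identical(none$damage_area_mm2, 0)

  # damage outside the rosette mask cannot count
  half <- matrix(FALSE, 50, 40); half[, 1:20] <- TRUE
  spill <- dmg; spill[, 21:40] <- TRUE
  a <- measure(dmg, mitedamage:::rosette_mask(half, 1200))
  b <- measure(spill & half, mitedamage:::rosette_mask(half, 1200))
  expect_equal(a$damage_area_mm2, b$damage_area_mm2)
  expect_error(measure(dmg, mitedamage:::rosette_mask(ros & FALSE, 1200)),
               class = "mitedamage_no_plant")
})

test_that("correction model is the mean control damage fraction", {
  model <- fit_correction(toy_controls())
  expect_equal(model$mean_control_fraction, 0.03)
  expect_identical(model$n_controls, 2L)

  expect_equal(fit_correction(toy_controls(da = c(0, 0)))$mean_control_fraction, 0)
  # scale invariance of the fraction
  doubled <- fit_correction(toy_controls(da = c(4, 8), ta = c(200, 200)))
  expect_equal(doubled$mean_control_fraction, 0.03)

  mixed <- dplyr::mutate(toy_controls(), genotype = c("g", "h"))
  expect_error(fit_correction(mixed), class = "mitedamage_mixed_group")
  expect_error(fit_correction(toy_controls()[0, ]), "non-empty")
})

test_that("corrected area subtracts the scaled control fraction, dropping non-positives", {
  model <- fit_correction(toy_controls())
  out <- apply_correction(toy_treated(), model)
  expect_equal(out$corrected_area_mm2, 4.0)
  expect_identical(out$status, "ok")

  zero <- fit_correction(toy_controls(da = c(0, 0)))
  expect_equal(apply_correction(toy_treated(), zero)$corrected_area_mm2, 10)

  heavy <- fit_correction(toy_controls(da = c(10, 10)))
  dropped <- apply_correction(toy_treated(), heavy)
  expect_identical(dropped$status, "dropped_nonpositive")
  expect_true(is.na(dropped$corrected_area_mm2))

  wrong <- dplyr::mutate(toy_treated(), condition_id = "b9")
  expect_error(apply_correction(wrong, model), class = "mitedamage_mixed_group")
  # corrected never exceeds the uncorrected damage
  out2 <- apply_correction(toy_treated(da = c(5, 12, 30), ta = c(90, 140, 400)),
                           model)
  expect_true(all(out2$corrected_area_mm2 <= c(5, 12, 30), na.rm = TRUE))
})

test_that("group-wise correction fits one model per group and reports attrition", {
  meas <- dplyr::bind_rows(
    toy_controls(), toy_treated(),
    dplyr::mutate(toy_controls(da = c(8, 8)), genotype = "h",
                  rosette_id = c("c3", "c4")),
    dplyr::mutate(toy_treated(da = 5, ta = 100), genotype = "h",
                  rosette_id = "t2")
  )
  out <- correct_damage(meas)
  expect_identical(nrow(out), 2L)
  g <- out[out$genotype == "g", ]
  expect_equal(g$corrected_area_mm2, 4.0)
  h <- out[out$genotype == "h", ]
  expect_identical(h$status, "dropped_nonpositive") # 5 - 0.08*100 < 0

  orphan <- dplyr::mutate(toy_treated(), genotype = "z")
  expect_error(correct_damage(dplyr::bind_rows(toy_controls(), orphan)),
               class = "mitedamage_no_controls")
  expect_warning(correct_damage(toy_controls()), "empty")
})
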