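test_that("Bland-Altman bias and limits of agreement match hand arithmetic", {
  df <- tibble::tibble(y = c(10, 20, 30), x = y + c(1, 2, 3))
  ba <- bland_altman(df, x, y)
  expect_equal(ba$bias, 2)
  expect_equal(ba$loa_low, 2 - 1.96)
  expect_equal(ba$loa_high, 2 + 1.96)
  expect_identical(ba$n_pairs, 3L)

  same <- tibble::tibble(x = c(1, 5, 9), y = x)
  ba0 <- bland_altman(same, x, y)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_low, 0)
  expect_equal(ba0$loa_high, 0)
})

test_that("percent mode divides differences by the pair mean", {
  df <- tibble::tibble(y = c(2, 7, 11), x = 2 * y)
  ba <- bland_altman(df, x, y, mode = "percent")
  expect_true(all(abs(ba$differences - 2 / 3) < 1e-12))
  # percent differences of positive data are bounded in (-2, 2)
  set.seed(3)
  rnd <- tibble::tibble(x = rlnorm(200), y = rlnorm(200))
  bar <- bland_altman(rnd, x, y, mode = "percent")
  expect_true(all(bar$differences > -2 & bar$differences < 2))
})

test_that("incomplete pairs are excluded and counted; too few pairs rejected", {
  df <- tibble::tibble(x = c(1, 2, NA, 4), y = c(1.5, NA, 3, 4.5))
  ba <- bland_altman(df, x, y)
  expect_identical(ba$n_pairs, 2L)
  expect_identical(ba$n_excluded, 2L)
  expect_error(bland_altman(df[1:2, ], x, y),
               class = "mitedamage_too_few_pairs")
})

test_that("repeatability coefficient and its chi-square interval behave", {
  df <- tibble::tibble(y = c(5, 6, 7), x = y + c(-1, 0, 1))
  cr <- repeatability(df, x, y)
  expect_equal(cr$cr, 1.96)
  expect_lt(cr$cr_low, cr$cr)
  expect_gt(cr$cr_high, cr$cr)

  same <- tibble::tibble(x = c(2, 4, 9), y = x)
  expect_equal(repeatability(same, x, y)$cr, 0)

  # interval shrinks with n at fixed sd of the differences
  mk <- function(n, seed) {
    set.seed(seed)
    d <- rnorm(n); d <- (d - mean(d)) / sd(d) # exact unit sd
    tibble::tibble(x = d, y = 0)
  }
  small <- repeatability(mk(5, 1), x, y)
  large <- repeatability(mk(50, 1), x, y)
  expect_lt(large$cr_high - large$cr_low, small$cr_high - small$cr_low)
  expect_error(repeatability(df[1:2, ], x, y),
               class = "mitedamage_too_few_pairs")
})

test_that("Lin's concordance equals the moment formula and its known cases", {
  x <- c(1, 2, 3, 4)
  df <- tibble::tibble(x = x, y = x + 0.5)
  cc <- lin_ccc(df, x, y)
  sxy <- mean((x - mean(x))^2) # y is a shifted copy, so s_xy = s_x^2
  expect_equal(cc$ccc, 2 * sxy / (2 * sxy + 0.25))
  expect_equal(cc$ccc, oracle_ccc(df$x, df$y))

  perfect <- lin_ccc(tibble::tibble(x = x, y = x), x, y)
  expect_equal(perfect$ccc, 1)

  # location shift penalises concordance monotonically while r stays 1
  cccs <- vapply(c(0.5, 1, 2, 4), function(cst) {
    lin_ccc(tibble::tibble(x = x, y = x + cst), x, y)$ccc
  }, numeric(1))
  expect_true(all(diff(cccs) < 0))
  expect_true(all(cccs < 1))

  expect_error(lin_ccc(tibble::tibble(x = x, y = rep(2, 4)), x, y),
               class = "mitedamage_zero_variance")
})

test_that("concordance never exceeds correlation in magnitude", {
  set.seed(7)
  for (k in 1:30) {
    n <- sample(4:12, 1)
    df <- tibble::tibble(x = rnorm(n, 5, 2), y = rnorm(n, 3, 1))
    cc <- lin_ccc(df, x, y)
    expect_lte(abs(cc$ccc), abs(cc$pearson) + 1e-12)
    expect_equal(cc$ccc, oracle_ccc(df$x, df$y))
  }
})

test_that("Spearman rank correlation is monotone-invariant", {
  df <- tibble::tibble(x = c(2, 5, 1, 9, 4), y = c(1.1, 2.5, 0.3, 7, 2))
  up <- spearman_cor(df, x, y)
  expect_equal(up$rho, 1)
  down <- spearman_cor(dplyr::mutate(df, y = -y), x, y)
  expect_equal(down$rho, -1)
  cubed <- spearman_cor(dplyr::mutate(df, y = y^3), x, y)
  expect_equal(cubed$rho, up$rho)
  expect_error(spearman_cor(dplyr::mutate(df, y = 1), x, y),
               class = "mitedamage_zero_variance")
})

test_that("damage quotient is the ratio of group means with attrition reported", {
  df <- tibble::tibble(
    area = c(9, 9, NA, 2, 2, 2),
    geno = c("kon", "kon", "kon", "col", "col", "col")
  )
  q <- damage_quotient(df, area, geno, "kon", "col")
  expect_equal(q$quotient, 4.5)
  expect_identical(q$n_numerator, 2L)
  expect_identical(q$dropped_numerator, 1L)

  same <- tibble::tibble(area = rep(3, 4), g = rep(c("a", "b"), 2))
  expect_equal(damage_quotient(same, area, g, "a", "b")$quotient, 1)

  gone <- tibble::tibble(area = c(1, NA, NA), g = c("a", "b", "b"))
  expect_error(damage_quotient(gone, area, g, "a", "b"),
               class = "mitedamage_empty_group")
})

test_that("limits of agreement cover about 95% of simulated normal differences", {
  set.seed(11)
  df <- tibble::tibble(y = rep(0, 10000), x = rnorm(10000, 1, 2))
  ba <- bland_altman(df, x, y)
  cover <- mean(ba$differences >= ba$loa_low & ba$differences <= ba$loa_high)
  expect_gt(cover, 0.94)
  expect_lt(cover, 0.96)
})

test_that("pairwise comparison of a method with itself is perfect agreement", {
  vals <- c(3, 8, 2, 10, 6)
  long <- tibble::tibble(
    id = rep(1:5, 2),
    method = rep(c("a", "b"), each = 5),
    value = c(vals, vals),
    geno = rep(rep(c("g1", "g2"), c(3, 2)), 2)
  )
  out <- compare_methods(long, value, method, id, group = geno)
  pooled <- out[out$group == "(pooled)", ]
  expect_equal(pooled$bias, 0)
  expect_equal(pooled$ccc, 1)
  expect_equal(pooled$rho, 1)
  # one row per group plus the pooled row for the single method pair
  expect_identical(nrow(out), 3L)
})

test_that("agreement report bundles the whole suite with pair bookkeeping", {
  set.seed(5)
  df <- tibble::tibble(x = rlnorm(12, 2), y = x * 1.1 + rnorm(12, 0, 0.3))
  rep <- agreement_report(df, x, y)
  expect_identical(rep$n_pairs, 12L)
  expect_true(rep$loa_low <= rep$bias && rep$bias <= rep$loa_high)
  expect_lte(abs(rep$ccc), abs(rep$pearson) + 1e-12)
  expect_equal(rep$cr, 1.96 * rep$sd_diff)
})
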