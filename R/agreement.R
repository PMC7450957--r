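#' Bland-Altman agreement analysis
#'
#' Computes the paired differences `d_i = x_i - y_i` (absolute mode) or
#' `d_i = (x_i - y_i) / ((x_i + y_i) / 2)` (percent mode, differences
#' expressed relative to the pair mean), the bias (mean difference), and the
#' 95% limits of agreement `bias +/- 1.96 sd(d)` with the sample (n - 1)
#' standard deviation. Pairs with either side missing are excluded and
#' counted in `n_excluded`.
#'
#' @param data Data frame holding the paired measurements.
#' @param x,y Columns (unquoted) with the two methods' measurements, aligned
#'   row-wise.
#' @param mode `"absolute"` or `"percent"`.
#' @return A `bland_altman` object; see [tidy()] for the one-row summary and
#'   [autoplot()] for the classic plot.
#' @export
bland_altman <- function(data, x, y, mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  ok <- stats::complete.cases(xv, yv)
  n_excluded <- sum(!ok)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 2L) {
    abort("need at least 2 complete pairs.", class = "mitedamage_too_few_pairs")
  }
  d <- if (mode == "absolute") xv - yv else (xv - yv) / ((xv + yv) / 2)
  m <- (xv + yv) / 2
  bias <- mean(d)
  sd_d <- sd(d)
  structure(
    list(
      bias = bias, sd_diff = sd_d,
      loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
      n_pairs = length(d), n_excluded = n_excluded, mode = mode,
      differences = d, means = m
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> bias %.4g, LoA [%.4g, %.4g], n = %d (%s mode, %d excluded)\n",
    x$bias, x$loa_low, x$loa_high, x$n_pairs, x$mode, x$n_excluded
  ))
  invisible(x)
}

#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    bias = x$bias, sd_diff = x$sd_diff,
    loa_low = x$loa_low, loa_high = x$loa_high,
    n_pairs = x$n_pairs, n_excluded = x$n_excluded, mode = x$mode
  )
}

#' Coefficient of repeatability
#'
#' `CR = 1.96 sd(d)` over the paired differences: the value below which the
#' absolute difference between two repeated measurements falls with 95%
#' probability. The 95% confidence interval follows from the chi-square
#' distribution of the variance with n - 1 degrees of freedom, scaled by
#' 1.96.
#'
#' @inheritParams bland_altman
#' @return A `repeatability` object with `cr`, `cr_low`, `cr_high`,
#'   `n_pairs`.
#' @export
repeatability <- function(data, x, y) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  ok <- stats::complete.cases(xv, yv)
  d <- xv[ok] - yv[ok]
  n <- length(d)
  if (n < 3L) abort("need at least 3 complete pairs.",
                    class = "mitedamage_too_few_pairs")
  s <- sd(d)
  structure(
    list(
      cr = 1.96 * s,
      cr_low = 1.96 * s * sqrt((n - 1) / qchisq(0.975, n - 1)),
      cr_high = 1.96 * s * sqrt((n - 1) / qchisq(0.025, n - 1)),
      n_pairs = n
    ),
    class = "repeatability"
  )
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("<repeatability> CR %.4g, 95%% CI [%.4g, %.4g], n = %d\n",
              x$cr, x$cr_low, x$cr_high, x$n_pairs))
  invisible(x)
}

#' @export
tidy.repeatability <- function(x, ...) {
  tibble::tibble(cr = x$cr, cr_low = x$cr_low, cr_high = x$cr_high,
                 n_pairs = x$n_pairs)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement with the 45-degree line through the origin:
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moments — Lin's original estimator, which penalises location and
#' scale shifts on top of imperfect correlation, so `|ccc| <= |pearson|`
#' always. The 95% confidence interval uses the Fisher z-transform with
#' Lin's large-sample standard error.
#'
#' @inheritParams bland_altman
#' @return A `lin_ccc` object with `ccc`, `ccc_low`, `ccc_high`, `pearson`,
#'   `n_pairs`.
#' @export
lin_ccc <- function(data, x, y) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3L) abort("need at least 3 complete pairs.",
                    class = "mitedamage_too_few_pairs")
  if (var(xv) == 0 || var(yv) == 0) {
    abort("zero variance in x or y.", class = "mitedamage_zero_variance")
  }
  mx <- mean(xv); my <- mean(yv)
  sx2 <- mean((xv - mx)^2); sy2 <- mean((yv - my)^2)
  sxy <- mean((xv - mx) * (yv - my))
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- cor(xv, yv)
  u <- (mx - my) / sqrt(sqrt(sx2) * sqrt(sy2))
  # Lin's large-sample variance of the z-transformed estimator
  se_z <- sqrt(
    ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
       2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
       ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
  )
  z <- atanh(ccc)
  ci <- if (is.finite(se_z)) tanh(z + c(-1, 1) * 1.96 * se_z) else c(NA_real_, NA_real_)
  structure(
    list(ccc = ccc, ccc_low = ci[1], ccc_high = ci[2], pearson = r,
         n_pairs = n, x = xv, y = yv),
    class = "lin_ccc"
  )
}

#' @export
print.lin_ccc <- function(x, ...) {
  cat(sprintf("<lin_ccc> CCC %.4f (95%% CI %.4f-%.4f), Pearson r %.4f, n = %d\n",
              x$ccc, x$ccc_low, x$ccc_high, x$pearson, x$n_pairs))
  invisible(x)
}

#' @export
tidy.lin_ccc <- function(x, ...) {
  tibble::tibble(ccc = x$ccc, ccc_low = x$ccc_low, ccc_high = x$ccc_high,
                 pearson = x$pearson, n_pairs = x$n_pairs)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; the p-value comes from the
#' standard large-sample approximation (via [stats::cor.test()] with
#' `exact = FALSE`).
#'
#' @inheritParams bland_altman
#' @return A tibble with `rho`, `p_value`, `n_pairs`.
#' @export
spearman_cor <- function(data, x, y) {
  xv <- eval_tidy(enquo(x), data)
  yv <- eval_tidy(enquo(y), data)
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3L) abort("need at least 3 complete pairs.",
                             class = "mitedamage_too_few_pairs")
  if (var(xv) == 0 || var(yv) == 0) {
    abort("constant input.", class = "mitedamage_zero_variance")
  }
  ct <- suppressWarnings(cor.test(xv, yv, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n_pairs = length(xv))
}

#' Genotype damage quotient
#'
#' Ratio of mean corrected damage between two genotype groups (classically a
#' susceptible over a resistant accession); missing values — rosettes
#' dropped by the control correction — are excluded, with the attrition
#' reported.
#'
#' @param data Data frame of per-rosette values.
#' @param value Column (unquoted) with corrected areas (NA = dropped).
#' @param group Column (unquoted) with the group labels.
#' @param numerator,denominator Group labels forming the quotient.
#' @return A tibble: `quotient`, group means, group n used, n dropped.
#' @export
damage_quotient <- function(data, value, group, numerator, denominator) {
  v <- eval_tidy(enquo(value), data)
  g <- eval_tidy(enquo(group), data)
  va <- v[g == numerator]; vb <- v[g == denominator]
  if (length(va) == 0L || length(vb) == 0L) {
    abort("both groups must be non-empty.", class = "mitedamage_empty_group")
  }
  dropped_a <- sum(is.na(va)); dropped_b <- sum(is.na(vb))
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (length(vb) == 0L || mean(vb) <= 0) {
    abort(
      sprintf(
        "denominator group `%s` has no usable mean (%d of its values dropped).",
        denominator, dropped_b
      ),
      class = "mitedamage_empty_group"
    )
  }
  tibble::tibble(
    numerator = as.character(numerator), denominator = as.character(denominator),
    quotient = mean(va) / mean(vb),
    mean_numerator = mean(va), mean_denominator = mean(vb),
    n_numerator = length(va), n_denominator = length(vb),
    dropped_numerator = dropped_a, dropped_denominator = dropped_b
  )
}

#' Full agreement report for one method pair
#'
#' Bundles the whole agreement suite for one pair of measurement columns:
#' Bland-Altman bias and limits of agreement, coefficient of repeatability
#' with its confidence interval, Lin's concordance with its interval,
#' Spearman's rho, Pearson's r, and the pair counts.
#'
#' @inheritParams bland_altman
#' @return One-row tibble.
#' @export
agreement_report <- function(data, x, y, mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  qx <- enquo(x); qy <- enquo(y)
  ba <- bland_altman(data, !!qx, !!qy, mode = mode)
  rp <- tryCatch(repeatability(data, !!qx, !!qy),
                 mitedamage_too_few_pairs = function(e) NULL)
  cc <- tryCatch(lin_ccc(data, !!qx, !!qy),
                 error = function(e) NULL)
  sp <- tryCatch(spearman_cor(data, !!qx, !!qy),
                 error = function(e) NULL)
  na_if_null <- function(obj, field) if (is.null(obj)) NA_real_ else obj[[field]]
  tibble::tibble(
    bias = ba$bias, sd_diff = ba$sd_diff,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    cr = na_if_null(rp, "cr"),
    cr_low = na_if_null(rp, "cr_low"),
    cr_high = na_if_null(rp, "cr_high"),
    ccc = na_if_null(cc, "ccc"),
    ccc_low = na_if_null(cc, "ccc_low"),
    ccc_high = na_if_null(cc, "ccc_high"),
    pearson = na_if_null(cc, "pearson"),
    rho = na_if_null(sp, "rho"),
    rho_p = na_if_null(sp, "p_value"),
    n_pairs = ba$n_pairs, n_excluded = ba$n_excluded, mode = mode
  )
}

#' Pairwise method comparison
#'
#' Compares every pair of methods in a long measurement table: values are
#' aligned by `id`, and an [agreement_report()] is produced per method pair
#' within each group (if `group` is given) and pooled over all rows.
#'
#' @param data Long data frame with one row per (id, method) measurement.
#' @param value,method,id Columns (unquoted): the measurement, the method
#'   label, the rosette id aligning pairs.
#' @param group Optional grouping column (e.g. genotype).
#' @param mode Difference mode, see [bland_altman()].
#' @return Tibble of agreement reports, one row per (method pair, group) plus
#'   a pooled row per pair (`group = "(pooled)"`).
#' @export
compare_methods <- function(data, value, method, id, group = NULL,
                            mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  v <- eval_tidy(enquo(value), data)
  m <- as.character(eval_tidy(enquo(method), data))
  i <- eval_tidy(enquo(id), data)
  qg <- enquo(group)
  g <- if (rlang::quo_is_null(qg)) rep("(pooled)", length(v)) else
    as.character(eval_tidy(qg, data))
  long <- tibble::tibble(value = v, method = m, id = i, group = g)
  methods <- sort(unique(long$method))
  if (length(methods) < 2L) abort("need at least two methods to compare.")
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  groups <- unique(long$group)
  scopes <- c(groups, if (length(groups) > 1L) "(pooled)")
  out <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(scopes, function(sc) {
      sub <- if (sc == "(pooled)") long else dplyr::filter(long, .data$group == sc)
      wide <- tidyr::pivot_wider(sub[, c("id", "method", "value")],
                                 names_from = "method", values_from = "value")
      if (!all(pr %in% names(wide))) return(NULL)
      rep <- tryCatch(
        agreement_report(wide, !!rlang::sym(pr[1]), !!rlang::sym(pr[2]),
                         mode = mode),
        mitedamage_too_few_pairs = function(e) NULL
      )
      if (is.null(rep)) return(NULL)
      dplyr::bind_cols(
        tibble::tibble(method_a = pr[1], method_b = pr[2], group = sc), rep
      )
    })
  })
  out
}
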