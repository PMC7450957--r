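#' Describe a synthetic rosette phenotype
#'
#' A phenotype spec parameterises the synthetic scan generator: rosette
#' geometry, the target chlorotic damage fraction, the lesion size
#' distribution, and the density of confounding features (bright trichome-like
#' specks, pale young-leaf centre, lightened leaf margins) that make control
#' rosettes non-trivially clean.
#'
#' Defaults describe a mid-sized Arabidopsis rosette (about 8 cm^2 of tissue)
#' with moderately heavy trichome speckling. Lesion morphology is a free
#' parameter of the generator — no quantitative size distribution for real
#' chlorotic lesions is claimed — and defaults to a log-normal with mean
#' 0.25 mm^2 and coefficient of variation 0.6.
#'
#' @param genotype_label Free-text genotype name.
#' @param damage_fraction Target fraction of rosette pixels chlorotic, in
#'   `[0, 1]`; 0 for uninfested controls.
#' @param n_leaves Number of leaves (>= 3).
#' @param rosette_radius Nominal rosette radius in mm (> 0).
#' @param spot_size_mean Mean lesion area in mm^2.
#' @param spot_size_cv Coefficient of variation of lesion area.
#' @param confounder_density Trichome-like specks per cm^2 of rosette (>= 0).
#' @param pale_center Whether the rosette centre (young leaves) is pale.
#' @return A `phenotype_spec` object.
#' @export
phenotype_spec <- function(genotype_label,
                           damage_fraction,
                           n_leaves = 9L,
                           rosette_radius = 16,
                           spot_size_mean = 0.25,
                           spot_size_cv = 0.6,
                           confounder_density = 3,
                           pale_center = FALSE) {
  if (!is.numeric(damage_fraction) || length(damage_fraction) != 1L ||
      is.na(damage_fraction) || damage_fraction < 0 || damage_fraction > 1) {
    abort("`damage_fraction` must lie in [0, 1].", class = "mitedamage_bad_spec")
  }
  if (!is.numeric(rosette_radius) || rosette_radius <= 0) {
    abort("`rosette_radius` must be > 0.", class = "mitedamage_bad_spec")
  }
  if (!is.numeric(n_leaves) || n_leaves < 3) {
    abort("`n_leaves` must be >= 3.", class = "mitedamage_bad_spec")
  }
  if (!is.numeric(confounder_density) || confounder_density < 0) {
    abort("`confounder_density` must be >= 0.", class = "mitedamage_bad_spec")
  }
  if (!is.numeric(spot_size_mean) || spot_size_mean <= 0) {
    abort("`spot_size_mean` must be > 0.", class = "mitedamage_bad_spec")
  }
  structure(
    list(
      genotype_label = as.character(genotype_label),
      n_leaves = as.integer(n_leaves),
      rosette_radius = as.numeric(rosette_radius),
      damage_fraction = as.numeric(damage_fraction),
      spot_size_mean = as.numeric(spot_size_mean),
      spot_size_cv = as.numeric(spot_size_cv),
      confounder_density = as.numeric(confounder_density),
      pale_center = isTRUE(pale_center)
    ),
    class = "phenotype_spec"
  )
}

#' @export
print.phenotype_spec <- function(x, ...) {
  cat(sprintf(
    "<phenotype_spec> %s: %d leaves, radius %.1f mm, damage %.1f%%, %g specks/cm2%s\n",
    x$genotype_label, x$n_leaves, x$rosette_radius, 100 * x$damage_fraction,
    x$confounder_density, if (x$pale_center) ", pale centre" else ""
  ))
  invisible(x)
}

# Reference colours of the synthetic colour model (8-bit RGB). Healthy tissue
# is green with per-leaf variation; chlorosis interpolates towards pale
# yellow-white; trichome specks are near-white; the pale centre is a pale
# green clearly distinct from chlorosis.
COL_CHLOROTIC <- c(245, 238, 200)
COL_SPECK <- c(250, 250, 245)
COL_PALE_CENTER <- c(170, 190, 110)

#' Generate one synthetic rosette scan with ground truth
#'
#' Draws a rosette of overlapping teardrop-shaped leaves with thin petioles
#' radiating from a centre, adds chlorotic lesions until the target damage
#' fraction of rosette pixels is reached, adds confounders (near-white
#' trichome-like specks, optional pale centre, lightened leaf margins —
#' labelled `confounder`, never `damaged`), and composes the result over a
#' white or black background with mild pixel noise. Output is bit-identical
#' for a fixed `(spec, seed, dpi, background)`.
#'
#' The scan window is square with side `2.5 * rosette_radius` mm, converted
#' to pixels at `dpi`.
#'
#' @param spec A [phenotype_spec()].
#' @param seed Integer seed; the draw is fully determined by it.
#' @param dpi Scan resolution (>= 150).
#' @param background `"white"` or `"black"`.
#' @return A `synthetic_scan`: list with `image` ([scan_image()]), `truth`
#'   (class map plus true areas), `spec`, `seed`, and a `meta` record.
#' @export
generate_rosette <- function(spec, seed, dpi = 300,
                             background = c("white", "black")) {
  background <- match.arg(background)
  if (!inherits(spec, "phenotype_spec")) {
    abort("`spec` must be a phenotype_spec.", class = "mitedamage_bad_spec")
  }
  if (dpi < 150) abort("`dpi` must be >= 150.", class = "mitedamage_bad_spec")
  withr::with_seed(as.integer(seed), {
    scan <- draw_rosette(spec, dpi, background)
  })
  scan$seed <- as.integer(seed)
  scan
}

draw_rosette <- function(spec, dpi, background) {
  px_mm <- 25.4 / dpi
  side_mm <- 2.5 * spec$rosette_radius
  n <- max(32L, as.integer(round(side_mm / px_mm)))
  # mm coordinates of pixel centres, origin at the image centre
  ax <- ((seq_len(n) - 0.5) - n / 2) * px_mm
  X <- matrix(rep(ax, each = n), n, n)   # column coordinate (mm)
  Y <- matrix(rep(ax, times = n), n, n)  # row coordinate (mm)

  class_map <- matrix(CLASS_BACKGROUND, n, n)
  R <- matrix(0, n, n); G <- matrix(0, n, n); B <- matrix(0, n, n)

  angles <- 2 * pi * (seq_len(spec$n_leaves) - 1) / spec$n_leaves +
    rnorm(spec$n_leaves, 0, 0.12)
  for (k in seq_len(spec$n_leaves)) {
    th <- angles[k]
    len <- spec$rosette_radius * runif(1, 0.62, 1.0)
    wmax <- len * runif(1, 0.20, 0.30)
    base <- spec$rosette_radius * 0.16
    u <- cos(th) * X + sin(th) * Y
    v <- -sin(th) * X + cos(th) * Y
    # teardrop lamina: half-width follows a smoothed sine bump along the axis
    t_ <- (u - base) / len
    lam <- t_ >= 0 & t_ <= 1 & abs(v) <= wmax * sin(pi * pmin(pmax(t_, 0), 1))^0.7
    pet <- u >= 0 & u <= base & abs(v) <= 0.35
    leaf_col <- c(
      max(30, min(130, rnorm(1, 75, 12))),
      max(90, min(190, rnorm(1, 135, 12))),
      max(20, min(100, rnorm(1, 55, 10)))
    )
    R[lam] <- leaf_col[1]; G[lam] <- leaf_col[2]; B[lam] <- leaf_col[3]
    # petioles are paler, whitish green (the white-background failure mode)
    R[pet] <- leaf_col[1] + 45; G[pet] <- leaf_col[2] + 25; B[pet] <- leaf_col[3] + 45
    class_map[lam | pet] <- CLASS_HEALTHY
  }
  rosette <- class_map != CLASS_BACKGROUND
  n_ros <- sum(rosette)
  if (n_ros == 0L) abort("degenerate spec: empty rosette.")

  # lightened leaf margins (confounder): 1-px outer ring of the rosette
  margin <- rosette & !erode4(rosette)
  R[margin] <- R[margin] + 30; G[margin] <- G[margin] + 30; B[margin] <- B[margin] + 30
  class_map[margin] <- CLASS_CONFOUNDER

  # pale young-leaf centre (confounder)
  if (spec$pale_center) {
    ctr <- rosette & (X^2 + Y^2 <= (0.25 * spec$rosette_radius)^2)
    R[ctr] <- 0.5 * R[ctr] + 0.5 * COL_PALE_CENTER[1]
    G[ctr] <- 0.5 * G[ctr] + 0.5 * COL_PALE_CENTER[2]
    B[ctr] <- 0.5 * B[ctr] + 0.5 * COL_PALE_CENTER[3]
    class_map[ctr] <- CLASS_CONFOUNDER
  }

  # chlorotic lesions: elliptical blobs with perturbed boundary, confined to
  # healthy tissue, added until the target pixel count is reached
  if (spec$damage_fraction > 0) {
    target <- round(spec$damage_fraction * n_ros)
    sigma2 <- log(1 + spec$spot_size_cv^2)
    mu <- log(spec$spot_size_mean) - sigma2 / 2
    healthy_idx <- which(class_map == CLASS_HEALTHY)
    placed <- 0L
    attempts <- 0L
    while (placed < target && attempts < 20000L) {
      attempts <- attempts + 1L
      area_mm2 <- rlnorm(1, mu, sqrt(sigma2))
      r_px <- sqrt(area_mm2 / pi) / px_mm
      if (r_px < 0.6) r_px <- 0.6
      ctr_idx <- healthy_idx[sample.int(length(healthy_idx), 1L)]
      ci <- ((ctr_idx - 1L) %% n) + 1L
      cj <- ((ctr_idx - 1L) %/% n) + 1L
      ecc <- exp(runif(1, -0.35, 0.35))
      phi <- runif(1, 0, pi)
      amp <- runif(1, 0.05, 0.25)
      ph2 <- runif(1, 0, 2 * pi)
      half <- ceiling(2.2 * r_px * max(ecc, 1 / ecc)) + 1L
      ii <- max(1L, ci - half):min(n, ci + half)
      jj <- max(1L, cj - half):min(n, cj + half)
      dy <- matrix(rep(ii - ci, times = length(jj)), length(ii), length(jj))
      dx <- matrix(rep(jj - cj, each = length(ii)), length(ii), length(jj))
      ru <- cos(phi) * dx + sin(phi) * dy
      rv <- -sin(phi) * dx + cos(phi) * dy
      ang <- atan2(rv, ru)
      rad2 <- (ru / (r_px * ecc))^2 + (rv / (r_px / ecc))^2
      blob <- rad2 <= (1 + amp * sin(3 * ang + ph2))^2
      sub_cls <- class_map[ii, jj, drop = FALSE]
      hit <- blob & sub_cls == CLASS_HEALTHY
      if (!any(hit)) next
      beta <- runif(1, 0.75, 0.95)
      subR <- R[ii, jj, drop = FALSE]; subG <- G[ii, jj, drop = FALSE]
      subB <- B[ii, jj, drop = FALSE]
      subR[hit] <- (1 - beta) * subR[hit] + beta * COL_CHLOROTIC[1]
      subG[hit] <- (1 - beta) * subG[hit] + beta * COL_CHLOROTIC[2]
      subB[hit] <- (1 - beta) * subB[hit] + beta * COL_CHLOROTIC[3]
      sub_cls[hit] <- CLASS_DAMAGED
      R[ii, jj] <- subR; G[ii, jj] <- subG; B[ii, jj] <- subB
      class_map[ii, jj] <- sub_cls
      placed <- placed + sum(hit)
    }
  }

  # trichome-like specks (confounder): tiny near-white dots on healthy tissue
  area_cm2 <- n_ros * px_mm^2 / 100
  n_specks <- rpois(1, spec$confounder_density * area_cm2)
  if (n_specks > 0) {
    healthy_idx <- which(class_map == CLASS_HEALTHY)
    if (length(healthy_idx) > 0) {
      centers <- healthy_idx[sample.int(length(healthy_idx),
                                        min(n_specks, length(healthy_idx)))]
      for (ctr_idx in centers) {
        ci <- ((ctr_idx - 1L) %% n) + 1L
        cj <- ((ctr_idx - 1L) %/% n) + 1L
        r_sp <- sample(0:1, 1L, prob = c(0.6, 0.4))
        ii <- max(1L, ci - r_sp):min(n, ci + r_sp)
        jj <- max(1L, cj - r_sp):min(n, cj + r_sp)
        sub_cls <- class_map[ii, jj, drop = FALSE]
        hit <- sub_cls == CLASS_HEALTHY
        subR <- R[ii, jj, drop = FALSE]; subG <- G[ii, jj, drop = FALSE]
        subB <- B[ii, jj, drop = FALSE]
        subR[hit] <- 0.1 * subR[hit] + 0.9 * COL_SPECK[1]
        subG[hit] <- 0.1 * subG[hit] + 0.9 * COL_SPECK[2]
        subB[hit] <- 0.1 * subB[hit] + 0.9 * COL_SPECK[3]
        sub_cls[hit] <- CLASS_CONFOUNDER
        R[ii, jj] <- subR; G[ii, jj] <- subG; B[ii, jj] <- subB
        class_map[ii, jj] <- sub_cls
      }
    }
  }

  # background fill + mild sensor noise
  bgv <- if (background == "white") 252 else 6
  bgm <- class_map == CLASS_BACKGROUND
  R[bgm] <- bgv; G[bgm] <- bgv; B[bgm] <- bgv
  R <- R + rnorm(n * n, 0, 2.5)
  G <- G + rnorm(n * n, 0, 2.5)
  B <- B + rnorm(n * n, 0, 2.5)
  px <- array(0, c(n, n, 3))
  px[, , 1] <- R; px[, , 2] <- G; px[, , 3] <- B
  px <- round(pmin(pmax(px, 0), 255))

  pa <- pixel_area_mm2(dpi)
  truth <- structure(
    list(
      class_map = class_map,
      true_damage_area = sum(class_map == CLASS_DAMAGED) * pa,
      true_rosette_area = sum(class_map != CLASS_BACKGROUND) * pa,
      dpi = dpi
    ),
    class = "ground_truth"
  )
  structure(
    list(
      image = scan_image(px, dpi = dpi, background = background),
      truth = truth,
      spec = spec,
      seed = NA_integer_,
      meta = list(
        rosette_id = NA_character_,
        genotype = spec$genotype_label,
        treatment = if (spec$damage_fraction > 0) "infested" else "control"
      )
    ),
    class = "synthetic_scan"
  )
}

# binary erosion with the 4-neighbour cross structuring element
erode4 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-n1, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -n2, drop = FALSE])
  m & up & dn & lf & rt
}

#' @export
print.synthetic_scan <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scan> %s (%s), seed %s: rosette %.1f mm2, damage %.2f mm2\n",
    x$meta$genotype, x$meta$treatment, x$seed,
    x$truth$true_rosette_area, x$truth$true_damage_area
  ))
  invisible(x)
}

#' Generate a replicated cohort of synthetic scans
#'
#' For each phenotype spec, draws `n_replicates` infested scans (spec as
#' given) and `n_replicates` uninfested controls (damage fraction forced to 0,
#' confounders retained — controls are damage-free but not confounder-free).
#' Replicate-level biological variation is emulated by jittering rosette
#' radius (+/- 10%) and leaf count (+/- 1). Child seeds are derived
#' deterministically from `seed`, so two cohorts from the same arguments are
#' identical.
#'
#' @param specs List of [phenotype_spec()]s.
#' @param n_replicates Replicates per spec per treatment arm (>= 1).
#' @param seed Cohort seed.
#' @inheritParams generate_rosette
#' @return List of `synthetic_scan`s, each with a populated `meta` record
#'   (`rosette_id`, `genotype`, `treatment`, `replicate`). Use
#'   [cohort_manifest()] for a tabular view.
#' @export
generate_cohort <- function(specs, n_replicates, seed, dpi = 300,
                            background = c("white", "black")) {
  background <- match.arg(background)
  if (length(specs) == 0L) abort("`specs` must not be empty.")
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  scans <- list()
  idx <- 0L
  for (j in seq_along(specs)) {
    spec <- specs[[j]]
    if (!inherits(spec, "phenotype_spec")) {
      abort("every element of `specs` must be a phenotype_spec.")
    }
    for (treatment in c("infested", "control")) {
      df <- if (treatment == "infested") spec$damage_fraction else 0
      for (k in seq_len(n_replicates)) {
        idx <- idx + 1L
        child <- child_seed(seed, idx)
        rep_spec <- withr::with_seed(child, {
          phenotype_spec(
            genotype_label = spec$genotype_label,
            damage_fraction = df,
            n_leaves = max(3L, spec$n_leaves + sample(-1:1, 1L)),
            rosette_radius = spec$rosette_radius * runif(1, 0.9, 1.1),
            spot_size_mean = spec$spot_size_mean,
            spot_size_cv = spec$spot_size_cv,
            confounder_density = spec$confounder_density,
            pale_center = spec$pale_center
          )
        })
        scan <- generate_rosette(rep_spec, seed = child_seed(seed, idx + 100000L),
                                 dpi = dpi, background = background)
        scan$meta$treatment <- treatment
        scan$meta$replicate <- k
        scan$meta$rosette_id <- sprintf(
          "%s_%s_r%02d", spec$genotype_label,
          substr(treatment, 1, 1), k
        )
        scans[[idx]] <- scan
      }
    }
  }
  scans
}

child_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 100000) * 13001 + 104729 * as.numeric(i)) %% 2147483629)
}

#' Tabular manifest of a cohort
#'
#' @param scans A list of `synthetic_scan`s from [generate_cohort()].
#' @return A tibble with one row per scan: id, genotype, treatment, replicate,
#'   seed, true rosette and damage areas (mm^2).
#' @export
cohort_manifest <- function(scans) {
  purrr::map_dfr(scans, function(s) {
    tibble::tibble(
      rosette_id = s$meta$rosette_id,
      genotype = s$meta$genotype,
      treatment = s$meta$treatment,
      replicate = s$meta$replicate %||% NA_integer_,
      seed = s$seed,
      true_rosette_area_mm2 = s$truth$true_rosette_area,
      true_damage_area_mm2 = s$truth$true_damage_area
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
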