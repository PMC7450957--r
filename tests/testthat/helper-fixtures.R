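# Shared fixtures and independent oracles. Everything is generated in code;
# expensive shared objects are memoised for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A small, quick-to-draw phenotype for unit tests.
quick_spec <- function(genotype = "qk", damage = 0.05, ...) {
  phenotype_spec(genotype, damage_fraction = damage, rosette_radius = 12,
                 n_leaves = 7, confounder_density = 3, ...)
}

quick_scan <- function(seed = 11, damage = 0.05, background = "white", ...) {
  generate_rosette(quick_spec(damage = damage, ...), seed = seed, dpi = 150,
                   background = background)
}

# Independent connected-component oracle: plain-R flood fill with an explicit
# stack, no shared code with the package's labelling.
oracle_label <- function(mask, connectivity) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        ni <- p[1] + nb[k, 1]; nj <- p[2] + nb[k, 2]
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- cur
          stack[[length(stack) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

oracle_size_filter <- function(mask, min_size, connectivity) {
  lab <- oracle_label(mask, connectivity)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (max(lab) == 0L) return(out)
  for (k in seq_len(max(lab))) {
    px <- lab == k
    if (sum(px) >= min_size) out <- out | px
  }
  out
}

# Independent manual-grid oracle: loops over grid cells and accumulates the
# exact rectangle overlap of every damaged pixel with every cell.
oracle_grid_area <- function(mask, grid_size, rule, dpi) {
  p <- 25.4 / dpi
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  ncr <- ceiling(nrow(mask) * p / grid_size)
  ncc <- ceiling(ncol(mask) * p / grid_size)
  count <- 0L
  for (I in seq_len(ncr)) for (J in seq_len(ncc)) {
    rlo <- (I - 1) * grid_size; rhi <- I * grid_size
    clo <- (J - 1) * grid_size; chi <- J * grid_size
    ov <- 0
    for (k in seq_len(nrow(idx))) {
      prlo <- (idx[k, 1] - 1) * p; prhi <- idx[k, 1] * p
      pclo <- (idx[k, 2] - 1) * p; pchi <- idx[k, 2] * p
      a <- max(0, min(rhi, prhi) - max(rlo, prlo)) *
        max(0, min(chi, pchi) - max(clo, pclo))
      ov <- ov + a
    }
    hit <- if (rule == "any-overlap") ov > 1e-12 else ov > grid_size^2 / 2
    if (hit) count <- count + 1L
  }
  count * grid_size^2
}

# Random blob mask: union of a few discs on a small grid.
random_blob_mask <- function(n = 48, n_blobs = 3) {
  m <- matrix(FALSE, n, n)
  for (b in seq_len(n_blobs)) {
    ci <- runif(1, 5, n - 5); cj <- runif(1, 5, n - 5)
    r <- runif(1, 1.5, 6)
    for (i in seq_len(n)) {
      jj <- which((ci - i)^2 + (cj - seq_len(n))^2 <= r^2)
      m[i, jj] <- TRUE
    }
  }
  m
}

# Direct evaluation of Lin's moment formula, kept loop-explicit so it shares
# nothing with the implementation.
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- 0; sy2 <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx2 <- sx2 + (x[i] - mx)^2 / n
    sy2 <- sy2 + (y[i] - my)^2 / n
    sxy <- sxy + (x[i] - mx) * (y[i] - my) / n
  }
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# Toy measurement tables for the correction arithmetic.
toy_controls <- function(da = c(2, 4), ta = c(100, 100)) {
  tibble::tibble(
    rosette_id = paste0("c", seq_along(da)), genotype = "g",
    treatment = "control", condition_id = "w1", background = "white",
    total_area_mm2 = ta, damage_area_mm2 = da
  )
}

toy_treated <- function(da = 10, ta = 200) {
  tibble::tibble(
    rosette_id = paste0("t", seq_along(da)), genotype = "g",
    treatment = "infested", condition_id = "w1", background = "white",
    total_area_mm2 = ta, damage_area_mm2 = da
  )
}

# The study cohort used by the end-to-end acceptance checks: three genotypes
# at the low / mid / high ends of the susceptibility spectrum, eight treated
# and eight control rosettes each.
study_specs <- function() {
  list(
    phenotype_spec("low", damage_fraction = 0.01, pale_center = TRUE),
    phenotype_spec("mid", damage_fraction = 0.015),
    phenotype_spec("high", damage_fraction = 0.05)
  )
}

study_config <- function(seed = 7) {
  run_config(seed = seed, dpi = 150, background = "white",
             specs = study_specs(), n_replicates = 8, n_train = 6,
             labels_per_class = 300, scales = c(1, 2, 4), n_trees = 100)
}

study_run <- function() memo("study_run", run_pipeline(study_config()))
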