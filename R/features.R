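#' Multi-scale per-pixel image features
#'
#' Computes the feature stack the pixel classifier consumes, in the style of
#' interactive-segmentation tools: raw R, G, B, plus at each smoothing scale
#' sigma (in pixels) the Gaussian-smoothed R, G, B, the gradient magnitude,
#' the Laplacian, and the two structure-tensor eigenvalues of the smoothed
#' intensity. Total features per pixel: `3 + 7 * length(scales)`.
#'
#' Smoothing is separable convolution with a truncated Gaussian kernel
#' (radius `ceiling(3 * sigma)`), rows renormalised at the image border;
#' gradients are central differences with replicated edges; the Laplacian is
#' the 4-neighbour discrete Laplacian; structure-tensor entries are the
#' gradient products re-smoothed at the same sigma, with eigenvalues from the
#' closed form for symmetric 2x2 matrices. All steps are deterministic.
#'
#' @param image A [scan_image()].
#' @param scales Smoothing radii in pixels (>= 1 scale).
#' @return Numeric matrix of `H * W` rows (column-major pixel order) and
#'   `3 + 7 * length(scales)` named columns.
#' @export
extract_features <- function(image, scales = c(1, 2, 4, 8)) {
  stopifnot(inherits(image, "scan_image"))
  if (length(scales) < 1L) abort("need at least one scale.")
  R <- image$pixels[, , 1]; G <- image$pixels[, , 2]; B <- image$pixels[, , 3]
  I <- (R + G + B) / 3
  n_px <- length(R)
  feats <- matrix(0, n_px, 3 + 7 * length(scales))
  cn <- c("R", "G", "B")
  feats[, 1] <- as.vector(R); feats[, 2] <- as.vector(G); feats[, 3] <- as.vector(B)
  col <- 3L
  for (s in scales) {
    By <- gauss_blur_matrix(nrow(R), s)
    Bx <- gauss_blur_matrix(ncol(R), s)
    blur <- function(m) By %*% m %*% t(Bx)
    sR <- blur(R); sG <- blur(G); sB <- blur(B); sI <- blur(I)
    gx <- central_diff(sI, along = "col")
    gy <- central_diff(sI, along = "row")
    gm <- sqrt(gx^2 + gy^2)
    lap <- discrete_laplacian(sI)
    J11 <- blur(gx * gx); J12 <- blur(gx * gy); J22 <- blur(gy * gy)
    tr2 <- (J11 + J22) / 2
    disc <- sqrt(((J11 - J22) / 2)^2 + J12^2)
    feats[, col + 1L] <- as.vector(sR)
    feats[, col + 2L] <- as.vector(sG)
    feats[, col + 3L] <- as.vector(sB)
    feats[, col + 4L] <- as.vector(gm)
    feats[, col + 5L] <- as.vector(lap)
    feats[, col + 6L] <- as.vector(tr2 + disc)
    feats[, col + 7L] <- as.vector(tr2 - disc)
    cn <- c(cn, paste0(
      c("sR", "sG", "sB", "gradmag", "laplacian", "st_eig1", "st_eig2"),
      "_s", s
    ))
    col <- col + 7L
  }
  colnames(feats) <- cn
  attr(feats, "img_dim") <- dim(R)
  feats
}

# Row-normalised banded Gaussian smoothing matrix (n x n); multiplying from
# the left smooths columns, from the right (transposed) smooths rows.
gauss_blur_matrix <- function(n, sigma) {
  r <- ceiling(3 * sigma)
  offs <- (-r):r
  w <- dnorm(offs / sigma)
  M <- matrix(0, n, n)
  for (k in seq_along(offs)) {
    i <- seq_len(n)
    j <- i + offs[k]
    ok <- j >= 1 & j <= n
    M[cbind(i[ok], j[ok])] <- M[cbind(i[ok], j[ok])] + w[k]
  }
  M / rowSums(M)
}

# Central differences with replicated edges.
central_diff <- function(m, along = c("row", "col")) {
  along <- match.arg(along)
  n1 <- nrow(m); n2 <- ncol(m)
  if (along == "row") {
    dn <- m[c(2:n1, n1), , drop = FALSE]
    up <- m[c(1, 1:(n1 - 1)), , drop = FALSE]
  } else {
    dn <- m[, c(2:n2, n2), drop = FALSE]
    up <- m[, c(1, 1:(n2 - 1)), drop = FALSE]
  }
  (dn - up) / 2
}

# 4-neighbour discrete Laplacian with replicated edges.
discrete_laplacian <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c(2:n1, n1), ] + m[c(1, 1:(n1 - 1)), ] +
    m[, c(2:n2, n2)] + m[, c(1, 1:(n2 - 1))] - 4 * m
}
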