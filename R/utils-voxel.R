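# Low-level voxel-grid helpers shared by the segmentation, compaction and
# spot modules. All 3D arrays are indexed (z, y, x).

# Shift an array by one voxel along `axis` in direction `dir` (+1/-1),
# padding the vacated plane with `fill`. Used for neighbourhood operations.
axis_shift <- function(a, axis, dir, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  n <- d[axis]
  if (n <= 1L) return(out)
  src <- dst <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  if (dir > 0) {
    src[[axis]] <- 1:(n - 1L)
    dst[[axis]] <- 2:n
  } else {
    src[[axis]] <- 2:n
    dst[[axis]] <- 1:(n - 1L)
  }
  out <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(a), src, list(drop = FALSE))))))
  out
}

# Sum of the 6 face neighbours of a numeric array (per-axis weights allowed).
neighbor_sum6 <- function(a, weights = c(1, 1, 1)) {
  out <- array(0, dim = dim(a))
  for (ax in 1:3) {
    if (weights[ax] == 0) next
    out <- out + weights[ax] * (axis_shift(a, ax, +1) + axis_shift(a, ax, -1))
  }
  out
}

# Separable 1D convolution along one axis with reflective borders.
conv_axis <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(a * kernel)
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- dim(ap)[1]
  m <- prod(dim(ap)[-1])
  M <- matrix(ap, nrow = n, ncol = m)
  # reflective padding (edge value mirrored without repeating the border)
  idx_top <- pmin(n, pmax(1L, (r + 1L):2L))
  idx_bot <- pmin(n, pmax(1L, (n - 1L):(n - r)))
  Mp <- rbind(M[idx_top, , drop = FALSE], M, M[idx_bot, , drop = FALSE])
  out <- matrix(0, nrow = n, ncol = m)
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * Mp[(j):(j + n - 1L), , drop = FALSE]
  }
  res <- array(out, dim = dim(ap))
  aperm(res, order(perm))
}

gaussian_kernel1d <- function(sigma, radius = NULL) {
  if (sigma <= 0) return(1)
  if (is.null(radius)) radius <- max(1L, ceiling(3.5 * sigma))
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Otsu threshold on a vector of intensities, Fiji-style 256-bin histogram.
# Returns a threshold value on the intensity scale of `v`.
otsu_threshold <- function(v, n_bins = 256L) {
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(findInterval(v, breaks, all.inside = TRUE),
                           nbins = n_bins))
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  n <- w[n_bins]
  mt <- mu[n_bins]
  w1 <- w[-n_bins]; mu1 <- mu[-n_bins]
  w2 <- n - w1
  valid <- w1 > 0 & w2 > 0
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mt * w1[valid] - n * mu1[valid])^2 / (w1[valid] * w2[valid])
  k <- which.max(bcv)
  breaks[k + 1L]
}

quantile_threshold <- function(v, prob = 0.9) {
  stats::quantile(v[is.finite(v)], probs = prob, names = FALSE, type = 7)
}

# Connected-component labelling of a logical 3D array (6-connectivity) by
# iterative minimum-label propagation; returns an integer array with labels
# 1..K in arbitrary spatial order, then compacted to consecutive ids.
label_components <- function(mask, max_iter = 10000L) {
  d <- dim(mask)
  lab <- array(0, dim = d)
  idx <- which(mask)
  if (length(idx) == 0L) return(array(0L, dim = d))
  lab[idx] <- seq_along(idx)
  big <- .Machine$double.xmax
  for (i in seq_len(max_iter)) {
    lp <- lab
    lp[lp == 0] <- big
    nb <- lp
    for (ax in 1:3) {
      nb <- pmin(nb, axis_shift(lp, ax, +1, fill = big),
                 axis_shift(lp, ax, -1, fill = big))
    }
    new_lab <- lab
    new_lab[idx] <- pmin(lab[idx], nb[idx])
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  # compact labels to 1..K
  u <- sort(unique(lab[idx]))
  out <- array(0L, dim = d)
  out[idx] <- match(lab[idx], u)
  out
}

# Fill interior cavities of a binary mask: background voxels not connected
# to the array border become foreground.
fill_holes <- function(mask) {
  bg <- !mask
  lab <- label_components(bg)
  d <- dim(mask)
  border_labels <- unique(c(
    lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border_labels <- setdiff(border_labels, 0L)
  mask | !(lab %in% border_labels | !bg)
}

dilate6 <- function(mask, n = 1L) {
  m <- mask
  for (i in seq_len(n)) {
    m <- m | axis_shift(m, 1, +1, FALSE) | axis_shift(m, 1, -1, FALSE) |
      axis_shift(m, 2, +1, FALSE) | axis_shift(m, 2, -1, FALSE) |
      axis_shift(m, 3, +1, FALSE) | axis_shift(m, 3, -1, FALSE)
  }
  m
}

erode6 <- function(mask, n = 1L) {
  m <- mask
  for (i in seq_len(n)) {
    m <- m & axis_shift(m, 1, +1, TRUE) & axis_shift(m, 1, -1, TRUE) &
      axis_shift(m, 2, +1, TRUE) & axis_shift(m, 2, -1, TRUE) &
      axis_shift(m, 3, +1, TRUE) & axis_shift(m, 3, -1, TRUE)
  }
  m
}

# Erosion-count depth map: number of 6-connected erosions survived by each
# mask voxel (1 at the boundary layer). An integer approximation of the
# distance-to-boundary used for peripheral-rim geometry.
mask_depth <- function(mask) {
  d <- array(0L, dim = dim(mask))
  m <- mask
  k <- 0L
  while (any(m)) {
    k <- k + 1L
    d[m] <- k
    m <- erode6(m)
    if (k > max(dim(mask))) break
  }
  d
}

# voxel index helpers -------------------------------------------------------

coords_from_index <- function(idx, d) {
  idx0 <- idx - 1L
  z <- idx0 %% d[1] + 1L
  y <- (idx0 %/% d[1]) %% d[2] + 1L
  x <- idx0 %/% (d[1] * d[2]) + 1L
  cbind(z = z, y = y, x = x)
}

index_from_coords <- function(zyx, d) {
  (zyx[, 3] - 1L) * d[1] * d[2] + (zyx[, 2] - 1L) * d[1] + zyx[, 1]
}
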