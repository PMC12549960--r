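# Independent oracles used by the tests: deliberately naive implementations
# that do not share code with the package internals.

# flood-fill count of 6-connected components in a logical 3D array
oracle_count_components <- function(mask) {
  d <- dim(mask)
  visited <- array(FALSE, d)
  n <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (visited[start]) next
    n <- n + 1L
    stack <- start
    visited[start] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i0 <- cur - 1L
      z <- i0 %% d[1] + 1L
      y <- (i0 %/% d[1]) %% d[2] + 1L
      x <- i0 %/% (d[1] * d[2]) + 1L
      for (k in 1:6) {
        dz <- c(1, -1, 0, 0, 0, 0)[k]
        dy <- c(0, 0, 1, -1, 0, 0)[k]
        dx <- c(0, 0, 0, 0, 1, -1)[k]
        zz <- z + dz; yy <- y + dy; xx <- x + dx
        if (zz < 1 || zz > d[1] || yy < 1 || yy > d[2] || xx < 1 || xx > d[3])
          next
        nb <- (xx - 1L) * d[1] * d[2] + (yy - 1L) * d[1] + zz
        if (mask[nb] && !visited[nb]) {
          visited[nb] <- TRUE
          stack <- c(stack, nb)
        }
      }
    }
  }
  n
}

# brute-force Cliff's delta over all pairs
oracle_cliffs_delta <- function(a, b) {
  gt <- 0; lt <- 0
  for (x in a) for (y in b) {
    if (x > y) gt <- gt + 1
    if (x < y) lt <- lt + 1
  }
  (gt - lt) / (length(a) * length(b))
}

# analytic ellipsoid voxel count: voxels whose centers satisfy the inequality
oracle_ellipsoid_volume <- function(shape, semiaxes) {
  center <- (shape + 1) / 2
  n <- 0L
  for (z in seq_len(shape[1])) for (y in seq_len(shape[2]))
    for (x in seq_len(shape[3])) {
      if (((z - center[1]) / semiaxes[1])^2 + ((y - center[2]) / semiaxes[2])^2 +
          ((x - center[3]) / semiaxes[3])^2 <= 1) n <- n + 1L
    }
  n
}

# small default nucleus simulation shared across tests (kept modest so the
# suite stays fast)
test_nucleus_cfg <- function(...) {
  args <- list(shape = c(32, 64, 64), nucleus_semiaxes = c(12, 24, 24),
               n_chromocenters = 8, cc_radius = c(mean = 3.5, sd = 0.25),
               n_foci = 40)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_nucleus_config, args)
}

# a single voxel-centered 3D Gaussian spot on a flat background
planted_gaussian_stack <- function(shape = c(15, 15, 15), center = c(8, 8, 8),
                                   amplitude = 100, sigma = 2, background = 10) {
  v <- array(background, shape)
  for (z in 1:shape[1]) for (y in 1:shape[2]) for (x in 1:shape[3])
    v[z, y, x] <- v[z, y, x] + amplitude *
      exp(-((z - center[1])^2 + (y - center[2])^2 + (x - center[3])^2) /
            (2 * sigma^2))
  image_stack(v, c(1, 1, 1), "spot")
}
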