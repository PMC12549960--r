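test_that("constant images yield no seeds; isolated peaks are localized", {
  flat <- image_stack(array(5, c(10, 10, 10)), c(1, 1, 1))
  mask <- array(TRUE, c(10, 10, 10))
  se <- find_seeds(flat, mask, mean_radius = 0, normalize = FALSE,
                   noise_tolerance = 0.5)
  expect_equal(nrow(se), 0)
  # two planted Gaussians 12 voxels apart -> exactly 2 seeds within 1 voxel
  sf <- simulate_spot_field(n_spots = 2, spacing_vox = 12, amplitude = 100,
                            sigma = 2, background = 10, noise_sd = 0, seed = 3)
  se2 <- find_seeds(sf$stack, sf$mask, mean_radius = 0, normalize = FALSE,
                    noise_tolerance = 5)
  expect_equal(nrow(se2), 2)
  st <- spot_match_stats(se2, sf$centers, radius = 1)
  expect_equal(st$precision, 1)
  expect_equal(st$recall, 1)
})

test_that("a lone bright voxel becomes a single-voxel spot", {
  v <- array(0, c(9, 9, 9)); v[5, 5, 5] <- 100
  stack <- image_stack(v, c(1, 1, 1))
  se <- find_seeds(stack, array(TRUE, dim(v)), mean_radius = 0,
                   normalize = FALSE, noise_tolerance = 10)
  ss <- grow_spots(stack, se)
  expect_equal(nrow(ss$spots), 1)
  expect_equal(ss$spots$voxel_count, 1)
  expect_equal(ss$spots$integrated_intensity, 100)
  expect_equal(c(ss$spots$z, ss$spots$y, ss$spots$x), c(5, 5, 5))
})

test_that("grown spots match the analytic half-maximum voxel set", {
  stack <- planted_gaussian_stack(amplitude = 100, sigma = 2, background = 10)
  se <- find_seeds(stack, array(TRUE, dim(stack$voxels)), mean_radius = 0,
                   normalize = FALSE, noise_tolerance = 5)
  ss <- grow_spots(stack, se, stop_fraction = 0.5)
  # oracle: sum of the image over voxels at or above B + A/2 = 60
  oracle <- sum(stack$voxels[stack$voxels >= 60])
  expect_lt(abs(ss$spots$integrated_intensity / oracle - 1), 0.1)
})

test_that("watershed splits a dumbbell into one spot per seed, conserving voxels", {
  # two overlapping Gaussians: centers 5 voxels apart with sigma 2
  v <- array(10, c(13, 21, 13))
  mid <- c(7, 11, 7)
  add <- function(v, c0, A, s) {
    d <- dim(v)
    g <- array(0, d)
    for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3])
      g[z, y, x] <- A * exp(-((z - c0[1])^2 + (y - c0[2])^2 + (x - c0[3])^2) /
                              (2 * s^2))
    v + g
  }
  v <- add(v, c(7, 8, 7), 100, 2)
  v <- add(v, c(7, 14, 7), 100, 2)
  stack <- image_stack(v, c(1, 1, 1))
  se <- find_seeds(stack, array(TRUE, dim(v)), mean_radius = 0,
                   normalize = FALSE, noise_tolerance = 10)
  expect_equal(nrow(se), 2)
  ss <- grow_spots(stack, se, stop_fraction = 0.3)
  expect_equal(nrow(ss$spots), 1)   # merged dumbbell, two seeds
  expect_equal(ss$spots$n_seeds, 2)
  union_before <- which(ss$label_map > 0)
  total_before <- sum(ss$spots$integrated_intensity)
  split <- watershed_split(ss, stack)
  expect_equal(nrow(split$spots), 2)
  expect_true(all(split$spots$n_seeds == 1))
  expect_identical(which(split$label_map > 0), union_before)
  # integrated intensity is conserved by the split
  expect_equal(sum(split$spots$integrated_intensity), total_before)
  # each split spot contains its planted center
  labs <- split$label_map[rbind(c(7, 8, 7), c(7, 14, 7))]
  expect_true(all(labs > 0))
  expect_equal(length(unique(labs)), 2)
  # single-seed spots pass through unchanged
  expect_identical(watershed_split(split, stack)$label_map, split$label_map)
})

test_that("ROI counting follows the centroid rule, matching a point-in-mask oracle", {
  sf <- simulate_spot_field(n_spots = 10, spacing_vox = 10, amplitude = 100,
                            sigma = 1.5, background = 0, noise_sd = 0, seed = 5)
  se <- find_seeds(sf$stack, sf$mask, mean_radius = 0, normalize = FALSE,
                   noise_tolerance = 10)
  ss <- grow_spots(sf$stack, se)
  d <- dim(sf$stack$voxels)
  # ROI: half-space mask covering part of the volume
  roi_arr <- array(0L, d)
  roi_arr[, seq_len(floor(d[2] / 2)), ] <- 1L
  roi <- label_map(roi_arr, c(1, 1, 1))
  got <- count_spots_in_roi(ss, roi)
  oracle <- sum(roi_arr[cbind(round(ss$spots$z), round(ss$spots$y),
                              round(ss$spots$x))] > 0)
  expect_equal(got$total, oracle)
  expect_gt(oracle, 0)
  expect_lt(oracle, 10)
  # counting is invariant to label permutation (relabel by reversing ids)
  perm <- ss
  K <- nrow(ss$spots)
  perm$label_map[ss$label_map > 0] <- K + 1L - ss$label_map[ss$label_map > 0]
  perm$spots <- ss$spots[K:1, ]
  perm$spots$label <- 1:K
  expect_equal(count_spots_in_roi(perm, roi)$total, got$total)
  # empty spot set counts zero
  empty <- grow_spots(sf$stack, se[0, , drop = FALSE])
  expect_equal(count_spots_in_roi(empty, roi)$total, 0)
})

test_that("detection is precise on a dense benchmark field", {
  sf <- simulate_spot_field(n_spots = 60, spacing_vox = 7, amplitude = 500,
                            sigma = 1.5, background = 100, noise_sd = 100,
                            seed = 17)
  se <- find_seeds(sf$stack, sf$mask)
  proc <- attr(se, "processed")
  ss <- watershed_split(grow_spots(proc, se), proc)
  st <- spot_match_stats(ss$spots, sf$centers, radius = 2)
  expect_gte(st$precision, 0.95)
  expect_gte(st$recall, 0.95)
})
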