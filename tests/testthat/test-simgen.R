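test_that("identical seeds give bit-identical stacks; planted objects stay inside", {
  cfg <- test_nucleus_cfg(s_pattern = "SII", seed = 42)
  a <- simulate_nucleus_stack(cfg)
  b <- simulate_nucleus_stack(cfg)
  expect_identical(a$channels$DNA$voxels, b$channels$DNA$voxels)
  expect_identical(a$channels$EdU$voxels, b$channels$EdU$voxels)
  expect_identical(a$truth, b$truth)
  # bookkeeping: chromocenters and foci inside the nucleus mask
  expect_true(all(a$truth$nucleus_mask[a$truth$cc_label_map > 0]))
  fc <- round(a$truth$focus_centers)
  expect_true(all(a$truth$nucleus_mask[fc]))
})

test_that("a chromocenter-free nucleus is a constant plateau", {
  cfg <- test_nucleus_cfg(n_chromocenters = 0,
                          noise = list(gaussian_sd = 0, poisson_scale = 0))
  sim <- simulate_nucleus_stack(cfg)
  inside <- sim$channels$DNA$voxels[sim$truth$nucleus_mask]
  expect_true(all(inside == cfg$nucleoplasm_level))
  expect_equal(max(sim$truth$cc_label_map), 0)
  expect_true(all(sim$channels$DNA$voxels[!sim$truth$nucleus_mask] == 0))
})

test_that("the planted chromocenter count matches a flood-fill oracle", {
  cfg <- test_nucleus_cfg(shape = c(40, 80, 80),
                          nucleus_semiaxes = c(15, 30, 30),
                          n_chromocenters = 15, seed = 7)
  sim <- simulate_nucleus_stack(cfg)
  expect_equal(oracle_count_components(sim$truth$cc_label_map > 0), 15)
  expect_equal(max(sim$truth$cc_label_map), 15)
})

test_that("SII foci sit on chromocenter surfaces, SIII foci in the rim", {
  sim2 <- simulate_nucleus_stack(test_nucleus_cfg(s_pattern = "SII", seed = 3))
  # distance from each focus to its nearest chromocenter surface <= 2 voxels
  for (i in seq_len(nrow(sim2$truth$focus_centers))) {
    p <- sim2$truth$focus_centers[i, ]
    dists <- sqrt(rowSums(sweep(sim2$truth$cc_centers, 2, p)^2))
    expect_lt(min(abs(dists - sim2$truth$cc_radii)), 2)
  }
  sim3 <- simulate_nucleus_stack(test_nucleus_cfg(s_pattern = "SIII", seed = 3))
  fc <- round(sim3$truth$focus_centers)
  expect_true(all(sim3$truth$rim_mask[fc]))
  # SI foci avoid chromocenters
  sim1 <- simulate_nucleus_stack(test_nucleus_cfg(s_pattern = "SI", seed = 3))
  fc1 <- round(sim1$truth$focus_centers)
  expect_true(all(sim1$truth$cc_label_map[fc1] == 0))
  # invalid geometry is rejected
  expect_error(sim_nucleus_config(shape = c(10, 10, 10),
                                  nucleus_semiaxes = c(10, 10, 10)),
               "geometry")
})

test_that("population allocation is deterministic and features follow config", {
  cfg <- sim_population_config(n_cells = 2000,
                               stage_proportions = c(G1 = 0.15, S = 0.70, G2 = 0.15))
  tab <- simulate_population_table(cfg)
  expect_equal(nrow(tab), 2000)
  expect_equal(sum(tab$stage_true == "S"), 1400)
  expect_equal(sum(tab$stage_true == "G1"), 300)
  # S fraction ~70%, the mESC-like regime
  expect_equal(mean(tab$stage_true == "S"), 0.70)
  # zero CVs pin G1 DAPI to the configured mean exactly
  cfg0 <- sim_population_config(n_cells = 100,
                                dapi_cv = c(G1 = 0, S = 0, G2 = 0),
                                edu_cv = c(G1 = 0, S = 0, G2 = 0), ptm_cv = 0)
  tab0 <- simulate_population_table(cfg0)
  expect_true(all(tab0$total_dna[tab0$stage_true == "G1"] == 2))
  expect_true(all(tab0$total_dna[tab0$stage_true == "G2"] == 4))
  expect_error(sim_population_config(stage_proportions = c(G1 = 0.5, S = 0.6,
                                                           G2 = 0.1)),
               "sum to 1")
})

test_that("FRAP traces follow the closed-form recovery model", {
  cfg <- sim_frap_config(pre_frames = 6, post_frames = 60, dt = 10,
                         tau = 50, mobile_fraction = 0.6, bleach_depth = 0.2,
                         noise_sd = 0, acquisition_bleach_rate = 0.002)
  sim <- simulate_frap_curve(cfg)
  cv <- sim$curve
  expect_length(cv$time, 66)
  expect_equal(range(cv$time), c(-60, 600))
  nn <- normalize_frap(cv)
  i50 <- which(cv$time == 50)
  expect_equal(nn$normalized[i50],
               0.2 + 0.6 * 0.8 * (1 - exp(-1)), tolerance = 1e-10)
  # immobile pool: post-bleach trace pinned at the bleach depth
  sim0 <- simulate_frap_curve(sim_frap_config(mobile_fraction = 0, noise_sd = 0))
  n0 <- normalize_frap(sim0$curve)
  expect_equal(n0$normalized[n0$time > 0], rep(0.2, 60), tolerance = 1e-10)
  expect_error(sim_frap_config(mobile_fraction = 1.5), "mobile_fraction")
})

test_that("the compaction texture plants coherent labels with exact bookkeeping", {
  tex <- simulate_compaction_texture(shape = c(24, 24, 24),
                                     semiaxes = c(10, 10, 10), seed = 5)
  expect_true(all(tex$labels[tex$nucleus_mask] %in% 1:7))
  expect_true(all(tex$labels[!tex$nucleus_mask] == 0))
  # equal-count binning: class occupancies within 1% of each other
  tab <- table(tex$labels[tex$nucleus_mask])
  expect_lt(diff(range(tab)) / mean(tab), 0.02)
  # planted class means increase with class id
  m <- tapply(tex$dna$voxels[tex$nucleus_mask], tex$labels[tex$nucleus_mask], mean)
  expect_true(all(diff(m) > 0))
})
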