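test_that("gating separates G1/S/G2 and never calls dim-EdU cells S", {
  pop <- simulate_population_table(sim_population_config(seed = 1))
  gated <- gate_population(pop)
  expect_gte(mean(gated$stage == gated$stage_true), 0.95)
  gm <- attr(gated, "gate_model")
  expect_true(all(gated$stage[gated$mean_edu <= gm$edu_threshold] %in%
                    c("G1", "G2")))
  # recovered S fraction close to the simulated 70%
  expect_lt(abs(mean(gated$stage == "S") - 0.70), 0.02)
})

test_that("gating is invariant to a global linear intensity rescale", {
  pop <- simulate_population_table(sim_population_config(n_cells = 600,
                                                         seed = 8))
  g1 <- gate_population(pop)
  pop2 <- pop
  pop2$total_dna <- pop$total_dna * 3.7
  pop2$mean_edu <- pop$mean_edu * 3.7
  g2 <- gate_population(pop2)
  expect_identical(g1$stage, g2$stage)
})

test_that("PTM fold change is G1-referenced and recovers planted enrichment", {
  pop <- simulate_population_table(
    sim_population_config(ptm_enrichment = c(G1 = 1, S = 2, G2 = 1), seed = 2))
  gated <- gate_population(pop)
  fc <- ptm_fold_change(gated)
  expect_equal(fc[["G1"]], 1)
  expect_lt(abs(fc[["S"]] / 2 - 1), 0.05)
  # PTM exactly proportional to DNA -> all folds 1
  pop$ptm <- 0.5 * pop$total_dna
  fc1 <- ptm_fold_change(gate_population(pop))
  expect_equal(unname(fc1), c(1, 1, 1))
  g0 <- gated[gated$stage != "G1", ]
  expect_error(ptm_fold_change(g0), "G1")
})

test_that("ROI enrichment reduces to hand-computable sums", {
  ch <- array(0, c(2, 2, 2)); dn <- array(1, c(2, 2, 2))
  ch[1:4] <- c(2, 4, 6, 8); dn[4] <- 17
  roi <- array(FALSE, c(2, 2, 2)); roi[1:4] <- TRUE
  st <- function(v) image_stack(v, c(1, 1, 1))
  expect_equal(measure_enrichment_in_roi(st(ch), st(dn), roi), 1.0)  # 20/20
  expect_equal(measure_enrichment_in_roi(st(dn), st(dn), roi), 1.0)
  expect_equal(measure_enrichment_in_roi(st(ch), roi = roi, statistic = "mean"),
               mean(c(2, 4, 6, 8)))
  expect_error(measure_enrichment_in_roi(st(ch), st(dn),
                                         array(FALSE, c(2, 2, 2))),
               "empty ROI")
})

test_that("PCH enrichment recovers the planted ratio on simulated nuclei", {
  cfg <- test_nucleus_cfg(ptm_cc_enrichment = 2,
                          noise = list(gaussian_sd = 0, poisson_scale = 0),
                          seed = 6)
  sim <- simulate_nucleus_stack(cfg)
  truth_roi <- sim$truth$cc_label_map > 0
  ratio <- measure_enrichment_in_roi(sim$channels$PTM, sim$channels$DNA,
                                     truth_roi)
  expect_lt(abs(ratio / 2 - 1), 0.01)
  # through the full segmentation pipeline, with noise
  cfg2 <- test_nucleus_cfg(ptm_cc_enrichment = 2, seed = 6)
  sim2 <- simulate_nucleus_stack(cfg2)
  nuc <- segment_nucleus(sim2$channels$DNA)
  cc <- segment_chromocenters(sim2$channels$DNA, nuc)
  ratio2 <- measure_enrichment_in_roi(sim2$channels$PTM, sim2$channels$DNA, cc)
  expect_lt(abs(ratio2 / 2 - 1), 0.1)
})

test_that("replication-foci patterns classify to their planted substage", {
  call_for <- function(pattern, seed) {
    sim <- simulate_nucleus_stack(test_nucleus_cfg(s_pattern = pattern,
                                                   seed = seed))
    nuc <- segment_nucleus(sim$channels$DNA)
    cc <- segment_chromocenters(sim$channels$DNA, nuc)
    edu <- apply_mask(sim$channels$EdU, nuc)
    se <- find_seeds(edu, nuc)
    proc <- attr(se, "processed")
    ss <- watershed_split(grow_spots(proc, se, nucleus = nuc), proc)
    as.character(classify_rfi_pattern(ss, nuc, cc))
  }
  for (seed in c(5, 23)) {
    expect_equal(call_for("SI", seed), "SI")
    expect_equal(call_for("SII", seed), "SII")
    expect_equal(call_for("SIII", seed), "SIII")
  }
  # too few foci is unclassifiable
  sim <- simulate_nucleus_stack(test_nucleus_cfg(s_pattern = "SI", seed = 5))
  nuc <- segment_nucleus(sim$channels$DNA)
  cc <- segment_chromocenters(sim$channels$DNA, nuc)
  edu <- apply_mask(sim$channels$EdU, nuc)
  se <- find_seeds(edu, nuc)
  ss <- grow_spots(attr(se, "processed"), se[0, , drop = FALSE])
  expect_error(classify_rfi_pattern(ss, nuc, cc), "Unclassifiable")
})

test_that("the pulse-chase truth table is total, pure and validated", {
  expect_equal(assign_pulse_chase_stage(FALSE, TRUE), "SI")
  expect_equal(assign_pulse_chase_stage(TRUE, TRUE, edu_pattern = "SI",
                                        pcna_pattern = "SII"), "SII")
  expect_equal(assign_pulse_chase_stage(TRUE, FALSE, edu_pattern = "SIII"),
               "SIII_exited")
  expect_equal(assign_pulse_chase_stage(FALSE, FALSE), "nonS")
  # purity: repeated evaluation gives identical calls over the whole domain
  grid <- expand.grid(edu = c(TRUE, FALSE), pcna = c(TRUE, FALSE))
  calls1 <- mapply(assign_pulse_chase_stage, grid$edu, grid$pcna)
  calls2 <- mapply(assign_pulse_chase_stage, grid$edu, grid$pcna)
  expect_identical(calls1, calls2)
  expect_setequal(unique(calls1), c("SII", "SI", "SIII_exited", "nonS"))
  # contradictory inputs are rejected
  expect_error(assign_pulse_chase_stage(FALSE, TRUE, edu_pattern = "SI"),
               "input error")
  expect_error(assign_pulse_chase_stage(TRUE, FALSE, pcna_pattern = "SII"),
               "input error")
})

test_that("Cliff's delta equals the brute-force pair count", {
  expect_equal(cliffs_delta(c(5, 5, 5), c(5, 5, 5)), 0)
  expect_equal(cliffs_delta(c(4, 5, 6), c(1, 2, 3)), 1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(2, 3, 4)), -5 / 9)
  set.seed(99)
  for (i in 1:20) {
    a <- sample(0:10, sample(1:6, 1), replace = TRUE)
    b <- sample(0:10, sample(1:6, 1), replace = TRUE)
    expect_equal(cliffs_delta(a, b), oracle_cliffs_delta(a, b))
  }
  # large-sample rank path agrees with the pairwise formula
  set.seed(7)
  a <- rnorm(3000); b <- rnorm(2000, 0.3)
  expect_equal(cliffs_delta(a, b),
               {
                 d <- sign(outer(a, b, `-`)); sum(d) / (3000 * 2000)
               })
  expect_error(cliffs_delta(numeric(0), 1), "empty")
})

test_that("the 2D fallback segmenter separates touching nuclei", {
  img <- matrix(0, 60, 60)
  xy <- as.matrix(expand.grid(1:60, 1:60))
  d1 <- sqrt((xy[, 1] - 25)^2 + (xy[, 2] - 30)^2)
  d2 <- sqrt((xy[, 1] - 40)^2 + (xy[, 2] - 30)^2)
  img[d1 < 9] <- 1
  img[d2 < 9] <- 1
  lab <- segment_nuclei_2d(img, sigma = 1, min_size = 30)
  expect_equal(length(setdiff(unique(as.vector(lab)), 0L)), 2)
})
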