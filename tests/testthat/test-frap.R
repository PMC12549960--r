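test_that("double normalization matches the hand-computed case and is idempotent", {
  # bg 5; pre: roi 25, nuc 105 -> r = 0.2; post: roi 15, nuc 95 -> r = 1/9;
  # normalized post value = (1/9) / 0.2 = 0.5556
  cv <- frap_curve(time = c(-10, 10), roi_mean = c(25, 15),
                   nucleus_mean = c(105, 95), background = 5, n_pre = 1)
  nn <- normalize_frap(cv)
  expect_equal(nn$normalized, c(1, 0.555555555555556), tolerance = 1e-12)
  # constant traces with zero background normalize to 1
  cv1 <- frap_curve(time = c(-20, -10, 10, 20), roi_mean = rep(50, 4),
                    nucleus_mean = rep(80, 4), background = 0, n_pre = 2)
  expect_equal(normalize_frap(cv1)$normalized, rep(1, 4))
  # idempotence: renormalizing the normalized trace is the identity
  cv2 <- frap_curve(time = nn$time, roi_mean = nn$normalized,
                    nucleus_mean = rep(1, 2), background = 0, n_pre = 1)
  expect_equal(normalize_frap(cv2)$normalized, nn$normalized)
  bad <- frap_curve(time = c(-10, 10), roi_mean = c(25, 15),
                    nucleus_mean = c(5, 95), background = 5, n_pre = 1)
  expect_error(normalize_frap(bad), "background")
})

test_that("replicate averaging gives pointwise mean and SEM", {
  mk <- function(val) frap_curve(time = c(-10, 10), roi_mean = c(1, val),
                                 nucleus_mean = c(1, 1), background = 0,
                                 n_pre = 1)
  avg <- average_curves(list(mk(0.4), mk(0.6)))
  expect_equal(avg$normalized[2], 0.5)
  expect_equal(attr(avg, "sem")[2], sd(c(0.4, 0.6)) / sqrt(2))
  expect_equal(attr(avg, "sem")[2], 0.1, tolerance = 1e-6)
  # identical replicates: mean equals each, SEM 0
  same <- average_curves(list(mk(0.5), mk(0.5), mk(0.5)))
  expect_equal(same$normalized[2], 0.5)
  expect_equal(attr(same, "sem")[2], 0)
  expect_warning(average_curves(list(mk(0.5))), "SEM")
})

test_that("exponential fits recover noise-free kinetics to solver precision", {
  sim <- simulate_frap_curve(sim_frap_config(tau = 50, mobile_fraction = 0.6,
                                             bleach_depth = 0.2, noise_sd = 0))
  fit <- fit_exponential_recovery(sim$curve)
  expect_true(fit$converged)
  expect_lt(abs(fit$tau / 50 - 1), 0.001)
  expect_lt(abs(fit$mobile_fraction / 0.6 - 1), 0.001)
  expect_lt(abs(fit$bleach_depth / 0.2 - 1), 0.001)
  expect_equal(fit$halftime, fit$tau * log(2))
})

test_that("fits tolerate realistic noise and acquisition bleaching", {
  sim <- simulate_frap_curve(sim_frap_config(tau = 50, mobile_fraction = 0.6,
                                             bleach_depth = 0.2,
                                             noise_sd = 0.02, seed = 12))
  fit <- fit_exponential_recovery(sim$curve)
  expect_true(fit$converged)
  expect_lt(abs(fit$tau / 50 - 1), 0.1)
  expect_lt(abs(fit$mobile_fraction / 0.6 - 1), 0.1)
})

test_that("mobile fraction is invariant to linear rescaling of raw intensities", {
  sim <- simulate_frap_curve(sim_frap_config(noise_sd = 0.01, seed = 4))
  cv <- sim$curve
  cv2 <- frap_curve(cv$time, cv$roi_mean * 7, cv$nucleus_mean * 7,
                    cv$background * 7, cv$n_pre)
  f1 <- fit_exponential_recovery(cv)
  f2 <- fit_exponential_recovery(cv2)
  expect_equal(f1$mobile_fraction, f2$mobile_fraction, tolerance = 1e-8)
  expect_equal(f1$tau, f2$tau, tolerance = 1e-8)
})

test_that("an immobile control distinguishes chromatin-bound from mobile protein", {
  bound <- simulate_frap_curve(sim_frap_config(mobile_fraction = 0.02,
                                               noise_sd = 0.01, seed = 3))
  mobile <- simulate_frap_curve(sim_frap_config(mobile_fraction = 0.9,
                                                tau = 20, noise_sd = 0.01,
                                                seed = 3))
  fb <- fit_exponential_recovery(bound$curve)
  fm <- fit_exponential_recovery(mobile$curve)
  expect_lt(fb$mobile_fraction, 0.1)
  expect_gt(fm$mobile_fraction, 0.8)
})

test_that("FRAP CSV round-trips through the reader", {
  sim <- simulate_frap_curve(sim_frap_config(noise_sd = 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = sim$curve$time, roi_mean = sim$curve$roi_mean,
                       nucleus_mean = sim$curve$nucleus_mean,
                       background = sim$curve$background),
            path, row.names = FALSE)
  back <- read_frap_csv(path)
  expect_equal(back$time, sim$curve$time)
  expect_equal(back$roi_mean, sim$curve$roi_mean)
  fit <- fit_exponential_recovery(back)
  expect_lt(abs(fit$tau / 50 - 1), 0.001)
})
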