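test_that("covariate tables satisfy the demographic invariants", {
  cov <- generate_covariates(25, 24, ground_truth(), seed = 11)
  expect_equal(cov$pp, cov$sbp - cov$dbp)
  expect_true(all(cov$pwv_true > 0))
  par_age <- range(cov$age[cov$group == "parent"])
  off_age <- range(cov$age[cov$group == "offspring"])
  expect_gte(par_age[1], 43); expect_lte(par_age[2], 67)
  expect_gte(off_age[1], 19); expect_lte(off_age[2], 39)
  expect_lt(off_age[2], par_age[1])  # disjoint generations
  expect_error(generate_covariates(1, 5), class = "argument_error")
})

test_that("degenerate regression collapses PWV to the intercept", {
  tr <- ground_truth(beta_age = 0, beta_sbp = 0, beta_height = 0,
                     sex_sd = 0, pwv_noise_sd = 0)
  cov <- generate_covariates(5, 5, tr, seed = 2)
  expect_equal(cov$pwv_true, rep(tr$intercept, 10))
})

test_that("OLS on a large generated cohort recovers the age slope", {
  tr <- ground_truth(beta_age = 0.08, beta_sbp = 0, beta_height = 0,
                     sex_sd = 0, pwv_noise_sd = 0.3)
  cov <- generate_covariates(1000, 1000, tr, seed = 1)
  fit <- summary(lm(pwv_true ~ age, cov))$coefficients
  expect_lt(abs(fit["age", "Estimate"] - 0.08), 3 * fit["age", "Std. Error"])
})

test_that("parent-group pulse pressure matches its generative targets", {
  cov <- generate_covariates(2500, 100, ground_truth(), seed = 3)
  pp <- cov$pp[cov$group == "parent"]
  # target means 122.5 / 67.5 mmHg imply a mean PP of 55.0 mmHg
  expect_equal(mean(pp), 55.0, tolerance = 0.02)
})

test_that("generators are bit-identical under identical seeds", {
  expect_identical(generate_covariates(5, 5, seed = 7),
                   generate_covariates(5, 5, seed = 7))
  expect_identical(generate_flow_waveforms(6, noise_sd = 3, seed = 7),
                   generate_flow_waveforms(6, noise_sd = 3, seed = 7))
  expect_identical(generate_atlases(c(8, 8, 4), seed = 7),
                   generate_atlases(c(8, 8, 4), seed = 7))
  cov <- generate_covariates(2, 2, seed = 1)
  expect_identical(
    generate_pcasl_series(cov[1, ], dims = c(6, 6, 4), n_frames = 20, seed = 7),
    generate_pcasl_series(cov[1, ], dims = c(6, 6, 4), n_frames = 20, seed = 7))
})

test_that("waveform pairs encode the x/t transit delay", {
  wf <- generate_flow_waveforms(5, path_length = 0.356, noise_sd = 0)
  expect_equal(wf$true_delay_ms, 71.2)
  wf2 <- generate_flow_waveforms(10, path_length = 0.356, noise_sd = 0)
  expect_equal(wf2$true_delay_ms, wf$true_delay_ms / 2)
  # delay an exact multiple of the sampling step: shifted samples coincide
  wf3 <- generate_flow_waveforms(0.356 / 0.020, path_length = 0.356,
                                 noise_sd = 0, sampling_dt = 5)
  lag <- 4  # 20 ms / 5 ms
  n <- nrow(wf3$arch)
  expect_equal(wf3$abdominal$flow[(lag + 1):n], wf3$arch$flow[1:(n - lag)],
               tolerance = 1e-12)
  expect_error(generate_flow_waveforms(0.2, path_length = 0.356),
               class = "config_error")
  expect_error(generate_flow_waveforms(-1), class = "argument_error")
})

test_that("tissue masks partition the brain and vessels hit their target", {
  at <- generate_atlases(c(12, 12, 6), seed = 5)
  expect_false(any(at$gm & at$wm))
  expect_false(any(at$gm & at$csf))
  expect_false(any(at$wm & at$csf))
  expect_identical(at$gm | at$wm | at$csf, at$brain)
  expect_true(all(at$vessel_prob >= 0 & at$vessel_prob <= 1))
  frac <- sum(at$vessel_prob > 0) / sum(at$brain)
  expect_lt(abs(frac - 0.10), 0.02)
  expect_false(any(at$arterial & at$venous))
  expect_true(all(at$vessel_prob[at$arterial] > 0))
  at2 <- generate_atlases(c(10, 10, 8), seed = 5, vessel_fraction = 0.2)
  expect_lt(abs(sum(at2$vessel_prob > 0) / sum(at2$brain) - 0.2), 0.02)
})

test_that("pcasl generator validates arguments", {
  cov <- generate_covariates(2, 2, seed = 1)
  expect_error(generate_pcasl_series(cov[1, ], n_frames = 25),
               class = "argument_error")
  expect_error(generate_pcasl_series(cov[1, ], dims = c(2, 8, 8),
                                     n_frames = 20),
               class = "argument_error")
})

test_that("a no-effect configuration leaves amplitudes independent of PWV", {
  tr <- null_truth()
  cov <- generate_covariates(2, 2, tr, seed = 1)
  cov$pwv_true <- c(3, 12, 5, 7)
  ser <- lapply(1:4, function(i)
    generate_pcasl_series(cov[i, ], tr, dims = c(8, 8, 4), n_frames = 20,
                          seed = 20 + i))
  betas <- vapply(ser, function(s) s$truth_subject$beta, numeric(1))
  gammas <- vapply(ser, function(s) s$truth_subject$gamma, numeric(1))
  expect_equal(diff(range(betas)), 0)
  expect_equal(diff(range(gammas)), 0)
})

test_that("with pure label signal, surround subtraction recovers delta", {
  tr <- null_truth(gamma0 = 0, beta_out = 0, beta_base = 0)
  cov <- generate_covariates(2, 2, tr, seed = 1)
  s <- generate_pcasl_series(cov[1, ], tr, dims = c(8, 8, 4), n_frames = 24,
                             seed = 3)
  dm <- surround_subtract(s$echo1, s$frame_role)
  expected <- s$truth_subject$delta
  for (i in seq_len(dim(dm)[4]))
    expect_equal(dm[, , , i], expected, tolerance = 1e-10)
})
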