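test_that("initial-frame discard preserves parity and counts", {
  cov <- generate_covariates(2, 2, seed = 1)
  s <- generate_pcasl_series(cov[1, ], dims = c(6, 6, 4), n_frames = 100,
                             seed = 2)
  s4 <- discard_initial_frames(s, 4)
  expect_equal(dim(s4$echo1)[4], 96)
  expect_equal(s4$frame_role[1], "control")
  expect_true(all(s4$frame_role[c(TRUE, FALSE)] == "control"))
  expect_identical(discard_initial_frames(s, 0), s)
  expect_error(discard_initial_frames(s, 3), class = "argument_error")
  expect_error(discard_initial_frames(s, 100), class = "argument_error")
})

test_that("surround stencils separate alternating and slow components", {
  s <- one_voxel_series(c(10, 6, 10, 6, 10))
  expect_equal(as.vector(surround_average(s)), c(8, 8, 8))
  expect_equal(as.vector(surround_subtract(s, roles(5))), c(4, 4, 4))
  drift <- one_voxel_series(1:7)
  expect_equal(as.vector(surround_average(drift)), 2:6)
  expect_equal(as.vector(surround_subtract(drift, roles(7))), rep(0, 5))
  # s_i = c + (-1)^i d + 0.01 i  ->  average = c + 0.01 i, subtract = d
  i <- 0:9
  comp <- one_voxel_series(3 + (-1)^i * 2 + 0.01 * i)
  expect_equal(as.vector(surround_average(comp)), 3 + 0.01 * i[2:9],
               tolerance = 1e-12)
  expect_equal(as.vector(surround_subtract(comp, roles(10))), rep(2 * 2, 8),
               tolerance = 1e-12)
  expect_error(surround_average(one_voxel_series(c(1, 2))),
               class = "argument_error")
})

test_that("compcor removes an injected shared nuisance from gray matter", {
  set.seed(42)
  dims <- c(8, 8, 4)
  at <- generate_atlases(dims, seed = 1)
  nt <- 60
  nuis <- sin(2 * pi * 0.03 * (0:(nt - 1)) * 4) + rnorm(nt, 0, 0.2)
  e1 <- array(rnorm(prod(dims) * nt, 100, 1), dim = c(dims, nt))
  gm_idx <- which(as.vector(at$gm))
  half_gm <- sample(gm_idx, length(gm_idx) %/% 2)
  csf_idx <- which(as.vector(at$csf) | as.vector(at$wm))
  flat <- matrix(e1, ncol = nt)
  flat[csf_idx, ] <- flat[csf_idx, ] + 5 * rep(nuis, each = length(csf_idx))
  flat[half_gm, ] <- flat[half_gm, ] + 5 * rep(nuis, each = length(half_gm))
  s <- structure(list(echo1 = array(flat, dim = c(dims, nt)),
                      echo2 = array(flat, dim = c(dims, nt)),
                      frame_role = roles(nt), tr = 4, masks = at),
                 class = "dual_echo_series")
  den <- compcor_denoise(s, k = 1)
  res_gm <- matrix(den$echo1, ncol = nt)[half_gm, , drop = FALSE]
  cors <- apply(res_gm, 1, function(v) {
    # correlate each stream with the matching nuisance samples
    max(abs(cor(v[c(TRUE, FALSE)], nuis[c(TRUE, FALSE)])),
        abs(cor(v[c(FALSE, TRUE)], nuis[c(FALSE, TRUE)])))
  })
  expect_lt(median(cors), 0.1)
})

test_that("compcor is an idempotent projection and k=0 only de-means", {
  cov <- generate_covariates(2, 2, seed = 1)
  s <- generate_pcasl_series(cov[1, ], dims = c(6, 6, 4), n_frames = 24,
                             seed = 5)
  d1 <- compcor_denoise(s, k = 2)
  # re-applying the same projection (fixed components) changes nothing
  d2 <- compcor_denoise(d1, k = 2, components = d1$compcor_components)
  expect_equal(d2$echo1, d1$echo1, tolerance = 1e-8)
  expect_equal(d2$echo2, d1$echo2, tolerance = 1e-8)
  d0 <- compcor_denoise(s, k = 0)
  X <- t(matrix(s$echo1, ncol = 24))
  for (str in list(c(TRUE, FALSE), c(FALSE, TRUE))) {
    manual <- sweep(X[str, ], 2, colMeans(X[str, ]))
    expect_equal(t(matrix(d0$echo1, ncol = 24))[str, ], manual,
                 tolerance = 1e-10)
  }
  expect_error(compcor_denoise(s, k = 12), class = "argument_error")
})

test_that("band-pass preserves in-band tones and rejects DC and high band", {
  tt <- (0:95) * 4
  inband <- matrix(sin(2 * pi * 0.04 * tt), ncol = 1)
  out <- bandpass(inband, tr = 4)
  amp <- sqrt(2) * sd(out[25:72, 1])
  expect_gt(amp, 0.98); expect_lt(amp, 1.02)
  dc <- bandpass(matrix(rep(7, 96), ncol = 1), tr = 4)
  expect_lt(max(abs(dc)), 1e-3 * 7)
  # out-of-band rejection at 2x the upper edge (shorter TR so 0.2 Hz exists)
  t1 <- (0:199) * 1
  mix <- matrix(sin(2 * pi * 0.04 * t1) + sin(2 * pi * 0.2 * t1), ncol = 1)
  o <- bandpass(mix, tr = 1)
  resid_high <- o[50:150, 1] - sin(2 * pi * 0.04 * t1[50:150]) *
    (sqrt(2) * sd(o[50:150, 1]))
  # project onto the 0.2 Hz tone to measure its surviving amplitude
  carrier <- sin(2 * pi * 0.2 * t1[50:150])
  amp_high <- 2 * mean(o[50:150, 1] * carrier)
  expect_lt(abs(amp_high), 0.1)
  expect_error(bandpass(inband, tr = 4, hi = 0.2), class = "config_error")
  expect_error(bandpass(inband, tr = 4, lo = 0.09, hi = 0.08),
               class = "config_error")
})

test_that("demodulation recovers the label envelope and rejects BOLD band", {
  d <- 4
  carrier <- one_voxel_series(rep(c(d, -d), 48))
  env <- demodulate_first_echo(carrier, 4, roles(96))
  expect_lt(abs(mean(env[1, 1, 1, 30:66]) - d) / d, 0.02)
  tt <- (0:95) * 4
  bold <- one_voxel_series(sin(2 * pi * 0.02 * tt))
  leak <- demodulate_first_echo(bold, 4, roles(96))
  expect_lt(max(abs(leak[1, 1, 1, 20:76])), 0.05)
  zero <- demodulate_first_echo(one_voxel_series(rep(0, 96)), 4, roles(96))
  expect_equal(max(abs(zero)), 0)
  expect_error(demodulate_first_echo(carrier, 4, roles(96), lp_cutoff = 0.2),
               class = "config_error")
})

test_that("gaussian smoothing has the right width and conserves mass", {
  # cubic grid wide enough that the 4-sigma kernel support stays interior
  dims <- c(21, 21, 21)
  delta <- array(0, dim = dims); delta[11, 11, 11] <- 1
  sm <- spatial_smooth(delta, fwhm = 6, voxel_size = 2)
  prof <- sm[, 11, 11]
  half <- max(prof) / 2
  above <- which(prof >= half)
  # linear interpolation of the half-maximum crossings, in mm
  lo <- above[1]; hi <- above[length(above)]
  x1 <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  x2 <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  fwhm_mm <- (x2 - x1) * 2
  expect_lt(abs(fwhm_mm - 6), 1)           # within half a voxel
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  const <- array(3, dim = dims)
  expect_equal(spatial_smooth(const, 6, 2), const, tolerance = 1e-12)
  expect_identical(spatial_smooth(delta, 0, 2), delta)
})

test_that("the separation pipeline records provenance and is reproducible", {
  cov <- generate_covariates(2, 2, seed = 1)
  s <- generate_pcasl_series(cov[1, ], dims = c(8, 8, 4), n_frames = 40,
                             seed = 9)
  a <- separate_signals(s)
  b <- separate_signals(s)
  expect_identical(a$bold, b$bold)
  expect_identical(a$cbf_signal, b$cbf_signal)
  expect_true(any(grepl("discard_initial_frames", a$provenance)))
  expect_true(any(grepl("compcor", a$provenance)))
  expect_equal(dim(a$bold)[4], 40 - 4 - 2)
})

test_that("band-passed BOLD variance tracks the injected amplitude", {
  # beta known and the process slow enough that stencil/filter losses are a
  # few percent: variance ~ beta^2 M0^2 Var(b) within 10%
  tr <- null_truth(beta_out = 0.01, noise_sd = 0, fluct_band = c(0.005, 0.015))
  cov <- generate_covariates(2, 2, tr, seed = 1)
  s <- generate_pcasl_series(cov[1, ], tr, dims = c(8, 8, 4), n_frames = 100,
                             seed = 13)
  s <- discard_initial_frames(s, 4)
  bold <- bandpass(surround_average(s$echo2), s$tr)
  gm1 <- which(s$masks$gm, arr.ind = TRUE)[1, , drop = FALSE]
  v <- var(bold[gm1[1], gm1[2], gm1[3], ])
  m0e2 <- 1000 * 0.8
  expected <- (0.01 * m0e2)^2 * var(s$truth_subject$b[5:100])
  expect_lt(abs(v - expected) / expected, 0.10)
})
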