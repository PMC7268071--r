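test_that("noise-free cohorts give exact fixed-effect recovery", {
  tr <- ground_truth(pwv_noise_sd = 0, sex_sd = 0.3)
  cov <- generate_covariates(30, 30, tr, seed = 21)
  fit <- fit_pwv_mixed_model(cov, "sbp")
  fe <- fit$fixed_effects
  expect_equal(fe$estimate[fe$term == "age"], tr$beta_age, tolerance = 1e-6)
  expect_equal(fe$estimate[fe$term == "height"], tr$beta_height,
               tolerance = 1e-6)
  expect_equal(fe$estimate[fe$term == "sbp"], tr$beta_sbp, tolerance = 1e-6)
})

test_that("the age effect is detected with high power at large n", {
  cov <- generate_covariates(1000, 1000, ground_truth(), seed = 22)
  fit <- fit_pwv_mixed_model(cov, "sbp")
  fe <- fit$fixed_effects
  expect_gt(fe$estimate[fe$term == "age"], 0)
  expect_lt(fe$p[fe$term == "age"], 0.05)
  expect_true(is.finite(fit$random_intercept_var))
})

test_that("mixed model rejects degenerate inputs", {
  cov <- generate_covariates(10, 10, seed = 23)
  cov$age[1] <- NA
  expect_error(fit_pwv_mixed_model(cov), class = "model_error")
  cov2 <- generate_covariates(10, 10, seed = 23)
  cov2$sex <- factor(rep("F", 20), levels = c("F", "M"))
  expect_error(fit_pwv_mixed_model(cov2), class = "model_error")
})

test_that("voxelwise GLM matches the closed-form simple-regression t", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  Y <- cbind(c(2, 4, 3, 8, 6), c(10, 7, 8, 3, 5))
  design <- cbind(1, x)
  tt <- voxelwise_glm(Y, design, c(0, 1))
  oracle <- vapply(1:2, function(v) {
    r <- cor(x, Y[, v])
    r * sqrt(3) / sqrt(1 - r^2)
  }, numeric(1))
  expect_equal(as.numeric(tt), oracle, tolerance = 1e-10)
  expect_equal(attr(tt, "df"), 3)
  # zero contrast -> identically zero
  expect_true(all(voxelwise_glm(Y, design, c(0, 0)) == 0))
  expect_error(voxelwise_glm(Y, cbind(1, x, x), c(0, 1, 0)),
               class = "model_error")
})

test_that("null-model GLM t-statistics have nominal tail mass", {
  set.seed(24)
  n <- 30; V <- 4000
  Y <- matrix(rnorm(n * V), n, V)
  design <- cbind(1, rnorm(n))
  tt <- voxelwise_glm(Y, design, c(0, 1))
  frac <- mean(abs(tt) > qt(0.975, n - 2))
  expect_gt(frac, 0.035); expect_lt(frac, 0.065)
})

test_that("TFCE reproduces the isolated-voxel closed form", {
  tm <- array(0, dim = c(7, 7, 3))
  expect_true(all(tfce(tm, dh = 0.1) == 0))
  h0 <- 2.5
  tm[4, 4, 2] <- h0
  score <- tfce(tm, dh = h0 / 1000)[4, 4, 2]
  expect_lt(abs(score - h0^3 / 3) / (h0^3 / 3), 0.005)
})

test_that("TFCE equals a brute-force per-threshold evaluation", {
  set.seed(25)
  for (conn in c(6L, 26L)) {
    tm <- array(pmax(rnorm(6 * 5 * 3), 0), dim = c(6, 5, 3))
    dh <- max(tm) / 25
    got <- tfce(tm, dh = dh, connectivity = conn)
    expect_equal(got, tfce_oracle(tm, dh = dh, connectivity = conn),
                 tolerance = 1e-10)
  }
})

test_that("raising one voxel never lowers any TFCE score", {
  set.seed(26)
  for (rep in 1:10) {
    tm <- array(pmax(rnorm(8 * 8 * 4, 0.5), 0), dim = c(8, 8, 4))
    dh <- max(tm) / 50
    base <- tfce(tm, dh = dh)
    v <- sample(length(tm), 1)
    tm2 <- tm
    tm2[v] <- tm2[v] + runif(1, 0.1, 2)
    raised <- tfce(tm2, dh = dh)
    expect_true(all(raised - base > -1e-10))
  }
})

test_that("permutation p-values respect their estimator bound and seed", {
  set.seed(27)
  Y <- array(rnorm(6 * 6 * 3 * 16), dim = c(6, 6, 3, 16))
  design <- cbind(1, rnorm(16))
  r1 <- permutation_correct(Y, design, c(0, 1), n_perm = 150, seed = 5)
  r2 <- permutation_correct(Y, design, c(0, 1), n_perm = 150, seed = 5)
  expect_identical(r1$pcorr_map$values, r2$pcorr_map$values)
  expect_gte(min(r1$pcorr_map$values), 1 / 151)
  expect_warning(permutation_correct(Y, design, c(0, 1), n_perm = 50, seed = 1),
                 "coarse")
  expect_error(permutation_correct(Y, design, c(0, 0), n_perm = 150, seed = 1),
               class = "model_error")
})

test_that("vessel-probability regression is exact on a linear relation", {
  dims <- c(10, 10, 4)
  set.seed(28)
  p <- array(runif(prod(dims)), dim = dims)
  tmap <- 10 - 8 * p
  sig <- array(TRUE, dim = dims)
  for (binned in c(TRUE, FALSE)) {
    fit <- vessel_bin_regression(tmap, p, sig, binned = binned)
    expect_equal(fit$slope, -8, tolerance = 1e-10)
    expect_equal(fit$intercept, 10, tolerance = 1e-10)
  }
  expect_error(vessel_bin_regression(tmap, array(0.5, dim = dims), sig),
               class = "regression_error")
  expect_error(vessel_bin_regression(tmap, p, array(FALSE, dim = dims)),
               class = "argument_error")
  noisy <- 10 - 8 * p + array(rnorm(prod(dims)), dim = dims)
  fit2 <- vessel_bin_regression(noisy, p, sig)
  expect_gt(fit2$slope, -9); expect_lt(fit2$slope, -7)
})

test_that("overlap fraction is plain percentage arithmetic", {
  a <- array(FALSE, dim = c(5, 4, 1)); b <- a
  a[1:20] <- TRUE; b[1:20] <- TRUE
  expect_equal(overlap_fraction(a, b), 100)
  b[] <- FALSE
  expect_equal(overlap_fraction(a, b), 0)
  b[1:9] <- TRUE
  expect_equal(overlap_fraction(a, b), 45)
  expect_error(overlap_fraction(array(FALSE, dim = c(2, 2, 1)), b),
               class = "argument_error")
})

test_that("mediation is deterministic, additive and validates input", {
  set.seed(29)
  n <- 80
  x <- rnorm(n); m <- 1.5 * x + rnorm(n); y <- 0.8 * m + 0.3 * x + rnorm(n)
  r1 <- mediate(x, m, y, n_boot = 300, seed = 4)
  r2 <- mediate(x, m, y, n_boot = 300, seed = 4)
  expect_identical(r1$ci95, r2$ci95)
  expect_equal(r1$c, r1$c_prime + r1$ab, tolerance = 1e-8)
  cov1 <- rnorm(n)
  r3 <- mediate(x, m, y, covariates = cov1, n_boot = 200, seed = 4)
  expect_equal(r3$c, r3$c_prime + r3$ab, tolerance = 1e-8)
  expect_error(mediate(rep(1, n), m, y), class = "model_error")
  expect_error(mediate(x[1:5], m[1:5], y[1:5]), class = "argument_error")
})

test_that("an injected group effect is found by the corrected inference", {
  set.seed(30)
  dims <- c(6, 6, 3)
  n <- 40
  x <- rnorm(n)
  Y <- array(rnorm(prod(dims) * n), dim = c(dims, n))
  roi <- array(FALSE, dim = dims); roi[2:3, 2:3, 2] <- TRUE
  for (s in 1:n)
    Y[, , , s][roi] <- Y[, , , s][roi] - 1.2 * x[s]
  res <- permutation_correct(Y, cbind(1, x), c(0, 1), n_perm = 300, seed = 6,
                             direction = "negative")
  expect_lt(min(res$pcorr_map$values[roi]), 0.05)
  # positive direction finds nothing comparable
  pos <- permutation_correct(Y, cbind(1, x), c(0, 1), n_perm = 300, seed = 6,
                             direction = "positive")
  expect_gt(min(pos$pcorr_map$values[roi]), 0.05)
})
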