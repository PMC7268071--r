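# Cross-subject inference: mixed-effects PWV models, voxelwise GLM with TFCE
# and Freedman-Lane permutation FWE correction, vessel-probability
# regression, overlap fraction, and bootstrap mediation.

#' Mixed-effects model of PWV on demographics
#'
#' Fits `pwv ~ 1 + age + height + <bp term> + (1 | sex)` by REML. With only
#' two sex levels the random-intercept variance frequently degenerates to 0;
#' in that case (or on any fit failure) the model falls back to ordinary
#' least squares with sex as a fixed covariate, and the fallback is recorded.
#'
#' @param cov covariate table with columns `age`, `height`, `sex` and the
#'   blood-pressure term; the response is column `pwv` if present, else
#'   `pwv_true`.
#' @param bp_term `"sbp"`, `"dbp"` or `"pp"`.
#' @return A `pwv_mixed_model` object: `fixed_effects` data frame (term,
#'   estimate, se, p, ci_lo, ci_hi), `random_intercept_var`, `fallback_ols`,
#'   `n`, `bp_term`, and the underlying `fit`.
#' @export
fit_pwv_mixed_model <- function(cov, bp_term = c("sbp", "dbp", "pp")) {
  bp_term <- match.arg(bp_term)
  response <- if ("pwv" %in% names(cov)) "pwv" else "pwv_true"
  need <- c(response, "age", "height", "sex", bp_term)
  if (anyNA(cov[need])) model_error("missing covariates in the table")
  if (length(unique(cov$sex)) < 2L) model_error("need two sex levels")
  cov <- as.data.frame(cov)

  lmer_form <- stats::as.formula(
    sprintf("%s ~ 1 + age + height + %s + (1 | sex)", response, bp_term))
  ols_form <- stats::as.formula(
    sprintf("%s ~ 1 + age + height + %s + sex", response, bp_term))

  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(lmer_form, data = cov, REML = TRUE))),
    error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)

  terms_keep <- c("(Intercept)", "age", "height", bp_term)
  if (!singular) {
    sm <- summary(fit)$coefficients
    fe <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                     se = sm[, "Std. Error"], p = sm[, "Pr(>|t|)"],
                     row.names = NULL)
    crit <- stats::qt(0.975, df = sm[, "df"])
    fe$ci_lo <- fe$estimate - crit * fe$se
    fe$ci_hi <- fe$estimate + crit * fe$se
    rand_var <- as.numeric(lme4::VarCorr(fit)$sex[1])
    fallback <- FALSE
  } else {
    fit <- lm(ols_form, data = cov)
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit)
    fe <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                     p = sm[, 4], ci_lo = ci[, 1], ci_hi = ci[, 2],
                     row.names = NULL)
    rand_var <- 0
    fallback <- TRUE
  }
  fe <- fe[fe$term %in% terms_keep, , drop = FALSE]
  structure(list(fixed_effects = fe, random_intercept_var = rand_var,
                 fallback_ols = fallback, n = nrow(cov), bp_term = bp_term,
                 fit = fit),
            class = "pwv_mixed_model")
}

#' @export
print.pwv_mixed_model <- function(x, ...) {
  cat(sprintf("PWV mixed model (bp term: %s, n = %d%s)\n", x$bp_term, x$n,
              if (x$fallback_ols) ", OLS fallback: singular sex intercept" else ""))
  print(x$fixed_effects, digits = 4, row.names = FALSE)
  invisible(x)
}

# vectorized per-voxel OLS t-statistics; Y is n x V, X n x p
glm_tstats <- function(Y, X, contrast) {
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) arg_error("design rows must match subjects")
  if (length(contrast) != p) arg_error("contrast length must match design columns")
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) model_error("rank-deficient design"))
  XtXi <- chol2inv(R)
  B <- XtXi %*% crossprod(X, Y)                 # p x V
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / (n - p)
  cb <- drop(crossprod(contrast, B))
  se <- sqrt(sigma2 * drop(crossprod(contrast, XtXi %*% contrast)))
  tt <- cb / se
  tt[se == 0] <- 0
  tt
}

#' Voxelwise general linear model
#'
#' Per-voxel OLS of the subject stack on the design matrix;
#' `t = contrast' beta / SE`. Supports the covariate-adjusted model (e.g.
#' PWV + age + intercept) through the design.
#'
#' @param stack 4-D array (subject = 4th dim) or n-by-V matrix.
#' @param design n-by-p design matrix (include the intercept explicitly).
#' @param contrast length-p contrast vector.
#' @param mask logical 3-D mask when `stack` is 4-D.
#' @return A `stat_map` of t values (4-D input) or a numeric vector
#'   (matrix input), with attribute `df` = n - p.
#' @export
voxelwise_glm <- function(stack, design, contrast, mask = NULL) {
  design <- as.matrix(design)
  if (all(contrast == 0)) {
    # a zero contrast tests nothing: t is identically zero
    if (is.matrix(stack)) return(structure(rep(0, ncol(stack)),
                                           df = nrow(design) - ncol(design)))
    v <- array(0, dim = dim(stack)[1:3])
    out <- stat_map(v, "tstat", mask = mask)
    attr(out, "df") <- nrow(design) - ncol(design)
    return(out)
  }
  if (is.matrix(stack)) {
    tt <- glm_tstats(stack, design, contrast)
    return(structure(tt, df = nrow(design) - ncol(design)))
  }
  d <- dim(stack)
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  Y <- series_to_matrix(stack, mask)
  tt <- glm_tstats(Y, design, contrast)
  out <- stat_map(map_values_to_volume(tt, d[1:3], mask), "tstat", mask = mask)
  attr(out, "df") <- nrow(design) - ncol(design)
  out
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(v) = sum over h = dh, 2dh, ... <= t(v) of e_h(v)^E * h^H * dh`,
#' where `e_h(v)` is the voxel count of the connected component containing v
#' in the suprathreshold set `{t >= h}`. Only positive values are enhanced;
#' pass `-t` for the negative direction.
#'
#' @param tmap `stat_map` or 3-D array of statistics.
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step; default `max(t)/100`.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A `stat_map` of kind `"tfce"` (or 3-D array for array input).
#' @export
tfce <- function(tmap, E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  v <- if (inherits(tmap, "stat_map")) tmap$values else tmap
  if (!connectivity %in% c(6L, 18L, 26L)) arg_error("connectivity must be 6, 18 or 26")
  tmax <- max(v, 0)
  if (is.null(dh)) dh <- if (tmax > 0) tmax / 100 else 1
  if (dh <= 0) arg_error("dh must be > 0")
  scores <- tfce_cpp(as.numeric(v), as.integer(dim(v)), E, H, dh,
                     as.integer(connectivity))
  out <- array(scores, dim = dim(v))
  if (inherits(tmap, "stat_map"))
    stat_map(out, "tfce", mask = tmap$mask)
  else out
}

#' Permutation FWE correction with TFCE (Freedman-Lane)
#'
#' One-sided voxelwise inference in the requested direction. The nuisance
#' part of the design (columns with zero contrast weight) is fitted, its
#' residuals are permuted by seeded whole-row shuffles, the full model is
#' refitted on each permuted dataset, the permuted t-map is TFCE-enhanced,
#' and the maximum TFCE statistic forms the null distribution. Corrected
#' p-values are `(1 + #{perm max >= observed TFCE(v)}) / (n_perm + 1)`.
#'
#' @param stack 4-D subject stack or n-by-V matrix.
#' @param design n-by-p design matrix (intercept included).
#' @param contrast length-p contrast; must weight at least one column.
#' @param n_perm number of permutations (warning below 100).
#' @param seed integer seed for the permutation stream.
#' @param direction `"negative"` (default, tests contrast < 0) or
#'   `"positive"`.
#' @param mask logical 3-D mask for 4-D stacks.
#' @param E,H,dh,connectivity TFCE options; `dh` defaults to 1/100 of the
#'   observed maximum enhanced statistic and is held fixed across
#'   permutations.
#' @return A `permutation_result`: `tmap`, `tfce_map`, `pcorr_map` (each a
#'   `stat_map` for 4-D input, vector otherwise), `max_null`, `n_perm`,
#'   `seed`, `direction`.
#' @export
permutation_correct <- function(stack, design, contrast, n_perm = 1000,
                                seed = 1L, direction = c("negative", "positive"),
                                mask = NULL, E = 0.5, H = 2, dh = NULL,
                                connectivity = 26) {
  direction <- match.arg(direction)
  design <- as.matrix(design)
  if (all(contrast == 0)) model_error("contrast must weight at least one column")
  if (n_perm < 100) warning("n_perm < 100 gives very coarse p-values")
  is_mat <- is.matrix(stack)
  if (!is_mat) {
    d <- dim(stack)
    if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
    Y <- series_to_matrix(stack, mask)
    vdims <- dim(mask)
  } else Y <- stack
  n <- nrow(Y)
  flip <- if (direction == "negative") -1 else 1

  score_dims <- if (is_mat) c(ncol(Y), 1L, 1L) else vdims
  tfce_of <- function(tt, step) {
    arr <- if (is_mat) array(pmax(flip * tt, 0), dim = score_dims)
    else map_values_to_volume(pmax(flip * tt, 0), vdims, mask)
    tfce_cpp(as.numeric(arr), as.integer(score_dims), E, H, step,
             as.integer(connectivity))[if (is_mat) TRUE else as.vector(mask)]
  }

  t_obs <- glm_tstats(Y, design, contrast)
  step <- dh
  if (is.null(step)) {
    m <- max(flip * t_obs, 0)
    step <- if (m > 0) m / 100 else 1
  }
  tfce_obs <- tfce_of(t_obs, step)

  nuis_cols <- which(contrast == 0)
  Z <- design[, nuis_cols, drop = FALSE]
  if (ncol(Z) > 0) {
    qz <- qr(Z)
    fitted_z <- Z %*% qr.coef(qz, Y)
    fitted_z[is.na(fitted_z)] <- 0
    resid_z <- Y - fitted_z
  } else {
    fitted_z <- matrix(0, n, ncol(Y))
    resid_z <- Y
  }
  max_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(n)
      Yb <- fitted_z + resid_z[perm, , drop = FALSE]
      max(tfce_of(glm_tstats(Yb, design, contrast), step))
    }, numeric(1))
  })
  pcorr <- (1 + vapply(tfce_obs, function(s) sum(max_null >= s), numeric(1))) /
    (n_perm + 1)

  wrap <- function(vals, kind) {
    if (is_mat) return(vals)
    stat_map(map_values_to_volume(vals, vdims, mask,
                                  fill = if (kind == "pcorr") 1 else 0),
             kind, mask = mask)
  }
  structure(list(tmap = wrap(t_obs, "tstat"),
                 tfce_map = wrap(tfce_obs, "tfce"),
                 pcorr_map = wrap(pcorr, "pcorr"),
                 max_null = max_null, n_perm = n_perm, seed = seed,
                 direction = direction, dh = step),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  pc <- if (inherits(x$pcorr_map, "stat_map"))
    x$pcorr_map$values[x$pcorr_map$mask] else x$pcorr_map
  cat(sprintf(
    "<permutation_result %s direction, %d permutations, min pcorr = %.4g, %d voxels < 0.05>\n",
    x$direction, x$n_perm, min(pc), sum(pc < 0.05)))
  invisible(x)
}

#' Regression of association strength on vessel probability
#'
#' Within significant voxels, vessel probabilities are split into equidistant
#' bins; per-bin mean t and mean probability feed an OLS of t on probability.
#' In unbinned mode (used for the arterial/venous submask analyses) the
#' regression is voxelwise.
#'
#' @param tmap `stat_map` or 3-D array of t values.
#' @param vessel_prob 3-D vessel-probability array.
#' @param sig_mask logical array of significant voxels (non-empty).
#' @param n_bins number of equidistant bins (default 30).
#' @param binned bin before regressing (default `TRUE`).
#' @return List with `slope`, `intercept`, `bins` (data frame of per-bin
#'   means; `NULL` when unbinned), `n_voxels`.
#' @export
vessel_bin_regression <- function(tmap, vessel_prob, sig_mask, n_bins = 30,
                                  binned = TRUE) {
  tv <- if (inherits(tmap, "stat_map")) tmap$values else tmap
  if (!any(sig_mask)) arg_error("sig_mask is empty")
  tt <- tv[sig_mask]
  pp <- vessel_prob[sig_mask]
  if (diff(range(pp)) == 0)
    regression_error("vessel probability is constant within the mask")
  if (binned) {
    breaks <- seq(min(pp), max(pp), length.out = n_bins + 1)
    bin <- cut(pp, breaks, include.lowest = TRUE)
    bt <- tapply(tt, bin, mean)
    bp <- tapply(pp, bin, mean)
    keep <- !is.na(bt)
    if (sum(keep) < 2L) regression_error("fewer than 2 non-empty bins")
    fit <- lm(bt[keep] ~ bp[keep])
    bins <- data.frame(prob = as.numeric(bp[keep]), t = as.numeric(bt[keep]),
                       n = as.numeric(table(bin)[keep]))
  } else {
    fit <- lm(tt ~ pp)
    bins <- NULL
  }
  cf <- coef(fit)
  list(slope = unname(cf[2]), intercept = unname(cf[1]), bins = bins,
       n_voxels = length(tt))
}

#' Percentage of significant voxels inside the vessel mask
#'
#' `100 * |sig AND vessel| / |sig|`.
#'
#' @param sig_mask logical array of significant voxels (non-empty).
#' @param vessel_mask logical array of vascularized voxels.
#' @return Percentage in \[0, 100\].
#' @export
overlap_fraction <- function(sig_mask, vessel_mask) {
  if (!any(sig_mask)) arg_error("sig_mask is empty")
  100 * sum(sig_mask & vessel_mask) / sum(sig_mask)
}

# OLS slope helpers on raw matrices (fast path for the bootstrap loop)
ols_coefs <- function(X, y) {
  qr.coef(qr(X), y)
}

#' Bootstrap mediation analysis
#'
#' Product-of-coefficients mediation with nonparametric case-resampling
#' bootstrap: path `a` from `m ~ x (+ cov)`, paths `b` and `c'` from
#' `y ~ x + m (+ cov)`, total effect `c` from `y ~ x (+ cov)`; the indirect
#' effect is `ab = a * b` with a percentile 95% CI over `n_boot` resamples
#' and `p = 2 * min(P(ab* <= 0), P(ab* >= 0))` with the +1 finite-sample
#' correction.
#'
#' @param x,m,y per-subject predictor, mediator and outcome (equal length,
#'   at least 10).
#' @param covariates optional numeric matrix of additional covariates.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return A `mediation_result`: `a`, `b`, `c`, `c_prime`, `ab`, `boot_ab`,
#'   `ci95`, `p_boot`, `n_boot`, `seed`.
#' @export
mediate <- function(x, m, y, covariates = NULL, n_boot = 1000, seed = 1L) {
  n <- length(x)
  if (length(m) != n || length(y) != n || n < 10L)
    arg_error("x, m, y must have equal length >= 10")
  if (sd(x) == 0 || sd(m) == 0 || sd(y) == 0)
    model_error("x, m and y must be non-constant")
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  base <- cbind(intercept = rep(1, n), C)

  paths <- function(idx) {
    Xa <- cbind(base[idx, , drop = FALSE], x = x[idx])
    Xb <- cbind(Xa, m = m[idx])
    a <- ols_coefs(Xa, m[idx])[["x"]]
    cb <- ols_coefs(Xb, y[idx])
    cc <- ols_coefs(Xa, y[idx])[["x"]]
    c(a = a, b = cb[["m"]], c_prime = cb[["x"]], c = cc)
  }
  obs <- paths(seq_len(n))
  ab <- obs[["a"]] * obs[["b"]]
  boot_ab <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      p <- tryCatch(paths(idx), error = function(e) c(a = NA_real_, b = NA_real_,
                                                      c_prime = NA, c = NA))
      p[["a"]] * p[["b"]]
    }, numeric(1))
  })
  boot_ab <- boot_ab[!is.na(boot_ab)]
  B <- length(boot_ab)
  ci <- unname(quantile(boot_ab, c(0.025, 0.975), type = 6))
  p_boot <- min(1, 2 * min((1 + sum(boot_ab <= 0)) / (B + 1),
                           (1 + sum(boot_ab >= 0)) / (B + 1)))
  structure(list(a = obs[["a"]], b = obs[["b"]], c = obs[["c"]],
                 c_prime = obs[["c_prime"]], ab = ab, boot_ab = boot_ab,
                 ci95 = ci, p_boot = p_boot, n_boot = n_boot, seed = seed),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "Mediation: a = %.4g, b = %.4g, indirect ab = %.4g [%.4g, %.4g], c = %.4g, c' = %.4g, p_boot = %.4g (%d resamples)\n",
    x$a, x$b, x$ab, x$ci95[1], x$ci95[2], x$c, x$c_prime, x$p_boot, x$n_boot))
  invisible(x)
}
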