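# Synthetic cohort generator: covariates, aortic flow waveforms, dual-echo
# pCASL series, tissue masks and a vessel-probability atlas. Every generator
# is seeded and bit-reproducible; the injected ground truth is carried in a
# `ground_truth` object so downstream recovery can be tested.

#' Ground-truth parameters for the synthetic cohort
#'
#' Bundles the generative regression for PWV, the mediation chain
#' PWV -> CBF-fluctuation amplitude -> BOLD-fluctuation amplitude, and the
#' signal/noise amplitudes of the dual-echo series. Defaults target an
#' offspring-group mean PWV near 4.17 m/s and a parent-group mean near
#' 5.74 m/s, with a negative stiffness effect (`a_path < 0`, `b_path > 0`)
#' confined to `effect_roi`.
#'
#' @param intercept intercept of the PWV generative regression (m/s).
#' @param beta_age,beta_sbp,beta_height fixed-effect slopes of the PWV
#'   regression, in m/s per year, per mmHg and per cm respectively.
#' @param sex_sd SD of the per-sex random intercept (m/s), drawn once per
#'   sex level.
#' @param pwv_noise_sd residual SD of PWV about the regression (m/s).
#' @param a_path slope of CBF-fluctuation amplitude (gamma, fractional label
#'   modulation) on PWV, per m/s; negative for a stiffness-related decline.
#' @param b_path slope of BOLD-fluctuation amplitude (beta, fractional signal
#'   modulation) on gamma.
#' @param gamma0 CBF-fluctuation amplitude at the reference PWV `pwv_ref`.
#' @param pwv_ref reference PWV (m/s) about which `a_path` acts.
#' @param beta_base baseline BOLD-fluctuation amplitude added to
#'   `b_path * gamma` inside the effect ROI.
#' @param beta_out BOLD-fluctuation amplitude outside the effect ROI
#'   (PWV-independent).
#' @param gamma_noise_sd,beta_noise_sd per-subject SDs of gamma and beta about
#'   their structural values.
#' @param m0_gm,m0_wm,m0_csf baseline signal per tissue (a.u., first echo).
#' @param m0_echo2_scale multiplicative baseline scale at the BOLD echo.
#' @param delta_frac perfusion label amplitude delta as a fraction of the GM
#'   baseline at the perfusion-weighted echo.
#' @param delta_wm_scale WM label amplitude relative to GM.
#' @param delta_echo2_scale label amplitude at the BOLD echo relative to the
#'   perfusion echo (the long echo carries little label contrast).
#' @param noise_sd white-noise SD of the series (a.u.).
#' @param n_sinusoids number of random-phase sinusoids summed to build the
#'   band-limited BOLD and CBF fluctuation processes.
#' @param fluct_band frequency band (Hz) of those processes.
#' @param seed integer seed stored with the truth so any simulation drawn
#'   from it is exactly reproducible.
#' @return An object of class `ground_truth` (a named list).
#' @export
ground_truth <- function(intercept = 1.63,
                         beta_age = 0.053,
                         beta_sbp = 0.010,
                         beta_height = 0,
                         sex_sd = 0.10,
                         pwv_noise_sd = 0.45,
                         a_path = -0.15,
                         b_path = 0.05,
                         gamma0 = 0.50,
                         pwv_ref = 5.0,
                         beta_base = 0.002,
                         beta_out = 0.008,
                         gamma_noise_sd = 0.08,
                         beta_noise_sd = 1.5e-3,
                         m0_gm = 1000, m0_wm = 700, m0_csf = 300,
                         m0_echo2_scale = 0.8,
                         delta_frac = 0.015,
                         delta_wm_scale = 0.2,
                         delta_echo2_scale = 0.3,
                         noise_sd = 2.0,
                         n_sinusoids = 8L,
                         fluct_band = c(0.01, 0.05),
                         seed = 1L) {
  if (pwv_noise_sd < 0 || sex_sd < 0 || noise_sd < 0)
    arg_error("noise SDs must be non-negative")
  structure(as.list(environment()), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth seed=%d: pwv = %.3g + %.3g*age + %.3g*sbp + %.3g*height; a_path=%.3g b_path=%.3g>\n",
    x$seed, x$intercept, x$beta_age, x$beta_sbp, x$beta_height,
    x$a_path, x$b_path))
  invisible(x)
}

# group-level demographic targets (parent / offspring cohorts)
cohort_demographics <- function() {
  list(
    parent = list(age_range = c(43, 67), sbp = c(122.5, 13.2),
                  dbp = c(67.5, 8.3), height = c(169.7, 8.2),
                  hr = c(69.0, 11.3), p_female = 0.64 / 1.64),
    offspring = list(age_range = c(19, 39), sbp = c(119.8, 14.8),
                     dbp = c(65.8, 5.8), height = c(171.3, 10.9),
                     hr = c(69.3, 8.5), p_female = 0.70 / 1.70)
  )
}

#' Generate a synthetic covariate table
#'
#' Draws a two-generation cohort (parents aged 43-67, offspring aged 19-39)
#' with demographics matched to healthy-adult targets and a true PWV produced
#' by the generative regression
#' `pwv = intercept + beta_age*age + beta_sbp*sbp + beta_height*height +
#' sex offset + noise`, i.e. the fixed-effect structure the mixed model in
#' [fit_pwv_mixed_model()] estimates.
#'
#' @param n_parent,n_offspring subjects per group (each >= 2).
#' @param truth a [ground_truth()] object.
#' @param seed integer seed.
#' @return A `data.frame` with columns `subject_id`, `group`, `age`, `sex`,
#'   `height`, `sbp`, `dbp`, `pp` (`= sbp - dbp` row-wise), `heart_rate`,
#'   `pwv_true` and `cortical_thickness`.
#' @export
generate_covariates <- function(n_parent, n_offspring, truth = ground_truth(),
                                seed = truth$seed) {
  if (n_parent < 2 || n_offspring < 2)
    arg_error("need at least 2 subjects per group")
  demo <- cohort_demographics()
  with_seed(seed, {
    grp <- rep(c("parent", "offspring"), c(n_parent, n_offspring))
    n <- length(grp)
    age <- height <- sbp <- dbp <- hr <- numeric(n)
    sex <- character(n)
    for (g in c("parent", "offspring")) {
      i <- grp == g
      d <- demo[[g]]
      age[i] <- runif(sum(i), d$age_range[1], d$age_range[2])
      height[i] <- rnorm(sum(i), d$height[1], d$height[2])
      sbp[i] <- rnorm(sum(i), d$sbp[1], d$sbp[2])
      dbp[i] <- pmin(rnorm(sum(i), d$dbp[1], d$dbp[2]), sbp[i] - 10)
      hr[i] <- rnorm(sum(i), d$hr[1], d$hr[2])
      sex[i] <- ifelse(runif(sum(i)) < d$p_female, "F", "M")
    }
    sex_offset <- stats::setNames(rnorm(2, 0, truth$sex_sd), c("F", "M"))
    pwv <- truth$intercept + truth$beta_age * age + truth$beta_sbp * sbp +
      truth$beta_height * height + sex_offset[sex] +
      rnorm(n, 0, truth$pwv_noise_sd)
    pwv <- pmax(pwv, 0.5)  # physical floor; essentially never binds
    data.frame(
      subject_id = sprintf("sub-%03d", seq_len(n)),
      group = grp, age = age, sex = factor(sex, levels = c("F", "M")),
      height = height, sbp = sbp, dbp = dbp, pp = sbp - dbp,
      heart_rate = hr, pwv_true = as.numeric(pwv),
      cortical_thickness = rnorm(n, 2.5, 0.15),
      stringsAsFactors = FALSE
    )
  })
}

# raised-cosine systolic bump on a flat diastolic baseline, as a function of
# time in ms; `onset` is the start of the upstroke, `dur` the systolic width
flow_pulse <- function(t, onset, dur = 300, amplitude = 400, baseline = 0) {
  phase <- (t - onset) / dur
  f <- ifelse(phase >= 0 & phase <= 1,
              amplitude * 0.5 * (1 - cos(2 * pi * phase)), 0)
  baseline + f
}

#' Generate a pair of aortic flow waveforms with a known transit delay
#'
#' Produces arch and abdominal flow curves over one cardiac cycle. The
#' abdominal waveform is the arch waveform delayed by exactly
#' `path_length / pwv_true` seconds; the delay is applied analytically before
#' sampling, so it is not quantized to the sampling step. Independent white
#' noise is added to each sampled curve.
#'
#' @param pwv_true true pulse-wave velocity (m/s), > 0.
#' @param path_length aortic path length (m), default 0.356.
#' @param heart_rate beats/min, sets the cardiac period.
#' @param sampling_dt sampling step (ms), must be <= 25.
#' @param onset_ms arch upstroke onset within the cycle (ms).
#' @param systole_ms systolic bump duration (ms).
#' @param amplitude peak flow (mL/s).
#' @param noise_sd additive white-noise SD (mL/s).
#' @param seed integer seed.
#' @return A list with `arch` and `abdominal` waveforms (each a `data.frame`
#'   with `time_ms`, `flow`, and attributes), plus `true_delay_ms` and the
#'   generating parameters.
#' @export
generate_flow_waveforms <- function(pwv_true, path_length = 0.356,
                                    heart_rate = 69, sampling_dt = 5,
                                    onset_ms = 150, systole_ms = 300,
                                    amplitude = 400, noise_sd = 0,
                                    seed = 1L) {
  if (pwv_true <= 0) arg_error("pwv_true must be > 0")
  if (path_length <= 0) arg_error("path_length must be > 0")
  if (sampling_dt > 25) arg_error("sampling_dt must be <= 25 ms")
  period <- 60000 / heart_rate
  delay <- 1000 * path_length / pwv_true  # ms
  if (delay >= period)
    config_error("transit delay exceeds the cardiac period")
  if (onset_ms + delay + systole_ms > period)
    config_error("delayed systole does not fit within one cardiac cycle")
  t <- seq(0, period, by = sampling_dt)
  with_seed(seed, {
    arch <- flow_pulse(t, onset_ms, systole_ms, amplitude) +
      rnorm(length(t), 0, noise_sd)
    abd <- flow_pulse(t, onset_ms + delay, systole_ms, amplitude) +
      rnorm(length(t), 0, noise_sd)
    mk <- function(flow, label) {
      structure(data.frame(time_ms = t, flow = flow),
                plane_label = label, class = c("flow_waveform", "data.frame"))
    }
    list(arch = mk(arch, "arch"), abdominal = mk(abd, "abdominal"),
         true_delay_ms = delay, pwv_true = pwv_true,
         path_length = path_length, onset_ms = onset_ms,
         systole_ms = systole_ms, amplitude = amplitude,
         sampling_dt = sampling_dt)
  })
}

#' Generate tissue masks and a vessel-probability atlas
#'
#' Builds mutually exclusive GM/WM/CSF masks partitioning an ellipsoidal
#' brain, and a sparse tree-like vessel-probability volume in \[0, 1\] whose
#' nonzero fraction of brain voxels hits `vessel_fraction` (the tree is grown
#' voxel by voxel until the exact target count is reached). Vessel voxels are
#' split into disjoint arterial (inferior-anterior trees) and venous
#' (superior-posterior trees) submasks.
#'
#' @param dims integer grid size, each >= 4.
#' @param seed integer seed.
#' @param vessel_fraction target fraction of brain voxels with nonzero vessel
#'   probability.
#' @return A list with logical arrays `brain`, `gm`, `wm`, `csf`, `arterial`,
#'   `venous` and numeric array `vessel_prob`.
#' @export
generate_atlases <- function(dims, seed = 1L, vessel_fraction = 0.10) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 4L)) arg_error("dims must be 3 values >= 4")
  cx <- (dims + 1) / 2
  ax <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                    z = seq_len(dims[3]))
  r2 <- ((ax$x - cx[1]) / (dims[1] / 2))^2 + ((ax$y - cx[2]) / (dims[2] / 2))^2 +
    ((ax$z - cx[3]) / (dims[3] / 2))^2
  brain <- array(r2 <= 1, dim = dims)
  wm <- array(r2 <= 0.45, dim = dims)
  csf <- array(r2 <= 0.08, dim = dims)
  wm <- wm & !csf
  gm <- brain & !wm & !csf
  n_target <- max(2L, round(vessel_fraction * sum(brain)))

  with_seed(seed, {
    # grow branching random-walk trees inside the brain until the target
    # voxel count is reached; first half of the trees are "arterial"
    vox <- matrix(0L, nrow = 0, ncol = 3)
    kind <- integer(0)
    in_brain <- function(p) all(p >= 1) && all(p <= dims) &&
      brain[p[1], p[2], p[3]]
    n_trees <- 4L
    heads <- lapply(seq_len(n_trees), function(k) {
      repeat {
        p <- c(sample(dims[1], 1), sample(dims[2], 1),
               if (k <= n_trees / 2) sample(max(1, dims[3] %/% 3), 1)
               else dims[3] - sample(max(1, dims[3] %/% 3), 1) + 1)
        if (in_brain(p)) return(p)
      }
    })
    steps <- rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0), c(-1, 0, 0),
                   c(0, 1, 0), c(0, -1, 0))
    seen <- array(FALSE, dim = dims)
    k <- 1L
    while (nrow(vox) < n_target) {
      p <- heads[[k]]
      if (!seen[p[1], p[2], p[3]]) {
        seen[p[1], p[2], p[3]] <- TRUE
        vox <- rbind(vox, p)
        kind <- c(kind, if (k <= n_trees / 2) 1L else 2L)
      }
      # biased walk: arterial trees drift up, venous drift down
      drift <- if (k <= n_trees / 2) c(0.4, 0.1) else c(0.1, 0.4)
      pr <- c(drift[1], drift[2], rep((1 - sum(drift)) / 4, 4))
      cand <- p + steps[sample.int(6, 1, prob = pr), ]
      if (in_brain(cand)) heads[[k]] <- cand
      if (runif(1) < 0.05) {  # occasional branch: respawn this head nearby
        j <- sample(nrow(vox), 1)
        heads[[k]] <- vox[j, ]
      }
      k <- k %% n_trees + 1L
    }
    prob <- array(0, dim = dims)
    arterial <- array(FALSE, dim = dims)
    venous <- array(FALSE, dim = dims)
    for (i in seq_len(nrow(vox))) {
      p <- vox[i, ]
      prob[p[1], p[2], p[3]] <- runif(1, 0.2, 1)
      if (kind[i] == 1L) arterial[p[1], p[2], p[3]] <- TRUE
      else venous[p[1], p[2], p[3]] <- TRUE
    }
    list(brain = brain, gm = gm, wm = wm, csf = csf,
         vessel_prob = prob, arterial = arterial, venous = venous)
  })
}

#' Default effect ROI: a compact gray-matter patch
#'
#' The region where the generator injects the PWV-dependent fluctuation
#' amplitudes: the `n_vox` GM voxels nearest an anchor point placed at 80% of
#' the lateral radius, giving a compact cortical patch for the cluster-based
#' inference to find.
#'
#' @param atlas output of [generate_atlases()].
#' @param n_vox patch size in voxels (default 48; capped at the GM size).
#' @return Logical 3-D array.
#' @export
default_effect_roi <- function(atlas, n_vox = 48L) {
  dims <- dim(atlas$gm)
  cx <- (dims + 1) / 2
  anchor <- c(cx[1] + 0.8 * dims[1] / 2, cx[2], cx[3])
  gm_idx <- which(atlas$gm, arr.ind = TRUE)
  d2 <- colSums((t(gm_idx) - anchor)^2)
  pick <- order(d2)[seq_len(min(n_vox, nrow(gm_idx)))]
  roi <- array(FALSE, dim = dims)
  roi[gm_idx[pick, , drop = FALSE]] <- TRUE
  roi
}

# band-limited unit-variance fluctuation process: sum of random-phase
# sinusoids with frequencies drawn in `band`
band_limited_process <- function(n_frames, tr, band, n_sin) {
  tt <- (seq_len(n_frames) - 1) * tr
  f <- runif(n_sin, band[1], band[2])
  ph <- runif(n_sin, 0, 2 * pi)
  x <- rowSums(sapply(seq_len(n_sin), function(j) sin(2 * pi * f[j] * tt + ph[j])))
  x <- x - mean(x)
  s <- sd(x)
  if (s > 0) x / s else x
}

# per-subject realized fluctuation amplitudes on the mediation chain
subject_amplitudes <- function(pwv, truth) {
  gamma <- truth$gamma0 + truth$a_path * (pwv - truth$pwv_ref) +
    rnorm(1, 0, truth$gamma_noise_sd)
  gamma <- min(max(gamma, 0), 1.5)
  beta <- truth$beta_base + truth$b_path * gamma + rnorm(1, 0, truth$beta_noise_sd)
  beta <- max(beta, 0)
  list(gamma = gamma, beta = beta)
}

#' Generate a dual-echo pCASL series for one subject
#'
#' Per voxel v, echo e and frame i (0-based, frame 0 = control) the signal is
#' \deqn{s(v,e,i) = M_0(v,e)[1 + \beta(v) b_i] + (-1)^i \frac{\delta(v,e)}{2}
#' [1 + \gamma(v) c_i] + \varepsilon}
#' where `b` is a band-limited (0.01-0.08 Hz) BOLD-like process, `c` an
#' independent CBF-fluctuation process, `delta` the perfusion label amplitude
#' (larger at the short echo, zero in CSF) and `epsilon` white Gaussian noise.
#' Inside `effect_roi` the amplitudes beta and gamma follow the mediation
#' chain of the supplied [ground_truth()]; outside they are PWV-independent.
#'
#' @param cov_row one row of a [generate_covariates()] table (needs
#'   `pwv_true`).
#' @param truth a [ground_truth()] object.
#' @param dims 3-D grid size, each >= 4.
#' @param n_frames even frame count >= 20 (interleaved control/tag).
#' @param seed integer seed.
#' @param atlas optional [generate_atlases()] output on the same grid; by
#'   default one is generated deterministically from `truth$seed` so all
#'   subjects share masks (data are simulated already co-registered).
#' @param effect_roi optional logical array; default [default_effect_roi()].
#' @param tr repetition time (s).
#' @return An object of class `dual_echo_series`: `echo1`/`echo2` 4-D arrays,
#'   `frame_role` ("control"/"tag"), acquisition parameters (`tr`, `te_cbf`,
#'   `te_bold`, `tau`, `pld`), `masks`, and a `truth_subject` list holding the
#'   realized `beta`, `gamma`, processes `b`, `c` and `delta` volumes.
#' @export
generate_pcasl_series <- function(cov_row, truth = ground_truth(),
                                  dims = c(12, 12, 6), n_frames = 100,
                                  seed = 1L, atlas = NULL, effect_roi = NULL,
                                  tr = 4) {
  n_frames <- as.integer(n_frames)
  if (n_frames %% 2L != 0L) arg_error("n_frames must be even")
  if (n_frames < 20L) arg_error("n_frames must be >= 20")
  dims <- as.integer(dims)
  if (any(dims < 4L)) arg_error("each grid dimension must be >= 4")
  if (is.null(atlas)) atlas <- generate_atlases(dims, seed = truth$seed)
  if (!all(dim(atlas$gm) == dims)) arg_error("atlas dims must match series dims")
  if (is.null(effect_roi)) effect_roi <- default_effect_roi(atlas)

  pwv <- cov_row$pwv_true
  with_seed(seed, {
    amp <- subject_amplitudes(pwv, truth)
    b <- band_limited_process(n_frames, tr, truth$fluct_band, truth$n_sinusoids)
    cproc <- band_limited_process(n_frames, tr, truth$fluct_band,
                                  truth$n_sinusoids)
    m0 <- array(0, dim = dims)
    m0[atlas$gm] <- truth$m0_gm
    m0[atlas$wm] <- truth$m0_wm
    m0[atlas$csf] <- truth$m0_csf
    delta <- array(0, dim = dims)
    delta[atlas$gm] <- truth$delta_frac * truth$m0_gm
    delta[atlas$wm] <- truth$delta_frac * truth$m0_gm * truth$delta_wm_scale
    # fluctuation amplitudes live in GM only: the WM/CSF noise ROI then
    # carries baseline + white noise, as the aCompCor model assumes
    beta_vol <- array(0, dim = dims)
    beta_vol[atlas$gm] <- truth$beta_out
    beta_vol[effect_roi] <- amp$beta
    gamma_vol <- array(0, dim = dims)
    gamma_vol[atlas$gm] <- truth$gamma0
    gamma_vol[effect_roi] <- amp$gamma

    sgn <- rep_len(c(1, -1), n_frames)  # frame 0 (R index 1) is control
    nv <- prod(dims)
    make_echo <- function(m0e, deltae) {
      m0v <- as.vector(m0e); dv <- as.vector(deltae)
      bv <- as.vector(beta_vol); gv <- as.vector(gamma_vol)
      sig <- matrix(0, nrow = nv, ncol = n_frames)
      for (i in seq_len(n_frames)) {
        sig[, i] <- m0v * (1 + bv * b[i]) +
          sgn[i] * (dv / 2) * (1 + gv * cproc[i])
      }
      sig <- sig + matrix(rnorm(nv * n_frames, 0, truth$noise_sd),
                          nrow = nv)
      array(sig, dim = c(dims, n_frames))
    }
    echo1 <- make_echo(m0, delta)
    echo2 <- make_echo(m0 * truth$m0_echo2_scale, delta * truth$delta_echo2_scale)
    structure(list(
      echo1 = echo1, echo2 = echo2,
      frame_role = rep_len(c("control", "tag"), n_frames),
      tr = tr, te_cbf = 10, te_bold = 30.7, tau = 1.5, pld = 1.0,
      masks = atlas, effect_roi = effect_roi,
      truth_subject = list(beta = amp$beta, gamma = amp$gamma, b = b,
                           c = cproc, delta = delta, m0 = m0,
                           pwv_true = pwv)
    ), class = "dual_echo_series")
  })
}

#' @export
print.dual_echo_series <- function(x, ...) {
  d <- dim(x$echo1)
  cat(sprintf("<dual_echo_series %dx%dx%d, %d frames, TR=%gs, roles %s...>\n",
              d[1], d[2], d[3], d[4], x$tr,
              paste(substr(x$frame_role[1:4], 1, 1), collapse = "")))
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' Convenience wrapper drawing covariates, per-subject waveform pairs and
#' dual-echo series with one shared atlas, plus the ground truth, under a
#' single master seed.
#'
#' @param n_parent,n_offspring group sizes.
#' @param truth a [ground_truth()] object.
#' @param dims grid size.
#' @param n_frames frames per series.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param path_length aortic path length (m).
#' @param waveform_noise_sd waveform noise SD (mL/s).
#' @return A list with `covariates`, `truth`, `atlas`, `effect_roi`,
#'   `waveforms` (per subject) and `series` (per subject).
#' @export
generate_cohort <- function(n_parent = 20, n_offspring = 20,
                            truth = ground_truth(), dims = c(12, 12, 6),
                            n_frames = 100, seed = truth$seed,
                            path_length = 0.356, waveform_noise_sd = 5) {
  seeds <- derive_seeds(seed, 2L * (n_parent + n_offspring) + 2L)
  cov <- generate_covariates(n_parent, n_offspring, truth, seed = seeds[1])
  atlas <- generate_atlases(dims, seed = seeds[2])
  roi <- default_effect_roi(atlas)
  n <- nrow(cov)
  waveforms <- vector("list", n)
  series <- vector("list", n)
  for (s in seq_len(n)) {
    waveforms[[s]] <- generate_flow_waveforms(
      cov$pwv_true[s], path_length = path_length,
      heart_rate = cov$heart_rate[s], noise_sd = waveform_noise_sd,
      seed = seeds[2 + s])
    series[[s]] <- generate_pcasl_series(
      cov[s, ], truth, dims = dims, n_frames = n_frames,
      seed = seeds[2 + n + s], atlas = atlas, effect_roi = roi)
  }
  names(waveforms) <- names(series) <- cov$subject_id
  list(covariates = cov, truth = truth, atlas = atlas, effect_roi = roi,
       waveforms = waveforms, series = series)
}
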