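# BOLD / CBF signal separation for interleaved dual-echo pCASL: frame
# discard, aCompCor-style physiological denoising, surround averaging and
# subtraction, first-echo demodulation, zero-phase band-pass filtering and
# Gaussian spatial smoothing.

#' Discard initial frames of a dual-echo series
#'
#' Removes the first `n` frames (to reach MR steady state) from both echoes,
#' keeping the control/tag alternation parity intact.
#'
#' @param s a `dual_echo_series`.
#' @param n even number of frames to drop (default 4), `<` frame count.
#' @return The trimmed `dual_echo_series`.
#' @export
discard_initial_frames <- function(s, n = 4) {
  n <- as.integer(n)
  if (n %% 2L != 0L) arg_error("n must be even to preserve alternation parity")
  nt <- dim(s$echo1)[4]
  if (n >= nt) arg_error("n must be smaller than the frame count")
  if (n == 0L) return(s)
  keep <- (n + 1L):nt
  s$echo1 <- s$echo1[, , , keep, drop = FALSE]
  s$echo2 <- s$echo2[, , , keep, drop = FALSE]
  s$frame_role <- s$frame_role[keep]
  s$provenance <- c(s$provenance, sprintf("discard_initial_frames(n=%d)", n))
  s
}

# signs: +1 for control frames, -1 for tag frames
role_signs <- function(frame_role) {
  if (!all(frame_role %in% c("control", "tag")))
    arg_error("frame_role must be 'control'/'tag'")
  ifelse(frame_role == "control", 1, -1)
}

# project the top-k principal components of the noise-ROI signal (plus the
# intercept) out of every voxel time series of one stream; X is time x voxel.
# Returns the residual with the component time courses attached.
project_out_components <- function(X, noise_cols, k, components = NULL) {
  Tn <- nrow(X)
  if (is.null(components)) {
    components <- matrix(numeric(0), nrow = Tn, ncol = 0)
    if (k > 0) {
      Xc <- sweep(X, 2, colMeans(X))
      N <- Xc[, noise_cols, drop = FALSE]
      sv <- svd(N, nu = min(k, Tn), nv = 0)
      components <- sv$u[, seq_len(min(k, ncol(sv$u))), drop = FALSE]
    }
  }
  regs <- cbind(1, components)
  qr_r <- qr(regs)
  structure(X - regs %*% qr.coef(qr_r, X), components = components)
}

#' aCompCor-style physiological denoising
#'
#' For the tag frames and the control frames of each echo independently:
#' extracts the voxel-by-time matrix within the WM+CSF noise ROI, de-means,
#' takes the top-`k` principal components of the time dimension, and regresses
#' them (plus an intercept) out of every brain voxel's stream; the streams are
#' then re-interleaved in the original frame order. With `k = 0` only the
#' per-stream temporal mean is removed.
#'
#' @param s a `dual_echo_series`.
#' @param k number of noise components (default 4), `<` frames per stream.
#' @param noise_mask logical array; default `WM | CSF` from the series masks.
#' @param components optional precomputed component list (as stored in
#'   `$compcor_components` of a previous result) to project out instead of
#'   re-estimating; with fixed components the operation is a projection and
#'   hence idempotent.
#' @return The denoised `dual_echo_series` (stream means removed), with the
#'   component time courses in `$compcor_components`.
#' @export
compcor_denoise <- function(s, k = 4, noise_mask = NULL, components = NULL) {
  if (is.null(noise_mask)) noise_mask <- s$masks$wm | s$masks$csf
  if (!any(noise_mask)) arg_error("noise mask is empty")
  sgn <- role_signs(s$frame_role)
  dims <- dim(s$echo1)[1:3]
  noise_idx <- which(as.vector(noise_mask))
  used <- list()
  for (echo in c("echo1", "echo2")) {
    X <- series_to_matrix(s[[echo]])  # time x all-voxels
    for (stream_sign in c(1, -1)) {
      rows <- which(sgn == stream_sign)
      if (k >= length(rows))
        arg_error("k must be smaller than the frames per stream")
      key <- paste0(echo, if (stream_sign > 0) "_control" else "_tag")
      res <- project_out_components(X[rows, , drop = FALSE], noise_idx, k,
                                    components = components[[key]])
      X[rows, ] <- res
      used[[key]] <- attr(res, "components")
    }
    s[[echo]] <- matrix_to_series(X, dims)
  }
  s$compcor_components <- used
  s$provenance <- c(s$provenance, sprintf("compcor_denoise(k=%d)", k))
  s
}

# apply a 3-point stencil along the 4th dimension; returns interior frames
stencil_interior <- function(arr, fun) {
  d <- dim(arr)
  if (d[4] < 3L) arg_error("need at least 3 frames")
  X <- series_to_matrix(arr)              # time x voxel
  i <- 2:(d[4] - 1L)
  out <- fun(X, i)
  array(t(out), dim = c(d[1:3], length(i)))
}

#' Surround averaging (BOLD extraction)
#'
#' For interior frame i returns `s_i/2 + (s_{i-1} + s_{i+1})/4`, which exactly
#' cancels any purely alternating (tag/control) component while preserving
#' slowly varying (locally linear) signal. Endpoint frames are dropped.
#'
#' @param echo2 4-D array with alternating control/tag frames (typically the
#'   long-echo, BOLD-weighted data).
#' @return 4-D array with two fewer frames.
#' @export
surround_average <- function(echo2) {
  stencil_interior(echo2, function(X, i)
    X[i, , drop = FALSE] / 2 +
      (X[i - 1L, , drop = FALSE] + X[i + 1L, , drop = FALSE]) / 4)
}

#' Surround subtraction (perfusion-weighted extraction)
#'
#' For interior frame i returns
#' `sigma_i * (s_i - (s_{i-1} + s_{i+1})/2)` with `sigma_i = +1` for control
#' and `-1` for tag frames, so the output approximates `control - tag` (> 0
#' for positive perfusion) while cancelling locally linear drift.
#'
#' @param echo1 4-D array with alternating frames (short-echo data).
#' @param frame_role character vector of `"control"`/`"tag"` per frame.
#' @return 4-D perfusion-weighted (delta-M) array with two fewer frames.
#' @export
surround_subtract <- function(echo1, frame_role) {
  sgn <- role_signs(frame_role)
  stencil_interior(echo1, function(X, i)
    sgn[i] * (X[i, , drop = FALSE] -
                (X[i - 1L, , drop = FALSE] + X[i + 1L, , drop = FALSE]) / 2))
}

# zero-phase order-4 Butterworth applied along columns of time x voxel
# matrix; coefficients from signal::butter, forward-backward pass compiled
butter_filtfilt <- function(X, W, type) {
  bf <- signal::butter(4, W, type = type)
  filtfilt_cols_cpp(X, as.numeric(bf$b), as.numeric(bf$a))
}

#' Zero-phase band-pass filter
#'
#' De-means each voxel's series, then applies cascaded order-4 Butterworth
#' high-pass (`lo`) and low-pass (`hi`) filters, each forward-backward
#' (zero phase). `lo <= 0` skips the high-pass (the explicit de-mean still
#' removes DC).
#'
#' @param series 4-D array (or time-by-voxel matrix).
#' @param tr sampling interval (s) of the frame dimension.
#' @param lo,hi pass-band edges (Hz); requires `lo < hi < 1/(2 tr)`.
#' @return Filtered array of the same shape.
#' @export
bandpass <- function(series, tr, lo = 0.001, hi = 0.08) {
  nyq <- 1 / (2 * tr)
  if (hi >= nyq) config_error(sprintf("hi (%g Hz) must be below Nyquist (%g Hz)", hi, nyq))
  if (lo >= hi) config_error("lo must be below hi")
  is_mat <- is.matrix(series)
  X <- if (is_mat) series else series_to_matrix(series)
  X <- sweep(X, 2, colMeans(X))
  if (lo > 0) X <- butter_filtfilt(X, lo / nyq, "high")
  X <- butter_filtfilt(X, hi / nyq, "low")
  if (is_mat) X else matrix_to_series(X, dim(series)[1:3])
}

#' Demodulate the first echo into a CBF-fluctuation series
#'
#' Isolates the slowly varying envelope of the alternating perfusion
#' component: each voxel's stream is de-meaned and high-pass filtered above
#' `hp_cutoff` (default `1/(4 tr)`, removing BOLD-band content), multiplied by
#' the tag/control carrier `sigma_i` (+1 control, -1 tag; the carrier sits at
#' the Nyquist frequency), and low-pass filtered below `lp_cutoff`. The output
#' approximates `delta/2 * (1 + gamma c_i)`; endpoints are not trimmed.
#'
#' @param echo1 4-D short-echo array.
#' @param tr frame interval (s).
#' @param frame_role `"control"`/`"tag"` labels per frame.
#' @param hp_cutoff high-pass cutoff (Hz); default `1/(4 tr)`.
#' @param lp_cutoff low-pass cutoff (Hz), default 0.08; must be below Nyquist.
#' @return 4-D CBF-fluctuation array, same shape as the input. The constant
#'   envelope level `delta/2` is carried by the Nyquist carrier itself, passes
#'   the high-pass, and therefore survives into the output.
#' @export
demodulate_first_echo <- function(echo1, tr, frame_role,
                                  hp_cutoff = 1 / (4 * tr), lp_cutoff = 0.08) {
  d <- dim(echo1)
  if (d[4] < 8L) arg_error("need at least 8 frames")
  nyq <- 1 / (2 * tr)
  if (hp_cutoff >= nyq || lp_cutoff >= nyq)
    config_error("filter cutoffs must be below the Nyquist frequency")
  sgn <- role_signs(frame_role)
  X <- series_to_matrix(echo1)
  mu <- colMeans(X)
  X <- sweep(X, 2, mu)
  X <- butter_filtfilt(X, hp_cutoff / nyq, "high")
  X <- X * sgn                       # demodulate the Nyquist carrier
  X <- butter_filtfilt(X, lp_cutoff / nyq, "low")
  matrix_to_series(X, d[1:3])
}

# dense 1-D Gaussian convolution operator with reflection at the borders;
# rows sum to 1 so constants are preserved
gauss_operator <- function(n, sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-0.5 * ((-r):r / sigma_vox)^2)
  k <- k / sum(k)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- i + ((-r):r)
    # reflect indices (without duplicating the edge sample)
    src <- ifelse(src < 1L, 2L - src, src)
    src <- ifelse(src > n, 2L * n - src, src)
    src <- pmin(pmax(src, 1L), n)
    for (j in seq_along(src)) A[i, src[j]] <- A[i, src[j]] + k[j]
  }
  A
}

# 1-D Gaussian convolution along one spatial axis of a 3-D or 4-D array,
# as a matrix product over all remaining dimensions at once
gauss_convolve_axis <- function(vol, sigma_vox, axis) {
  if (sigma_vox <= 0) return(vol)
  d <- dim(vol)
  A <- gauss_operator(d[axis], sigma_vox)
  perm <- c(axis, setdiff(seq_along(d), axis))
  v <- aperm(vol, perm)
  v[] <- A %*% matrix(v, nrow = d[axis])
  aperm(v, order(perm))
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 sqrt(2 log 2))` per
#' axis, in millimetres, using reflection padding (constants are preserved;
#' mass of interior-supported images is conserved). `fwhm = 0` is the
#' identity. 4-D inputs are smoothed frame by frame.
#'
#' @param vol 3-D or 4-D array.
#' @param fwhm full-width at half-maximum (mm), default 6.
#' @param voxel_size voxel edge lengths (mm), length 1 or 3.
#' @return Smoothed array, same shape.
#' @export
spatial_smooth <- function(vol, fwhm = 6, voxel_size = c(3.44, 3.44, 6)) {
  if (fwhm < 0) arg_error("fwhm must be >= 0")
  if (fwhm == 0) return(vol)
  voxel_size <- rep_len(voxel_size, 3L)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  sigma_vox <- sigma_mm / voxel_size
  for (ax in 1:3) vol <- gauss_convolve_axis(vol, sigma_vox[ax], ax)
  vol
}

#' Separate a dual-echo series into denoised BOLD and CBF series
#'
#' Applies the full separation pipeline in order: frame discard, aCompCor
#' denoising, surround averaging of the second echo (BOLD) and band-pass
#' filtering; demodulation of the first echo (CBF fluctuations); surround
#' subtraction of the first echo (perfusion-weighted delta-M, computed from
#' the non-denoised series so absolute label amplitude is preserved for
#' quantification).
#'
#' @param s a `dual_echo_series`.
#' @param discard frames to drop initially (even).
#' @param compcor_k noise components per stream.
#' @param band pass-band (Hz) for the BOLD series.
#' @param fwhm spatial smoothing FWHM (mm); 0 disables.
#' @param voxel_size voxel size (mm).
#' @return A `denoised_series` list: `bold` (band-passed, frame count =
#'   interior frames), `cbf_signal` (demodulated first echo), `delta_m`
#'   (surround-subtracted first echo), `frame_role_interior`, `tr`, `band`,
#'   `masks`, `provenance`.
#' @export
separate_signals <- function(s, discard = 4, compcor_k = 4,
                             band = c(0.001, 0.08), fwhm = 0,
                             voxel_size = c(3.44, 3.44, 6)) {
  s <- discard_initial_frames(s, discard)
  raw_echo1 <- s$echo1
  s <- compcor_denoise(s, k = compcor_k)
  if (fwhm > 0) {
    s$echo1 <- spatial_smooth(s$echo1, fwhm, voxel_size)
    s$echo2 <- spatial_smooth(s$echo2, fwhm, voxel_size)
    raw_echo1 <- spatial_smooth(raw_echo1, fwhm, voxel_size)
  }
  bold <- surround_average(s$echo2)
  bold <- bandpass(bold, s$tr, band[1], band[2])
  cbf <- demodulate_first_echo(s$echo1, s$tr, s$frame_role)
  dm <- surround_subtract(raw_echo1, s$frame_role)
  interior <- 2:(length(s$frame_role) - 1L)
  structure(list(
    bold = bold, cbf_signal = cbf, delta_m = dm,
    raw_echo1 = raw_echo1,
    frame_role = s$frame_role, frame_role_interior = s$frame_role[interior],
    tr = s$tr, band = band, masks = s$masks, effect_roi = s$effect_roi,
    provenance = c(s$provenance,
                   sprintf("surround_average+bandpass(%g,%g)", band[1], band[2]),
                   "demodulate_first_echo", "surround_subtract")
  ), class = "denoised_series")
}
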