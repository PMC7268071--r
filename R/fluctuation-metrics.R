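# Per-subject fluctuation-amplitude maps (temporal variance with robust
# outlier rejection), ROI summaries, outlier-volume rejection for the
# perfusion series, and quantitative CBF via the single-compartment general
# kinetic model.

#' Temporal variance map with robust outlier rejection
#'
#' Per voxel inside the mask, time points with
#' `|s - median(s)| > outlier_k * 1.4826 * MAD` are discarded and the unbiased
#' sample variance of the remainder is returned. `outlier_k = Inf` disables
#' rejection. Voxels outside the mask are 0; voxels with fewer than 3
#' surviving points are set to `NaN` and flagged.
#'
#' @param series 4-D array with >= 10 frames.
#' @param mask logical 3-D array.
#' @param outlier_k rejection threshold in (scaled) MAD multiples, default 5.
#' @param kind `stat_map` kind, default `"bold_var"`.
#' @return A `stat_map` with attribute `n_flagged` (voxels set to missing).
#' @export
variance_map <- function(series, mask, outlier_k = 5, kind = "bold_var") {
  d <- dim(series)
  if (d[4] < 10L) arg_error("need at least 10 frames")
  if (!all(d[1:3] == dim(mask))) arg_error("mask dims must match series")
  X <- series_to_matrix(series, mask)   # time x masked-voxel
  vals <- apply(X, 2, function(s) {
    if (is.finite(outlier_k)) {
      m <- median(s)
      thr <- outlier_k * mad(s)         # mad() includes the 1.4826 constant
      s <- s[abs(s - m) <= thr]         # thr = 0 keeps the constant majority
    }
    if (length(s) < 3L) NaN else var(s)
  })
  out <- stat_map(map_values_to_volume(vals, d[1:3], mask), kind,
                  units = "signal^2", mask = mask)
  attr(out, "n_flagged") <- sum(is.nan(vals))
  out
}

#' Mean of a statistic map over an ROI
#'
#' @param map a `stat_map` (or 3-D array).
#' @param roi logical array on the same grid.
#' @return Mean over non-missing voxels of the ROI.
#' @export
roi_mean <- function(map, roi) {
  v <- if (inherits(map, "stat_map")) map$values else map
  if (!all(dim(v) == dim(roi))) arg_error("roi dims must match map")
  x <- v[roi]
  x <- x[!is.na(x)]
  if (length(x) == 0L) arg_error("ROI does not intersect the map")
  mean(x)
}

#' Greedy outlier-volume rejection for the perfusion series
#'
#' SNR-driven simplification of adaptive outlier-volume removal: frames whose
#' exclusion most increases the temporal SNR (mean/SD) of the GM-mean delta-M
#' series are removed greedily, stopping when the relative SNR gain drops
#' below `min_gain` or `max_frac` of frames have been removed. In
#' `mode = "default"` the series is returned unchanged.
#'
#' @param dm 4-D perfusion-weighted series with >= 10 frames.
#' @param mask GM mask.
#' @param mode `"default"` (no removal) or `"optimized"`.
#' @param min_gain minimal relative SNR gain to accept a removal.
#' @param max_frac maximal fraction of frames to remove.
#' @return List with `series` (reduced 4-D array), `kept` (frame indices) and
#'   `snr` (before/after).
#' @export
reject_outlier_volumes <- function(dm, mask, mode = c("default", "optimized"),
                                   min_gain = 0.01, max_frac = 0.2) {
  mode <- match.arg(mode)
  nt <- dim(dm)[4]
  if (nt < 10L) arg_error("need at least 10 frames")
  ts <- rowMeans(series_to_matrix(dm, mask))  # per-frame GM mean
  snr_of <- function(idx) {
    s <- sd(ts[idx])
    if (s == 0) Inf else mean(ts[idx]) / s
  }
  kept <- seq_len(nt)
  snr0 <- snr_of(kept)
  if (mode == "default")
    return(list(series = dm, kept = kept, snr = c(before = snr0, after = snr0)))
  snr <- snr0
  max_remove <- floor(max_frac * nt)
  while (length(kept) > nt - max_remove && is.finite(snr)) {
    cand <- vapply(seq_along(kept),
                   function(j) snr_of(kept[-j]), numeric(1))
    j <- which.max(cand)
    if (cand[j] <= snr * (1 + min_gain) && is.finite(cand[j])) break
    if (cand[j] <= snr) break
    kept <- kept[-j]
    snr <- cand[j]
  }
  list(series = dm[, , , kept, drop = FALSE], kept = kept,
       snr = c(before = snr0, after = snr))
}

#' General-kinetic-model parameters
#'
#' Single-compartment pCASL quantification constants. Defaults follow common
#' quantification practice; labeling duration and post-label delay default to
#' the acquisition values (1.5 s / 1.0 s).
#'
#' @param tau labeling duration (s).
#' @param pld post-labeling delay (s).
#' @param t1b longitudinal relaxation time of blood (s).
#' @param alpha labeling efficiency, in (0, 1].
#' @param lambda blood-brain partition coefficient (mL/g).
#' @return A `gkm_params` list.
#' @export
gkm_params <- function(tau = 1.5, pld = 1.0, t1b = 1.65, alpha = 0.85,
                       lambda = 0.9) {
  if (alpha <= 0 || alpha > 1) arg_error("alpha must be in (0, 1]")
  if (tau <= 0 || pld <= 0 || t1b <= 0) arg_error("tau, pld, t1b must be > 0")
  structure(list(tau = tau, pld = pld, t1b = t1b, alpha = alpha,
                 lambda = lambda), class = "gkm_params")
}

#' Quantitative CBF from mean label difference
#'
#' Single-compartment solution of the general kinetic model:
#' \deqn{f = \frac{6000\,\lambda\,\Delta M\, e^{PLD/T_{1b}}}
#'       {2\,\alpha\,T_{1b}\,M_0\,(1 - e^{-\tau/T_{1b}})}}
#' in mL/100g/min. Voxels with `M0 <= 0` are set to missing.
#'
#' @param mean_dm 3-D mean delta-M map.
#' @param m0 3-D equilibrium-magnetization map.
#' @param params a [gkm_params()] object.
#' @param mask optional logical array restricting the output.
#' @return A `stat_map` of kind `"cbf_quant"`.
#' @export
quantify_cbf <- function(mean_dm, m0, params = gkm_params(), mask = NULL) {
  p <- params
  denom <- 2 * p$alpha * p$t1b * m0 * (1 - exp(-p$tau / p$t1b))
  f <- 6000 * p$lambda * mean_dm * exp(p$pld / p$t1b) / denom
  f[m0 <= 0] <- NaN
  if (!is.null(mask)) f[!mask] <- 0
  stat_map(f, "cbf_quant", units = "mL/100g/min", mask = mask)
}

# inverse of quantify_cbf, used by simulations and round-trip tests
delta_m_from_cbf <- function(f, m0, params = gkm_params()) {
  p <- params
  f * 2 * p$alpha * p$t1b * m0 * (1 - exp(-p$tau / p$t1b)) /
    (6000 * p$lambda * exp(p$pld / p$t1b))
}

#' CBF-fluctuation variance map (gray matter only)
#'
#' [variance_map()] applied to the demodulated CBF-fluctuation series,
#' restricted to GM (white-matter perfusion is too unreliable to analyze).
#'
#' @param cbf_signal 4-D demodulated series.
#' @param gm_mask gray-matter mask.
#' @param outlier_k MAD-multiple rejection threshold.
#' @return A `stat_map` of kind `"cbf_var"`, zero outside GM.
#' @export
cbf_variance_map <- function(cbf_signal, gm_mask, outlier_k = 5) {
  variance_map(cbf_signal, gm_mask, outlier_k = outlier_k, kind = "cbf_var")
}
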