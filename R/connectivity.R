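# Intrinsic connectivity contrast: per-voxel sum of Fisher-z-transformed
# Pearson correlations with every other brain voxel.

#' Intrinsic connectivity contrast map
#'
#' For each masked voxel v,
#' `IC(v) = sum over u != v of atanh(clip(r_uv))`, with Pearson correlations
#' on the (band-passed, denoised) BOLD series and `|r|` clipped at `clip`
#' before the Fisher transform so degenerate series stay finite. Computation
#' proceeds block-wise over columns; the result is independent of the chunk
#' size. Zero-variance voxels are excluded from the mask with a warning.
#'
#' @param bold 4-D array with >= 4 frames.
#' @param mask logical 3-D array with >= 2 voxels.
#' @param clip maximum `|r|` before `atanh`, default 0.9999.
#' @param chunk number of voxels per correlation block (default: all).
#' @return An `icc_map` object: `values` (3-D summed-z map, 0 outside mask),
#'   `n_voxels`, `clip`, `mask`.
#' @export
icc_map <- function(bold, mask, clip = 0.9999, chunk = NULL) {
  d <- dim(bold)
  if (d[4] < 4L) arg_error("need at least 4 frames")
  if (!all(d[1:3] == dim(mask))) arg_error("mask dims must match series")
  X <- series_to_matrix(bold, mask)     # time x voxel
  v_ok <- apply(X, 2, sd) > 0
  if (!all(v_ok)) {
    warning(sprintf("excluding %d zero-variance voxel(s) from the ICC mask",
                    sum(!v_ok)))
    mask_vec <- which(as.vector(mask))[v_ok]
    mask <- array(FALSE, dim = d[1:3])
    mask[mask_vec] <- TRUE
    X <- X[, v_ok, drop = FALSE]
  }
  V <- ncol(X)
  if (V < 2L) arg_error("need at least 2 masked voxels with variance")
  if (is.null(chunk)) chunk <- V
  chunk <- max(1L, as.integer(chunk))
  Xs <- scale(X)                        # columns: mean 0, sd 1
  denom <- nrow(X) - 1
  self_z <- atanh(clip)                 # the clipped self-correlation term
  ic <- numeric(V)
  for (start in seq(1L, V, by = chunk)) {
    cols <- start:min(start + chunk - 1L, V)
    r <- crossprod(Xs, Xs[, cols, drop = FALSE]) / denom
    r <- pmin(pmax(r, -clip), clip)
    ic[cols] <- colSums(atanh(r)) - self_z
  }
  structure(list(values = map_values_to_volume(ic, d[1:3], mask),
                 n_voxels = V, clip = clip, mask = mask),
            class = "icc_map")
}

#' @export
print.icc_map <- function(x, ...) {
  cat(sprintf("<icc_map %d voxels, clip=%g, range [%.3g, %.3g]>\n",
              x$n_voxels, x$clip, min(x$values[x$mask]), max(x$values[x$mask])))
  invisible(x)
}

#' Stack per-subject maps for group inference
#'
#' Aligns per-subject 3-D maps (e.g. `icc_map` or `stat_map` objects) into a
#' subject-indexed 4-D array, pairing each map with its covariate row by
#' `subject_id`.
#'
#' @param maps named list of maps (names = subject ids) or list of 3-D arrays.
#' @param subject_ids subject ordering to align to; default the map names.
#' @return List with `data` (4-D array, subject last), `subject_ids`.
#' @export
group_icc_stack <- function(maps, subject_ids = names(maps)) {
  vols <- lapply(maps, function(m) {
    if (inherits(m, c("icc_map", "stat_map"))) m$values else m
  })
  dims <- dim(vols[[1]])
  if (!all(vapply(vols, function(v) identical(dim(v), dims), logical(1))))
    arg_error("all maps must share one grid")
  if (is.null(subject_ids)) subject_ids <- as.character(seq_along(vols))
  if (!is.null(names(vols)) && all(subject_ids %in% names(vols)))
    vols <- vols[subject_ids]
  arr <- array(unlist(vols, use.names = FALSE),
               dim = c(dims, length(vols)))
  list(data = arr, subject_ids = subject_ids)
}
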