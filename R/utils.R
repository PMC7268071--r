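#' @useDynLib pwvfmri, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm median sd var mad predict quantile rnorm runif
NULL

# classed conditions so callers can distinguish bad arguments from bad data
abort_class <- function(class, msg) {
  stop(structure(
    class = c(class, "pwvfmri_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

arg_error       <- function(msg) abort_class("argument_error", msg)
config_error    <- function(msg) abort_class("config_error", msg)
detection_error <- function(msg) abort_class("detection_error", msg)
estimation_error <- function(msg) abort_class("estimation_error", msg)
model_error     <- function(msg) abort_class("model_error", msg)
regression_error <- function(msg) abort_class("regression_error", msg)
dependency_error <- function(msg) abort_class("dependency_error", msg)

# Evaluate expr under a fixed RNG state, restoring the caller's stream after.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    arg_error("seed must be a single number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# k reproducible sub-seeds (< 2^31) derived from one master seed
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# 4D [x,y,z,t] array <-> (time x voxel) matrix restricted to a logical mask
series_to_matrix <- function(arr, mask = NULL) {
  d <- dim(arr)
  stopifnot(length(d) == 4L)
  m <- matrix(arr, nrow = prod(d[1:3]), ncol = d[4])
  if (!is.null(mask)) m <- m[as.vector(mask), , drop = FALSE]
  t(m)
}

matrix_to_series <- function(mat, dims, mask = NULL, fill = 0) {
  out <- array(fill, dim = c(dims, nrow(mat)))
  flat <- matrix(fill, nrow = prod(dims), ncol = nrow(mat))
  if (is.null(mask)) flat[] <- t(mat) else flat[as.vector(mask), ] <- t(mat)
  out[] <- flat
  out
}

map_values_to_volume <- function(values, dims, mask, fill = 0) {
  vol <- array(fill, dim = dims)
  vol[as.vector(mask)] <- values
  vol
}

#' Construct a 3D statistic map
#'
#' Light container pairing a 3-D array with its interpretation. Used for
#' variance, CBF, intrinsic-connectivity, t, TFCE and corrected-p volumes.
#'
#' @param values 3-D numeric array.
#' @param kind one of `"bold_var"`, `"cbf_var"`, `"cbf_quant"`, `"icc"`,
#'   `"tstat"`, `"tfce"`, `"pcorr"`.
#' @param units free-text unit label.
#' @param mask optional logical array marking voxels the map is defined on.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(values, kind, units = "dimensionless", mask = NULL) {
  if (length(dim(values)) != 3L) arg_error("stat_map values must be 3-D")
  kinds <- c("bold_var", "cbf_var", "cbf_quant", "icc", "tstat", "tfce", "pcorr")
  kind <- match.arg(kind, kinds)
  structure(list(values = values, kind = kind, units = units, mask = mask),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<stat_map kind=%s dims=%s range=[%.4g, %.4g]>\n",
              x$kind, paste(dim(x$values), collapse = "x"),
              min(v), max(v)))
  invisible(x)
}
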