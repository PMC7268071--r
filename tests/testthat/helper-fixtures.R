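# shared fixtures built in code at test time

# internals exercised directly by tests
flow_pulse <- pwvfmri:::flow_pulse
delta_m_from_cbf <- pwvfmri:::delta_m_from_cbf

# a noiseless ground truth where nothing depends on PWV; overrides win
null_truth <- function(...) {
  args <- utils::modifyList(
    list(a_path = 0, b_path = 0, gamma_noise_sd = 0, beta_noise_sd = 0,
         pwv_noise_sd = 0, sex_sd = 0, noise_sd = 0),
    list(...))
  do.call(ground_truth, args)
}

# minimal interleaved series from explicit per-frame values at one voxel
one_voxel_series <- function(values) {
  array(values, dim = c(1, 1, 1, length(values)))
}

roles <- function(n) rep_len(c("control", "tag"), n)

# dense-grid numerical oracle for the intersecting-tangent foot
foot_oracle <- function(flow_fun, t_lo, t_hi, dt = 0.01, baseline_win = 100,
                        onset_frac = 0.2) {
  t <- seq(t_lo, t_hi, by = dt)
  f <- flow_fun(t)
  n <- length(f)
  deriv <- c(NA, (f[3:n] - f[1:(n - 2)]) / (2 * dt), NA)
  imax <- which.max(deriv)
  i_on <- imax
  dmax <- deriv[imax]
  while (i_on > 2 && !is.na(deriv[i_on - 1]) &&
         deriv[i_on - 1] >= onset_frac * dmax) i_on <- i_on - 1
  base <- median(f[t >= t[i_on] - baseline_win & t < t[i_on]])
  t[imax] + (base - f[imax]) / dmax
}

# brute-force O(V^2) intrinsic-connectivity oracle
icc_oracle <- function(arr, mask, clip = 0.9999) {
  X <- t(apply(arr, 4, function(v) v)[as.vector(mask), , drop = FALSE])
  V <- ncol(X)
  ic <- numeric(V)
  for (v in seq_len(V)) {
    for (u in seq_len(V)) {
      if (u == v) next
      r <- cor(X[, v], X[, u])
      r <- min(max(r, -clip), clip)
      ic[v] <- ic[v] + atanh(r)
    }
  }
  out <- array(0, dim = dim(arr)[1:3])
  out[mask] <- ic
  out
}

# brute-force TFCE oracle: explicit per-threshold connected components with
# breadth-first search in plain R
tfce_oracle <- function(t3, E = 0.5, H = 2, dh, connectivity = 26) {
  dims <- dim(t3)
  n <- prod(dims)
  out <- array(0, dim = dims)
  tmax <- max(t3, 0)
  if (tmax <= 0) return(out)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs))
  offs <- offs[nz > 0 & (connectivity == 26 |
                           (connectivity == 18 & nz <= 2) |
                           (connectivity == 6 & nz <= 1)), , drop = FALSE]
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  for (h in seq(dh, tmax + 1e-7 * dh, by = dh)) {
    supra <- t3 >= h
    lab <- array(0L, dims)
    cur <- 0L
    for (s in seq_len(n)) {
      if (!supra[s] || lab[s] > 0L) next
      cur <- cur + 1L
      queue <- s
      members <- integer(0)
      lab[s] <- cur
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        members <- c(members, v)
        p <- idx[v, ]
        for (k in seq_len(nrow(offs))) {
          q <- p + offs[k, ]
          if (any(q < 1) || any(q > dims)) next
          u <- q[1] + dims[1] * (q[2] - 1 + dims[2] * (q[3] - 1))
          if (supra[u] && lab[u] == 0L) {
            lab[u] <- cur
            queue <- c(queue, u)
          }
        }
      }
      out[members] <- out[members] + length(members)^E * h^H * dh
    }
  }
  out
}
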