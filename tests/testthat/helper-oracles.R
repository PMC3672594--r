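# Independent oracles and synthetic signal builders used across the suite.

# Discrete-Fourier cross-spectral impedance at frequency f over an
# integer-period window: the independent oracle for the least-squares
# estimator. Phasor convention s(t) = Re(S exp(+j w t)).
dft_phasor <- function(x, f, fs) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  (2 / n) * sum(x * exp(-2i * pi * f * t))
}

dft_impedance <- function(window, f = 5) {
  fs <- 1 / diff(window$t_s[1:2])
  P <- dft_phasor(window$ptr_cmH2O, f, fs)
  Q <- dft_phasor(window$vao_ml_s, f, fs)
  Z <- P / Q
  list(rrs = Re(Z), xrs = Im(Z))
}

# Stationary series R-C record driven by a sinusoidal flow at f:
# P = EEP + R q + (1/C) int q dt, i.e. Z = R - j/(w C).
rc_record <- function(R = 0.01, C = 20, f = 5, fs = 200, periods = 5,
                      amp_q = 50, eep = 0, noise_sd = c(0, 0), seed = NULL,
                      ramp = 0) {
  n <- round(periods * fs / f)
  t <- (seq_len(n) - 1) / fs
  w <- 2 * pi * f
  q <- amp_q * sin(w * t)
  p <- eep + R * q - amp_q / (w * C) * cos(w * t) + ramp * t
  if (!is.null(seed)) {
    set.seed(seed)
    p <- p + rnorm(n, 0, noise_sd[1])
    q <- q + rnorm(n, 0, noise_sd[2])
  }
  tibble::tibble(t_s = t, ptr_cmH2O = p, vao_ml_s = q)
}

# Noise-free breaths that satisfy the equation of motion exactly:
# near-constant-flow inspiration (a small analytic ripple keeps volume and
# flow linearly independent), exponential passive expiration. Built directly
# (no simulator, no filtering) so fits can be checked against the exact
# coefficients.
synth_eom_breaths <- function(edyn = 0.05, rdyn = 0.01, eep = 12, vt = 150,
                              fs = 200, ti = 1, te = 2, n_breaths = 3,
                              flow_scale = 1) {
  q_i <- vt / ti
  tau <- rdyn / edyn
  w3 <- 2 * pi * 3
  a <- 0.05 * q_i
  one <- function(b) {
    t1 <- seq(0, ti - 1 / fs, by = 1 / fs)
    t2 <- seq(0, te - 1 / fs, by = 1 / fs)
    # inspiration: q = q_i + a sin(w3 t) integrates to
    # v = q_i t + a (1 - cos(w3 t)) / w3 -- exact pair
    q1 <- q_i + a * sin(w3 * t1)
    v1 <- q_i * t1 + a * (1 - cos(w3 * t1)) / w3
    # passive expiration from the inspired volume
    v_end <- q_i * ti + a * (1 - cos(w3 * ti)) / w3
    v2 <- v_end * exp(-t2 / tau)
    q2 <- -v_end / tau * exp(-t2 / tau)
    v <- c(v1, v2); q <- c(q1, q2)
    p <- edyn * v + rdyn * q + eep
    tibble::tibble(t_s = (b - 1) * (ti + te) + c(t1, ti + t2),
                   ptr_f = p, vao_f = q * flow_scale, volume = v * flow_scale,
                   ptr_raw = p, vao_raw = q * flow_scale)
  }
  d <- lapply(seq_len(n_breaths), one)
  tibble::tibble(
    breath = seq_len(n_breaths),
    t0 = vapply(d, function(x) x$t_s[1], 0),
    t_end = vapply(d, function(x) max(x$t_s), 0),
    vt_ml = vapply(d, function(x) max(x$volume), 0),
    drift_ml = 0,
    insp_end = as.integer(round(ti * fs) + 1L),
    data = d
  )
}

# small deterministic voxel tables
random_voxels <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(voxel_id = seq_len(n),
                 hu = runif(n, -1000, 100),
                 voxel_ml = runif(n, 0.2, 2))
}

# brute-force per-voxel aeration accounting (independent of the vectorized
# implementation)
brute_force_aeration <- function(voxels) {
  tot <- list(OA = c(0, 0, 0), NORM = c(0, 0, 0), PA = c(0, 0, 0),
              "NA" = c(0, 0, 0))
  for (i in seq_len(nrow(voxels))) {
    hu <- voxels$hu[i]; vol <- voxels$voxel_ml[i]
    lab <- if (hu >= -1000 && hu < -900) "OA"
    else if (hu < -500) "NORM"
    else if (hu < -100) "PA"
    else if (hu <= 100) "NA"
    else next
    gf <- min(max(-hu, 0), 1000) / 1000
    tot[[lab]] <- tot[[lab]] + c(vol, gf * vol, (1 - gf) * vol)
  }
  tot
}
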