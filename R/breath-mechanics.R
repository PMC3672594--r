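# Breath segmentation, volume integration, equation-of-motion fitting and
# the SLICE method for intra-tidal elastance.

# Remove the oscillation with a zero-phase trapezoidal moving average
# spanning exactly one oscillation period: the trapezoid rule over a full
# period nulls the oscillation frequency and all its harmonics exactly,
# with no ringing and only one period of smearing. Filtering is linear, so
# signals that obey the equation of motion still do afterwards and the
# tidal-mechanics fits stay unbiased.
deoscillate <- function(x, fs, f_osc = 5) {
  m <- round(fs / f_osc)
  w <- c(0.5, rep(1, m - 1), 0.5) / m
  h <- length(w) %/% 2
  xp <- c(rev(x[2:(h + 1)]), x, rev(x[(length(x) - h):(length(x) - 1)]))
  as.numeric(stats::filter(xp, w, sides = 2))[(h + 1):(h + length(x))]
}

#' Integrate flow to volume
#'
#' Trapezoidal integration of airway-opening flow, zeroed at the first
#' sample. With `drift_correct = TRUE` a linear ramp is subtracted so the
#' volume returns to zero at the last sample (per-breath drift correction);
#' the removed end-volume is attached as attribute `drift_ml`.
#'
#' @param vao flow, ml/s.
#' @param sample_rate Hz.
#' @param drift_correct logical.
#' @return volume trace, ml, with attribute `drift_ml`.
#' @export
integrate_volume <- function(vao, sample_rate, drift_correct = FALSE) {
  v <- pracma::cumtrapz(vao)[, 1] / sample_rate
  drift <- 0
  if (drift_correct && length(v) > 1) {
    drift <- v[length(v)]
    v <- v - drift * (seq_along(v) - 1) / (length(v) - 1)
  }
  attr(v, "drift_ml") <- drift
  v
}

#' Segment a record into breaths
#'
#' Inspiration onsets are negative-to-positive zero crossings of the
#' de-oscillated flow, with a hysteresis band (a fraction of peak flow)
#' so residual oscillation cannot trigger crossings. Hold periods are
#' excluded; breaths overlapping a hold are dropped. Each segment runs
#' onset-to-onset, carries de-oscillated pressure/flow for fitting and an
#' integrated, drift-corrected volume zeroed at the onset.
#'
#' @param waveforms tibble `t_s, ptr_cmH2O, vao_ml_s`.
#' @param annotations optional annotation tibble; its `insp_hold`/`exp_hold`
#'   rows are excluded from segmentation.
#' @param f_osc oscillation frequency to remove, Hz.
#' @param hysteresis_frac hysteresis band as a fraction of peak flow.
#' @return tibble with one row per breath: `breath`, `t0`, `t_end`, `vt_ml`,
#'   `drift_ml`, `insp_end` (sample index of maximum volume) and a `data`
#'   list-column (`t_s, ptr_f, vao_f, volume, ptr_raw, vao_raw`).
#' @export
segment_breaths <- function(waveforms, annotations = NULL, f_osc = 5,
                            hysteresis_frac = 0.05) {
  fs <- infer_fs(waveforms$t_s)
  ptr_f <- deoscillate(waveforms$ptr_cmH2O, fs, f_osc)
  vao_f <- deoscillate(waveforms$vao_ml_s, fs, f_osc)

  in_hold <- rep(FALSE, nrow(waveforms))
  holds <- NULL
  if (!is.null(annotations)) {
    holds <- dplyr::filter(annotations, .data$label %in% c("insp_hold", "exp_hold"))
    for (i in seq_len(nrow(holds))) {
      in_hold <- in_hold | (waveforms$t_s >= holds$t_start_s[i] &
                              waveforms$t_s < holds$t_end_s[i])
    }
  }

  peak <- max(abs(vao_f[!in_hold]), 0)
  band <- hysteresis_frac * peak
  s <- ifelse(vao_f > band, 1, ifelse(vao_f < -band, -1, 0))
  nz <- which(s != 0)
  if (length(nz) < 2) {
    warn("no flow crossings found; returning zero breaths")
    return(empty_breaths())
  }
  filled <- approx(nz, s[nz], xout = seq_along(s), method = "constant",
                   rule = 2)$y
  crossings <- which(diff(filled) == 2) + 1L
  # refine each onset to the half-rise crossing: the zero-phase low-pass
  # smears the flow step symmetrically, so its 50% level marks the true edge
  onsets <- purrr::map_int(crossings, function(i) {
    # inspiratory plateau level: upper quantile so the smoothed rise before
    # the crossing does not drag the estimate down
    plat <- stats::quantile(vao_f[i:min(i + round(0.4 * fs), length(vao_f))],
                            0.9, names = FALSE)
    a <- max(1L, i - round(0.6 * fs))
    b <- min(length(vao_f), i + round(0.6 * fs))
    j <- a + which(vao_f[a:b] >= 0.5 * plat)[1] - 1L
    as.integer(if (is.na(j)) i else j)
  })
  onsets <- onsets[!in_hold[onsets]]
  if (length(onsets) < 2) {
    warn("fewer than two inspiration onsets; returning zero breaths")
    return(empty_breaths())
  }

  segs <- purrr::map(seq_len(length(onsets) - 1L), function(i) {
    a <- onsets[i]; b <- onsets[i + 1L] - 1L
    if (any(in_hold[a:b])) return(NULL)
    # one lead-in sample so the trapezoidal integral starts from the
    # pre-inspiratory baseline
    a0 <- max(a - 1L, 1L)
    # synchronous de-oscillation: a sinusoid at the oscillation frequency is
    # least-squares fitted per segment (the moving-average trace serving as
    # the ventilatory trend) and subtracted from the raw signals, keeping
    # the ventilatory waveform's edges intact. The fit skips samples near
    # the flow corners, where the moving-average trend is biased, and allows
    # linear amplitude/phase modulation (the oscillation's elastic-resistive
    # split drifts as tangent compliance changes over the breath).
    tt <- 2 * pi * f_osc * waveforms$t_s[a0:b]
    tc <- waveforms$t_s[a0:b] - mean(waveforms$t_s[a0:b])
    Xo <- cbind(cos(tt), sin(tt), tc * cos(tt), tc * sin(tt))
    p_raw <- waveforms$ptr_cmH2O[a0:b]
    q_raw <- waveforms$vao_ml_s[a0:b]
    n_seg <- b - a0 + 1L
    guard <- round(0.15 * fs)
    turn <- which(vao_f[a0:b] < -band)[1] # inspiration-to-expiration corner
    keep <- rep(TRUE, n_seg)
    near <- function(i) max(1L, i - guard):min(n_seg, i + guard)
    keep[near(1L)] <- FALSE
    keep[near(n_seg)] <- FALSE
    if (!is.na(turn)) keep[near(turn)] <- FALSE
    if (sum(keep) < 4 * round(fs / f_osc)) keep <- rep(TRUE, n_seg)
    cp <- stats::lm.fit(Xo[keep, , drop = FALSE],
                        (p_raw - ptr_f[a0:b])[keep])$coefficients
    cq <- stats::lm.fit(Xo[keep, , drop = FALSE],
                        (q_raw - vao_f[a0:b])[keep])$coefficients
    p_deosc <- p_raw - as.numeric(Xo %*% cp)
    q_deosc <- q_raw - as.numeric(Xo %*% cq)
    vol_full <- integrate_volume(q_deosc, fs, drift_correct = TRUE)
    off <- a - a0
    # zero against the pre-onset baseline sample: the onset sample itself
    # already carries half a sample of inspiratory flow
    vol <- vol_full[(off + 1L):n_seg] - vol_full[1L]
    tibble::tibble(
      breath = i, t0 = waveforms$t_s[a], t_end = waveforms$t_s[b],
      vt_ml = max(vol_full) - vol_full[1L],
      drift_ml = attr(vol_full, "drift_ml"),
      insp_end = which.max(vol),
      data = list(tibble::tibble(
        t_s = waveforms$t_s[a:b],
        ptr_f = p_deosc[(off + 1L):n_seg], vao_f = q_deosc[(off + 1L):n_seg],
        volume = as.numeric(vol),
        ptr_raw = waveforms$ptr_cmH2O[a:b], vao_raw = waveforms$vao_ml_s[a:b]))
    )
  })
  out <- dplyr::bind_rows(segs)
  if (nrow(out) == 0) return(empty_breaths())
  out$breath <- seq_len(nrow(out))
  out
}

empty_breaths <- function() {
  tibble::tibble(breath = integer(), t0 = numeric(), t_end = numeric(),
                 vt_ml = numeric(), drift_ml = numeric(),
                 insp_end = integer(), data = list())
}

#' Fit the single-compartment equation of motion
#'
#' Ordinary least squares of tracheal pressure on volume, flow and an
#' intercept, `Ptr = Edyn * V + Rdyn * Vao + EEP`, pooled over all samples
#' of the supplied breaths (typically the 5-10 breaths preceding a hold).
#'
#' @param breaths tibble from [segment_breaths()] (all rows are pooled).
#' @return an `eom_fit` object: `edyn` (cm H2O/ml), `rdyn` (cm H2O.s/ml),
#'   `eep` (cm H2O), `n_breaths`, `n_samples`, `rmse`.
#' @export
fit_eom <- function(breaths) {
  if (nrow(breaths) < 1) {
    abort("at least one breath is required", class = "oscillung_error_data")
  }
  d <- dplyr::bind_rows(breaths$data)
  X <- cbind(1, d$volume, d$vao_f)
  qx <- qr(X)
  if (qx$rank < 3) {
    abort("rank-deficient equation-of-motion design (volume and flow collinear)",
          class = "oscillung_error_conditioning")
  }
  beta <- qr.coef(qx, d$ptr_f)
  res <- d$ptr_f - X %*% beta
  structure(
    list(edyn = unname(beta[2]), rdyn = unname(beta[3]), eep = unname(beta[1]),
         n_breaths = nrow(breaths), n_samples = nrow(d),
         rmse = sqrt(mean(res^2))),
    class = "eom_fit")
}

#' @export
print.eom_fit <- function(x, ...) {
  cat(sprintf(
    "<eom_fit> Edyn %.4f cm H2O/ml, Rdyn %.4f cm H2O.s/ml, EEP %.2f cm H2O (%d breaths, rmse %.3f)\n",
    x$edyn, x$rdyn, x$eep, x$n_breaths, x$rmse))
  invisible(x)
}

#' @export
tidy.eom_fit <- function(x, ...) {
  tibble::tibble(term = c("edyn", "rdyn", "eep"),
                 estimate = c(x$edyn, x$rdyn, x$eep),
                 unit = c("cmH2O/ml", "cmH2O.s/ml", "cmH2O"))
}

#' @export
glance.eom_fit <- function(x, ...) {
  tibble::tibble(edyn = x$edyn, rdyn = x$rdyn, eep = x$eep,
                 n_breaths = x$n_breaths, n_samples = x$n_samples,
                 rmse = x$rmse)
}

#' Intra-tidal elastance by the SLICE method
#'
#' Restricts the inspiratory samples of each breath to 10-90% of its
#' inspired volume, partitions that range into six equal-width contiguous
#' volume bins and fits the equation of motion (with a per-slice offset)
#' within each bin, pooling all breaths. The first and last slice give
#' E_LOW and E_HIGH.
#'
#' Under constant-flow ventilation the flow barely varies inside one volume
#' bin, so a per-slice resistance is not identifiable; the resistance is
#' therefore estimated once from the pooled restricted inspiration and the
#' per-slice fit estimates elastance and offset with the resistive pressure
#' removed.
#'
#' @param breaths tibble from [segment_breaths()].
#' @param n_slices number of volume bins.
#' @param vol_range inspiratory volume-fraction range analysed.
#' @param min_samples minimum pooled samples per slice; slices below it are
#'   marked invalid, and the profile is invalid if the first or last slice is.
#' @return a `slice_profile` object: tibble of per-slice elastance and
#'   volume centers with `e_low`, `e_high`, `valid` attributes.
#' @export
slice_analysis <- function(breaths, n_slices = 6L, vol_range = c(0.1, 0.9),
                           min_samples = 20L) {
  if (nrow(breaths) < 1) {
    abort("at least one breath is required", class = "oscillung_error_data")
  }
  insp <- purrr::map2(breaths$data, breaths$insp_end, function(d, ie) {
    d <- d[seq_len(ie), ]
    vt <- max(d$volume)
    d$vfrac <- d$volume / vt
    d[d$vfrac >= vol_range[1] & d$vfrac <= vol_range[2], ]
  }) |> dplyr::bind_rows()

  edges <- seq(vol_range[1], vol_range[2], length.out = n_slices + 1)
  insp$slice <- pmin(pmax(findInterval(insp$vfrac, edges,
                                       rightmost.closed = TRUE), 1L), n_slices)

  # shared resistance from the pooled restricted inspiration (per-slice
  # resistance is unidentifiable at near-constant flow)
  Xp <- cbind(1, insp$volume, insp$vao_f)
  qp <- qr(Xp)
  if (qp$rank < 3) {
    abort("rank-deficient SLICE design (volume and flow collinear)",
          class = "oscillung_error_conditioning")
  }
  rdyn_shared <- unname(qr.coef(qp, insp$ptr_f)[3])
  insp$p_el <- insp$ptr_f - rdyn_shared * insp$vao_f

  prof <- purrr::map(seq_len(n_slices), function(s) {
    d <- insp[insp$slice == s, ]
    if (nrow(d) < min_samples || diff(range(d$volume)) < 1e-9) {
      return(tibble::tibble(slice = s, elastance = NA_real_, rdyn = rdyn_shared,
                            volume_center = mean(d$volume), n = nrow(d),
                            valid = FALSE))
    }
    beta <- qr.coef(qr(cbind(1, d$volume)), d$p_el)
    tibble::tibble(slice = s, elastance = unname(beta[2]),
                   rdyn = rdyn_shared, volume_center = mean(d$volume),
                   n = nrow(d), valid = TRUE)
  }) |> dplyr::bind_rows()

  structure(prof,
            e_low = prof$elastance[1],
            e_high = prof$elastance[n_slices],
            valid = prof$valid[1] && prof$valid[n_slices],
            class = c("slice_profile", class(tibble::tibble())))
}

#' @export
tidy.slice_profile <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.slice_profile <- function(x, ...) {
  tibble::tibble(e_low = attr(x, "e_low"), e_high = attr(x, "e_high"),
                 valid = attr(x, "valid"), n_slices = nrow(x))
}
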