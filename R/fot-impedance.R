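# Least-squares estimation of respiratory input impedance at the forced
# oscillation frequency, and extraction of end-expiratory/end-inspiratory
# oscillatory elastance from ventilator holds.

# design matrix: cos/sin at f plus a polynomial trend, over local time
osc_design <- function(n, fs, frequency, trend_order) {
  x <- (seq_len(n) - 1) / fs
  X <- cbind(cos(2 * pi * frequency * x), sin(2 * pi * frequency * x))
  for (d in 0:trend_order) X <- cbind(X, (x - mean(x))^d)
  X
}

check_window <- function(n, fs, frequency) {
  cycles <- n * frequency / fs
  if (abs(cycles - round(cycles)) > 1e-6 || round(cycles) < 2) {
    abort(sprintf(
      "window must span an integer number (>= 2) of oscillation periods, got %.4f",
      cycles), class = "oscillung_error_window")
  }
}

infer_fs <- function(t) {
  dt <- diff(t)
  if (diff(range(dt)) > 1e-6) {
    abort("waveform time grid is not uniform", class = "oscillung_error_sampling")
  }
  1 / mean(dt)
}

phasor_from_coef <- function(beta) complex(real = beta[1], imaginary = -beta[2])

#' Least-squares impedance estimate over one analysis window
#'
#' Regresses pressure and flow on a sine/cosine pair at the oscillation
#' frequency plus a polynomial trend that absorbs the ventilatory waveform.
#' The sinusoid coefficients form complex phasors (convention
#' `s(t) = Re(S exp(+j w t))`, so a compliance-dominated system has negative
#' reactance) and the impedance is the phasor ratio `Z = P / Q`.
#'
#' @param window tibble with columns `t_s`, `ptr_cmH2O`, `vao_ml_s` spanning
#'   an integer number (>= 2) of oscillation periods.
#' @param frequency oscillation frequency, Hz.
#' @param trend_order polynomial trend order (2 absorbs the tidal waveform
#'   under breathing; 1 suffices during holds).
#' @return one-row tibble: `t_center_s`, `f_hz`, `rrs`, `xrs`, `ex5`,
#'   `residual_fraction`, `flagged`.
#' @export
estimate_impedance_ls <- function(window, frequency = 5, trend_order = 2) {
  stopifnot(all(c("t_s", "ptr_cmH2O", "vao_ml_s") %in% names(window)))
  if (!all(is.finite(window$ptr_cmH2O)) || !all(is.finite(window$vao_ml_s))) {
    abort("non-finite values in analysis window", class = "oscillung_error_data")
  }
  fs <- infer_fs(window$t_s)
  n <- nrow(window)
  check_window(n, fs, frequency)
  X <- osc_design(n, fs, frequency, trend_order)
  fit <- stats::lm.fit(X, cbind(window$ptr_cmH2O, window$vao_ml_s))
  bp <- fit$coefficients[, 1]; bq <- fit$coefficients[, 2]
  P <- phasor_from_coef(bp); Q <- phasor_from_coef(bq)
  if (Mod(Q) < 1e-9) {
    abort("degenerate window: no oscillatory flow", class = "oscillung_error_degenerate")
  }
  Z <- P / Q
  rss <- colSums(fit$residuals^2)
  osc_ss <- n / 2 * c(Mod(P)^2, Mod(Q)^2)
  rf <- min(max(sum(rss) / (sum(rss) + sum(osc_ss)), 0), 1)
  tibble::tibble(t_center_s = mean(window$t_s), f_hz = frequency,
                 rrs = Re(Z), xrs = Im(Z),
                 ex5 = ex5_from_xrs(Im(Z), frequency),
                 residual_fraction = rf, flagged = FALSE)
}

#' Sliding-window impedance tracking
#'
#' Applies the least-squares estimator of [estimate_impedance_ls()] on a
#' sliding window (all windows share one design matrix, so the whole record
#' is solved in a single least-squares pass). Degenerate windows are flagged
#' rather than dropped.
#'
#' @param waveforms tibble `t_s, ptr_cmH2O, vao_ml_s` on a uniform grid.
#' @param frequency oscillation frequency, Hz.
#' @param window_periods window length in oscillation periods (>= 2).
#' @param hop_s hop between window starts, s.
#' @param trend_order polynomial trend order per window.
#' @return tibble with one row per window, columns as in
#'   [estimate_impedance_ls()] plus `window_s`.
#' @export
track_impedance <- function(waveforms, frequency = 5, window_periods = 5,
                            hop_s = 0.2, trend_order = 2) {
  fs <- infer_fs(waveforms$t_s)
  nw <- round(window_periods * fs / frequency)
  check_window(nw, fs, frequency)
  n <- nrow(waveforms)
  if (n < nw) abort("record shorter than one window", class = "oscillung_error_window")
  starts <- seq(1L, n - nw + 1L, by = max(1L, round(hop_s * fs)))

  X <- osc_design(nw, fs, frequency, trend_order)
  qrX <- qr(X)
  idx <- outer(0:(nw - 1L), starts, `+`)
  Pm <- matrix(waveforms$ptr_cmH2O[idx], nrow = nw)
  Qm <- matrix(waveforms$vao_ml_s[idx], nrow = nw)
  bP <- qr.coef(qrX, Pm); bQ <- qr.coef(qrX, Qm)
  rssP <- colSums(qr.resid(qrX, Pm)^2); rssQ <- colSums(qr.resid(qrX, Qm)^2)

  P <- complex(real = bP[1, ], imaginary = -bP[2, ])
  Q <- complex(real = bQ[1, ], imaginary = -bQ[2, ])
  flagged <- Mod(Q) < 1e-9
  Z <- ifelse(flagged, NA_complex_, P / Q)
  osc <- nw / 2 * (Mod(P)^2 + Mod(Q)^2)
  rf <- pmin(pmax((rssP + rssQ) / (rssP + rssQ + osc), 0), 1)

  tibble::tibble(
    t_center_s = waveforms$t_s[starts] + (nw - 1) / (2 * fs),
    f_hz = frequency, rrs = Re(Z), xrs = Im(Z),
    ex5 = ex5_from_xrs(Im(Z), frequency),
    residual_fraction = rf, flagged = flagged,
    window_s = nw / fs
  )
}

#' Oscillatory elastance from reactance
#'
#' `E = -2 * pi * f * X`: at 5 Hz this is the oscillatory elastance E_X5,
#' the inverse of the oscillatory compliance. Below resonance the reactance
#' of a passive respiratory system is negative, so the elastance is positive.
#'
#' @param xrs reactance, cm H2O.s/ml.
#' @param frequency Hz.
#' @return elastance, cm H2O/ml.
#' @export
ex5_from_xrs <- function(xrs, frequency = 5) {
  stopifnot(frequency > 0)
  -2 * pi * frequency * xrs
}

#' Extract end-expiratory and end-inspiratory values from holds
#'
#' Averages elastance (and resistance) over the impedance-tracking windows
#' that fall wholly inside the initial part of each inspiratory and
#' expiratory hold. Inspiratory holds yield end-inspiration samples,
#' expiratory holds end-expiration.
#'
#' @param estimates output of [track_impedance()].
#' @param annotations annotation tibble (`t_start_s, t_end_s, label,
#'   peep_cmH2O, limb`) with one `insp_hold` and one `exp_hold` per step.
#' @param initial_fraction fraction of the hold counted as its "initial
#'   part" (window centers must fall there).
#' @return tibble `peep_cmH2O, limb, phase, ex5, rrs, xrs, n_windows`.
#' @export
extract_hold_values <- function(estimates, annotations, initial_fraction = 1 / 3) {
  holds <- dplyr::filter(annotations, .data$label %in% c("insp_hold", "exp_hold"))
  if (nrow(holds) == 0) {
    abort("no hold annotations", class = "oscillung_error_data")
  }
  out <- purrr::pmap(holds, function(t_start_s, t_end_s, label, peep_cmH2O, limb, ...) {
    lo <- t_start_s; hi <- t_end_s
    w <- if (!is.null(estimates$window_s)) estimates$window_s else 0
    inside <- estimates$t_center_s - w / 2 >= lo - 1e-9 &
      estimates$t_center_s + w / 2 <= hi + 1e-9 &
      estimates$t_center_s <= lo + initial_fraction * (hi - lo) + 1e-9 &
      !estimates$flagged
    if (!any(inside)) {
      abort(sprintf("no impedance window inside the initial part of %s at PEEP %g (%s)",
                    label, peep_cmH2O, limb),
            class = "oscillung_error_missing_sample")
    }
    e <- estimates[inside, ]
    tibble::tibble(
      peep_cmH2O = peep_cmH2O, limb = limb,
      phase = if (label == "insp_hold") "end_inspiration" else "end_expiration",
      ex5 = mean(e$ex5), rrs = mean(e$rrs), xrs = mean(e$xrs),
      n_windows = sum(inside)
    )
  })
  dplyr::bind_rows(out)
}
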