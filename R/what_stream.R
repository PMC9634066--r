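#' Van der Pol neuronal unit
#'
#' Each landmark-selective neuronal ensemble is a Van der Pol oscillator
#' \deqn{\dot X = (\lambda - Y^2) X - P^2 Y + B A_s \sin(\omega_s t), \qquad
#'       \dot Y = X}
#' with output `Y`. The bifurcation parameter `lam` sets the regime: for
#' `lam < 0` the unforced unit decays to rest; for `0 < lam <= 1` it settles
#' on a quasi-sinusoidal limit cycle of angular frequency `P` and amplitude
#' `2 sqrt(lam)`; for large `lam` (e.g. 15.2, the Alzheimer regime) it
#' produces slow, harmonic-rich relaxation oscillations. `B` couples an
#' incoming sinusoidal stimulus into the unit.
#'
#' @param lam bifurcation parameter (0.2 healthy, 15.2 Alzheimer regime).
#' @param P natural angular frequency in code units.
#' @param B stimulus coupling coefficient (default 1.5).
#' @return An object of class `vdp_unit`.
#' @export
vdp_unit <- function(lam = 0.2, P, B = 1.5) {
  stopifnot(is.finite(lam), is.finite(P), P > 0, is.finite(B))
  structure(list(lam = lam, P = P, B = B), class = "vdp_unit")
}

#' Sinusoidal landmark stimulus
#'
#' A landmark drives the bank with `As * sin(omega_s t)` between `onset` and
#' `onset + duration`; `omega_s` is the landmark's identification frequency
#' code.
#'
#' @param omega_s drive angular frequency in code units.
#' @param As amplitude (default 1); `As = 0` is a null stimulus.
#' @param onset,duration active window in time units.
#' @return An object of class `vdp_stimulus`.
#' @export
stimulus <- function(omega_s, As = 1, onset = 0, duration = Inf) {
  stopifnot(is.finite(omega_s), omega_s > 0, is.finite(As), As >= 0,
            onset >= 0, duration > 0)
  structure(list(omega_s = omega_s, As = As, onset = onset,
                 duration = duration), class = "vdp_stimulus")
}

# Analytic-signal magnitude via FFT (instantaneous amplitude).
hilbert_envelope <- function(y) {
  n <- length(y)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else if (n > 1) {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(y) * h, inverse = TRUE) / n)
}

# Welch power spectral density on the code-unit (angular frequency) axis.
# Hann-windowed segments with 50% overlap; one-sided, density-normalized so
# that sum(power) * d_omega approximates the series variance.
welch_psd <- function(y, dt, n_segments = 8) {
  n <- length(y)
  seg <- max(16, floor(n / (n_segments / 2 + 0.5)))
  seg <- min(seg, n)
  step <- max(1, floor(seg / 2))
  win <- 0.5 * (1 - cos(2 * pi * seq_len(seg) / (seg + 1)))
  norm <- sum(win^2)
  starts <- seq(1, n - seg + 1, by = step)
  acc <- numeric(floor(seg / 2) + 1)
  for (s in starts) {
    x <- y[s:(s + seg - 1)]
    x <- (x - mean(x)) * win
    p <- Mod(stats::fft(x))^2 / norm
    acc <- acc + p[seq_along(acc)]
  }
  acc <- acc / length(starts)
  f_hz <- (seq_along(acc) - 1) / (seg * dt)
  data.frame(freq = 2 * pi * f_hz, power = acc * dt / (2 * pi))
}

# Dominant angular frequency from a zero-padded periodogram with parabolic
# interpolation around the peak bin.
dominant_frequency <- function(y, dt, pad = 4) {
  y <- y - mean(y)
  n <- length(y)
  np <- pad * n
  p <- Mod(stats::fft(c(y, numeric(np - n))))^2
  half <- floor(np / 2)
  k <- which.max(p[2:half]) + 1
  d_om <- 2 * pi / (np * dt)
  if (k > 2 && k < half) {
    a <- p[k - 1]; b <- p[k]; cc <- p[k + 1]
    denom <- a - 2 * b + cc
    delta <- if (denom != 0) 0.5 * (a - cc) / denom else 0
  } else {
    delta <- 0
  }
  (k - 1 + delta) * d_om
}

#' Simulate a driven or unforced Van der Pol unit
#'
#' Integrates the unit's equations with an adaptive solver
#' ([deSolve::ode()], `lsoda`, falling back to fixed-step `rk4` if the
#' adaptive run fails) on a uniform output grid, then summarizes the
#' post-transient window: Hilbert envelope, Welch power spectral density on
#' the code-unit (angular frequency) axis, dominant frequency, and envelope
#' levels.
#'
#' Initial state defaults to `(0, 0)` for driven runs and `(0.1, 0)` for
#' unforced runs (a limit cycle needs a nonzero seed).
#'
#' @param unit a [vdp_unit()].
#' @param stim a [stimulus()] or `NULL` for an unforced run.
#' @param t_end simulation length in time units (default 100).
#' @param dt output grid step; must satisfy `dt * max(P, omega_s) <= 0.1`.
#' @param init optional initial state `c(X, Y)`.
#' @param transient_frac fraction of the run discarded as transient before
#'   computing summaries (default 0.3).
#' @return An object of class `unit_response`: `t`, `y` (full series),
#'   `envelope` (post-transient instantaneous amplitude), `psd`
#'   (data.frame `freq`, `power`), `dominant_freq`, `peak_envelope` (99th
#'   percentile, edge-robust), `sustained_envelope` (median, used for
#'   threshold crossing), plus the unit and stimulus.
#' @examples
#' u <- vdp_unit(lam = 0.2, P = 4)
#' r <- simulate_unit(u, stimulus(omega_s = 4), t_end = 60, dt = 0.005)
#' r$sustained_envelope
#' @export
simulate_unit <- function(unit, stim = NULL, t_end = 100, dt = 0.002,
                          init = NULL, transient_frac = 0.3) {
  stopifnot(inherits(unit, "vdp_unit"), t_end > 0, dt > 0,
            transient_frac >= 0, transient_frac < 1)
  omega_s <- if (is.null(stim)) 0 else stim$omega_s
  fastest <- max(unit$P, omega_s)
  if (dt * fastest > 0.1) {
    stop("dt = ", dt, " too coarse for max(P, omega_s) = ", fastest,
         ": need dt * max(P, omega_s) <= 0.1")
  }
  driven <- !is.null(stim) && stim$As > 0
  if (is.null(init)) init <- if (driven) c(0, 0) else c(0.1, 0)
  stopifnot(length(init) == 2, all(is.finite(init)))

  pars <- list(lam = unit$lam, P2 = unit$P^2, B = unit$B,
               As = if (driven) stim$As else 0,
               ws = omega_s,
               onset = if (driven) stim$onset else 0,
               off = if (driven) stim$onset + stim$duration else 0)
  rhs <- function(t, s, p) {
    drive <- if (p$As > 0 && t >= p$onset && t < p$off) {
      p$B * p$As * sin(p$ws * t)
    } else 0
    list(c((p$lam - s[2]^2) * s[1] - p$P2 * s[2] + drive, s[1]))
  }
  tt <- seq(0, t_end, by = dt)
  out <- tryCatch(
    deSolve::ode(init, tt, rhs, pars, method = "lsoda",
                 rtol = 1e-8, atol = 1e-8),
    warning = function(w) NULL, error = function(e) NULL
  )
  if (is.null(out) || nrow(out) < length(tt) || !all(is.finite(out[, 3]))) {
    out <- deSolve::ode(init, tt, rhs, pars, method = "rk4")
  }
  y <- out[, 3]
  if (!all(is.finite(y))) {
    stop("Van der Pol integration blew up (non-finite state) for lam = ",
         unit$lam, ", dt = ", dt)
  }
  i0 <- floor(length(y) * transient_frac) + 1
  yw <- y[i0:length(y)]
  env <- hilbert_envelope(yw)
  psd <- welch_psd(yw, dt)
  structure(
    list(t = tt, y = y, window_start = tt[i0], envelope = env,
         psd = psd,
         dominant_freq = dominant_frequency(yw, dt),
         peak_envelope = unname(stats::quantile(env, 0.99)),
         sustained_envelope = stats::median(env),
         unit = unit, stim = stim, dt = dt,
         transient_frac = transient_frac),
    class = "unit_response"
  )
}

#' Bank of landmark-selective units
#'
#' @param P natural frequencies of the units (default `4:9`, one per route
#'   landmark LM1--LM6).
#' @param lam shared bifurcation parameter.
#' @param B shared coupling coefficient.
#' @return List of [vdp_unit()]s.
#' @export
vdp_bank <- function(P = 4:9, lam = 0.2, B = 1.5) {
  lapply(P, function(p) vdp_unit(lam = lam, P = p, B = B))
}

#' Drive every unit of a bank with one landmark's stimulus
#'
#' @param bank list of [vdp_unit()]s.
#' @param landmark a one-row landmark data.frame (with `freq_code`) or a bare
#'   numeric frequency code.
#' @param t_end,dt,... passed to [simulate_unit()].
#' @param As stimulus amplitude.
#' @return List of `unit_response`, one per unit.
#' @export
bank_response <- function(bank, landmark, t_end = 100, dt = 0.002, As = 1,
                          ...) {
  if (length(bank) == 0) stop("empty oscillator bank")
  code <- if (is.data.frame(landmark)) landmark$freq_code[1] else
    as.numeric(landmark)
  stopifnot(is.finite(code), code > 0)
  stim <- if (As > 0) stimulus(omega_s = code, As = As) else NULL
  lapply(bank, simulate_unit, stim = stim, t_end = t_end, dt = dt, ...)
}

#' Recognize a landmark from the bank's responses
#'
#' A landmark is recognized when exactly one unit's sustained post-transient
#' envelope crosses the unity threshold -- the resonance signature. If no
#' unit crosses, or several cross (the non-specific response of the
#' high-`lam` Alzheimer regime, where every unit rides a large relaxation
#' limit cycle), no landmark is recognized.
#'
#' @param responses list of `unit_response` from a common drive.
#' @param threshold envelope threshold (default 1).
#' @return The index of the recognized unit, or `NA_integer_` with an
#'   attribute `reason` (`"none_above"` or `"non_specific"`).
#' @export
recognize_landmark <- function(responses, threshold = 1) {
  if (length(responses) == 0) {
    return(structure(NA_integer_, reason = "none_above"))
  }
  lev <- vapply(responses, function(r) r$sustained_envelope, numeric(1))
  above <- which(lev >= threshold)
  if (length(above) == 1) return(above)
  if (length(above) == 0) return(structure(NA_integer_, reason = "none_above"))
  structure(NA_integer_, reason = "non_specific")
}

#' Spectral summary of a unit response
#'
#' Dominant frequency plus band powers below/above a split frequency,
#' integrated from the Welch power spectral density of the post-transient
#' window. The window must hold at least 20 cycles of the slower of the
#' unit's natural frequency and the drive.
#'
#' @param resp a `unit_response`.
#' @param split band boundary on the code-unit axis (default 3).
#' @return Named vector `c(dominant_freq, low_band_power, high_band_power)`.
#' @export
spectral_summary <- function(resp, split = 3) {
  stopifnot(inherits(resp, "unit_response"))
  omega_s <- if (is.null(resp$stim)) Inf else resp$stim$omega_s
  slow <- min(resp$unit$P, omega_s)
  window_len <- resp$t[length(resp$t)] - resp$window_start
  need <- 20 * 2 * pi / slow
  if (window_len < need) {
    stop("post-transient window (", round(window_len, 1), " time units) too ",
         "short: need >= 20 cycles of the slower frequency (",
         round(need, 1), " time units)")
  }
  psd <- resp$psd
  d_om <- diff(psd$freq[1:2])
  low <- sum(psd$power[psd$freq < split]) * d_om
  high <- sum(psd$power[psd$freq >= split]) * d_om
  c(dominant_freq = resp$dominant_freq, low_band_power = low,
    high_band_power = high)
}

#' Export a unit response as CSV
#'
#' `write_response` writes the post-transient series (`t`, `y`, `envelope`);
#' `write_psd` writes the spectrum (`freq`, `power`).
#'
#' @param resp a `unit_response`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_response <- function(resp, path) {
  i0 <- match(resp$window_start, resp$t)
  df <- data.frame(t = resp$t[i0:length(resp$t)],
                   y = resp$y[i0:length(resp$y)],
                   envelope = resp$envelope)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_response
#' @export
write_psd <- function(resp, path) {
  utils::write.csv(resp$psd, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.unit_response <- function(x, ...) {
  cat("<unit_response> P =", x$unit$P, "lam =", x$unit$lam,
      if (is.null(x$stim)) "(unforced)" else
        paste0("driven at ", x$stim$omega_s),
      "\n  dominant freq:", signif(x$dominant_freq, 4),
      " sustained envelope:", signif(x$sustained_envelope, 4),
      " peak envelope:", signif(x$peak_envelope, 4), "\n")
  invisible(x)
}
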