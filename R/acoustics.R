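#' Monopole-type acoustic source from the glottal flow
#'
#' Tiles one cycle of the periodic volume flow `Q(t)` over `n_cycles` at the
#' audio sample rate and differentiates in time. The result is scaled as a
#' far-field monopole, `p(t) = rho / (4 pi r_ref) * dQ/dt`, evaluated at the
#' reference distance `r_ref` (default 1 m), so downstream stages only apply
#' linear filtering and spherical spreading. The output is zero-mean by
#' construction up to numerical error and is explicitly de-meaned.
#'
#' @param flow A [solve_flow()] result (one cycle).
#' @param n_cycles Number of cycles to synthesize (>= 1).
#' @param sample_rate Audio sample rate in Hz; must exceed `20 * f0`.
#' @param r_ref Monopole reference distance in m.
#' @param rho Air density in kg/m^3; defaults to the flow's conditions.
#' @return An object of class `acoustic_signal` (see [acoustic_signal()]) at
#'   distance `r_ref`.
#' @export
source_signal <- function(flow, n_cycles = 20, sample_rate = 44100,
                          r_ref = 1, rho = attr(flow, "cond")$rho) {
  stopifnot(inherits(flow, "flow_series"))
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  f0 <- attr(flow, "f0")
  if (sample_rate < 20 * f0) {
    stop("sample_rate below 20 * f0: the harmonic stack would alias")
  }
  n <- floor(n_cycles * sample_rate / f0)
  t <- (seq_len(n) - 1) / sample_rate
  ph <- (t * f0) %% 1
  # periodic linear interpolation of Q on the flow phase grid
  grid <- c(flow$phase, 1)
  qg <- c(flow$Q_m3_s, flow$Q_m3_s[1])
  Q <- stats::approx(grid, qg, xout = ph)$y
  dQ <- (c(Q[-1], Q[n]) - c(Q[1], Q[-n])) / (2 / sample_rate)
  dQ[1] <- (Q[2] - Q[1]) * sample_rate
  dQ[n] <- (Q[n] - Q[n - 1]) * sample_rate
  p <- rho / (4 * pi * r_ref) * dQ
  acoustic_signal(p - mean(p), sample_rate, mic_distance = r_ref,
                  label = "source")
}

#' Acoustic pressure signal
#'
#' Uniformly sampled sound pressure at a named virtual microphone.
#'
#' @param samples Sound pressure samples in Pa.
#' @param sample_rate Sample rate in Hz (>= 8000).
#' @param mic_distance Distance from the vocal-tract exit in m.
#' @param label Microphone name.
#' @return An object of class `acoustic_signal`.
#' @export
acoustic_signal <- function(samples, sample_rate, mic_distance = 1,
                            label = "mic") {
  if (sample_rate < 8000) stop("sample_rate must be at least 8000 Hz")
  if (any(!is.finite(samples))) stop("samples must be finite")
  if (mic_distance <= 0) stop("mic_distance must be positive")
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 mic_distance = mic_distance, label = label),
            class = "acoustic_signal")
}

#' @export
print.acoustic_signal <- function(x, ...) {
  cat(sprintf("<acoustic_signal '%s'>  %d samples @ %g Hz (%.3f s), %.2g m, rms %.3g Pa\n",
              x$label, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, x$mic_distance,
              sqrt(mean(x$samples^2))))
  invisible(x)
}

#' Vocal-tract resonator filter
#'
#' All-pole /a/ vocal-tract model realised as a cascade of two-pole resonator
#' sections, one per formant. The default formants are 1020 and 1350 Hz with
#' conventional bandwidths of 130 and 160 Hz. Because neighbouring resonances
#' skew each other, the pole angles are calibrated numerically at construction
#' so that the local maxima of the cascade magnitude response sit at the
#' requested formant frequencies (fixed-point iteration on a 0.25 Hz grid).
#'
#' @param formants Strictly increasing formant frequencies in Hz.
#' @param bandwidths Formant bandwidths in Hz (recycled to length of
#'   `formants`).
#' @param sample_rate Sample rate in Hz.
#' @param gain Overall linear gain.
#' @return An object of class `vocal_tract_filter` holding the biquad
#'   sections and the achieved peak frequencies (`peaks_hz`).
#' @export
#' @examples
#' vt <- vocal_tract_filter()
#' vt$peaks_hz
vocal_tract_filter <- function(formants = c(1020, 1350),
                               bandwidths = c(130, 160),
                               sample_rate = 44100, gain = 1) {
  if (is.unsorted(formants, strictly = TRUE)) {
    stop("formant frequencies must be strictly increasing")
  }
  if (any(formants >= sample_rate / 2)) {
    stop("formants must lie below the Nyquist frequency")
  }
  bandwidths <- rep_len(bandwidths, length(formants))
  if (any(bandwidths <= 0)) stop("bandwidths must be positive")

  r <- exp(-pi * bandwidths / sample_rate)
  theta <- 2 * pi * formants / sample_rate
  grid <- seq(0.25, min(sample_rate / 2 - 1, 2 * max(formants)), by = 0.25)
  for (it in 1:40) {
    H <- .cascade_mag(grid, r, theta, sample_rate)
    pk <- .nearest_local_max(grid, H, formants)
    err <- formants - pk
    if (all(abs(err) < 0.1)) break
    theta <- theta + 2 * pi * err / sample_rate
  }
  structure(list(formants = formants, bandwidths = bandwidths,
                 sample_rate = sample_rate, gain = gain,
                 r = r, theta = theta,
                 peaks_hz = .nearest_local_max(
                   grid, .cascade_mag(grid, r, theta, sample_rate), formants)),
            class = "vocal_tract_filter")
}

# |H(f)| of the resonator cascade (unit DC gain per section)
.cascade_mag <- function(freq, r, theta, fs) {
  w <- 2 * pi * freq / fs
  H <- rep(1, length(freq))
  for (k in seq_along(r)) {
    b <- 1 - 2 * r[k] * cos(theta[k]) + r[k]^2      # unity gain at DC
    z1 <- exp(-1i * w)
    H <- H * abs(b / (1 - 2 * r[k] * cos(theta[k]) * z1 + r[k]^2 * z1^2))
  }
  H
}

# nearest interior local maximum of H to each target frequency
.nearest_local_max <- function(freq, H, targets) {
  n <- length(H)
  is_max <- c(FALSE, H[2:(n - 1)] > H[1:(n - 2)] & H[2:(n - 1)] >= H[3:n], FALSE)
  fmax <- freq[is_max]
  if (length(fmax) == 0) return(rep(NA_real_, length(targets)))
  vapply(targets, function(f) fmax[which.min(abs(fmax - f))], numeric(1))
}

#' Magnitude frequency response of a vocal-tract filter
#'
#' @param vt A [vocal_tract_filter()].
#' @param freq Frequencies in Hz at which to evaluate the response.
#' @return A `spectral_density`-classed data.frame (`freq_hz`, `amplitude`)
#'   usable with [extract_formants()].
#' @export
vt_frequency_response <- function(vt, freq = seq(0, 4000, by = 1)) {
  stopifnot(inherits(vt, "vocal_tract_filter"))
  amp <- vt$gain * .cascade_mag(freq, vt$r, vt$theta, vt$sample_rate)
  structure(data.frame(freq_hz = freq, amplitude = amp),
            window_meta = list(kind = "transfer_function"),
            class = c("spectral_density", "data.frame"))
}

#' Filter a signal through the vocal tract
#'
#' Runs the source through the resonator cascade (stable recursive biquads,
#' unity gain at DC per section) and, optionally, a first-difference lip
#' radiation stage (+6 dB/octave), the standard source-filter radiation
#' characteristic.
#'
#' @param source An [acoustic_signal()] or numeric vector.
#' @param vt A [vocal_tract_filter()].
#' @param lip_radiation Apply the first-difference radiation stage?
#' @return Same type as `source`, filtered.
#' @export
apply_vocal_tract <- function(source, vt, lip_radiation = FALSE) {
  stopifnot(inherits(vt, "vocal_tract_filter"))
  x <- if (inherits(source, "acoustic_signal")) source$samples else source
  if (inherits(source, "acoustic_signal") &&
      source$sample_rate != vt$sample_rate) {
    stop("source and filter sample rates differ")
  }
  if (any(!is.finite(x))) stop("source must be finite")
  for (k in seq_along(vt$r)) {
    b0 <- 1 - 2 * vt$r[k] * cos(vt$theta[k]) + vt$r[k]^2
    y <- stats::filter(b0 * x,
                       c(2 * vt$r[k] * cos(vt$theta[k]), -vt$r[k]^2),
                       method = "recursive")
    x <- as.numeric(y)
  }
  if (lip_radiation) x <- c(x[1], diff(x))
  x <- vt$gain * x
  if (inherits(source, "acoustic_signal")) {
    out <- source
    out$samples <- x
    out$label <- paste0(source$label, "+vt")
    out
  } else x
}

#' Spherical-spreading radiation between microphone distances
#'
#' Rescales a pressure signal from one distance to another under free-field
#' spherical spreading (amplitude proportional to 1/r): the amplitude is
#' multiplied by `from_distance / to_distance`.
#'
#' @param signal An [acoustic_signal()].
#' @param to_distance Target distance in m.
#' @param from_distance Source distance in m; defaults to the signal's
#'   `mic_distance`.
#' @param label Label of the new microphone.
#' @return An [acoustic_signal()] at `to_distance`.
#' @export
#' @examples
#' s <- acoustic_signal(sin(2 * pi * 148 * (0:999) / 44100), 44100, 0.08)
#' radiate(s, 0.20)  # amplitude x 0.4
radiate <- function(signal, to_distance, from_distance = signal$mic_distance,
                    label = sprintf("mic@%gcm", 100 * to_distance)) {
  stopifnot(inherits(signal, "acoustic_signal"))
  if (to_distance <= 0 || from_distance <= 0) {
    stop("distances must be positive")
  }
  acoustic_signal(signal$samples * from_distance / to_distance,
                  signal$sample_rate, to_distance, label)
}
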