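#' Amplitude spectral density (Welch average)
#'
#' One-sided amplitude spectral density in Pa/sqrt(Hz), computed by Welch
#' averaging of Hann-windowed segments with 50% overlap. The segment length
#' defaults to four fundamental periods so that harmonics of `f0` fall on (or
#' next to) bin centres. The underlying power spectral density is scaled so
#' that `sum(asd^2) * df` recovers the signal power (Parseval) for stationary
#' signals.
#'
#' @param signal An [acoustic_signal()].
#' @param segment_cycles Segment length in fundamental periods (used with
#'   `f0`); ignored when `segment_samples` is given.
#' @param f0 Fundamental frequency in Hz used to size segments.
#' @param segment_samples Explicit segment length in samples (optional).
#' @return A `spectral_density`-classed data.frame with `freq_hz` and
#'   `amplitude` (Pa/sqrt(Hz)); attribute `window_meta` records the analysis
#'   parameters.
#' @export
compute_asd <- function(signal, segment_cycles = 4, f0 = 148,
                        segment_samples = NULL) {
  stopifnot(inherits(signal, "acoustic_signal"))
  fs <- signal$sample_rate
  x <- signal$samples
  L <- segment_samples %||% round(segment_cycles * fs / f0)
  if (length(x) < L) stop("signal shorter than one analysis segment")
  hop <- floor(L / 2)
  starts <- seq(1, length(x) - L + 1, by = hop)
  w <- .hann(L)
  U <- sum(w^2)
  acc <- numeric(floor(L / 2) + 1)
  for (s in starts) {
    X <- stats::fft(x[s:(s + L - 1)] * w)[seq_along(acc)]
    acc <- acc + Mod(X)^2
  }
  psd <- acc / length(starts) / (fs * U)
  # one-sided: double all bins except DC and (for even L) Nyquist
  scale2 <- rep(2, length(acc))
  scale2[1] <- 1
  if (L %% 2 == 0) scale2[length(acc)] <- 1
  psd <- psd * scale2
  freq <- (seq_along(acc) - 1) * fs / L
  structure(data.frame(freq_hz = freq, amplitude = sqrt(psd)),
            window_meta = list(window = "hann", segment_samples = L,
                               overlap = 0.5, n_segments = length(starts),
                               df_hz = fs / L),
            class = c("spectral_density", "data.frame"))
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' @export
print.spectral_density <- function(x, ...) {
  meta <- attr(x, "window_meta")
  cat(sprintf("<spectral_density>  %d bins, df = %.3g Hz (%s)\n",
              nrow(x), x$freq_hz[2] - x$freq_hz[1],
              meta$kind %||% sprintf("welch, %d segs", meta$n_segments)))
  invisible(x)
}

#' Frequency of the dominant spectral peak
#'
#' @param asd A `spectral_density`.
#' @param fmax Restrict the search to frequencies below `fmax` (Hz).
#' @param fmin Exclude bins below `fmin` (Hz) to skip DC leakage.
#' @return Peak frequency in Hz (bin centre).
#' @export
dominant_peak <- function(asd, fmax = Inf, fmin = 0) {
  sel <- asd$freq_hz <= fmax & asd$freq_hz >= fmin
  asd$freq_hz[sel][which.max(asd$amplitude[sel])]
}

#' Sound pressure level
#'
#' `SPL = 20 log10(rms(p) / p_ref)` in dB re 20 uPa.
#'
#' @param signal An [acoustic_signal()] or numeric pressure vector in Pa.
#' @param p_ref Reference pressure in Pa.
#' @return SPL in dB; `-Inf` with a warning for an all-zero signal.
#' @export
#' @examples
#' compute_spl(acoustic_signal(rep(2e-5 * sqrt(2), 100) *
#'                             sin(2 * pi * (1:100) / 10 + 0.3), 44100))
compute_spl <- function(signal, p_ref = 20e-6) {
  x <- if (inherits(signal, "acoustic_signal")) signal$samples else signal
  if (length(x) == 0) stop("empty signal")
  r <- sqrt(mean(x^2))
  if (r == 0) {
    warning("all-zero signal: SPL undefined (-Inf)")
    return(-Inf)
  }
  20 * log10(r / p_ref)
}

#' Vocal efficiency
#'
#' Ratio of radiated acoustic power to aerodynamic power,
#' `VE = P_r / P_a = 4 pi R^2 * 10^((SPL - 120) / 10) / (P_sub * Qbar)`,
#' where the radiated power assumes spherical spreading from a point source
#' (reference intensity 1e-12 W/m^2 at 0 dB) and the aerodynamic power is the
#' subglottal pressure times the cycle-mean flow.
#'
#' @param spl Sound pressure level in dB re 20 uPa at distance `mic_distance`.
#' @param mic_distance Microphone distance R in m.
#' @param p_sub Subglottal pressure in Pa.
#' @param q_mean Mean volume flow in m^3/s.
#' @return List with `ve` (dimensionless), `ve_percent`, `P_r_W`, `P_a_W`.
#' @export
#' @examples
#' vocal_efficiency(120, 1, 1000, 1e-3)$ve  # 4*pi
vocal_efficiency <- function(spl, mic_distance, p_sub, q_mean) {
  if (mic_distance <= 0) stop("mic_distance must be positive")
  if (p_sub <= 0 || q_mean <= 0) stop("p_sub and q_mean must be positive")
  p_r <- 4 * pi * mic_distance^2 * 10^((spl - 120) / 10)
  p_a <- p_sub * q_mean
  ve <- p_r / p_a
  list(ve = ve, ve_percent = 100 * ve, P_r_W = p_r, P_a_W = p_a)
}

#' Cepstral peak prominence
#'
#' Hillenbrand-style CPP: the signal is cut into Hann-windowed frames
#' (default 40 ms, 50% overlap); for each frame the power cepstrum of the log
#' power spectrum is computed, a linear regression of the cepstrum (in dB)
#' against quefrency is fitted over `regression_ms`, and the CPP of the frame
#' is the height of the cepstral peak inside the fundamental-period search
#' band above the regression line at that quefrency. The mean over frames is
#' returned. Both log transforms are floored 200 dB below their in-frame
#' peak so that exact spectral zeros cannot dominate the cepstrum.
#'
#' @param signal An [acoustic_signal()].
#' @param f0_search Fundamental-frequency search interval in Hz; the cepstral
#'   peak is sought at quefrencies `1/f0_search`.
#' @param frame_ms Frame length in ms.
#' @param overlap Frame overlap fraction.
#' @param regression_ms Quefrency range (ms) for the regression line.
#' @return CPP in dB, with per-frame values in attribute `frames` and a
#'   `low_confidence` attribute flagging frames whose band maximum is not a
#'   local peak.
#' @export
compute_cpp <- function(signal, f0_search = c(60, 300), frame_ms = 40,
                        overlap = 0.5, regression_ms = c(1, 15)) {
  stopifnot(inherits(signal, "acoustic_signal"))
  fs <- signal$sample_rate
  if (f0_search[1] <= 20 || f0_search[2] >= fs / 4) {
    stop("f0_search must lie within (20 Hz, sample_rate/4)")
  }
  L <- round(frame_ms / 1000 * fs)
  hop <- max(1, round(L * (1 - overlap)))
  x <- signal$samples
  if (length(x) < L + 3 * hop) {
    stop("signal must cover at least 4 analysis frames")
  }
  starts <- seq(1, length(x) - L + 1, by = hop)
  w <- .hann(L)
  quef <- (seq_len(L) - 1) / fs
  reg_sel <- quef >= regression_ms[1] / 1000 & quef <= regression_ms[2] / 1000
  band <- quef >= 1 / f0_search[2] & quef <= 1 / f0_search[1]
  if (!any(band)) stop("no quefrency bins inside the f0 search band")
  vals <- numeric(length(starts))
  lowconf <- logical(length(starts))
  for (i in seq_along(starts)) {
    fr <- x[starts[i]:(starts[i] + L - 1)] * w
    pw <- Mod(stats::fft(fr))^2
    if (max(pw) == 0) next                     # silent frame: CPP 0
    # floor the log spectra 200 dB below their peaks: exact spectral zeros
    # would otherwise dominate the cepstrum through the log
    log_spec <- 10 * log10(pmax(pw, max(pw) * 1e-20))
    cp <- Mod(stats::fft(log_spec))^2
    cep_db <- 10 * log10(pmax(cp, max(cp) * 1e-20))
    fit <- stats::lm.fit(cbind(1, quef[reg_sel]), cep_db[reg_sel])
    ipk <- which(band)[which.max(cep_db[band])]
    # peak must be a local maximum within the band; otherwise low confidence
    lowconf[i] <- ipk > 1 && ipk < L &&
      !(cep_db[ipk] >= cep_db[ipk - 1] && cep_db[ipk] >= cep_db[ipk + 1])
    trend <- fit$coefficients[1] + fit$coefficients[2] * quef[ipk]
    vals[i] <- cep_db[ipk] - trend
  }
  structure(mean(vals), frames = vals, low_confidence = any(lowconf))
}

#' Extract formant frequencies from a spectral density
#'
#' Finds the `n_formants` lowest-frequency local maxima of the (optionally
#' smoothed) log-amplitude spectrum whose prominence exceeds a threshold.
#' Each peak is refined by the classic three-point parabolic vertex through
#' the maximum and its two neighbours, which removes most of the bin
#' quantisation without being biased by the skirts of neighbouring
#' resonances. The default prominence of 1 dB accommodates closely spaced
#' formants (F1/F2 of /a/ are separated by a saddle of only about 1.5 dB).
#'
#' @param asd A `spectral_density` ([compute_asd()] or
#'   [vt_frequency_response()] output).
#' @param n_formants Number of formants requested.
#' @param prominence_db Minimum peak prominence in dB.
#' @param smooth_bins Half-width (bins) of the moving-average smoother applied
#'   to the log spectrum before peak picking (0 disables).
#' @param fmax Search ceiling in Hz.
#' @return Numeric vector of formant frequencies (ascending). If fewer peaks
#'   than requested are found, the found ones are returned with a warning.
#' @export
extract_formants <- function(asd, n_formants = 2, prominence_db = 1,
                             smooth_bins = 2, fmax = 4000) {
  stopifnot(inherits(asd, "spectral_density"))
  sel <- asd$freq_hz <= fmax & asd$freq_hz > 0
  f <- asd$freq_hz[sel]
  a_db <- 20 * log10(pmax(asd$amplitude[sel], .Machine$double.xmin))
  s_db <- if (smooth_bins > 0) .movavg(a_db, smooth_bins) else a_db
  pk <- .find_peaks(s_db, prominence_db)
  if (length(pk) == 0) {
    warning("no spectral peaks above the prominence threshold")
    return(numeric(0))
  }
  pk <- utils::head(sort(pk), n_formants)
  if (length(pk) < n_formants) {
    warning(sprintf("only %d of %d requested formants found",
                    length(pk), n_formants))
  }
  df <- f[2] - f[1]
  out <- vapply(pk, function(i) {
    if (i <= 1 || i >= length(f)) return(f[i])
    denom <- s_db[i - 1] - 2 * s_db[i] + s_db[i + 1]
    if (denom >= 0) return(f[i])
    delta <- 0.5 * (s_db[i - 1] - s_db[i + 1]) / denom
    f[i] + max(-0.5, min(0.5, delta)) * df
  }, numeric(1))
  sort(out)
}

.movavg <- function(x, hw) {
  k <- 2 * hw + 1
  y <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  y[is.na(y)] <- x[is.na(y)]
  y
}

# indices of local maxima with simple prominence (height above the higher of
# the two flanking minima reached before a taller sample)
.find_peaks <- function(x, min_prom) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  keep <- vapply(cand, function(i) {
    left <- x[1:i]; right <- x[i:n]
    hl <- which(left > x[i]); hr <- which(right > x[i])
    lmin <- min(left[if (length(hl)) (max(hl) + 1):i else 1:i])
    rmin <- min(right[if (length(hr)) 1:(min(hr) - 1) else seq_along(right)])
    x[i] - max(lmin, rmin) >= min_prom
  }, logical(1))
  cand[keep]
}

#' Open and speed quotients of a GAW
#'
#' `OQ` is the fraction of the cycle during which the glottal area exceeds
#' `A_min + threshold * (A_max - A_min)`; `SQ` is the duration of the opening
#' phase (onset to peak) divided by the closing phase (peak to offset) within
#' the open interval.
#'
#' @param gaw An `area_waveform`.
#' @param threshold Open threshold as a fraction of the cycle amplitude, in
#'   `[0, 0.2]`.
#' @return List with `oq` and `sq`.
#' @export
#' @examples
#' gaw_quotients(baseline_gaw())  # OQ 0.8, SQ ~ 0.48
gaw_quotients <- function(gaw, threshold = 0) {
  stopifnot(inherits(gaw, "area_waveform"))
  if (threshold < 0 || threshold > 0.2) stop("threshold must be in [0, 0.2]")
  a <- gaw$area_mm2
  amin <- min(a); amax <- max(a)
  if (amax - amin <= 0) stop("constant waveform: quotients undefined")
  thr <- amin + threshold * (amax - amin)
  open <- a > thr
  oq <- mean(open)
  idx <- which(open)
  ipk <- which.max(a)
  t_open <- gaw$phase[idx[1]]
  t_close <- gaw$phase[idx[length(idx)]]
  sq <- (gaw$phase[ipk] - t_open) / (t_close - gaw$phase[ipk])
  list(oq = oq, sq = sq)
}
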