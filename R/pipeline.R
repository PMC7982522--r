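#' Global simulation configuration
#'
#' Collects the physical constants and resolution settings shared by all
#' cases. Defaults reproduce the study conditions: 148 Hz fundamental, 775 Pa
#' driving pressure, 4.66 mm maximum symmetric glottal width, 15 mm fold
#' length, microphones 5 and 8 cm from the mouth with SPL/efficiency reported
#' at 20 cm, and 10 initialization plus 10 analysis cycles.
#'
#' `n_cpp_cycles` controls the length of the signal handed to the cepstral
#' analysis: the 40 ms CPP frames need several hundred milliseconds of audio,
#' so more cycles are synthesized for that metric than the 10 used for the
#' aerodynamic and spectral averages (synthesis is deterministic, so the extra
#' cycles carry no new information beyond the added aspiration noise).
#'
#' `noise_coefficient` scales the broadband aspiration-noise source that
#' models turbulence at the residual glottal gap: the noise RMS is
#' `noise_coefficient * rho/(4 pi r) * 2 pi f0 * Q_min`, i.e. proportional to
#' the leakage flow through the minimum opening. Larger residual gaps produce
#' breathier, less periodic signals.
#'
#' @param frame A [larynx_frame()].
#' @param cond A [flow_conditions()].
#' @param f0 Fundamental frequency in Hz.
#' @param sample_rate Audio sample rate in Hz.
#' @param n_gaw_samples GAW samples per cycle.
#' @param n_stations Anterior-posterior stations of the motion field.
#' @param n_init_cycles Discarded start-up cycles.
#' @param n_analysis_cycles Cycles analyzed for SPL/ASD.
#' @param n_cpp_cycles Cycles synthesized for the cepstral analysis.
#' @param noise_coefficient Aspiration-noise coefficient (dimensionless).
#' @param mic1_m,mic2_m Microphone distances in m.
#' @param spl_distance_m Distance SPL/efficiency are reported at, in m.
#' @param p_sub Subglottal pressure used in the vocal-efficiency ratio, Pa.
#' @param formants,bandwidths Vocal-tract resonance parameters in Hz.
#' @param lip_radiation Apply the +6 dB/octave radiation stage?
#' @return A named list of class `phonosim_config`.
#' @export
phonosim_config <- function(frame = larynx_frame(), cond = flow_conditions(),
                            f0 = 148, sample_rate = 44100,
                            n_gaw_samples = 2048, n_stations = 128,
                            n_init_cycles = 10, n_analysis_cycles = 10,
                            n_cpp_cycles = 256, noise_coefficient = 0.25,
                            mic1_m = 0.05, mic2_m = 0.08,
                            spl_distance_m = 0.20, p_sub = cond$p_inlet,
                            formants = c(1020, 1350),
                            bandwidths = c(130, 160), lip_radiation = FALSE) {
  structure(list(frame = frame, cond = cond, f0 = f0,
                 sample_rate = sample_rate, n_gaw_samples = n_gaw_samples,
                 n_stations = n_stations, n_init_cycles = n_init_cycles,
                 n_analysis_cycles = n_analysis_cycles,
                 n_cpp_cycles = n_cpp_cycles,
                 noise_coefficient = noise_coefficient,
                 mic1_m = mic1_m, mic2_m = mic2_m,
                 spl_distance_m = spl_distance_m, p_sub = p_sub,
                 formants = formants, bandwidths = bandwidths,
                 lip_radiation = lip_radiation),
            class = "phonosim_config")
}

#' Specification of one simulated case
#'
#' @param gc `"GC1"` ... `"GC5"`.
#' @param symmetry `"symmetric"` or `"asymmetric"`.
#' @param amplitude_factor_reduced Amplitude factor of the reduced (upper)
#'   fold in the asymmetric case (default 0.5).
#' @param seed Integer seed for the stochastic aspiration noise.
#' @return A list of class `case_spec` with a stable `label` such as
#'   `"GC3-asym"`.
#' @export
case_spec <- function(gc, symmetry = c("symmetric", "asymmetric"),
                      amplitude_factor_reduced = 0.5, seed = 1L) {
  symmetry <- match.arg(symmetry)
  if (amplitude_factor_reduced <= 0 || amplitude_factor_reduced > 1) {
    stop("amplitude_factor_reduced must be in (0, 1]")
  }
  structure(list(gc = gc, symmetry = symmetry,
                 amplitude_factor_reduced = amplitude_factor_reduced,
                 seed = as.integer(seed),
                 label = paste0(gc, "-", substr(symmetry, 1, 3))),
            class = "case_spec")
}

#' The ten canonical study cases
#'
#' GC1-GC5 crossed with symmetric and asymmetric vocal-fold motion. The two
#' symmetry variants of each closure type share a noise seed (common random
#' numbers), so the symmetric/asymmetric contrast isolates the motion
#' asymmetry from the aspiration-noise realization.
#'
#' @param seed Base seed; closure type `GCi` uses `seed + i - 1` for both
#'   symmetry variants.
#' @return List of ten [case_spec()] objects.
#' @export
canonical_cases <- function(seed = 1L) {
  specs <- list()
  i <- 0L
  for (gi in 1:5) {
    for (sym in c("symmetric", "asymmetric")) {
      i <- i + 1L
      specs[[i]] <- case_spec(paste0("GC", gi), sym, seed = seed + gi - 1L)
    }
  }
  names(specs) <- vapply(specs, `[[`, "", "label")
  specs
}

# area_waveform carrying the asymmetry-scaled GAW implied by a motion field
.motion_gaw <- function(motion) {
  structure(data.frame(phase = motion$phase, area_mm2 = motion$gaw_mm2),
            f0 = motion$f0, A_max = max(motion$gaw_mm2),
            A_min = min(motion$gaw_mm2),
            darea_dphase = motion$gaw_darea_dphase,
            class = c("area_waveform", "data.frame"))
}

#' Run one case end to end
#'
#' Executes geometry, kinematics, flow, energy transfer, acoustic synthesis,
#' and the metric layer for a single case. Deterministic given the case
#' specification and configuration (the aspiration noise is seeded from
#' `spec$seed`; the global RNG state is restored on exit).
#'
#' @param spec A [case_spec()].
#' @param config A [phonosim_config()].
#' @param keep_series Attach intermediate series (`gaw`, `motion`, `flow`,
#'   `energy`, `signals`) to the report?
#' @return A list of class `metrics_report` with fields `case_label`,
#'   `q_mean_l_s`, `r_glottis_Pa_s_l`, `w_net_J`, `spl_db`, `ve`,
#'   `ve_percent`, `cpp_db`, `f0_detected_hz`, `formants_hz`, `oq`, `sq`,
#'   `a_min_mm2`, `a_max_mm2`.
#' @export
#' @examples
#' \donttest{
#' rep1 <- run_case(case_spec("GC1"), phonosim_config(n_cpp_cycles = 24))
#' rep1$q_mean_l_s
#' }
run_case <- function(spec, config = phonosim_config(), keep_series = FALSE) {
  stopifnot(inherits(spec, "case_spec"))
  frame <- config$frame
  gc <- make_gc(spec$gc, frame = frame)
  base <- baseline_gaw(config$f0, reference_a0max(frame),
                       config$n_gaw_samples)
  gaw <- modify_gaw(base, gc)
  factors <- if (spec$symmetry == "asymmetric") {
    c(spec$amplitude_factor_reduced, 1)   # upper fold reduced
  } else c(1, 1)
  motion <- build_motion(gaw, frame, gc, factors, config$n_stations)
  gaw_eff <- .motion_gaw(motion)
  flow <- solve_flow(gaw_eff, config$cond)
  energy <- energy_transfer(motion, flow)
  q_mean_ls <- attr(flow, "Q_mean_l_s")
  r_glottis <- glottal_resistance(flow)

  fs <- config$sample_rate
  n_total <- config$n_init_cycles + max(config$n_analysis_cycles,
                                        config$n_cpp_cycles)
  src <- source_signal(flow, n_total, fs, r_ref = 1, rho = config$cond$rho)
  # seeded aspiration noise proportional to the leakage flow
  q_min <- min(flow$Q_m3_s)
  n_rms <- config$noise_coefficient * config$cond$rho / (4 * pi) *
    2 * pi * config$f0 * q_min
  if (n_rms > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()), add = TRUE)
    set.seed(spec$seed)
    src$samples <- src$samples + stats::rnorm(length(src$samples), 0, n_rms)
  }
  vt <- vocal_tract_filter(config$formants, config$bandwidths, fs)
  mouth <- apply_vocal_tract(src, vt, lip_radiation = config$lip_radiation)

  skip <- floor(config$n_init_cycles * fs / config$f0)
  steady <- mouth
  steady$samples <- mouth$samples[(skip + 1):length(mouth$samples)]
  n_an <- floor(config$n_analysis_cycles * fs / config$f0)
  analysis <- steady
  analysis$samples <- steady$samples[seq_len(min(n_an, length(steady$samples)))]

  mic1 <- radiate(analysis, config$mic1_m, from_distance = 1, label = "Mic.1")
  mic2 <- radiate(analysis, config$mic2_m, from_distance = 1, label = "Mic.2")
  far <- radiate(mic2, config$spl_distance_m)
  far_long <- radiate(steady, config$spl_distance_m, from_distance = 1,
                      label = sprintf("mic@%gcm", 100 * config$spl_distance_m))

  asd1 <- compute_asd(mic1, f0 = config$f0)
  f0_detected <- dominant_peak(asd1, fmax = 500, fmin = 50)
  spl <- compute_spl(far)
  ve <- vocal_efficiency(spl, config$spl_distance_m, config$p_sub,
                         attr(flow, "Q_mean_m3_s"))
  cpp <- compute_cpp(far_long)
  quot <- gaw_quotients(gaw_eff)

  rep <- structure(list(
    case_label = spec$label, gc = spec$gc, symmetry = spec$symmetry,
    q_mean_l_s = q_mean_ls, r_glottis_Pa_s_l = r_glottis,
    w_net_J = energy$W_net_J, spl_db = spl,
    ve = ve$ve, ve_percent = ve$ve_percent, cpp_db = as.numeric(cpp),
    f0_detected_hz = f0_detected, formants_hz = vt$peaks_hz,
    oq = quot$oq, sq = quot$sq,
    a_min_mm2 = attr(gaw_eff, "A_min"), a_max_mm2 = attr(gaw_eff, "A_max"),
    cpp_low_confidence = attr(cpp, "low_confidence")),
    class = "metrics_report")
  if (keep_series) {
    rep$series <- list(gaw = gaw, motion = motion, flow = flow,
                       energy = energy,
                       signals = list(mic1 = mic1, mic2 = mic2, far = far,
                                      far_long = far_long))
  }
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report %s>\n", x$case_label))
  cat(sprintf("  Q_mean     %.3f l/s     R_glottis  %.1f Pa.s/l\n",
              x$q_mean_l_s, x$r_glottis_Pa_s_l))
  cat(sprintf("  W_net      %.1f uJ      SPL(20cm)  %.1f dB\n",
              1e6 * x$w_net_J, x$spl_db))
  cat(sprintf("  VE         %.4f %%      CPP        %.1f dB\n",
              x$ve_percent, x$cpp_db))
  cat(sprintf("  f0 peak    %.1f Hz     formants   %s Hz\n",
              x$f0_detected_hz, paste(round(x$formants_hz), collapse = ", ")))
  cat(sprintf("  OQ %.2f  SQ %.2f  A_min %.2f mm^2  A_max %.2f mm^2\n",
              x$oq, x$sq, x$a_min_mm2, x$a_max_mm2))
  invisible(x)
}

#' Run a study over several cases
#'
#' Runs [run_case()] for each specification, collects a per-case metric table,
#' and evaluates the directional trends expected under increasing glottal
#' insufficiency and left-right asymmetry. Per-case failures are recorded and
#' the study continues.
#'
#' @param cases List of [case_spec()] (default: the ten canonical cases).
#' @param config A [phonosim_config()].
#' @return A list of class `study_report` with `reports`, `table`
#'   (data.frame), `trends` (named logical, `NA` when a comparison is not
#'   applicable), `errors`, and a `provenance` block (config hash, package
#'   version, timestamp).
#' @export
run_study <- function(cases = canonical_cases(), config = phonosim_config()) {
  if (length(cases) == 0) stop("empty case list")
  reports <- list()
  errors <- list()
  for (cs in cases) {
    res <- tryCatch(run_case(cs, config), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[cs$label]] <- conditionMessage(res)
    } else {
      reports[[cs$label]] <- res
    }
  }
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(case = r$case_label, gc = r$gc, symmetry = r$symmetry,
               q_mean_l_s = r$q_mean_l_s,
               r_glottis_Pa_s_l = r$r_glottis_Pa_s_l,
               w_net_uJ = 1e6 * r$w_net_J, spl_db = r$spl_db,
               ve_percent = r$ve_percent, cpp_db = r$cpp_db,
               f0_hz = r$f0_detected_hz, oq = r$oq, sq = r$sq)
  }))
  rownames(tab) <- NULL
  trends <- .study_trends(tab)
  structure(list(reports = reports, table = tab, trends = trends,
                 errors = errors,
                 provenance = list(config_hash = config_hash(config),
                                   package_version =
                                     as.character(utils::packageVersion("phonosim")),
                                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "study_report")
}

.study_trends <- function(tab) {
  gc_order <- paste0("GC", 1:5)
  get <- function(sym, col) {
    s <- tab[tab$symmetry == sym, ]
    s <- s[match(gc_order, s$gc), col]
    s
  }
  pairwise <- function(col, cmp) {
    a <- get("symmetric", col); b <- get("asymmetric", col)
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(NA)
    all(cmp(b[ok], a[ok]))
  }
  inc <- function(x) if (any(is.na(x))) NA else all(diff(x) > 0)
  dec <- function(x) if (any(is.na(x))) NA else all(diff(x) < 0)
  c(q_increasing_sym = inc(get("symmetric", "q_mean_l_s")),
    q_increasing_asym = inc(get("asymmetric", "q_mean_l_s")),
    q_asym_below_sym = pairwise("q_mean_l_s", `<`),
    r_decreasing_sym = dec(get("symmetric", "r_glottis_Pa_s_l")),
    r_asym_above_sym = pairwise("r_glottis_Pa_s_l", `>`),
    w_net_decreasing_sym = dec(get("symmetric", "w_net_uJ")),
    w_net_asym_below_sym = pairwise("w_net_uJ", `<`),
    w_net_positive = if (nrow(tab)) all(tab$w_net_uJ > 0) else NA,
    spl_gc1_above_gc5_sym = {
      s <- get("symmetric", "spl_db")
      if (is.na(s[1]) || is.na(s[5])) NA else s[1] > s[5]
    },
    ve_decreasing_sym = dec(get("symmetric", "ve_percent")),
    cpp_decreasing_sym = dec(get("symmetric", "cpp_db")),
    cpp_asym_at_most_sym = pairwise("cpp_db", `<=`))
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report>  %d cases, %d errors\n",
              nrow(x$table), length(x$errors)))
  print(x$table, digits = 4)
  cat("trends:\n")
  for (nm in names(x$trends)) {
    cat(sprintf("  %-22s %s\n", nm, x$trends[[nm]]))
  }
  invisible(x)
}

#' Hash a configuration for provenance records
#'
#' MD5 of the deparsed configuration (written through a temporary file, since
#' base R hashes files, not strings).
#'
#' @param config Any R object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config, control = "all"), tf)
  unname(tools::md5sum(tf))
}

#' Write a study report to disk
#'
#' Writes the per-case metric table as CSV and the full report (table, trends,
#' errors, provenance) as JSON.
#'
#' @param study A [run_study()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "study_metrics.csv")
  jsn <- file.path(dir, "study_report.json")
  utils::write.csv(study$table, csv, row.names = FALSE)
  jsonlite::write_json(list(table = study$table,
                            trends = as.list(study$trends),
                            errors = study$errors,
                            provenance = study$provenance),
                       jsn, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv, json = jsn))
}

#' Synthetic test signals
#'
#' Reproducible fixture generator for the metric layer.
#'
#' * `sine`: pure tone (`freq`, `amp`).
#' * `pulse_train`: unit impulses at the fundamental period (`freq`, `amp`).
#' * `white_noise`: Gaussian noise (`sd`).
#' * `noisy_harmonic`: harmonic stack (`freq`, `n_harmonics`, 1/k amplitude
#'   roll-off) plus white noise at `snr_db`.
#'
#' @param kind One of `"sine"`, `"pulse_train"`, `"white_noise"`,
#'   `"noisy_harmonic"`.
#' @param params Named list of parameters (see Details); all optional.
#' @param seed Integer seed for the stochastic kinds.
#' @param duration_s Signal duration in s.
#' @param sample_rate Sample rate in Hz.
#' @return An [acoustic_signal()].
#' @export
#' @examples
#' make_fixture("sine", list(freq = 148, amp = 1), duration_s = 0.1)
make_fixture <- function(kind, params = list(), seed = 1L, duration_s = 1,
                         sample_rate = 44100) {
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  freq <- params$freq %||% 148
  amp <- params$amp %||% 1
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(seed)
  x <- switch(kind,
    sine = amp * sin(2 * pi * freq * t),
    pulse_train = {
      x <- numeric(n)
      x[round(seq(1, n, by = sample_rate / freq))] <- amp
      x
    },
    white_noise = stats::rnorm(n, 0, params$sd %||% 1),
    noisy_harmonic = {
      nh <- params$n_harmonics %||% 10
      h <- Reduce(`+`, lapply(seq_len(nh), function(k) {
        amp / k * sin(2 * pi * k * freq * t)
      }))
      snr <- params$snr_db %||% 20
      noise_sd <- sqrt(mean(h^2)) / 10^(snr / 20)
      h + stats::rnorm(n, 0, noise_sd)
    },
    stop("unknown fixture kind: ", kind))
  acoustic_signal(x, sample_rate, mic_distance = params$mic_distance %||% 1,
                  label = kind)
}
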