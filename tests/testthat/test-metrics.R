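test_that("ASD peaks at the tone frequency and respects Parseval", {
  s <- make_fixture("sine", list(freq = 148, amp = 0.8), duration_s = 0.5)
  asd <- compute_asd(s, f0 = 148)
  df <- attr(asd, "window_meta")$df_hz
  expect_lt(abs(dominant_peak(asd) - 148), df)
  # integrated one-sided PSD recovers the sine power a^2/2
  power <- sum(asd$amplitude^2) * df
  expect_lt(abs(power - 0.8^2 / 2) / (0.8^2 / 2), 0.05)
  # frequency resolution at least f0/4
  expect_lte(df, 148 / 4 + 1e-9)
})

test_that("ASD of broadband noise satisfies Parseval within 5%", {
  s <- make_fixture("white_noise", list(sd = 0.3), seed = 11, duration_s = 1)
  asd <- compute_asd(s, segment_samples = 2048)
  df <- attr(asd, "window_meta")$df_hz
  power <- sum(asd$amplitude^2) * df
  expect_lt(abs(power - mean(s$samples^2)) / mean(s$samples^2), 0.05)
})

test_that("ASD handles degenerate input", {
  z <- acoustic_signal(rep(0, 4410), 44100)
  expect_equal(max(compute_asd(z, f0 = 148)$amplitude), 0)
  short <- acoustic_signal(rep(1, 100), 44100)
  expect_error(compute_asd(short, f0 = 148), "shorter")
})

test_that("SPL follows the logarithmic level law", {
  n <- 44100
  t <- (0:(n - 1)) / 44100
  ref <- acoustic_signal(20e-6 * sqrt(2) * sin(2 * pi * 100 * t), 44100)
  expect_equal(compute_spl(ref), 0, tolerance = 1e-4)
  one <- acoustic_signal(sin(2 * pi * 100 * t), 44100)
  expect_equal(compute_spl(one), 20 * log10(sqrt(0.5) / 2e-5),
               tolerance = 1e-6)   # ~90.97 dB
  ten <- acoustic_signal(10 * sin(2 * pi * 100 * t), 44100)
  expect_equal(compute_spl(ten) - compute_spl(one), 20, tolerance = 1e-8)
  expect_warning(z <- compute_spl(acoustic_signal(rep(0, 10), 44100)),
                 "undefined")
  expect_identical(z, -Inf)
})

test_that("vocal efficiency implements the radiated/aerodynamic power ratio", {
  ve <- vocal_efficiency(120, 1, 1000, 1e-3)
  expect_equal(ve$P_r_W, 4 * pi)
  expect_equal(ve$P_a_W, 1)
  expect_equal(ve$ve, 4 * pi)
  expect_equal(vocal_efficiency(110, 1, 1000, 1e-3)$ve, 0.4 * pi)
  expect_equal(vocal_efficiency(120, 2, 1000, 1e-3)$ve, 16 * pi)
  expect_error(vocal_efficiency(100, 1, -5, 1e-3), "positive")
  expect_error(vocal_efficiency(100, 1, 1000, 0), "positive")
})

test_that("CPP separates periodic from aperiodic signals", {
  pulses <- make_fixture("pulse_train", list(freq = 148), duration_s = 0.6)
  harm <- make_fixture("noisy_harmonic", list(snr_db = 60), seed = 5,
                       duration_s = 0.6)
  noisy <- make_fixture("noisy_harmonic", list(snr_db = 0), seed = 5,
                        duration_s = 0.6)
  noise <- make_fixture("white_noise", list(sd = 1), seed = 6,
                        duration_s = 0.6)
  cpp_p <- compute_cpp(pulses)
  cpp_h <- compute_cpp(harm)
  cpp_n0 <- compute_cpp(noisy)
  cpp_w <- compute_cpp(noise)
  expect_gt(cpp_p, cpp_n0)
  expect_gt(cpp_h, cpp_n0)
  expect_gt(cpp_n0, cpp_w)
  expect_error(compute_cpp(make_fixture("sine", duration_s = 0.01)), "frames")
})

test_that("CPP decreases monotonically as noise drowns the harmonics", {
  # 10-point sweep through the SNR range where the cepstral peak responds
  # (CPP saturates both for nearly clean and for noise-dominated signals)
  snrs <- seq(21, -6, by = -3)
  cpps <- vapply(snrs, function(s) {
    as.numeric(compute_cpp(make_fixture("noisy_harmonic", list(snr_db = s),
                                        seed = 17, duration_s = 2)))
  }, numeric(1))
  expect_true(all(diff(cpps) < 0))
})

test_that("CPP agrees with a direct-DFT cepstrum oracle", {
  s <- make_fixture("pulse_train", list(freq = 148), duration_s = 0.3,
                    sample_rate = 16000)
  got <- as.numeric(compute_cpp(s))
  want <- oracle_cpp(s$samples, s$sample_rate)
  expect_lt(abs(got - want), 0.1)
  n <- make_fixture("noisy_harmonic", list(snr_db = 6), seed = 2,
                    duration_s = 0.3, sample_rate = 16000)
  expect_lt(abs(as.numeric(compute_cpp(n)) -
                oracle_cpp(n$samples, n$sample_rate)), 0.1)
})

test_that("formants are recovered from the filter response and from noise", {
  vt <- vocal_tract_filter()
  # analytic transfer function route
  expect_equal(extract_formants(vt_frequency_response(vt)), c(1020, 1350),
               tolerance = 2e-3)
  # white-noise-driven route at the Welch resolution (the F1/F2 saddle of
  # /a/ is only ~1.5 dB deep, so heavy segment averaging is needed)
  set.seed(8)
  x <- apply_vocal_tract(rnorm(30 * 44100), vt)
  asd <- compute_asd(acoustic_signal(x, 44100), segment_samples = 4096)
  df <- attr(asd, "window_meta")$df_hz
  f <- extract_formants(asd)
  expect_lt(abs(f[1] - 1020), df)
  expect_lt(abs(f[2] - 1350), df)
})

test_that("formant extraction handles sparse and flat spectra", {
  single <- vocal_tract_filter(500, 100)
  expect_warning(f <- extract_formants(vt_frequency_response(single), 2),
                 "only 1")
  expect_equal(f, 500, tolerance = 2e-3)
  flat <- structure(data.frame(freq_hz = seq(1, 4000, by = 4),
                               amplitude = rep(1, 1000)),
                    window_meta = list(kind = "flat"),
                    class = c("spectral_density", "data.frame"))
  expect_warning(f0 <- extract_formants(flat), "no spectral peaks")
  expect_length(f0, 0)
})

test_that("glottal quotients reflect the closure interval and skew", {
  q <- gaw_quotients(baseline_gaw(n_samples = 2000))
  expect_equal(q$oq, 0.8, tolerance = 2e-3)   # closed on [0.9 T, 0.1 T)
  expect_lt(q$sq, 1)                          # opening faster than closing
  # a sine never closes
  n <- 1000
  sine <- constant_gaw(1, n = n)
  sine$area_mm2 <- 10 + sin(2 * pi * sine$phase)
  attr(sine, "A_min") <- min(sine$area_mm2)
  attr(sine, "A_max") <- max(sine$area_mm2)
  expect_gt(gaw_quotients(sine)$oq, 1 - 3 / n)
  # time reversal inverts the speed quotient
  g <- baseline_gaw(n_samples = 2000)
  rev_g <- g
  rev_g$area_mm2 <- rev(g$area_mm2)
  sq_fwd <- gaw_quotients(g)$sq
  sq_rev <- gaw_quotients(rev_g)$sq
  expect_equal(sq_rev, 1 / sq_fwd, tolerance = 0.01)
  expect_error(gaw_quotients(constant_gaw(5)), "constant")
})
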