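# Shared fixtures for the test suite. Everything is generated in code.

# constant-area waveform (stationary glottis) on the standard phase grid
constant_gaw <- function(area_mm2 = 10, n = 512, f0 = 148) {
  structure(data.frame(phase = (seq_len(n) - 1) / n,
                       area_mm2 = rep(area_mm2, n)),
            f0 = f0, A_max = area_mm2, A_min = area_mm2,
            darea_dphase = rep(0, n),
            class = c("area_waveform", "data.frame"))
}

# the full ten-case study is reused by several files; computed once
study_cache <- local({
  st <- NULL
  function() {
    if (is.null(st)) st <<- run_study(canonical_cases(), phonosim_config())
    st
  }
})

# naive O(N^2) DFT, the independent oracle for FFT-based metrics
naive_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  W <- exp(-2i * pi * outer(k, k) / n)
  as.vector(W %*% x)
}

# independent cepstral-peak-prominence computation on explicit frames using
# the naive DFT and a hand-rolled least-squares line
oracle_cpp <- function(x, fs, frame_ms = 40, overlap = 0.5,
                       f0_search = c(60, 300), regression_ms = c(1, 15)) {
  L <- round(frame_ms / 1000 * fs)
  hop <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, length(x) - L + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
  quef <- (seq_len(L) - 1) / fs
  reg <- quef >= regression_ms[1] / 1000 & quef <= regression_ms[2] / 1000
  band <- quef >= 1 / f0_search[2] & quef <= 1 / f0_search[1]
  vals <- vapply(starts, function(s) {
    fr <- x[s:(s + L - 1)] * w
    pw <- Mod(naive_dft(fr))^2
    ls <- 10 * log10(pmax(pw, max(pw) * 1e-20))
    cpw <- Mod(naive_dft(ls))^2
    cep <- 10 * log10(pmax(cpw, max(cpw) * 1e-20))
    qx <- quef[reg]; cy <- cep[reg]
    slope <- sum((qx - mean(qx)) * (cy - mean(cy))) / sum((qx - mean(qx))^2)
    icpt <- mean(cy) - slope * mean(qx)
    i <- which(band)[which.max(cep[band])]
    cep[i] - (icpt + slope * quef[i])
  }, numeric(1))
  mean(vals)
}
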