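test_that("baseline GAW is closed on [0.9, 0.1) and peaks at A0max", {
  gaw <- baseline_gaw(n_samples = 1000)
  closed <- gaw$phase >= 0.9 | gaw$phase < 0.1
  expect_true(all(gaw$area_mm2[closed] == 0))
  expect_true(all(gaw$area_mm2 >= 0))
  expect_equal(max(gaw$area_mm2), reference_a0max(), tolerance = 1e-6)
  # peak before mid-cycle: opening shorter than closing (SQ < 1)
  expect_lt(gaw$phase[which.max(gaw$area_mm2)], 0.5)
  expect_error(baseline_gaw(f0 = -1), "positive")
  expect_error(baseline_gaw(A0max = 0), "positive")
  expect_error(baseline_gaw(n_samples = 8), "16")
})

test_that("baseline GAW refinement is consistent at shared phases", {
  g1 <- baseline_gaw(n_samples = 1024)
  g2 <- baseline_gaw(n_samples = 2048)
  shared <- match(g1$phase, g2$phase)
  expect_true(all(!is.na(shared)))
  expect_lt(max(abs(g1$area_mm2 - g2$area_mm2[shared])),
            1e-3 * reference_a0max())
})

test_that("the insufficiency modification is the documented affine map", {
  base <- baseline_gaw(n_samples = 512)
  a0max <- attr(base, "A_max")
  # closed form check: A0max = 40, Ai0 = 10, A0 = 20 -> 25
  expect_equal(10 + (40 - 10) / 40 * 20, 25)
  for (id in paste0("GC", 1:5)) {
    gc <- make_gc(id)
    mod <- modify_gaw(base, gc)
    expect_equal(attr(mod, "A_min"), gc$initial_gap_area)
    expect_equal(attr(mod, "A_max"), a0max)
    # pointwise affine in the baseline
    expect_equal(mod$area_mm2,
                 gc$initial_gap_area +
                   (a0max - gc$initial_gap_area) / a0max * base$area_mm2)
  }
  expect_error(modify_gaw(base, make_gc("GC3", list(initial_gap_area = 80))),
               "exceeds")
})

test_that("modification scales affinely for attenuated baselines", {
  base <- baseline_gaw(n_samples = 256)
  a0max <- attr(base, "A_max")
  gc <- make_gc("GC3")
  for (alpha in c(0.25, 0.5, 1)) {
    scaled <- base
    scaled$area_mm2 <- alpha * base$area_mm2
    attr(scaled, "A_max") <- alpha * a0max
    attr(scaled, "darea_dphase") <- alpha * attr(base, "darea_dphase")
    out <- modify_gaw(scaled, make_gc("GC3",
      list(initial_gap_area = gc$initial_gap_area)))
    direct <- gc$initial_gap_area +
      (alpha * a0max - gc$initial_gap_area) / (alpha * a0max) *
      alpha * base$area_mm2
    expect_equal(out$area_mm2, direct)
  }
})

test_that("duct angle schedule attains the printed extremes in phase", {
  dense <- seq(0, 1 - 1e-9, length.out = 20001)
  ang <- duct_angle(dense)
  conv <- dense >= 0.1 & dense <= 0.32
  dive <- dense >= 0.32 & dense <= 0.9
  closed <- dense >= 0.9 | dense < 0.1
  expect_equal(max(ang[conv]), 5)
  expect_true(all(ang[conv] >= 0 & ang[conv] <= 5))
  expect_equal(min(ang[dive]), -10)
  expect_true(all(ang[dive] >= -10 & ang[dive] <= 0))
  expect_true(all(ang[closed] == 0))
  expect_equal(duct_angle(0.05), 0)
  expect_warning(out <- duct_angle(1.25), "wrapped")
  expect_equal(out, duct_angle(0.25))
})

test_that("symmetric motion reaches the maximum glottal width", {
  mf <- build_motion(baseline_gaw(n_samples = 512), n_stations = 200)
  expect_equal(max(mf$gap_width_mm), 4.66, tolerance = 1e-4)
  # mirror symmetry of the oscillatory displacement
  expect_equal(mf$displacement_mm["upper", , ], mf$displacement_mm["lower", , ])
  expect_true(all(mf$gap_width_mm >= 0))
})

test_that("single-fold amplitude reduction scales GAW maxima as the mean factor", {
  gaw <- modify_gaw(baseline_gaw(n_samples = 512), make_gc("GC2"))
  sym <- build_motion(gaw, gc = make_gc("GC2"), amplitude_factors = c(1, 1))
  for (f in c(0.5, 0)) {
    asym <- build_motion(gaw, gc = make_gc("GC2"), amplitude_factors = c(f, 1))
    amin <- min(sym$gaw_mm2)
    ratio <- max(asym$gaw_mm2 - amin) / max(sym$gaw_mm2 - amin)
    expect_equal(ratio, (1 + f) / 2)
    # the initial gap area is a geometric offset, untouched by asymmetry
    expect_equal(min(asym$gaw_mm2), min(sym$gaw_mm2))
  }
  expect_error(build_motion(gaw, amplitude_factors = c(1.2, 1)), "factors")
  expect_error(build_motion(gaw, amplitude_factors = c(0, 0)), "factors")
})

test_that("station-integrated gap width reproduces the area waveform", {
  for (id in c("GC1", "GC3", "GC5")) {
    for (factors in list(c(1, 1), c(0.5, 1))) {
      gc <- make_gc(id)
      gaw <- modify_gaw(baseline_gaw(n_samples = 256), gc)
      mf <- build_motion(gaw, gc = gc, amplitude_factors = factors,
                         n_stations = 128)
      integ <- colSums(mf$gap_width_mm) * mf$dz_mm
      expect_lt(max(abs(integ - mf$gaw_mm2)) / max(mf$gaw_mm2), 0.01)
    }
  }
})

test_that("stored wall velocity matches finite differences of displacement", {
  gaw <- modify_gaw(baseline_gaw(n_samples = 1024), make_gc("GC2"))
  mf <- build_motion(gaw, gc = make_gc("GC2"), n_stations = 32)
  f0 <- mf$f0
  n <- length(mf$phase)
  x <- mf$displacement_mm["upper", 16, ] * 1e-3      # m
  v <- mf$velocity_m_s["upper", 16, ]
  dfd <- (x[c(2:n, 1)] - x[c(n, 1:(n - 1))]) / (2 / (n * f0))
  expect_lt(sqrt(mean((v - dfd)^2)) / sqrt(mean(v^2)), 0.01)
})

test_that("fully open types never close anywhere along the folds", {
  for (id in c("GC4", "GC5")) {
    gc <- make_gc(id)
    gaw <- modify_gaw(baseline_gaw(n_samples = 256), gc)
    mf <- build_motion(gaw, gc = gc, n_stations = 64)
    expect_true(all(mf$gap_width_mm > 0))
    expect_true(all(mf$gaw_mm2 >= gc$initial_gap_area - 1e-12))
  }
})

test_that("GAW CSV round-trips and validates", {
  gaw <- modify_gaw(baseline_gaw(n_samples = 128), make_gc("GC4"))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_gaw_csv(gaw, tf)
  back <- read_gaw_csv(tf, f0 = attr(gaw, "f0"))
  expect_equal(back$area_mm2, gaw$area_mm2)
  expect_equal(attr(back, "A_min"), attr(gaw, "A_min"))
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1:3), bad, row.names = FALSE)
  expect_error(read_gaw_csv(bad), "columns")
})
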