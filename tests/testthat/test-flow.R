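test_that("orifice law reproduces hand-computed flow values", {
  # A = 10 mm^2, dp = 775 Pa, rho = 1.18415, Cd = 1  ->  Q = 3.6180e-4 m^3/s
  fl <- solve_flow(constant_gaw(10), flow_conditions())
  expect_equal(fl$Q_m3_s[1], 3.618e-4, tolerance = 1e-4)
  expect_equal(attr(fl, "Q_mean_m3_s"), fl$Q_m3_s[1])
  # closed glottis carries no flow
  gaw <- baseline_gaw(n_samples = 512)
  fl0 <- solve_flow(gaw)
  expect_true(all(fl0$Q_m3_s[gaw$area_mm2 == 0] == 0))
  expect_equal(solve_flow(constant_gaw(0))$Q_m3_s, rep(0, 512))
})

test_that("flow scales with the square root of the pressure drop", {
  g <- constant_gaw(10)
  q1 <- attr(solve_flow(g, flow_conditions(p_inlet = 775)), "Q_mean_m3_s")
  q4 <- attr(solve_flow(g, flow_conditions(p_inlet = 4 * 775)), "Q_mean_m3_s")
  expect_equal(q4 / q1, 2)
})

test_that("flow conditions validate their physical ranges", {
  expect_error(flow_conditions(p_inlet = 0, p_outlet = 10), "exceed")
  expect_error(flow_conditions(rho = -1), "positive")
  expect_error(flow_conditions(discharge_coefficient = 1.5), "discharge")
})

test_that("glottal resistance is pressure over mean flow", {
  # dp = 775 Pa, Q_mean = 0.775 l/s -> 1000 Pa.s/l
  area <- 775e-6 / sqrt(2 * 775 / 1.18415) * 1e6   # mm^2 giving 0.775 l/s
  fl <- solve_flow(constant_gaw(area), flow_conditions())
  expect_equal(glottal_resistance(fl), 1000, tolerance = 1e-10)
  fl2 <- solve_flow(constant_gaw(2 * area), flow_conditions())
  expect_equal(glottal_resistance(fl2), 500, tolerance = 1e-10)
  expect_error(glottal_resistance(solve_flow(constant_gaw(0))), "undefined")
})

test_that("mean flow increases with insufficiency and drops with asymmetry", {
  q <- sapply(paste0("GC", 1:5), function(id) {
    gc <- make_gc(id)
    gaw <- modify_gaw(baseline_gaw(n_samples = 512), gc)
    sapply(list(c(1, 1), c(0.5, 1)), function(f) {
      mf <- build_motion(gaw, gc = gc, amplitude_factors = f, n_stations = 64)
      eff <- structure(data.frame(phase = mf$phase, area_mm2 = mf$gaw_mm2),
                       f0 = mf$f0, A_max = max(mf$gaw_mm2),
                       A_min = min(mf$gaw_mm2),
                       darea_dphase = mf$gaw_darea_dphase,
                       class = c("area_waveform", "data.frame"))
      attr(solve_flow(eff), "Q_mean_l_s")
    })
  })
  expect_true(all(diff(q[1, ]) > 0))   # symmetric: GC1 -> GC5 rising
  expect_true(all(diff(q[2, ]) > 0))   # asymmetric
  expect_true(all(q[2, ] < q[1, ]))    # asymmetry reduces the flow
  r_sym <- 775 / q[1, ]; r_asym <- 775 / q[2, ]
  expect_true(all(r_asym > r_sym))
})

test_that("stationary walls transfer no energy", {
  gaw <- constant_gaw(10)
  mf <- build_motion(gaw, gc = NULL, n_stations = 32)
  fl <- solve_flow(gaw)
  en <- energy_transfer(mf, fl)
  expect_equal(en$Edot_net_W, rep(0, length(mf$phase)))
  expect_equal(en$W_net_J, 0)
})

test_that("net cycle work is positive and ordered across cases", {
  w <- sapply(paste0("GC", 1:5), function(id) {
    gc <- make_gc(id)
    gaw <- modify_gaw(baseline_gaw(n_samples = 512), gc)
    sapply(list(c(1, 1), c(0.5, 1)), function(f) {
      mf <- build_motion(gaw, gc = gc, amplitude_factors = f, n_stations = 64)
      eff <- structure(data.frame(phase = mf$phase, area_mm2 = mf$gaw_mm2),
                       f0 = mf$f0, A_max = max(mf$gaw_mm2),
                       A_min = min(mf$gaw_mm2),
                       darea_dphase = mf$gaw_darea_dphase,
                       class = c("area_waveform", "data.frame"))
      energy_transfer(mf, solve_flow(eff))$W_net_J
    })
  })
  expect_true(all(w > 0))                 # physiological energy influx
  expect_true(all(diff(w[1, ]) < 0))      # decreasing with insufficiency
  expect_true(all(w[2, ] < w[1, ]))       # asymmetry reduces the net work
})

test_that("both folds contribute equally under symmetric motion", {
  gc <- make_gc("GC3")
  gaw <- modify_gaw(baseline_gaw(n_samples = 256), gc)
  mf <- build_motion(gaw, gc = gc, n_stations = 32)
  expect_equal(mf$velocity_m_s["upper", , ], mf$velocity_m_s["lower", , ])
})

test_that("energy quadrature converges under phase-step halving", {
  gc <- make_gc("GC2")
  w <- sapply(c(512, 1024), function(n) {
    gaw <- modify_gaw(baseline_gaw(n_samples = n), gc)
    mf <- build_motion(gaw, gc = gc, n_stations = 64)
    energy_transfer(mf, solve_flow(gaw))$W_net_J
  })
  expect_lt(abs(w[2] - w[1]) / abs(w[2]), 0.005)
})

test_that("energy transfer rejects mismatched grids", {
  gc <- make_gc("GC2")
  gaw1 <- modify_gaw(baseline_gaw(n_samples = 256), gc)
  gaw2 <- modify_gaw(baseline_gaw(n_samples = 128), gc)
  mf <- build_motion(gaw1, gc = gc, n_stations = 16)
  expect_error(energy_transfer(mf, solve_flow(gaw2)), "phase grid")
})
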