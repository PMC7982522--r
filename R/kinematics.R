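#' Baseline glottal area waveform
#'
#' Parametric stand-in for the glottal area waveform (GAW) of the validated
#' synthetic larynx: the glottis is closed between phase 0.9 of one cycle and
#' phase 0.1 of the next, and the open phase is a skewed raised-cosine pulse
#' peaking before mid-cycle (default peak phase 0.36) so that the opening
#' phase is shorter than the closing phase (speed quotient < 1). The waveform
#' is continuously differentiable; its analytic phase-derivative is stored in
#' attribute `darea_dphase` and used downstream for wall velocities.
#'
#' @param f0 Fundamental frequency in Hz (default 148).
#' @param A0max Cycle maximum area in mm^2; default [reference_a0max()].
#' @param n_samples Samples per cycle (>= 16).
#' @param open_interval Phase interval `[start, end]` of the open phase.
#' @param peak_phase Phase of the area maximum, inside `open_interval`.
#' @return An object of class `area_waveform`: a data.frame with columns
#'   `phase` and `area_mm2`, attributes `f0`, `A_max`, `A_min`,
#'   `darea_dphase`.
#' @export
#' @examples
#' gaw <- baseline_gaw()
#' range(gaw$area_mm2)
baseline_gaw <- function(f0 = 148, A0max = reference_a0max(),
                         n_samples = 2048,
                         open_interval = c(0.1, 0.9), peak_phase = 0.36) {
  if (!is.finite(f0) || f0 <= 0) stop("f0 must be positive")
  if (!is.finite(A0max) || A0max <= 0) stop("A0max must be positive")
  if (n_samples < 16) stop("n_samples must be at least 16")
  n <- as.integer(n_samples)
  phase <- (seq_len(n) - 1) / n
  shape <- .gaw_pulse(phase, open_interval, peak_phase)
  area <- A0max * shape$h
  darea <- A0max * shape$dh            # d area / d phase
  out <- data.frame(phase = phase, area_mm2 = area)
  # amplitude attributes are those of the continuous waveform: the sampled
  # maximum can undershoot A0max by O(dphase^2) when the peak phase is off-grid
  structure(out,
            f0 = f0, A_max = A0max, A_min = 0,
            darea_dphase = darea,
            open_interval = open_interval, peak_phase = peak_phase,
            class = c("area_waveform", "data.frame"))
}

# Skewed raised-cosine pulse h(phase) in [0, 1] with analytic derivative.
# Zero (with zero slope) outside the open interval.
.gaw_pulse <- function(phase, open_interval, peak_phase) {
  o1 <- open_interval[1]; o2 <- open_interval[2]
  if (!(o1 < peak_phase && peak_phase < o2)) {
    stop("peak_phase must lie inside the open interval")
  }
  s <- (phase - o1) / (o2 - o1)
  sp <- (peak_phase - o1) / (o2 - o1)
  h <- numeric(length(phase))
  dh <- numeric(length(phase))
  rise <- s >= 0 & s <= sp
  fall <- s > sp & s <= 1
  h[rise] <- 0.5 * (1 - cos(pi * s[rise] / sp))
  dh[rise] <- 0.5 * pi / sp * sin(pi * s[rise] / sp) / (o2 - o1)
  h[fall] <- 0.5 * (1 + cos(pi * (s[fall] - sp) / (1 - sp)))
  dh[fall] <- -0.5 * pi / (1 - sp) * sin(pi * (s[fall] - sp) / (1 - sp)) / (o2 - o1)
  list(h = h, dh = dh)
}

#' @export
print.area_waveform <- function(x, ...) {
  cat(sprintf("<area_waveform>  f0 = %g Hz, %d samples/cycle, area %0.4g..%0.4g mm^2\n",
              attr(x, "f0"), nrow(x), attr(x, "A_min"), attr(x, "A_max")))
  invisible(x)
}

#' Modify the baseline GAW for a glottal-closure type
#'
#' Applies the affine glottal-insufficiency map
#' `A_i(t) = A_i0 + (A0max - A_i0) / A0max * A_0(t)`,
#' which lifts the baseline waveform `A_0(t)` so that its minimum becomes the
#' initial gap area `A_i0` of the closure type while the cycle maximum `A0max`
#' is preserved.
#'
#' @param base An [baseline_gaw()] (or any `area_waveform` whose minimum is 0).
#' @param gc A [make_gc()] object supplying `A_i0`.
#' @return An `area_waveform` with `A_min = gc$initial_gap_area` and the same
#'   `A_max` as `base`.
#' @export
#' @examples
#' gaw1 <- modify_gaw(baseline_gaw(), make_gc("GC1"))
#' attr(gaw1, "A_min")  # 0.5 mm^2
modify_gaw <- function(base, gc) {
  stopifnot(inherits(base, "area_waveform"), inherits(gc, "gc_type"))
  a0max <- attr(base, "A_max")
  ai0 <- gc$initial_gap_area
  if (ai0 > a0max) stop("initial_gap_area exceeds the baseline maximum")
  slope <- (a0max - ai0) / a0max
  out <- base
  out$area_mm2 <- ai0 + slope * base$area_mm2
  # the affine map fixes the continuous maximum and pins the minimum at A_i0
  attr(out, "A_max") <- a0max
  attr(out, "A_min") <- ai0
  attr(out, "darea_dphase") <- slope * attr(base, "darea_dphase")
  attr(out, "gc_id") <- gc$id
  out
}

#' Convergent-divergent duct-angle schedule
#'
#' Prescribed mucosal-wave angle of the glottal duct over one cycle:
#' convergent (positive) during the opening interval 0.1 T to 0.32 T, reaching
#' +5 degrees, divergent (negative) during 0.32 T to 0.9 T, reaching -10
#' degrees, and zero while the glottis is closed (0.9 T to 0.1 T). The
#' published schedule gives only the interval ranges; here the trajectory is
#' piecewise linear through the vertices 0 deg at 0.1, +5 deg at 0.21, 0 deg
#' at 0.32, -10 deg at 0.61, 0 deg at 0.9, which is continuous and attains
#' both extremes at interval midpoints.
#'
#' @param phase Cycle phase `t/T`; values outside `[0, 1)` are wrapped with a
#'   warning.
#' @return Duct angle in degrees (convergent > 0, divergent < 0), same length
#'   as `phase`.
#' @export
#' @examples
#' duct_angle(c(0.05, 0.21, 0.61))  # 0, +5, -10
duct_angle <- function(phase) {
  if (any(phase < 0 | phase >= 1)) {
    warning("phase outside [0, 1) wrapped by modulo")
    phase <- phase %% 1
  }
  vx <- c(0.0, 0.1, 0.21, 0.32, 0.61, 0.9, 1.0)
  vy <- c(0, 0, 5, 0, -10, 0, 0)
  stats::approx(vx, vy, xout = phase, method = "linear")$y
}

#' Build the prescribed vocal-fold motion field
#'
#' Converts an area waveform into medial-lateral wall positions of the two
#' vocal folds. The oscillatory gap width is distributed along the
#' anterior-posterior axis by a half-sine envelope `sin(pi * z / L)` and added
#' to the minimum-opening gap profile of the closure type; each fold carries
#' half of the gap, scaled by its amplitude factor. Reducing one fold's factor
#' to 0.5 (left-right asymmetric motion) scales the oscillatory part of the
#' resulting GAW to 75% of the symmetric case while leaving the initial gap
#' area unchanged (the residual gap is a geometric insufficiency, not a motion
#' amplitude).
#'
#' Per-fold wall velocities are the analytic time derivative of the
#' displacement. The integral of the gap width over the stations reproduces
#' the (asymmetry-scaled) GAW to discretisation accuracy.
#'
#' @param gaw An `area_waveform` ([baseline_gaw()] or [modify_gaw()] output).
#' @param frame A [larynx_frame()].
#' @param gc Optional [make_gc()]; `NULL` means the baseline configuration
#'   with no residual gap.
#' @param amplitude_factors Length-2 numeric `(upper, lower)` in `[0, 1]`
#'   (not both zero); 0 models a completely immobile fold.
#' @param n_stations Number of anterior-posterior stations (>= 2).
#' @return An object of class `motion_field`: list with `phase`, `z_mm`
#'   (station midpoints), `displacement_mm` and `velocity_m_s` (arrays
#'   `[fold, station, phase]`, folds `upper`/`lower`, displacement measured
#'   laterally outward from the midline), `gap_width_mm` (`[station, phase]`),
#'   `gaw_mm2` (area waveform implied by the motion), `duct_angle_deg`, `f0`,
#'   `amplitude_factors`.
#' @export
#' @examples
#' mf <- build_motion(baseline_gaw(n_samples = 256), n_stations = 64)
#' max(mf$gap_width_mm)  # ~4.66 mm
build_motion <- function(gaw, frame = larynx_frame(), gc = NULL,
                         amplitude_factors = c(1, 1), n_stations = 128) {
  stopifnot(inherits(gaw, "area_waveform"))
  if (length(amplitude_factors) != 2 ||
      any(amplitude_factors < 0) || any(amplitude_factors > 1) ||
      sum(amplitude_factors) == 0) {
    stop("amplitude_factors must be two values in [0, 1], not both zero")
  }
  if (n_stations < 2) stop("n_stations must be at least 2")
  n_z <- as.integer(n_stations)
  L <- frame$vf_length
  dz <- L / n_z
  z <- (seq_len(n_z) - 0.5) * dz
  env <- sin(pi * z / L)

  w_min <- if (is.null(gc)) rep(0, n_z) else
    gap_width_profile(gc, frame, n_z)$width_mm
  a_min <- attr(gaw, "A_min")
  f0 <- attr(gaw, "f0")
  phase <- gaw$phase
  n_t <- length(phase)

  # oscillatory width amplitude: (A(t) - A_min) spread over the half-sine
  # envelope whose analytic integral over [0, L] is 2 L / pi
  W_t <- (gaw$area_mm2 - a_min) * pi / (2 * L)          # mm
  dW_t <- attr(gaw, "darea_dphase") * pi / (2 * L) * f0 # mm/s per unit phase deriv

  fu <- amplitude_factors[1]
  fl <- amplitude_factors[2]
  disp <- array(0, dim = c(2, n_z, n_t),
                dimnames = list(fold = c("upper", "lower"), NULL, NULL))
  vel <- array(0, dim = dim(disp), dimnames = dimnames(disp))
  half_min <- w_min / 2
  for (k in seq_len(n_t)) {
    osc <- env * W_t[k] / 2
    disp["upper", , k] <- half_min + fu * osc
    disp["lower", , k] <- half_min + fl * osc
    vosc <- env * dW_t[k] / 2 * 1e-3   # mm/s -> m/s
    vel["upper", , k] <- fu * vosc
    vel["lower", , k] <- fl * vosc
  }
  gap <- disp["upper", , ] + disp["lower", , ]          # [station, phase]
  gaw_eff <- a_min + (fu + fl) / 2 * (gaw$area_mm2 - a_min)

  structure(list(phase = phase, z_mm = z, dz_mm = dz,
                 displacement_mm = disp, velocity_m_s = vel,
                 gap_width_mm = gap, gaw_mm2 = gaw_eff,
                 gaw_darea_dphase = (fu + fl) / 2 * attr(gaw, "darea_dphase"),
                 duct_angle_deg = duct_angle(phase),
                 f0 = f0, amplitude_factors = c(upper = fu, lower = fl),
                 frame = frame, gc = gc),
            class = "motion_field")
}

#' @export
print.motion_field <- function(x, ...) {
  cat(sprintf("<motion_field>  %d stations x %d phases, factors (%.2f, %.2f), max gap %.3f mm\n",
              length(x$z_mm), length(x$phase),
              x$amplitude_factors[1], x$amplitude_factors[2],
              max(x$gap_width_mm)))
  invisible(x)
}

#' Read a sampled GAW from a CSV file
#'
#' Loads an externally measured glottal area waveform (columns `phase`,
#' `area_mm2`; one cycle, phase in `[0, 1)`). The phase derivative is
#' estimated by centred finite differences with periodic wrap-around.
#'
#' @param path CSV file path.
#' @param f0 Fundamental frequency in Hz the waveform is cycled at.
#' @return An `area_waveform`.
#' @export
read_gaw_csv <- function(path, f0 = 148) {
  d <- utils::read.csv(path)
  if (!all(c("phase", "area_mm2") %in% names(d))) {
    stop("GAW CSV must have columns 'phase' and 'area_mm2'")
  }
  if (any(d$area_mm2 < 0)) stop("GAW areas must be nonnegative")
  n <- nrow(d)
  dp <- c(d$phase[2] - d$phase[1])
  darea <- (d$area_mm2[c(2:n, 1)] - d$area_mm2[c(n, 1:(n - 1))]) / (2 * dp)
  structure(d, f0 = f0, A_max = max(d$area_mm2), A_min = min(d$area_mm2),
            darea_dphase = darea,
            class = c("area_waveform", "data.frame"))
}

#' Write a GAW to CSV
#'
#' @param gaw An `area_waveform`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_gaw_csv <- function(gaw, path) {
  utils::write.csv(as.data.frame(gaw)[c("phase", "area_mm2")], path,
                   row.names = FALSE)
  invisible(path)
}
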