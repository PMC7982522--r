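#' Aerodynamic boundary conditions
#'
#' Driving pressures and air properties for the quasi-steady glottal flow
#' model. Defaults: subglottal inlet pressure 775 Pa, outlet (mouth) 0 Pa, air
#' density 1.18415 kg/m^3, kinematic viscosity 1.5666e-5 m^2/s (retained for
#' Reynolds-number reporting only; the flow law is inviscid), discharge
#' coefficient 1.
#'
#' @param p_inlet Subglottal pressure in Pa.
#' @param p_outlet Supraglottal/mouth pressure in Pa.
#' @param rho Air density in kg/m^3.
#' @param nu Kinematic viscosity in m^2/s.
#' @param discharge_coefficient Orifice discharge coefficient in `(0, 1]`.
#' @return An object of class `flow_conditions`.
#' @export
flow_conditions <- function(p_inlet = 775, p_outlet = 0, rho = 1.18415,
                            nu = 1.5666e-5, discharge_coefficient = 1) {
  if (p_inlet <= p_outlet) stop("p_inlet must exceed p_outlet")
  if (rho <= 0 || nu <= 0) stop("rho and nu must be positive")
  if (discharge_coefficient <= 0 || discharge_coefficient > 1) {
    stop("discharge_coefficient must be in (0, 1]")
  }
  structure(list(p_inlet = p_inlet, p_outlet = p_outlet, rho = rho, nu = nu,
                 discharge_coefficient = discharge_coefficient),
            class = "flow_conditions")
}

#' Quasi-steady orifice flow through the glottis
#'
#' Reduced-order surrogate for the resolved laryngeal flow: at every phase the
#' volume flow follows the incompressible Bernoulli orifice law
#' `Q(t) = Cd * A(t) * sqrt(2 * (p_inlet - p_outlet) / rho)`,
#' so the flow tracks the glottal area waveform instantaneously. Inertance and
#' viscous losses are neglected. A simplified wall-pressure record is attached
#' for the energy-transfer computation (see Details).
#'
#' Wall pressure model: during the convergent (opening) part of the cycle the
#' medial wall is exposed to near-inlet pressure; during the divergent
#' (closing) part, flow separation at a contracted upstream section leaves the
#' wall at the Bernoulli static pressure of the intraglottal jet, which falls
#' below the outlet pressure and sucks the folds together. The wall pressure
#' is blended between these limits according to the instantaneous duct angle:
#' `p_wall = alpha * dp + (1 - alpha) * (dp - 0.5 * rho * u^2)` with
#' `alpha = max(angle, 0) / 5` and jet speed
#' `u = Cd * sqrt(2 dp / rho) / k(angle)`, `k = 1 + angle/40` an effective
#' area contraction. While the glottis is at minimum opening the walls do not
#' move, so the wall pressure there does no work.
#'
#' @param gaw An `area_waveform`.
#' @param cond A [flow_conditions()].
#' @param duct_angle_deg Optional duct angle per phase sample; default
#'   [duct_angle()] evaluated on the waveform's phase grid.
#' @return An object of class `flow_series`: data.frame with columns `phase`,
#'   `Q_l_s`, `Q_m3_s`, `wall_pressure_Pa`; attributes `Q_mean_l_s`,
#'   `Q_mean_m3_s` (trapezoidal phase averages), `dp_Pa`, `f0`, `cond`.
#' @export
#' @examples
#' fl <- solve_flow(modify_gaw(baseline_gaw(), make_gc("GC1")))
#' attr(fl, "Q_mean_l_s")
solve_flow <- function(gaw, cond = flow_conditions(), duct_angle_deg = NULL) {
  stopifnot(inherits(gaw, "area_waveform"))
  if (any(gaw$area_mm2 < 0)) stop("glottal area must be nonnegative")
  dp <- cond$p_inlet - cond$p_outlet
  cd <- cond$discharge_coefficient
  u_ref <- cd * sqrt(2 * dp / cond$rho)          # orifice velocity, m/s
  A_m2 <- gaw$area_mm2 * 1e-6
  Q <- A_m2 * u_ref                               # m^3/s
  if (is.null(duct_angle_deg)) duct_angle_deg <- duct_angle(gaw$phase)

  alpha <- pmax(duct_angle_deg, 0) / 5
  k <- pmax(1 + duct_angle_deg / 40, 0.25)        # effective contraction
  u_jet <- u_ref / k
  p_bern <- dp - 0.5 * cond$rho * u_jet^2
  p_wall <- alpha * dp + (1 - alpha) * p_bern
  p_wall[A_m2 == 0] <- 0                          # no flow, ambient wall load

  q_mean <- .phase_mean(gaw$phase, Q)
  out <- data.frame(phase = gaw$phase, Q_l_s = Q * 1e3, Q_m3_s = Q,
                    wall_pressure_Pa = p_wall)
  structure(out, Q_mean_l_s = q_mean * 1e3, Q_mean_m3_s = q_mean,
            dp_Pa = dp, f0 = attr(gaw, "f0"), cond = cond,
            duct_angle_deg = duct_angle_deg,
            class = c("flow_series", "data.frame"))
}

# trapezoidal cycle average of a periodic sample on phase grid [0, 1)
.phase_mean <- function(phase, x) {
  n <- length(phase)
  ph <- c(phase, 1)
  xx <- c(x, x[1])
  sum(diff(ph) * (xx[-1] + xx[-(n + 1)]) / 2)
}

#' @export
print.flow_series <- function(x, ...) {
  cat(sprintf("<flow_series>  Q_mean = %.3f l/s, dp = %g Pa, %d phases\n",
              attr(x, "Q_mean_l_s"), attr(x, "dp_Pa"), nrow(x)))
  invisible(x)
}

#' Glottal flow resistance
#'
#' Transglottal pressure drop divided by the cycle-mean volume flow, after
#' van den Berg. Reported in Pa.s/l, i.e. Pa per (l/s).
#'
#' @param flow A [solve_flow()] result.
#' @param cond A [flow_conditions()]; defaults to the conditions stored in
#'   `flow`.
#' @return Resistance in Pa.s/l.
#' @export
#' @examples
#' glottal_resistance(solve_flow(baseline_gaw()))
glottal_resistance <- function(flow, cond = attr(flow, "cond")) {
  q_mean <- attr(flow, "Q_mean_l_s")
  if (is.null(q_mean) || q_mean <= 0) {
    stop("glottal resistance undefined: mean flow is zero (closed glottis)")
  }
  (cond$p_inlet - cond$p_outlet) / q_mean
}

#' Aerodynamic energy transfer into the vocal folds
#'
#' Net rate of work done by the aerodynamic wall pressure on the moving
#' vocal-fold walls, `Edot_net(t) = sum_folds sum_stations p_wall * (v . n) *
#' dS`, with the wall normal pointing from the fluid into the tissue
#' (laterally outward) and `dS = dz * duct_depth`. Positive values mean energy
#' flows from the laryngeal air stream into the tissue. `W_net` integrates
#' `Edot_net` over one cycle; a positive cycle total is the physiological
#' regime that sustains flow-induced oscillation.
#'
#' @param motion A [build_motion()] result.
#' @param flow A [solve_flow()] result on the same phase grid.
#' @return List with `phase`, `Edot_net_W` (per phase), `W_net_J` (cycle
#'   total), and `physiological` (`TRUE` when `W_net_J > 0`).
#' @export
energy_transfer <- function(motion, flow) {
  stopifnot(inherits(motion, "motion_field"), inherits(flow, "flow_series"))
  if (length(motion$phase) != nrow(flow) ||
      max(abs(motion$phase - flow$phase)) > 1e-12) {
    stop("motion and flow must share the same phase grid")
  }
  depth_m <- motion$frame$duct_depth * 1e-3
  dz_m <- motion$dz_mm * 1e-3
  dS <- dz_m * depth_m
  p_wall <- flow$wall_pressure_Pa
  # outward wall-normal velocity per fold and station: velocity_m_s as stored
  v_sum <- colSums(motion$velocity_m_s["upper", , , drop = FALSE][1, , ]) +
           colSums(motion$velocity_m_s["lower", , , drop = FALSE][1, , ])
  edot <- p_wall * v_sum * dS
  f0 <- motion$f0
  w_net <- .phase_mean(motion$phase, edot) / f0   # integral over T = mean / f0
  list(phase = motion$phase, Edot_net_W = edot, W_net_J = w_net,
       physiological = w_net > 0)
}
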