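#' Laryngeal frame dimensions
#'
#' Scalar dimensions of the simulated larynx: the anterior-posterior vocal-fold
#' length, the maximum medial-lateral glottal width reached during a symmetric
#' oscillation cycle, the fixed gap between the ventricular ("false") folds,
#' the distance from the vocal folds to the vocal-tract exit (mouth), and the
#' inferior-superior depth of the glottal duct's medial wall (used only for
#' wall-work integration).
#'
#' Defaults describe a normal adult male larynx driven at 148 Hz.
#'
#' @param vf_length Vocal-fold length, anterior-posterior, in mm.
#' @param max_glottal_width Maximum medial-lateral glottal width in mm.
#' @param vef_gap Ventricular-fold gap in mm.
#' @param vf_to_mouth Distance from the vocal folds to the mouth in mm.
#' @param duct_depth Inferior-superior depth of the glottal duct wall in mm.
#' @return An object of class `larynx_frame`.
#' @export
#' @examples
#' larynx_frame()
larynx_frame <- function(vf_length = 15, max_glottal_width = 4.66,
                         vef_gap = 5, vf_to_mouth = 171, duct_depth = 3) {
  dims <- c(vf_length = vf_length, max_glottal_width = max_glottal_width,
            vef_gap = vef_gap, vf_to_mouth = vf_to_mouth,
            duct_depth = duct_depth)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("all larynx frame dimensions must be positive and finite")
  }
  structure(as.list(dims), class = "larynx_frame")
}

#' @export
print.larynx_frame <- function(x, ...) {
  cat("<larynx_frame>\n")
  cat(sprintf("  vocal fold length  : %.2f mm\n", x$vf_length))
  cat(sprintf("  max glottal width  : %.2f mm\n", x$max_glottal_width))
  cat(sprintf("  ventricular gap    : %.2f mm\n", x$vef_gap))
  cat(sprintf("  VF to mouth        : %.1f mm\n", x$vf_to_mouth))
  cat(sprintf("  duct wall depth    : %.2f mm\n", x$duct_depth))
  invisible(x)
}

# Closed-length fractions of the five closure types (fraction of vf_length
# still in contact at minimum opening) and the shape of the residual gap.
.gc_closed_fraction <- c(GC1 = 1.0, GC2 = 0.6, GC3 = 0.3, GC4 = 0.0, GC5 = 0.0)
.gc_gap_shape <- c(GC1 = "none", GC2 = "triangular_posterior",
                   GC3 = "triangular_posterior", GC4 = "triangular_posterior",
                   GC5 = "rectangular")

#' Reference maximum glottal area of the baseline waveform
#'
#' The cycle maximum of the baseline glottal area waveform implied by a
#' half-sine width envelope along the folds: `(2/pi) * vf_length *
#' max_glottal_width`. With the default frame this is 44.4993 mm^2.
#'
#' @param frame A [larynx_frame()].
#' @return Maximum glottal area in mm^2.
#' @export
reference_a0max <- function(frame = larynx_frame()) {
  2 / pi * frame$vf_length * frame$max_glottal_width
}

#' Construct a glottal-closure (GC) type
#'
#' The five closure types span increasing glottal insufficiency. Each type is
#' fully described by two parameters: the fraction of the vocal-fold length
#' closed at minimum opening, and the initial (residual) glottal gap area
#' `A_i0` left open at minimum opening:
#'
#' * `GC1`: full closure (100% of the length); a residual slit of 0.5 mm^2 is
#'   kept as a numerical-stability floor but still interrupts the flow.
#' * `GC2`, `GC3`: partial posterior closure (60% / 30% of the length closed)
#'   with a triangular gap opening toward the posterior end.
#' * `GC4`: no contact, triangular posterior gap over the whole length.
#' * `GC5`: no contact, rectangular (midmembranous-type) gap whose area is
#'   half the baseline waveform maximum.
#'
#' Initial gap areas for GC2-GC4 are not fixed by the closure-type definition
#' (in the source experiments they derive from an ex vivo glottal gap index);
#' the shipped defaults 2, 5 and 10 mm^2 are package defaults chosen strictly
#' increasing between GC1's floor and GC5's half-maximum. Override via
#' `overrides`.
#'
#' @param gc_id One of `"GC1"` ... `"GC5"`.
#' @param overrides Optional named list; recognised entries
#'   `initial_gap_area` (mm^2) and `closed_fraction` (in `[0, 1]`).
#' @param frame A [larynx_frame()], used to derive the GC5 default gap area.
#' @return An object of class `gc_type` with fields `id`, `closed_fraction`,
#'   `gap_shape`, `initial_gap_area`.
#' @export
#' @examples
#' make_gc("GC1")$initial_gap_area   # 0.5 mm^2 stability floor
#' make_gc("GC5")$initial_gap_area   # half the baseline maximum area
make_gc <- function(gc_id, overrides = list(), frame = larynx_frame()) {
  if (length(gc_id) != 1L || !gc_id %in% names(.gc_closed_fraction)) {
    stop("unknown glottal closure type: ", paste(gc_id, collapse = ", "),
         " (expected one of GC1..GC5)")
  }
  a0max <- reference_a0max(frame)
  default_area <- switch(gc_id,
    GC1 = 0.5,           # numerical-stability floor
    GC2 = 2,             # package default, see ?make_gc
    GC3 = 5,
    GC4 = 10,
    GC5 = 0.5 * a0max)   # half the baseline GAW maximum
  area <- overrides$initial_gap_area %||% default_area
  cf <- overrides$closed_fraction %||% unname(.gc_closed_fraction[gc_id])
  if (!is.finite(area) || area < 0) stop("initial_gap_area must be >= 0")
  if (area > a0max) {
    stop("initial_gap_area exceeds the baseline maximum area (",
         signif(a0max, 6), " mm^2)")
  }
  if (!is.finite(cf) || cf < 0 || cf > 1) stop("closed_fraction must be in [0, 1]")
  structure(list(id = gc_id,
                 closed_fraction = cf,
                 gap_shape = unname(.gc_gap_shape[gc_id]),
                 initial_gap_area = area),
            class = "gc_type")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gc_type <- function(x, ...) {
  cat(sprintf("<gc_type %s>  closed %.0f%% of length, %s gap, A_i0 = %.3g mm^2\n",
              x$id, 100 * x$closed_fraction, x$gap_shape, x$initial_gap_area))
  invisible(x)
}

#' Minimum-opening gap width profile along the folds
#'
#' Samples the medial-lateral gap width at minimum glottal opening at
#' `n_stations` uniformly spaced station midpoints along the anterior-posterior
#' axis (`z = 0` anterior, `z = vf_length` posterior). Triangular gaps ramp
#' linearly from zero at the closure boundary to their maximum at the posterior
#' end; rectangular gaps are constant. Stations inside the closed fraction have
#' width exactly zero. GC1's 0.5 mm^2 stability floor is materialised as a
#' uniform hairline slit over the full length so that the profile integrates to
#' the initial gap area.
#'
#' @param gc A [make_gc()] object.
#' @param frame A [larynx_frame()].
#' @param n_stations Number of stations (>= 2).
#' @return A data.frame with columns `z_mm` (station midpoints) and `width_mm`,
#'   with the station spacing in attribute `dz_mm`.
#' @export
#' @examples
#' p <- gap_width_profile(make_gc("GC2"), n_stations = 200)
#' mean(p$width_mm == 0)  # 0.6: 60% of the length is closed
gap_width_profile <- function(gc, frame = larynx_frame(), n_stations = 200) {
  stopifnot(inherits(gc, "gc_type"))
  if (!is.numeric(n_stations) || n_stations < 2) {
    stop("n_stations must be at least 2")
  }
  n <- as.integer(n_stations)
  L <- frame$vf_length
  dz <- L / n
  z <- (seq_len(n) - 0.5) * dz        # station midpoints
  A <- gc$initial_gap_area
  w <- switch(gc$gap_shape,
    none = rep(A / L, n),             # uniform hairline slit (GC1 floor)
    rectangular = rep(A / L, n),
    triangular_posterior = {
      z0 <- gc$closed_fraction * L    # closure boundary
      open_len <- L - z0
      w_post <- 2 * A / open_len      # width at the posterior end
      ifelse(z <= z0, 0, w_post * (z - z0) / open_len)
    },
    stop("unknown gap shape: ", gc$gap_shape))
  structure(data.frame(z_mm = z, width_mm = w), dz_mm = dz)
}

#' Closed-length fraction of a width profile
#'
#' Fraction of stations whose gap width does not exceed `tol`. Contiguity of
#' the closed region is not assumed.
#'
#' @param profile A data.frame as returned by [gap_width_profile()], or a
#'   numeric vector of widths in mm.
#' @param tol Width threshold below which a station counts as closed, in mm
#'   (default 1e-6 mm = 1e-9 m).
#' @return Fraction in `[0, 1]`.
#' @export
closed_fraction_of <- function(profile, tol = 1e-6) {
  w <- if (is.data.frame(profile)) profile$width_mm else profile
  if (length(w) == 0) stop("empty width profile")
  if (!is.numeric(tol) || tol < 0) stop("tol must be >= 0")
  mean(w <= tol)
}
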