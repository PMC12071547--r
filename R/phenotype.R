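#' Sphincter phenotype: generative parameters of the pressure field
#'
#' A phenotype describes one patient's anal sphincter complex as a smooth
#' axial-by-angular pressure field: a Gaussian high-pressure zone along the
#' pull axis whose amplitude may be attenuated over an anterior angular
#' window ("anterior deficit"). A deficit of 0 is a fully circular
#' sphincter; a deficit of 1 means the sphincter is completely absent at
#' the center of the anterior window, as seen when the anal opening lies
#' outside the sphincter complex.
#'
#' @param baseline_pressure Resting recto-luminal background pressure, mmHg.
#' @param peak_amplitude Height of the high-pressure zone above baseline, mmHg.
#' @param axial_center Location of the sphincter complex along the pull
#'   axis, cm (0 at the anal verge, positive toward the rectum).
#' @param axial_sigma Axial spread (Gaussian sigma) of the high-pressure
#'   zone, cm. Must be positive.
#' @param anterior_deficit Fraction in `[0, 1]`: 0 = circular sphincter,
#'   1 = complete anterior absence at the window center.
#' @param deficit_halfwidth Angular half-width of the deficit window,
#'   degrees, in `(0, 180]`.
#' @param angular_offset Center of the deficit window relative to the
#'   anterior midline, degrees.
#'
#' @return An object of class `sphincter_phenotype`.
#' @seealso [pressure_field()], [simulate_pullthrough()]
#' @export
#' @examples
#' ph <- sphincter_phenotype(anterior_deficit = 0.9)
#' pressure_field(ph, axial_cm = ph$axial_center, angle_deg = 0)
sphincter_phenotype <- function(baseline_pressure = 15,
                                peak_amplitude = 120,
                                axial_center = 1.0,
                                axial_sigma = 0.6,
                                anterior_deficit = 0,
                                deficit_halfwidth = 90,
                                angular_offset = 0) {
  ph <- structure(
    list(
      baseline_pressure = as.numeric(baseline_pressure),
      peak_amplitude = as.numeric(peak_amplitude),
      axial_center = as.numeric(axial_center),
      axial_sigma = as.numeric(axial_sigma),
      anterior_deficit = as.numeric(anterior_deficit),
      deficit_halfwidth = as.numeric(deficit_halfwidth),
      angular_offset = as.numeric(angular_offset)
    ),
    class = "sphincter_phenotype"
  )
  validate_phenotype(ph)
  ph
}

validate_phenotype <- function(ph) {
  stopifnot(inherits(ph, "sphincter_phenotype"))
  with(ph, {
    if (!is.finite(baseline_pressure) || baseline_pressure < 0) {
      stop("baseline_pressure must be finite and >= 0", call. = FALSE)
    }
    if (!is.finite(peak_amplitude) || peak_amplitude < 0) {
      stop("peak_amplitude must be finite and >= 0", call. = FALSE)
    }
    if (!is.finite(axial_sigma) || axial_sigma <= 0) {
      stop("axial_sigma must be > 0", call. = FALSE)
    }
    if (!is.finite(anterior_deficit) ||
        anterior_deficit < 0 || anterior_deficit > 1) {
      stop("anterior_deficit must be in [0, 1]", call. = FALSE)
    }
    if (!is.finite(deficit_halfwidth) ||
        deficit_halfwidth <= 0 || deficit_halfwidth > 180) {
      stop("deficit_halfwidth must be in (0, 180]", call. = FALSE)
    }
  })
  invisible(ph)
}

#' @export
print.sphincter_phenotype <- function(x, ...) {
  cat("Sphincter phenotype\n")
  cat(sprintf("  baseline %.1f mmHg, amplitude %.1f mmHg\n",
              x$baseline_pressure, x$peak_amplitude))
  cat(sprintf("  axial center %.2f cm, sigma %.2f cm\n",
              x$axial_center, x$axial_sigma))
  cat(sprintf("  anterior deficit %.2f over +/-%.0f deg (offset %.0f deg)\n",
              x$anterior_deficit, x$deficit_halfwidth, x$angular_offset))
  invisible(x)
}

# Raised-cosine angular window: 1 at phi = 0, falling smoothly to 0 at
# |phi| = halfwidth, 0 outside. phi in degrees, taken modulo 360 into
# (-180, 180].
deficit_window <- function(phi_deg, halfwidth) {
  phi <- ((phi_deg + 180) %% 360) - 180
  w <- ifelse(abs(phi) <= halfwidth,
              0.5 * (1 + cos(pi * phi / halfwidth)),
              0)
  w
}

#' Noise-free pressure field of a sphincter phenotype
#'
#' Evaluates the deterministic pressure surface
#' \deqn{P(z, \theta) = b + A \, e^{-(z - z_0)^2 / (2\sigma^2)}
#'   \left[1 - d \, w(\theta - \theta_0)\right]}
#' where \eqn{w} is a raised-cosine window of half-width `deficit_halfwidth`
#' degrees: \eqn{w(\phi) = \tfrac12 (1 + \cos(\pi \phi / h))} for
#' \eqn{|\phi| \le h} and 0 otherwise. Angles are interpreted modulo 360.
#'
#' @param phenotype A [sphincter_phenotype()].
#' @param axial_cm Axial position(s), cm.
#' @param angle_deg Angle(s), degrees; recycled against `axial_cm`.
#' @return Pressure(s) in mmHg, numeric vector.
#' @export
#' @examples
#' ph <- sphincter_phenotype(baseline_pressure = 20, peak_amplitude = 120,
#'                           axial_center = 2, axial_sigma = 0.5,
#'                           anterior_deficit = 0.5)
#' pressure_field(ph, 2, 45)  # 20 + 120 * (1 - 0.5 * 0.5) = 110
pressure_field <- function(phenotype, axial_cm, angle_deg) {
  validate_phenotype(phenotype)
  axial <- exp(-(axial_cm - phenotype$axial_center)^2 /
                 (2 * phenotype$axial_sigma^2))
  g <- 1 - phenotype$anterior_deficit *
    deficit_window(angle_deg - phenotype$angular_offset,
                   phenotype$deficit_halfwidth)
  phenotype$baseline_pressure + phenotype$peak_amplitude * axial * g
}

#' Radial channel geometry of the eight-channel catheter
#'
#' Channel 2 faces the anterior midline (0 degrees); channels 1 and 8 flank
#' it at -45 and +45 degrees, so channels 1, 2 and 8 form the contiguous
#' 135-degree anterior sector. The remaining channels fill the circle at
#' 45-degree spacing.
#'
#' @return Named numeric vector of 8 angles in degrees (names `"1"`..`"8"`).
#' @export
channel_angles <- function() {
  c(`1` = -45, `2` = 0, `3` = 90, `4` = 135,
    `5` = 180, `6` = 225, `7` = 270, `8` = 45)
}

#' Indices of the anterior channels
#'
#' The three radial channels facing the anterior midline; their mean
#' pressure probes anterior sphincter presence.
#' @return Integer vector `c(1, 2, 8)`.
#' @export
anterior_channels <- function() c(1L, 2L, 8L)
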