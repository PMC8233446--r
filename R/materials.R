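# Material records, derived acoustic quantities and drive-power conversion.
#
# The shipped library (inst/extdata/materials.csv) holds the media used by
# the two reference devices: water, polystyrene, PDMS, YX 128-degree LiNbO3,
# leukocytes (WBC) and MCF-7 breast-cancer cells, all at 25 C.

#' Construct a material record
#'
#' A `saw_material` bundles the acoustic bulk properties of one medium:
#' density, sound speed, compressibility and (for fluids) the dynamic and
#' bulk viscosities. Particles and cells additionally carry a mean diameter.
#'
#' For fluids the tabulated compressibility must agree with \eqn{1/(\rho c^2)}
#' to 1% relative; a stored value always takes precedence over recomputation
#' but a mismatch beyond the tolerance is rejected for fluids and warned
#' about for solids (the polystyrene library row is the known case where the
#' Landau-Lifshitz footnote formula and the tabulated value disagree).
#'
#' @param name character label.
#' @param kind one of `"fluid"`, `"solid"`, `"particle"`, `"cell"`,
#'   `"substrate"`.
#' @param density kg/m^3.
#' @param sound_speed m/s (optional for cells specified by compressibility).
#' @param compressibility 1/Pa; defaults to `1/(density*sound_speed^2)`.
#' @param dynamic_viscosity,bulk_viscosity Pa s, fluids only.
#' @param poisson Poisson ratio (optional, solids).
#' @param diameter particle/cell mean diameter, m.
#' @return object of class `saw_material`.
#' @export
#' @examples
#' material("water", "fluid", density = 997, sound_speed = 1497,
#'          dynamic_viscosity = 0.89e-3, bulk_viscosity = 2.47e-3)
material <- function(name, kind = c("fluid", "solid", "particle", "cell",
                                    "substrate"),
                     density, sound_speed = NA_real_,
                     compressibility = NULL,
                     dynamic_viscosity = NA_real_,
                     bulk_viscosity = NA_real_,
                     poisson = NA_real_, diameter = NA_real_) {
  kind <- match.arg(kind)
  assert_positive(density, "density")
  if (!is.na(sound_speed)) assert_positive(sound_speed, "sound_speed")
  if (is.null(compressibility)) {
    if (is.na(sound_speed))
      stopf("material '%s': need sound_speed or compressibility", name)
    compressibility <- compressibility_from_rho_c(density, sound_speed)
  }
  assert_positive(compressibility, "compressibility")
  if (kind == "fluid") {
    assert_positive(dynamic_viscosity, "dynamic_viscosity")
    kappa_rc <- compressibility_from_rho_c(density, sound_speed)
    if (abs(kappa_rc - compressibility) / compressibility > 0.01)
      stopf("material '%s': fluid compressibility %.3e disagrees with 1/(rho c^2) = %.3e by more than 1%%",
            name, compressibility, kappa_rc)
  } else if (!is.na(sound_speed)) {
    kappa_rc <- compressibility_from_rho_c(density, sound_speed)
    if (abs(kappa_rc - compressibility) / compressibility > 0.01)
      warnf("material '%s': stored compressibility %.3e differs from 1/(rho c^2) = %.3e; stored value takes precedence",
            name, compressibility, kappa_rc)
  }
  structure(list(name = name, kind = kind, density = density,
                 sound_speed = sound_speed,
                 compressibility = compressibility,
                 dynamic_viscosity = dynamic_viscosity,
                 bulk_viscosity = bulk_viscosity,
                 poisson = poisson, diameter = diameter),
            class = "saw_material")
}

#' @export
print.saw_material <- function(x, ...) {
  cat(sprintf("<saw_material> %s (%s)\n", x$name, x$kind))
  cat(sprintf("  density          %.6g kg/m^3\n", x$density))
  if (!is.na(x$sound_speed))
    cat(sprintf("  sound speed      %.6g m/s\n", x$sound_speed))
  cat(sprintf("  compressibility  %.4g 1/Pa\n", x$compressibility))
  if (!is.na(x$dynamic_viscosity))
    cat(sprintf("  dynamic visc.    %.4g Pa s\n", x$dynamic_viscosity))
  if (!is.na(x$bulk_viscosity))
    cat(sprintf("  bulk visc.       %.4g Pa s\n", x$bulk_viscosity))
  if (!is.na(x$poisson))
    cat(sprintf("  Poisson ratio    %.3g\n", x$poisson))
  if (!is.na(x$diameter))
    cat(sprintf("  mean diameter    %.4g m\n", x$diameter))
  invisible(x)
}

#' Shipped material library
#'
#' Reads the packaged library of media at 25 C. Stored compressibilities take
#' precedence over recomputation from density and sound speed.
#'
#' @param name optional material name; when given, returns that single
#'   record instead of the full list.
#' @return named list of [material()] records, or one record.
#' @export
#' @examples
#' water <- material_library("water")
#' water$compressibility
material_library <- function(name = NULL) {
  path <- system.file("extdata", "materials.csv", package = "sawstream",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lib <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    suppressWarnings(material(
      name = r$name, kind = r$kind, density = r$density,
      sound_speed = r$sound_speed,
      compressibility = if (is.na(r$compressibility)) NULL else r$compressibility,
      dynamic_viscosity = r$dynamic_viscosity,
      bulk_viscosity = r$bulk_viscosity,
      poisson = r$poisson, diameter = r$diameter))
  })
  names(lib) <- tab$name
  if (is.null(name)) return(lib)
  if (!name %in% names(lib))
    stopf("unknown material '%s'; library has: %s", name,
          paste(names(lib), collapse = ", "))
  lib[[name]]
}

#' Isentropic compressibility from density and sound speed
#'
#' \eqn{\kappa = 1/(\rho c^2)}.
#'
#' @param rho density, kg/m^3. @param c sound speed, m/s.
#' @return compressibility, 1/Pa.
#' @export
compressibility_from_rho_c <- function(rho, c) {
  assert_positive(rho, "rho"); assert_positive(c, "c")
  1 / (rho * c^2)
}

#' Compressibility of an elastic solid from its Poisson ratio
#'
#' Landau-Lifshitz elasticity relation
#' \eqn{\kappa = \frac{3(1-\sigma)}{1+\sigma}\,\frac{1}{\rho c^2}}
#' with \eqn{c} the longitudinal sound speed. At \eqn{\sigma = 1/2} the
#' prefactor is 1 and the fluid formula is recovered. Note that for the
#' polystyrene constants in the shipped library this expression does not
#' reproduce the tabulated compressibility (which equals \eqn{1/(\rho c^2)});
#' the tabulated value is treated as authoritative throughout.
#'
#' @param sigma Poisson ratio, must lie in (-1, 0.5].
#' @param rho density, kg/m^3. @param c longitudinal sound speed, m/s.
#' @return compressibility, 1/Pa.
#' @export
compressibility_landau <- function(sigma, rho, c) {
  if (!is.finite(sigma) || sigma <= -1 || sigma > 0.5)
    stopf("Poisson ratio must lie in (-1, 0.5], got %g", sigma)
  assert_positive(rho, "rho"); assert_positive(c, "c")
  3 * (1 - sigma) / (1 + sigma) / (rho * c^2)
}

#' Acoustic contrast factor
#'
#' \deqn{\varphi = \frac{5\rho_p - 2\rho_f}{2\rho_p + \rho_f} -
#'   \frac{\kappa_p}{\kappa_f}}
#' Particles with \eqn{\varphi > 0} migrate to pressure nodes, \eqn{\varphi <
#' 0} to antinodes. This is the inviscid monopole+dipole combination; see
#' [scattering_f1()]/[scattering_f2()] for the viscous-corrected
#' coefficients, to which it reduces as \eqn{3\Phi} in the thin-boundary-layer
#' limit.
#'
#' @param rho_p,kappa_p particle density (kg/m^3) and compressibility (1/Pa).
#' @param rho_f,kappa_f fluid density and compressibility.
#' @return dimensionless contrast factor.
#' @export
#' @examples
#' lib <- material_library()
#' contrast_factor(lib$polystyrene$density, lib$polystyrene$compressibility,
#'                 lib$water$density, lib$water$compressibility)  # ~0.66
contrast_factor <- function(rho_p, kappa_p, rho_f, kappa_f) {
  for (nm in c("rho_p", "kappa_p", "rho_f", "kappa_f"))
    assert_positive(get(nm), nm)
  (5 * rho_p - 2 * rho_f) / (2 * rho_p + rho_f) - kappa_p / kappa_f
}

#' Viscous boundary-layer thickness
#'
#' \eqn{\delta_\nu = \sqrt{2\nu/\omega}} with kinematic viscosity
#' \eqn{\nu = \eta/\rho} and \eqn{\omega = 2\pi f}.
#'
#' @param eta dynamic viscosity, Pa s. @param rho density, kg/m^3.
#' @param f drive frequency, Hz.
#' @return thickness, m.
#' @export
boundary_layer_thickness <- function(eta, rho, f) {
  if (eta < 0) stopf("viscosity must be non-negative")
  assert_positive(rho, "rho"); assert_positive(f, "f")
  sqrt(2 * (eta / rho) / (2 * pi * f))
}

#' Convert a drive voltage to input power in dBm
#'
#' Uses a per-device calibration pair `(V_ref, dbm_ref)` and the quadratic
#' voltage-power law: `dbm_ref + 20*log10(V/V_ref)`. Calibrations are never
#' global: the two reference devices ship with incompatible pairs
#' (7.5 V at 26.5 dBm for the validation device; 20 V at 26.5 dBm for the
#' sheathless separator), so the pair is always explicit.
#'
#' @param V drive voltage, volts. @param V_ref calibration voltage, volts.
#' @param dbm_ref calibration power, dBm.
#' @param rounding `"nearest"` (default) rounds to the nearest integer dBm,
#'   `"none"` returns the raw value.
#' @return input power, dBm.
#' @export
#' @examples
#' voltage_to_dbm(10, 7.5, 26.5)  # 29
voltage_to_dbm <- function(V, V_ref, dbm_ref,
                           rounding = c("nearest", "none")) {
  rounding <- match.arg(rounding)
  assert_positive(V, "V"); assert_positive(V_ref, "V_ref")
  out <- dbm_ref + 20 * log10(V / V_ref)
  if (rounding == "nearest") out <- round(out)
  out
}

#' SAW frequency from substrate speed and wavelength
#'
#' `f = c_sub / lambda`; the wavelength is set by the IDT pitch.
#'
#' @param c_sub substrate SAW speed, m/s. @param lambda wavelength, m.
#' @return frequency, Hz.
#' @export
frequency_from_wavelength <- function(c_sub, lambda) {
  assert_positive(c_sub, "c_sub"); assert_positive(lambda, "lambda")
  c_sub / lambda
}
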