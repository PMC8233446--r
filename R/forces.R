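# Acoustic radiation force with viscous scattering corrections, and
# Stokes drag.

#' Particle specification
#'
#' @param radius particle radius, m. A warning is issued above
#'   `radius/lambda = 0.05` when a wavelength is supplied, since the
#'   long-wavelength scattering expansion assumes `r << lambda`.
#' @param density kg/m^3. @param compressibility 1/Pa.
#' @param label text label.
#' @param lambda optional wavelength used for the validity warning, m.
#' @return object of class `particle_spec`.
#' @export
#' @examples
#' ps10 <- particle_spec(5e-6, 1050, 1.72e-10, "PS 10 um")
particle_spec <- function(radius, density, compressibility, label = "",
                          lambda = NULL) {
  assert_positive(radius, "radius")
  assert_positive(density, "density")
  assert_positive(compressibility, "compressibility")
  if (!is.null(lambda) && radius / lambda > 0.05)
    warnf("r/lambda = %.3f > 0.05: outside the long-wavelength validity of the scattering expansion",
          radius / lambda)
  structure(list(radius = radius, density = density,
                 compressibility = compressibility, label = label),
            class = "particle_spec")
}

#' Particle from a library cell/bead record
#'
#' @param mat [material()] record with a diameter (cells) or an explicit
#'   `diameter` override (beads of a chosen size).
#' @param diameter optional diameter, m.
#' @param lambda optional wavelength for the validity warning.
#' @return [particle_spec()].
#' @export
particle_from_material <- function(mat, diameter = NULL, lambda = NULL) {
  stopifnot(inherits(mat, "saw_material"))
  d <- diameter %||% mat$diameter
  if (is.null(d) || is.na(d))
    stopf("material '%s' has no diameter; supply one", mat$name)
  particle_spec(d / 2, mat$density, mat$compressibility, mat$name,
                lambda = lambda)
}

#' Monopole scattering coefficient
#'
#' `f1 = 1 - kappa_tilde` with `kappa_tilde = kappa_p / kappa_f`. Real,
#' but returned as the first element of the complex pair used in the
#' radiation-force expression (the conjugation there is a no-op).
#'
#' @param kappa_tilde compressibility ratio, >= 0.
#' @return complex scalar.
#' @export
scattering_f1 <- function(kappa_tilde) {
  if (any(kappa_tilde < 0)) stopf("kappa_tilde must be >= 0")
  (1 - kappa_tilde) + 0i
}

#' Dipole scattering coefficient with viscous correction
#'
#' \deqn{f_2 = \frac{2[1 - \Lambda](\tilde\rho - 1)}{2\tilde\rho + 1 -
#'   3\Lambda}, \qquad
#'   \Lambda(\tilde\delta_\nu) = -\frac{3}{2}\big[1 + i(1 +
#'   \tilde\delta_\nu)\big]\tilde\delta_\nu}
#' with `rho_tilde = rho_p/rho_f` and `delta_tilde = delta_nu / r`. The
#' inviscid limit `delta_tilde = 0` gives the classical real
#' `2(rho_tilde - 1)/(2 rho_tilde + 1)`.
#'
#' @param rho_tilde density ratio, > 0.
#' @param delta_tilde boundary-layer-to-radius ratio, >= 0.
#' @return complex scalar (vectorized).
#' @export
scattering_f2 <- function(rho_tilde, delta_tilde) {
  if (any(rho_tilde <= 0)) stopf("rho_tilde must be > 0")
  if (any(delta_tilde < 0)) stopf("delta_tilde must be >= 0")
  lam <- -1.5 * (1 + 1i * (1 + delta_tilde)) * delta_tilde
  2 * (1 - lam) * (rho_tilde - 1) / (2 * rho_tilde + 1 - 3 * lam)
}

#' Scattering coefficients of a particle in a fluid at a drive frequency
#'
#' @param particle [particle_spec()]. @param fluid [material()] fluid.
#' @param frequency Hz.
#' @return list with `f1`, `f2`, `kappa_tilde`, `rho_tilde`,
#'   `delta_tilde`, `delta_nu`.
#' @export
scattering_coefficients <- function(particle, fluid, frequency) {
  stopifnot(inherits(particle, "particle_spec"),
            inherits(fluid, "saw_material"))
  delta <- boundary_layer_thickness(fluid$dynamic_viscosity,
                                    fluid$density, frequency)
  kt <- particle$compressibility / fluid$compressibility
  rt <- particle$density / fluid$density
  dt <- delta / particle$radius
  list(f1 = scattering_f1(kt), f2 = scattering_f2(rt, dt),
       kappa_tilde = kt, rho_tilde = rt, delta_tilde = dt,
       delta_nu = delta)
}

#' Acoustic radiation force on a small particle
#'
#' \deqn{F^{rad} = -\pi r^3\Big[\frac{2\kappa_f}{3}
#'   \mathrm{Re}[f_1^* p_1^* \nabla p_1] -
#'   \rho_f \mathrm{Re}[f_2^* (v_1^*\!\cdot\!\nabla) v_1]\Big]}
#' with complex conjugation as written and the advective term evaluated
#' with the full first-order velocity Jacobian. For the analytic standing
#' wave in the inviscid limit this reduces to
#' `4 pi Phi r^3 k E_ac sin(2 k x_r)` with `Phi = f1/3 + Re(f2)/2`, and
#' `3 Phi` equals the acoustic contrast factor.
#'
#' @param f `first_order_field`.
#' @param particle [particle_spec()].
#' @param position numeric length-3, m; must lie inside the field domain.
#' @param fluid [material()] fluid record.
#' @param delta_tilde optional override of the boundary-layer-to-radius
#'   ratio (e.g. 0 for the inviscid limit); default computed from the
#'   fluid viscosity and the field frequency.
#' @return real force 3-vector, N.
#' @export
radiation_force <- function(f, particle, position, fluid,
                            delta_tilde = NULL) {
  stopifnot(inherits(f, "first_order_field"),
            inherits(particle, "particle_spec"),
            inherits(fluid, "saw_material"))
  g <- f$geometry
  lab <- c("x", "y", "z")
  lims <- rbind(c(0, g$L), c(0, g$w), c(0, g$h))
  bad <- which(position < lims[, 1] - 1e-12 | position > lims[, 2] + 1e-12)
  if (length(bad))
    stopf("position outside field domain: %s = %g not in [%g, %g]",
          lab[bad[1]], position[bad[1]], lims[bad[1], 1], lims[bad[1], 2])
  co <- scattering_coefficients(particle, fluid,
                                f$drive_frequency %||% f$frequency)
  if (!is.null(delta_tilde))
    co$f2 <- scattering_f2(co$rho_tilde, delta_tilde)
  x <- position[1]; y <- position[2]; z <- position[3]
  p1 <- f$pressure(x, y, z)
  gp <- as.vector(f$grad_pressure(x, y, z))
  v1 <- as.vector(f$velocity(x, y, z))
  jv <- f$velocity_jacobian(x, y, z)[[1]]
  adv <- as.vector(jv %*% Conj(v1))          # (v1* . grad) v1
  r3 <- particle$radius^3
  term1 <- (2 * fluid$compressibility / 3) *
    Re(Conj(co$f1) * Conj(p1) * gp)
  term2 <- fluid$density * Re(Conj(co$f2) * adv)
  -pi * r3 * (term1 - term2)
}

#' Stokes drag on a sphere
#'
#' `F = 6 pi eta r (v_fluid - v_particle)`; `v_fluid` is the superposition
#' of the background flow and the streaming velocity at the particle
#' position. Wall corrections are neglected.
#'
#' @param v_fluid,v_particle velocity 3-vectors, m/s.
#' @param r particle radius, m. @param eta dynamic viscosity, Pa s.
#' @return force 3-vector, N.
#' @export
stokes_drag <- function(v_fluid, v_particle, r, eta) {
  assert_positive(r, "r"); assert_positive(eta, "eta")
  6 * pi * eta * r * (v_fluid - v_particle)
}
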