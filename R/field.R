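# First-order time-harmonic standing-wave fields in the channel.
#
# Coordinates are right-handed with x the flow axis, y across the channel
# width and z the height above the substrate; the channel footprint is
# [0, L] x [0, w]. The standing-wave axis x_r makes an angle theta with the
# width axis so that pressure nodal lines lie at angle theta to the flow:
#   x_r = x sin(theta) + y cos(theta).
# theta = 0 is a conventional SSAW (nodal lines parallel to the flow),
# theta > 0 the tilted-angle (taSSAW) configuration.

#' Construct a (ta)SSAW first-order pressure field
#'
#' Semi-analytic standing-wave field
#' \deqn{p_1 = p_a \cos(k_s (x_r - x_{ref}))\, e^{-a x_r}, \qquad
#'   k_s = 2\pi/\lambda}
#' with `x_r = x sin(theta) + y cos(theta)`. The field is uniform in z by
#' default (shallow channel: a hard warning is logged when h/lambda > 0.5).
#' By default the phase reference is `x_ref = 0`, putting pressure nodes at
#' `x_r = (n + 1/2) lambda/2`; `node_at = "center"` shifts the pattern so a
#' nodal line passes through the footprint center (the symmetric
#' node/antinode arrangement of a device driven by IDT pairs at a pi phase
#' difference).
#'
#' @param p_a pressure amplitude, Pa.
#' @param lambda SAW wavelength, m.
#' @param theta_deg tilt angle of the nodal lines to the flow axis,
#'   degrees; |theta| < 90.
#' @param geometry list with `L`, `w`, `h` (m): footprint length, width,
#'   height.
#' @param fluid [material()] record of the fluid (density, sound speed).
#' @param frequency SAW drive frequency, Hz. Retained as metadata (it sets
#'   the viscous boundary-layer thickness entering the scattering
#'   coefficients); the *field's* effective angular frequency is
#'   `omega = c0 k_s`, the fluid dispersion of a standing plane wave with
#'   the imposed wavelength, so that `|v1| = p_a/(rho0 c0)` holds exactly.
#' @param node_at `"reference"` (nodes at `x_r = (n+1/2) lambda/2`) or
#'   `"center"` (node through the footprint center).
#' @param damping dimensionless bulk damping gamma of the lossy wavenumber
#'   `k = (1 + i gamma) omega/c0`; default 0 (bulk viscous damping
#'   negligible in water at MHz frequencies).
#' @param decay optional amplitude attenuation rate along `x_r`, 1/m
#'   (default 0, no decay).
#' @param z_profile `"uniform"` only (extension hook).
#' @return object of class `first_order_field` with closures
#'   `pressure(x, y, z)`, `grad_pressure(x, y, z)` (complex 3 columns),
#'   `velocity(x, y, z)`, `velocity_jacobian(x, y, z)` and metadata.
#' @export
make_tassaw_field <- function(p_a, lambda, theta_deg, geometry, fluid,
                              frequency, node_at = c("reference", "center"),
                              damping = 0, decay = 0,
                              z_profile = "uniform") {
  node_at <- match.arg(node_at)
  assert_positive(lambda, "lambda")
  if (abs(theta_deg) >= 90) stopf("|theta| must be < 90 degrees")
  stopifnot(inherits(fluid, "saw_material"))
  assert_positive(frequency, "frequency")
  if (p_a < 0) stopf("pressure amplitude must be >= 0")
  stopifnot(is.list(geometry), all(c("L", "w", "h") %in% names(geometry)))
  if (z_profile != "uniform")
    stopf("only the uniform z profile is implemented")
  if (geometry$h / lambda > 0.5)
    warnf("h/lambda = %.2f > 0.5: the uniform z profile is a poor model here",
          geometry$h / lambda)
  else if (geometry$h / lambda > 0.2)
    message(sprintf("note: h/lambda = %.2f > 0.2; uniform z profile marginal",
                    geometry$h / lambda))
  th <- deg2rad(theta_deg)
  ks <- 2 * pi / lambda
  rho0 <- fluid$density; c0 <- fluid$sound_speed
  # effective field frequency from the fluid dispersion of the imposed
  # standing wavelength; the SAW drive frequency is kept separately
  omega <- ks * c0
  sx <- sin(th); cy <- cos(th)
  x_ref <- if (node_at == "center") {
    # node through (L/2, w/2): ks*(x_rc - x_ref) = pi/2 (mod pi)
    (geometry$L / 2) * sx + (geometry$w / 2) * cy - lambda / 4
  } else 0
  xr <- function(x, y) x * sx + y * cy
  pressure <- function(x, y, z = 0) {
    u <- xr(x, y)
    p_a * cos(ks * (u - x_ref)) * exp(-decay * u) + 0i
  }
  grad_pressure <- function(x, y, z = 0) {
    u <- xr(x, y)
    d_du <- (-p_a * ks * sin(ks * (u - x_ref)) -
               decay * p_a * cos(ks * (u - x_ref))) * exp(-decay * u)
    cbind(d_du * sx, d_du * cy, rep(0, length(u))) + 0i
  }
  velocity <- function(x, y, z = 0) {
    -1i / (rho0 * omega) * grad_pressure(x, y, z)
  }
  velocity_jacobian <- function(x, y, z = 0) {
    # d2p/du2 along x_r, mapped to the xy frame; one 3x3 complex matrix
    # per point, returned as a list.
    u <- xr(x, y)
    d2 <- (-p_a * ks^2 * cos(ks * (u - x_ref)) +
             2 * decay * p_a * ks * sin(ks * (u - x_ref)) +
             decay^2 * p_a * cos(ks * (u - x_ref))) * exp(-decay * u)
    dirv <- c(sx, cy, 0)
    lapply(seq_along(u), function(i)
      (-1i / (rho0 * omega)) * d2[i] * (dirv %o% dirv))
  }
  structure(list(pressure = pressure, grad_pressure = grad_pressure,
                 velocity = velocity, velocity_jacobian = velocity_jacobian,
                 p_a = p_a, lambda = lambda, k_s = ks,
                 theta_deg = theta_deg, x_ref = x_ref,
                 omega = omega, frequency = omega / (2 * pi),
                 drive_frequency = frequency,
                 k = (1 + 1i * damping) * omega / c0, damping = damping,
                 decay = decay,
                 rho0 = rho0, c0 = c0, geometry = geometry,
                 fluid = fluid$name),
            class = "first_order_field")
}

#' @export
print.first_order_field <- function(x, ...) {
  cat(sprintf(
    "<first_order_field> p_a = %.4g Pa, lambda = %.4g m, theta = %g deg\n",
    x$p_a, x$lambda, x$theta_deg))
  cat(sprintf("  f = %.4g MHz, fluid rho0 = %g, c0 = %g\n",
              x$frequency / 1e6, x$rho0, x$c0))
  cat(sprintf("  footprint %g x %g mm, h = %g um\n",
              x$geometry$L * 1e3, x$geometry$w * 1e3, x$geometry$h * 1e6))
  invisible(x)
}

#' First-order velocity from the pressure field
#'
#' Momentum balance of the time-harmonic first-order flow:
#' \eqn{v_{1i} = -\frac{i}{\rho_0 \omega} p_{1,i}}. For the built-in
#' analytic fields the gradient is exact; `method = "grid"` instead
#' differentiates the pressure by central differences with the given
#' spacing (second-order accurate), which is how gridded (imported) fields
#' are handled.
#'
#' @param f `first_order_field`.
#' @param method `"analytic"` or `"grid"`.
#' @param spacing central-difference step, m (grid method).
#' @return `f` with the `velocity` closure (re)bound; for `"grid"` the
#'   closure wraps the finite-difference stencil.
#' @export
velocity_from_pressure <- function(f, method = c("analytic", "grid"),
                                   spacing = f$lambda / 400) {
  method <- match.arg(method)
  stopifnot(inherits(f, "first_order_field"))
  if (is.null(f$rho0) || is.null(f$omega))
    stopf("field is missing rho0 or omega")
  if (method == "analytic") return(f)
  h <- spacing
  pr <- f$pressure
  f$velocity <- function(x, y, z = 0) {
    gx <- (pr(x + h, y, z) - pr(x - h, y, z)) / (2 * h)
    gy <- (pr(x, y + h, z) - pr(x, y - h, z)) / (2 * h)
    gz <- rep(0 + 0i, length(x))
    -1i / (f$rho0 * f$omega) * cbind(gx, gy, gz)
  }
  f
}

#' Pressure nodal (and antinodal) line loci
#'
#' Nodal lines satisfy `x_r - x_ref = (n + 1/2) lambda/2`; antinodal lines
#' interleave them exactly halfway. Lines are clipped to the channel
#' footprint and ordered along the flow axis.
#'
#' @param f `first_order_field`.
#' @param what `"nodes"` or `"antinodes"`.
#' @return data.frame with one row per line: `n`, `x_r` (standing-wave
#'   coordinate of the line), and clipped endpoints `x0, y0, x1, y1`.
#' @export
nodal_lines <- function(f, what = c("nodes", "antinodes")) {
  what <- match.arg(what)
  stopifnot(inherits(f, "first_order_field"))
  g <- f$geometry
  th <- deg2rad(f$theta_deg)
  sx <- sin(th); cy <- cos(th)
  lam <- f$lambda
  # x_r range over the footprint corners
  corners <- rbind(c(0, 0), c(g$L, 0), c(0, g$w), c(g$L, g$w))
  xr_c <- corners[, 1] * sx + corners[, 2] * cy
  off <- if (what == "nodes") lam / 4 else 0
  n0 <- ceiling((min(xr_c) - f$x_ref - off) / (lam / 2))
  n1 <- floor((max(xr_c) - f$x_ref - off) / (lam / 2))
  if (n1 < n0)
    return(data.frame(n = integer(), x_r = numeric(), x0 = numeric(),
                      y0 = numeric(), x1 = numeric(), y1 = numeric()))
  out <- lapply(n0:n1, function(n) {
    xr_line <- f$x_ref + off + n * lam / 2
    seg <- clip_line_to_rect(xr_line, sx, cy, g$L, g$w)
    if (is.null(seg)) return(NULL)
    data.frame(n = n, x_r = xr_line, x0 = seg[1], y0 = seg[2],
               x1 = seg[3], y1 = seg[4])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(n = integer(), x_r = numeric(), x0 = numeric(),
                      y0 = numeric(), x1 = numeric(), y1 = numeric())
  out[order(out$x0, out$x_r), , drop = FALSE]
}

# Clip the line {(x, y): x*sx + y*cy = xr} to [0, L] x [0, w].
clip_line_to_rect <- function(xr, sx, cy, L, w) {
  pts <- list()
  if (abs(cy) > 1e-15) {
    for (x in c(0, L)) {
      y <- (xr - x * sx) / cy
      if (y >= -1e-12 && y <= w + 1e-12)
        pts[[length(pts) + 1]] <- c(x, min(max(y, 0), w))
    }
  }
  if (abs(sx) > 1e-15) {
    for (y in c(0, w)) {
      x <- (xr - y * cy) / sx
      if (x >= -1e-12 && x <= L + 1e-12)
        pts[[length(pts) + 1]] <- c(min(max(x, 0), L), y)
    }
  }
  if (length(pts) < 2) return(NULL)
  m <- unique(do.call(rbind, lapply(pts, round, digits = 15)))
  if (nrow(m) < 2) return(NULL)
  # take the two extreme points
  i <- order(m[, 1], m[, 2])
  c(m[i[1], ], m[i[nrow(m)], ])
}

#' Time-averaged acoustic energy density of the standing wave
#'
#' \eqn{E_{ac} = p_a^2 / (4 \rho_0 c_0^2)}; independent of the tilt angle.
#'
#' @param f `first_order_field`.
#' @return energy density, J/m^3.
#' @export
acoustic_energy_density <- function(f) {
  stopifnot(inherits(f, "first_order_field"))
  f$p_a^2 / (4 * f$rho0 * f$c0^2)
}

#' Helmholtz residual of a field on interior probe points
#'
#' Checks \eqn{|\nabla^2 p_1 + k_0^2 p_1| / (k_0^2 |p_1|)} by central
#' differences (for the analytic lossless standing wave this is limited
#' only by the stencil error). The operative wavenumber is the
#' standing-wave number `k_s`, which for a device-driven field differs
#' from `omega/c0` of the bulk fluid: the SAW imposes its own wavelength.
#'
#' @param f `first_order_field`.
#' @param n number of probe points per axis.
#' @param h stencil step, m.
#' @return maximum relative residual over the probes.
#' @export
helmholtz_residual <- function(f, n = 7, h = f$lambda / 2000) {
  g <- f$geometry
  xs <- seq(0.2, 0.8, length.out = n) * g$L
  ys <- seq(0.2, 0.8, length.out = n) * g$w
  k2 <- f$k_s^2
  worst <- 0
  for (x in xs) for (y in ys) {
    lap <- (f$pressure(x + h, y) + f$pressure(x - h, y) +
              f$pressure(x, y + h) + f$pressure(x, y - h) -
              4 * f$pressure(x, y)) / h^2
    res <- Mod(lap + k2 * f$pressure(x, y)) / (k2 * max(Mod(f$pressure(x, y)), f$p_a * 1e-6))
    worst <- max(worst, res)
  }
  worst
}
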