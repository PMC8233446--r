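# Limiting-velocity slip condition on the vibrating fluid-solid interface.
#
# Rayleigh-Schlichting boundary-layer theory: the oscillatory shear layer of
# thickness delta_nu = sqrt(2 nu / omega) at a vibrating wall drives a
# steady streaming just outside the layer. Rather than resolving the layer,
# the effective steady slip ("limiting velocity") is evaluated from the
# first-order velocity amplitudes at the interface and imposed as a
# boundary condition on the outer Stokes flow.

#' Interface velocity amplitudes on a planar fluid-solid interface
#'
#' In the interface frame (orthonormal tangents x, y and normal z) the
#' tangential components are fluid-minus-wall differences,
#' `u_a0 = v_1x - udot_x`, `v_a0 = v_1y - udot_y`, while the normal
#' component is continuous across the interface, `w_a0 = v_1z = udot_z`.
#'
#' @param f `first_order_field`.
#' @param wall_velocity `NULL` (wall at rest) or a function `(x, y)`
#'   returning an `n x 3` complex matrix of wall velocity amplitudes in the
#'   interface frame.
#' @param frame list with `origin` (3-vector) and `axes` (3x3 matrix whose
#'   columns are the interface tangents and normal, orthonormal). Default:
#'   the channel bottom z = 0 with global axes.
#' @return object of class `interface_velocities`: complex closures
#'   `u_a0(x, y)`, `v_a0(x, y)`, `w_a0(x, y)` and `jacobian(x, y)` giving
#'   the in-plane derivatives `du_dx, du_dy, dv_dx, dv_dy` and the normal
#'   derivative `dw_dz`, all as complex vectors. Coordinates are interface
#'   coordinates.
#' @export
interface_velocities <- function(f, wall_velocity = NULL, frame = NULL) {
  stopifnot(inherits(f, "first_order_field"))
  if (is.null(frame))
    frame <- list(origin = c(0, 0, 0), axes = diag(3))
  ax <- frame$axes
  g <- t(ax) %*% ax
  if (max(abs(g - diag(3))) > 1e-10)
    stopf("interface axes are not orthonormal (max deviation %.2e)",
          max(abs(g - diag(3))))
  to_global <- function(x, y) {
    p <- cbind(x, y, 0) %*% t(ax)
    sweep(p, 2, frame$origin, "+")
  }
  wallv <- wall_velocity %||% function(x, y)
    matrix(0 + 0i, length(x), 3)
  u_a0 <- function(x, y) {
    p <- to_global(x, y)
    vf <- f$velocity(p[, 1], p[, 2], p[, 3]) %*% ax   # project to frame
    vf[, 1] - wallv(x, y)[, 1]
  }
  v_a0 <- function(x, y) {
    p <- to_global(x, y)
    vf <- f$velocity(p[, 1], p[, 2], p[, 3]) %*% ax
    vf[, 2] - wallv(x, y)[, 2]
  }
  w_a0 <- function(x, y) {
    p <- to_global(x, y)
    (f$velocity(p[, 1], p[, 2], p[, 3]) %*% ax)[, 3]
  }
  jacobian <- function(x, y) {
    p <- to_global(x, y)
    jl <- f$velocity_jacobian(p[, 1], p[, 2], p[, 3])
    # project each fluid jacobian into the interface frame
    proj <- lapply(jl, function(j) t(ax) %*% j %*% ax)
    du_dx <- vapply(proj, function(j) j[1, 1], 0i)
    du_dy <- vapply(proj, function(j) j[1, 2], 0i)
    dv_dx <- vapply(proj, function(j) j[2, 1], 0i)
    dv_dy <- vapply(proj, function(j) j[2, 2], 0i)
    dw_dz <- vapply(proj, function(j) j[3, 3], 0i)
    # wall contribution to tangential derivatives (numeric, in-plane)
    if (!is.null(wall_velocity)) {
      hstep <- 1e-6
      wv <- function(xx, yy) wall_velocity(xx, yy)
      du_dx <- du_dx - (wv(x + hstep, y)[, 1] - wv(x - hstep, y)[, 1]) /
        (2 * hstep)
      du_dy <- du_dy - (wv(x, y + hstep)[, 1] - wv(x, y - hstep)[, 1]) /
        (2 * hstep)
      dv_dx <- dv_dx - (wv(x + hstep, y)[, 2] - wv(x - hstep, y)[, 2]) /
        (2 * hstep)
      dv_dy <- dv_dy - (wv(x, y + hstep)[, 2] - wv(x, y - hstep)[, 2]) /
        (2 * hstep)
    }
    list(du_dx = du_dx, du_dy = du_dy, dv_dx = dv_dx, dv_dy = dv_dy,
         dw_dz = dw_dz)
  }
  structure(list(u_a0 = u_a0, v_a0 = v_a0, w_a0 = w_a0,
                 jacobian = jacobian, frame = frame, omega = f$omega),
            class = "interface_velocities")
}

#' Limiting (slip) velocity on the interface
#'
#' Nyborg's near-boundary streaming solution with the Lee-Wang
#' modification, evaluated term by term:
#' \deqn{u_L = -\frac{1}{4\omega}\mathrm{Re}\Big\{
#'   u_{a0}\frac{du_{a0}^*}{dx} + v_{a0}\frac{du_{a0}^*}{dy}
#'   + u_{a0}^*\Big[(2+i)\Big(\frac{du_{a0}}{dx} + \frac{dv_{a0}}{dy}
#'   + \frac{dw_{a0}}{dz}\Big) - (2+3i)\frac{dw_{a0}}{dz}\Big]\Big\}}
#' and the y-component with `u <-> v` exchanged in the leading role. For a
#' one-dimensional standing wave `u_a0 = i v_a sin(kx)` over a resting wall
#' this reduces to the classical Rayleigh slip
#' `u_L = -(3/8)(v_a^2/c_0) sin(2kx)`.
#'
#' @param iv [interface_velocities()] object (or a compatible list of
#'   closures with an `omega`).
#' @param grid list with numeric vectors `x` and `y`: interface
#'   coordinates at which to evaluate.
#' @param derivs `"analytic"` (use `iv$jacobian`) or `"numeric"` (central
#'   differences of the amplitude closures with step `step`).
#' @param step central-difference step for `derivs = "numeric"`, m.
#' @return object of class `limiting_velocity_field`: matrices `uL`, `vL`
#'   (length(x) by length(y), m/s, real), the grid, and the frame.
#' @export
limiting_velocity <- function(iv, grid, derivs = c("analytic", "numeric"),
                              step = NULL) {
  derivs <- match.arg(derivs)
  omega <- iv$omega
  assert_positive(omega, "omega")
  xs <- grid$x; ys <- grid$y
  xg <- rep(xs, times = length(ys))
  yg <- rep(ys, each = length(xs))
  u <- iv$u_a0(xg, yg); v <- iv$v_a0(xg, yg)
  if (derivs == "analytic" && !is.null(iv$jacobian)) {
    j <- iv$jacobian(xg, yg)
  } else {
    h <- step %||% (min(diff(range(xs)), diff(range(ys))) / 400)
    if (h <= 0) h <- 1e-7
    j <- list(
      du_dx = (iv$u_a0(xg + h, yg) - iv$u_a0(xg - h, yg)) / (2 * h),
      du_dy = (iv$u_a0(xg, yg + h) - iv$u_a0(xg, yg - h)) / (2 * h),
      dv_dx = (iv$v_a0(xg + h, yg) - iv$v_a0(xg - h, yg)) / (2 * h),
      dv_dy = (iv$v_a0(xg, yg + h) - iv$v_a0(xg, yg - h)) / (2 * h),
      dw_dz = if (!is.null(iv$dw_dz)) iv$dw_dz(xg, yg)
              else rep(0 + 0i, length(xg)))
  }
  dil <- j$du_dx + j$dv_dy + j$dw_dz
  uL <- -1 / (4 * omega) * Re(
    u * Conj(j$du_dx) + v * Conj(j$du_dy) +
      Conj(u) * ((2 + 1i) * dil - (2 + 3i) * j$dw_dz))
  vL <- -1 / (4 * omega) * Re(
    u * Conj(j$dv_dx) + v * Conj(j$dv_dy) +
      Conj(v) * ((2 + 1i) * dil - (2 + 3i) * j$dw_dz))
  structure(list(x = xs, y = ys,
                 uL = matrix(uL, length(xs), length(ys)),
                 vL = matrix(vL, length(xs), length(ys)),
                 frame = iv$frame %||% list(origin = c(0, 0, 0),
                                            axes = diag(3)),
                 omega = omega),
            class = "limiting_velocity_field")
}

#' @export
print.limiting_velocity_field <- function(x, ...) {
  cat(sprintf("<limiting_velocity_field> %d x %d grid, max |slip| = %.4g m/s\n",
              length(x$x), length(x$y),
              max(sqrt(x$uL^2 + x$vL^2))))
  invisible(x)
}

# Bilinear interpolation of a grid matrix at query points (clamped).
interp2 <- function(xg, yg, m, xq, yq) {
  xq <- pmin(pmax(xq, xg[1]), xg[length(xg)])
  yq <- pmin(pmax(yq, yg[1]), yg[length(yg)])
  i <- pmin(pmax(findInterval(xq, xg), 1L), length(xg) - 1L)
  j <- pmin(pmax(findInterval(yq, yg), 1L), length(yg) - 1L)
  tx <- (xq - xg[i]) / (xg[i + 1] - xg[i])
  ty <- (yq - yg[j]) / (yg[j + 1] - yg[j])
  m[cbind(i, j)] * (1 - tx) * (1 - ty) +
    m[cbind(i + 1, j)] * tx * (1 - ty) +
    m[cbind(i, j + 1)] * (1 - tx) * ty +
    m[cbind(i + 1, j + 1)] * tx * ty
}

#' Limiting-velocity magnitude along a probe line
#'
#' Samples `sqrt(uL^2 + vL^2)` by bilinear interpolation along the segment
#' from `from` to `to` (interface coordinates), mirroring the
#' centre-line magnitude plots used to locate the slip extrema relative to
#' the pressure nodes and antinodes.
#'
#' @param lv `limiting_velocity_field`.
#' @param from,to numeric length-2 segment endpoints, m.
#' @param n number of samples.
#' @return data.frame with `s` (arc length), `x`, `y`, `magnitude`.
#' @export
limiting_velocity_profile <- function(lv, from, to, n = 200) {
  stopifnot(inherits(lv, "limiting_velocity_field"))
  tpar <- seq(0, 1, length.out = n)
  xq <- from[1] + tpar * (to[1] - from[1])
  yq <- from[2] + tpar * (to[2] - from[2])
  u <- interp2(lv$x, lv$y, lv$uL, xq, yq)
  v <- interp2(lv$x, lv$y, lv$vL, xq, yq)
  data.frame(s = tpar * sqrt(sum((to - from)^2)), x = xq, y = yq,
             magnitude = sqrt(u^2 + v^2))
}

#' Validity report for the limiting-velocity method
#'
#' The slip condition assumes (i) a boundary layer much thinner than both
#' the channel and any wall curvature radius and (ii) an established
#' streaming field at high Womersley-type number `|M| = h sqrt(omega/nu)`.
#'
#' @param omega angular frequency, rad/s.
#' @param eta dynamic viscosity, Pa s. @param rho fluid density, kg/m^3.
#' @param length_scales list with `h` (smallest channel dimension, m) and
#'   optionally `curvature_radius` (m, default `Inf` for planar walls).
#' @return list with `delta_nu`, `womersley`, `delta_over_curvature`,
#'   logical `valid` and character `flags` explaining any violation.
#' @export
limiting_validity <- function(omega, eta, rho, length_scales) {
  if (omega < 0 || eta < 0) stopf("omega and eta must be non-negative")
  assert_positive(rho, "rho")
  h <- length_scales$h
  assert_positive(h, "length_scales$h")
  rc <- length_scales$curvature_radius %||% Inf
  nu <- eta / rho
  delta <- if (omega > 0) sqrt(2 * nu / omega) else Inf
  m_w <- if (nu > 0) h * sqrt(omega / nu) else Inf
  flags <- character()
  if (!(m_w > 10))
    flags <- c(flags, sprintf(
      "Womersley number |M| = %.3g is not >> 1; outer-streaming expansion invalid",
      m_w))
  if (is.finite(delta) && delta / h > 0.1)
    flags <- c(flags, sprintf(
      "boundary layer delta_nu = %.3g m is not small versus channel %.3g m",
      delta, h))
  if (is.finite(rc) && is.finite(delta) && delta / rc > 0.1)
    flags <- c(flags, sprintf(
      "wall curvature radius %.3g m comparable to delta_nu = %.3g m", rc,
      delta))
  if (!is.finite(delta))
    flags <- c(flags, "omega = 0: no oscillatory boundary layer exists")
  list(delta_nu = delta, womersley = m_w,
       delta_over_curvature = if (is.finite(rc)) delta / rc else 0,
       valid = length(flags) == 0, flags = flags)
}
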