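# Free-surface Rayleigh SAW on a piezoelectric half-space via the
# partial-wave (Stroh) formalism under the quasi-static electric
# approximation. The substrate occupies z <= 0; partial waves go as
# exp(i k (x + alpha z - v t)) and decaying waves have Im(alpha) < 0.

# Nondimensionalized tensors: stiffness by c_ref, permittivity by eps_ref,
# piezo constants by sqrt(c_ref * eps_ref), and the potential rescaled as
# phi_tilde = phi * sqrt(eps_ref / c_ref). This keeps every Stroh block
# O(1); without it the z-block mixes 1e11 Pa with 1e-11 F/m entries and is
# numerically singular. Depth wavenumbers are unaffected.
scaled_tensors <- function(t) {
  cref <- max(abs(t$c)); eref <- max(abs(t$eps))
  list(cf = stiffness_full(t$c) / cref,
       ef = piezo_full(t$e) / sqrt(cref * eref),
       eps = t$eps / eref,
       cref = cref,
       phi_scale = sqrt(cref / eref))
}

# 4x4 acoustic tensor block: rows/cols 1:3 mechanical, 4 electric potential.
# G(p, q) contracts the material tensors with unit vectors p (first
# derivative slot) and q (second).
stroh_block <- function(cf, ef, eps, p, q) {
  g <- matrix(0, 4, 4)
  for (i in 1:3) for (k in 1:3)
    g[i, k] <- sum(outer(p, q) * cf[i, , k, ])   # c_{ijkl} p_j q_l
  for (i in 1:3)
    g[i, 4] <- sum(outer(p, q) * t(ef[, i, ]))   # e_{kij} p_k q_j
  for (k in 1:3)
    g[4, k] <- sum(outer(p, q) * ef[, k, ])      # e_{ikl} p_i q_l
  g[4, 4] <- -sum(outer(p, q) * eps)             # -eps_{ij} p_i q_j
  g
}

#' Partial-wave spectrum at a trial phase velocity
#'
#' Solves the quadratic (8x8 companion) eigenproblem of the quasi-static
#' Stroh formulation for plane waves `exp(i k (x + alpha z - v t))` in a
#' piezoelectric half-space: 3 mechanical displacement components plus the
#' electric potential. Eigenvalues `alpha` are the depth wavenumbers of the
#' eight partial waves; for a subsonic (true Rayleigh) search they come in
#' four conjugate pairs, and the four with `Im(alpha) < 0` decay into the
#' substrate `z < 0`.
#'
#' @param t [piezo_tensors()] rotated to the plate frame.
#' @param v trial phase velocity, m/s.
#' @return list with `alpha` (8 complex depth wavenumbers), `vectors`
#'   (4x8 complex matrix, rows u1, u2, u3, phi) and `decaying`
#'   (indices of the four decaying waves).
#' @export
partial_wave_spectrum <- function(t, v) {
  stopifnot(inherits(t, "piezo_tensors"))
  if (v < 0) stopf("phase velocity must be non-negative")
  st <- scaled_tensors(t)
  cf <- st$cf; ef <- st$ef; eps <- st$eps
  e1 <- c(1, 0, 0); e3 <- c(0, 0, 1)
  g11 <- stroh_block(cf, ef, eps, e1, e1)
  g13 <- stroh_block(cf, ef, eps, e1, e3)
  g31 <- stroh_block(cf, ef, eps, e3, e1)
  g33 <- stroh_block(cf, ef, eps, e3, e3)
  x <- diag(c(1, 1, 1, 0)) * t$rho * v^2 / st$cref
  g33i <- tryCatch(solve(g33), error = function(e)
    stopf("Stroh z-block is singular for this material orientation"))
  comp <- rbind(cbind(matrix(0, 4, 4), diag(4)),
                cbind(-g33i %*% (g11 - x), -g33i %*% (g13 + g31)))
  es <- eigen(comp)
  alpha <- es$values
  vecs <- es$vectors[1:4, , drop = FALSE]
  # normalize each partial-wave amplitude vector
  nrm <- sqrt(colSums(Mod(vecs)^2))
  if (any(nrm == 0))
    stopf("defective eigensystem at v = %g m/s; perturb the trial velocity", v)
  vecs <- sweep(vecs, 2, nrm, "/")
  # refine each eigenpair on the quadratic pencil (companion-form eigen()
  # leaves ~1e-8 noise; two Newton + inverse-iteration sweeps reach ~1e-13)
  g13s <- g13 + g31
  for (j in seq_along(alpha)) {
    al <- alpha[j]; a <- vecs[, j]
    for (it in 1:2) {
      q <- (g11 - x) + al * g13s + al^2 * g33
      den <- sum(Conj(a) * ((g13s + 2 * al * g33) %*% a))
      if (Mod(den) > 1e-14)
        al <- al - sum(Conj(a) * (q %*% a)) / den
      q <- (g11 - x) + al * g13s + al^2 * g33
      a_new <- tryCatch(solve(q, a), error = function(e) NULL)
      if (!is.null(a_new) && all(is.finite(Mod(a_new))) &&
          max(Mod(a_new)) > 0)
        a <- a_new / sqrt(sum(Mod(a_new)^2))
    }
    alpha[j] <- al; vecs[, j] <- a
  }
  dec <- which(Im(alpha) < -1e-9)
  list(alpha = alpha, vectors = vecs, decaying = dec)
}

# Surface boundary rows (traction T_13, T_23, T_33 and normal electric
# displacement D_3, all divided by i*k) for one partial wave.
boundary_column <- function(cf, ef, eps, alpha, a) {
  u <- a[1:4]
  tr <- complex(real = numeric(3))
  col <- complex(length.out = 4)
  for (i in 1:3) {
    s <- 0
    for (k in 1:3)
      s <- s + (cf[i, 3, k, 1] + alpha * cf[i, 3, k, 3]) * u[k]
    s <- s + (ef[1, i, 3] + alpha * ef[3, i, 3]) * u[4]
    col[i] <- s
  }
  s <- 0
  for (k in 1:3)
    s <- s + (ef[3, k, 1] + alpha * ef[3, k, 3]) * u[k]
  s <- s - (eps[3, 1] + alpha * eps[3, 3]) * u[4]
  col[4] <- s
  col
}

surface_boundary_matrix <- function(t, v) {
  sp <- partial_wave_spectrum(t, v)
  if (length(sp$decaying) != 4)
    stopf("expected 4 decaying partial waves at v = %g m/s, found %d (above a bulk-wave threshold?)",
          v, length(sp$decaying))
  st <- scaled_tensors(t)
  b <- sapply(sp$decaying, function(m)
    boundary_column(st$cf, st$ef, st$eps, sp$alpha[m], sp$vectors[, m]))
  list(B = b, spectrum = sp)
}

# |det| of a complex matrix via QR (base::det is real-only).
cdet_mod <- function(b) prod(Mod(diag(qr(b)$qr)))

# complex determinant (phase-consistent) via eigenvalues; 4x4 only.
cdet <- function(b) prod(eigen(b, only.values = TRUE)$values)

boundary_det_complex <- function(t, v) {
  bm <- surface_boundary_matrix(t, v)
  b <- bm$B
  cdet(sweep(b, 2, sqrt(colSums(Mod(b)^2)), "/"))
}

# Normalized boundary determinant magnitude: |det(B)| with unit columns,
# a scale-free measure in [0, O(1)] that vanishes at a surface-wave root.
boundary_residual <- function(t, v) {
  bm <- surface_boundary_matrix(t, v)
  b <- bm$B
  b <- sweep(b, 2, sqrt(colSums(Mod(b)^2)), "/")
  cdet_mod(b)
}

#' Free-surface SAW phase velocity and mode
#'
#' Finds the Rayleigh surface-wave root of the 4x4 surface
#' boundary-condition determinant (traction-free and charge-free surface)
#' over the four decaying partial waves, by a 201-sample scan of the
#' normalized determinant magnitude over the bracket followed by local
#' refinement. Leaky/pseudo-SAW branches (complex velocity roots) are out
#' of scope.
#'
#' @param t [piezo_tensors()] in the plate frame (z = surface normal,
#'   x = propagation).
#' @param bracket length-2 velocity interval to search, m/s.
#' @param n_scan number of scan samples (default 201).
#' @param tol acceptance threshold on the normalized boundary determinant.
#' @return object of class `saw_mode`: `v_R` (m/s), `alpha` (4 decaying
#'   depth wavenumbers), `amplitudes` (4x4 complex, rows u1,u2,u3,phi),
#'   `weights` (partial-wave weights, normalized to unit surface normal
#'   displacement), `residual`, `rho`.
#' @export
#' @examples
#' \donttest{
#' lno <- lithium_niobate_128yx()
#' mode <- saw_velocity_free_surface(lno, bracket = c(3600, 4300))
#' mode$v_R  # close to the tabulated 3997 m/s
#' }
saw_velocity_free_surface <- function(t, bracket, n_scan = 201,
                                      tol = 1e-6) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  vs <- seq(bracket[1], bracket[2], length.out = n_scan)
  g <- vapply(vs, function(v)
    tryCatch(boundary_residual(t, v), error = function(e) NA_real_), 0)
  ok <- which(!is.na(g))
  if (length(ok) < 3)
    stopf("boundary determinant undefined over almost all of [%g, %g]",
          bracket[1], bracket[2])
  # interior local minima of |det|
  cand <- ok[-c(1, length(ok))]
  is_min <- vapply(cand, function(i)
    !is.na(g[i - 1]) && !is.na(g[i + 1]) &&
      g[i] <= g[i - 1] && g[i] <= g[i + 1], TRUE)
  mins <- cand[is_min]
  if (length(mins) == 0)
    stopf("no surface-wave root in [%g, %g]: |det| at endpoints %.3e / %.3e",
          bracket[1], bracket[2], g[ok[1]], g[ok[length(ok)]])
  best <- NULL
  for (i in mins[order(g[mins])]) {
    opt <- stats::optimize(function(v) boundary_residual(t, v),
                           lower = vs[i - 1], upper = vs[i + 1],
                           tol = 1e-13 * vs[i])
    if (opt$objective < tol) { best <- opt; break }
  }
  if (is.null(best))
    stopf("no surface-wave root below tolerance %.1e in [%g, %g]; smallest |det| = %.3e at %g m/s (endpoints %.3e / %.3e)",
          tol, bracket[1], bracket[2], min(g[mins]), vs[which.min(g)],
          g[ok[1]], g[ok[length(ok)]])
  v_R <- best$minimum
  # optimize() stalls near sqrt(machine eps). The smallest singular
  # value of the normalized boundary matrix behaves as s*|v - v*| near
  # the root, so the vertex can be localized from two flanking samples
  # and sharpened geometrically down to machine precision.
  sigma4 <- function(v) {
    b <- surface_boundary_matrix(t, v)$B
    min(svd(sweep(b, 2, sqrt(colSums(Mod(b)^2)), "/"))$d)
  }
  hv <- 5e-5 * v_R
  for (it in 1:24) {
    fm1 <- tryCatch(sigma4(v_R - hv), error = function(e) NA_real_)
    fp1 <- tryCatch(sigma4(v_R + hv), error = function(e) NA_real_)
    if (!is.finite(fm1) || !is.finite(fp1)) break
    d <- hv * (fm1 - fp1) / (fm1 + fp1)
    if (!is.finite(d)) break
    v_R <- v_R + max(min(d, hv), -hv)
    hv <- hv / 3
    if (hv < 4 * .Machine$double.eps * v_R) break
  }
  if (boundary_residual(t, v_R) > best$objective) v_R <- best$minimum
  bm <- surface_boundary_matrix(t, v_R)
  b <- bm$B
  bn <- sweep(b, 2, sqrt(colSums(Mod(b)^2)), "/")
  sv <- svd(bn)
  w <- sv$v[, 4] / sqrt(colSums(Mod(b)^2))  # null weights of raw B
  amps <- bm$spectrum$vectors[, bm$spectrum$decaying, drop = FALSE]
  u0 <- amps %*% w
  if (Mod(u0[3]) < 1e-12 * max(Mod(u0)))
    stopf("degenerate mode: vanishing surface normal displacement")
  w <- w / u0[3]                      # unit surface normal displacement
  residual <- max(Mod(b %*% w)) / max(Mod(b))
  structure(list(v_R = v_R, alpha = bm$spectrum$alpha[bm$spectrum$decaying],
                 amplitudes = amps, weights = as.vector(w),
                 residual = residual, det_value = best$objective,
                 rho = t$rho, phi_scale = scaled_tensors(t)$phi_scale),
            class = "saw_mode")
}

#' @export
print.saw_mode <- function(x, ...) {
  cat(sprintf("<saw_mode> v_R = %.2f m/s  (boundary residual %.2e)\n",
              x$v_R, x$residual))
  invisible(x)
}

#' Depth profiles of a SAW mode
#'
#' Evaluates the complex displacement components and electric potential on
#' a depth grid (default 400 points over two wavelengths below the
#' surface).
#'
#' @param m [saw_velocity_free_surface()] result.
#' @param lambda SAW wavelength, m.
#' @param n number of grid points.
#' @return data.frame with `z` (<= 0, m) and complex `u1, u2, u3, phi`.
#' @export
saw_mode_profile <- function(m, lambda, n = 400) {
  stopifnot(inherits(m, "saw_mode"))
  assert_positive(lambda, "lambda")
  k <- 2 * pi / lambda
  z <- seq(-2 * lambda, 0, length.out = n)
  ph <- exp(1i * k * outer(z, m$alpha))      # n x 4
  f <- ph %*% (m$weights * t(m$amplitudes))  # n x 4 fields
  data.frame(z = z, u1 = f[, 1], u2 = f[, 2], u3 = f[, 3],
             phi = f[, 4] * (m$phi_scale %||% 1))
}

# Analytic depth integral of rho*|u|^2 over [-d, 0] (d = Inf allowed);
# proportional to the time-averaged kinetic energy in the layer.
mode_energy_integral <- function(m, k, d) {
  wamp <- sweep(m$amplitudes[1:3, , drop = FALSE], 2, m$weights, "*")
  tot <- 0
  for (mm in 1:4) for (nn in 1:4) {
    beta <- 1i * k * (m$alpha[mm] - Conj(m$alpha[nn]))
    intz <- if (is.infinite(d)) 1 / beta else (1 - exp(-beta * d)) / beta
    tot <- tot + sum(wamp[, mm] * Conj(wamp[, nn])) * intz
  }
  Re(tot)
}

#' Mode diagnostics: energy confinement and polarization
#'
#' Reports the fraction of the mode's kinetic energy within one wavelength
#' of the surface (a Rayleigh mode keeps about 90% there) and the surface
#' polarization: sagittal ellipse axes `|u1|, |u3|` and the transverse
#' amplitude `|u2|` (zero for an isotropic Rayleigh wave).
#'
#' @param m `saw_mode`. @param lambda wavelength, m.
#' @return list with `energy_fraction_1lambda`, `ellipse`
#'   (`ux`, `uy`, `uz`, `axis_ratio` = |u1|/|u3|, `transverse_fraction`).
#' @export
mode_diagnostics <- function(m, lambda) {
  stopifnot(inherits(m, "saw_mode"))
  assert_positive(lambda, "lambda")
  k <- 2 * pi / lambda
  frac <- mode_energy_integral(m, k, lambda) /
    mode_energy_integral(m, k, Inf)
  u0 <- as.vector(m$amplitudes[1:3, , drop = FALSE] %*% m$weights)
  amp <- Mod(u0)
  list(energy_fraction_1lambda = frac,
       ellipse = list(ux = amp[1], uy = amp[2], uz = amp[3],
                      axis_ratio = amp[1] / amp[3],
                      transverse_fraction =
                        amp[2] / sqrt(sum(amp^2))))
}
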