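# Piezoelectric tensor sets in Voigt notation and their rotation to
# arbitrary crystallographic cuts via Bond matrices.

#' Construct a piezoelectric tensor set
#'
#' Stress-charge form: stress `T = c S - e^T E`, electric displacement
#' `D = e S + eps E`, with `c` the 6x6 Voigt stiffness (Pa), `e` the 3x6
#' piezoelectric stress matrix (C/m^2) and `eps` the 3x3 clamped
#' permittivity (F/m).
#'
#' @param stiffness 6x6 symmetric positive-definite matrix, Pa.
#' @param piezo 3x6 matrix, C/m^2.
#' @param permittivity 3x3 symmetric positive-definite matrix, F/m.
#' @param density kg/m^3.
#' @param name optional label.
#' @return object of class `piezo_tensors`.
#' @export
piezo_tensors <- function(stiffness, piezo, permittivity, density,
                          name = "unnamed") {
  stopifnot(is.matrix(stiffness), all(dim(stiffness) == c(6, 6)),
            is.matrix(piezo), all(dim(piezo) == c(3, 6)),
            is.matrix(permittivity), all(dim(permittivity) == c(3, 3)))
  assert_positive(density, "density")
  if (max(abs(stiffness - t(stiffness))) > 1e-6 * max(abs(stiffness)))
    stopf("stiffness matrix is not symmetric")
  if (max(abs(permittivity - t(permittivity))) >
      1e-9 * max(abs(permittivity)))
    stopf("permittivity matrix is not symmetric")
  if (any(eigen(stiffness, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stopf("stiffness matrix is not positive definite")
  if (any(eigen(permittivity, symmetric = TRUE,
                only.values = TRUE)$values <= 0))
    stopf("permittivity matrix is not positive definite")
  structure(list(c = stiffness, e = piezo, eps = permittivity,
                 rho = density, name = name),
            class = "piezo_tensors")
}

#' @export
print.piezo_tensors <- function(x, ...) {
  cat(sprintf("<piezo_tensors> %s  (rho = %g kg/m^3)\n", x$name, x$rho))
  cat(sprintf("  c11 = %.4g GPa, c33 = %.4g GPa, c44 = %.4g GPa\n",
              x$c[1, 1] / 1e9, x$c[3, 3] / 1e9, x$c[4, 4] / 1e9))
  cat(sprintf("  max |e| = %.3g C/m^2, eps11/eps0 = %.3g\n",
              max(abs(x$e)), x$eps[1, 1] / 8.8541878128e-12))
  invisible(x)
}

#' Crystallographic cut as a proper rotation
#'
#' Builds the rotation from the crystal frame to the plate frame
#' (z = outward surface normal, x = propagation direction). Either a 3x3
#' proper rotation matrix or Euler-style axis angles (degrees, applied as
#' Rx then Ry then Rz) may be given.
#'
#' The rotated-Y-cut convention used for "128 deg YX" lithium niobate is a
#' single rotation about the crystal X axis by (cut angle - 90) degrees
#' so that propagation is along crystal X; the sense of the rotation is a
#' convention choice exposed through `sense`.
#'
#' @param rotation 3x3 proper rotation matrix, or `NULL` when `angles` given.
#' @param angles numeric length-3, degrees about x, y, z (applied in order).
#' @param sense +1 or -1, multiplies the angles (axis-sense convention).
#' @return object of class `crystal_cut` holding `$a`, the 3x3 rotation.
#' @export
#' @examples
#' crystal_cut(angles = c(38, 0, 0))  # 128-degree rotated Y cut, X propagation
crystal_cut <- function(rotation = NULL, angles = NULL, sense = 1) {
  if (is.null(rotation)) {
    stopifnot(length(angles) == 3)
    ang <- deg2rad(sense * angles)
    rx <- rot_axis(1, ang[1]); ry <- rot_axis(2, ang[2])
    rz <- rot_axis(3, ang[3])
    rotation <- rz %*% ry %*% rx
  }
  check_rotation(rotation)
  structure(list(a = rotation), class = "crystal_cut")
}

rot_axis <- function(axis, th) {
  c0 <- cos(th); s0 <- sin(th)
  m <- diag(3)
  idx <- setdiff(1:3, axis)
  m[idx[1], idx[1]] <- c0; m[idx[2], idx[2]] <- c0
  m[idx[1], idx[2]] <- -s0; m[idx[2], idx[1]] <- s0
  m
}

check_rotation <- function(a, tol = 1e-12) {
  stopifnot(is.matrix(a), all(dim(a) == c(3, 3)))
  g <- t(a) %*% a
  err <- abs(g - diag(3))
  if (max(err) > tol) {
    bad <- which.max(apply(err, 2, max))
    stopf("rotation matrix is not orthonormal: column %d deviates by %.2e",
          bad, max(err[, bad]))
  }
  if (abs(det(a) - 1) > 1e-10)
    stopf("rotation matrix must be proper (det = +1), got det = %.6f", det(a))
  invisible(a)
}

#' Bond stress transformation matrix
#'
#' 6x6 matrix `M` such that Voigt stress vectors transform as `T' = M T`
#' under the 3x3 rotation `a`; stiffness then transforms as `M c M^T`.
#'
#' @param a 3x3 rotation matrix.
#' @return 6x6 Bond matrix.
#' @export
bond_matrix <- function(a) {
  check_rotation(a)
  m <- matrix(0, 6, 6)
  pairs <- list(c(2, 3), c(3, 1), c(1, 2))
  for (i in 1:3) {
    m[i, 1:3] <- a[i, ]^2
    for (j in 1:3) {
      pq <- pairs[[j]]
      m[i, 3 + j] <- 2 * a[i, pq[1]] * a[i, pq[2]]
    }
  }
  for (i in 1:3) {
    pq_i <- pairs[[i]]
    p <- pq_i[1]; q <- pq_i[2]
    m[3 + i, 1:3] <- a[p, ] * a[q, ]
    for (j in 1:3) {
      rs <- pairs[[j]]
      r <- rs[1]; s <- rs[2]
      m[3 + i, 3 + j] <- a[p, r] * a[q, s] + a[p, s] * a[q, r]
    }
  }
  m
}

#' Rotate a piezoelectric tensor set to a crystallographic cut
#'
#' Applies the Bond-matrix transformation for the stiffness and the mixed
#' vector/Voigt transformation for the piezoelectric and permittivity
#' matrices: `c' = M c M^T`, `e' = a e M^T`, `eps' = a eps a^T`.
#'
#' @param t [piezo_tensors()] set in the crystal frame.
#' @param cut [crystal_cut()].
#' @return rotated `piezo_tensors` set (plate frame).
#' @export
rotate_tensors <- function(t, cut) {
  stopifnot(inherits(t, "piezo_tensors"), inherits(cut, "crystal_cut"))
  a <- cut$a
  m <- bond_matrix(a)
  cp <- m %*% t$c %*% t(m)
  cp <- (cp + t(cp)) / 2            # kill rotation round-off asymmetry
  ep <- a %*% t$e %*% t(m)
  epsp <- a %*% t$eps %*% t(a)
  epsp <- (epsp + t(epsp)) / 2
  piezo_tensors(cp, ep, epsp, t$rho,
                name = paste0(t$name, " [rotated]"))
}

#' Lithium niobate single-crystal constants
#'
#' Trigonal 3m stress-charge constants in the crystal frame. Values are the
#' standard single-crystal literature set (Warner, Onoe and Coquin's
#' measurements, as tabulated in Auld's reference tables): stiffness in Pa,
#' piezoelectric stress constants in C/m^2, clamped relative permittivities
#' 44 and 29, density 4700 kg/m^3. They are embedded as code because the
#' device papers only quote the effective SAW speed of the rotated cut; the
#' set is validated through the free-surface SAW speed it predicts for the
#' 128-degree YX cut rather than bit-exact values.
#'
#' @return [piezo_tensors()] in the crystal frame.
#' @export
#' @examples
#' lno <- lithium_niobate_tensors()
#' rot <- rotate_tensors(lno, crystal_cut(angles = c(38, 0, 0)))
lithium_niobate_tensors <- function() {
  c11 <- 2.03e11; c12 <- 0.53e11; c13 <- 0.75e11; c14 <- 0.09e11
  c33 <- 2.45e11; c44 <- 0.60e11; c66 <- (c11 - c12) / 2
  cc <- matrix(0, 6, 6)
  cc[1, 1] <- cc[2, 2] <- c11; cc[3, 3] <- c33
  cc[1, 2] <- cc[2, 1] <- c12
  cc[1, 3] <- cc[3, 1] <- cc[2, 3] <- cc[3, 2] <- c13
  cc[1, 4] <- cc[4, 1] <- c14
  cc[2, 4] <- cc[4, 2] <- -c14
  cc[5, 6] <- cc[6, 5] <- c14
  cc[4, 4] <- cc[5, 5] <- c44; cc[6, 6] <- c66
  e15 <- 3.7; e22 <- 2.5; e31 <- 0.2; e33 <- 1.3
  e <- matrix(0, 3, 6)
  e[1, 5] <- e15; e[1, 6] <- -e22
  e[2, 1] <- -e22; e[2, 2] <- e22; e[2, 4] <- e15
  e[3, 1] <- e31; e[3, 2] <- e31; e[3, 3] <- e33
  eps0 <- 8.8541878128e-12
  eps <- diag(c(44, 44, 29)) * eps0
  piezo_tensors(cc, e, eps, 4700, name = "LiNbO3 (crystal frame)")
}

#' @rdname lithium_niobate_tensors
#' @param sense rotation-sense convention passed to [crystal_cut()].
#' @return for `lithium_niobate_128yx()`: the tensor set rotated to the
#'   128-degree YX cut with propagation along crystal X.
#' @export
lithium_niobate_128yx <- function(sense = 1) {
  # Default sense rotates by -(128 - 90) degrees about crystal X under this
  # package's active rotation-matrix convention; it is the convention that
  # recovers the known ~3997 m/s SAW speed of the 128-degree YX cut
  # (sense = -1 selects the mirror cut, ~3677 m/s).
  rotate_tensors(lithium_niobate_tensors(),
                 crystal_cut(angles = c(-(128 - 90), 0, 0), sense = sense))
}

# 3x3x3x3 stiffness from Voigt, and the inverse map. Used by the SAW
# solver, and by tests as an independent rotation oracle.
voigt_pairs <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))

voigt_index <- function(i, j) {
  if (i == j) return(i)
  6 - i - j + 3   # (2,3)->4, (1,3)->5, (1,2)->6
}

stiffness_full <- function(cv) {
  cf <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    cf[i, j, k, l] <- cv[voigt_index(i, j), voigt_index(k, l)]
  cf
}

piezo_full <- function(ev) {
  ef <- array(0, c(3, 3, 3))
  for (i in 1:3) for (k in 1:3) for (l in 1:3)
    ef[i, k, l] <- ev[i, voigt_index(k, l)]
  ef
}

#' Isotropic elastic tensor set (non-piezoelectric limit)
#'
#' Convenience constructor mainly used to exercise the SAW solver against
#' classical Rayleigh-wave results: zero piezoelectric coupling and vacuum
#' permittivity.
#'
#' @param young Young's modulus, Pa. @param poisson Poisson ratio.
#' @param density kg/m^3.
#' @return [piezo_tensors()] set.
#' @export
isotropic_tensors <- function(young, poisson, density) {
  lam <- young * poisson / ((1 + poisson) * (1 - 2 * poisson))
  mu <- young / (2 * (1 + poisson))
  cc <- matrix(0, 6, 6)
  cc[1:3, 1:3] <- lam
  diag(cc)[1:3] <- lam + 2 * mu
  diag(cc)[4:6] <- mu
  eps0 <- 8.8541878128e-12
  piezo_tensors(cc, matrix(0, 3, 6), diag(3) * eps0, density,
                name = "isotropic")
}
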