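# Second-order (steady streaming) creeping flow in the channel box.
#
# grad p2 = eta lap v2, div v2 = 0, with the limiting-velocity slip on the
# bottom (substrate) face, no-slip on the top and side (PDMS) walls and
# periodic ends along the flow axis. Discretized on a staggered (MAC) grid
# in (y, z) with a Fourier (spectral) treatment of the periodic x
# direction: each x mode decouples into a small 2D saddle problem solved
# directly with sparse LU. The "stress-free" end option is realized by
# mirror extension (symmetry planes at both ends).
#
# Only the Stokes dynamic pressure is reported as p2; mean second-order
# pressures that include Reynolds-stress/Bernoulli contributions are a
# different quantity.

#' Solve the slip-driven second-order Stokes flow
#'
#' @param geometry list with `L`, `w`, `h` (m).
#' @param slip the bottom-face slip: either a
#'   [limiting_velocity()] field (bilinearly interpolated onto the solver
#'   grid) or a function `(x, y)` returning `list(u =, v =)` vectors.
#' @param eta dynamic viscosity, Pa s.
#' @param grid integer length-3 `c(nx, ny, nz)`; `nz >= 8` enforced.
#'   `ny = 1` solves the 2D (x, z) limit with no side walls.
#' @param ends `"periodic"` (default) or `"stress-free"` (symmetry planes
#'   via mirror extension).
#' @param pin_cell integer `c(j, k)` cell whose mean pressure is pinned to
#'   zero (the arbitrary gauge of the periodic problem); velocities are
#'   independent of this choice.
#' @return object of class `second_order_field`: cell-center coordinate
#'   vectors `x, y, z`, arrays `u, v, w` (m/s) and `p` (Pa) at centers,
#'   `divergence` (relative discrete divergence metric), and a
#'   trilinear interpolating closure `velocity(points)`.
#' @export
solve_stokes <- function(geometry, slip, eta, grid = c(96, 48, 16),
                         ends = c("periodic", "stress-free"),
                         pin_cell = c(1L, 1L)) {
  ends <- match.arg(ends)
  assert_positive(eta, "eta")
  stopifnot(length(grid) == 3)
  nx <- as.integer(grid[1]); ny <- as.integer(grid[2])
  nz <- as.integer(grid[3])
  if (nz < 8) stopf("need at least 8 cells across the channel height")
  L <- geometry$L; w <- geometry$w; h <- geometry$h
  xc <- (seq_len(nx) - 0.5) * L / nx
  yc <- (seq_len(ny) - 0.5) * w / ny
  # evaluate slip on the bottom cell centers
  sl <- eval_slip(slip, xc, yc)
  if (ends == "stress-free") {
    # mirror extension: solve periodic on [0, 2L] with reflected slip;
    # symmetry planes fall at x = 0 and x = L.
    sl_u <- rbind(sl$u, -sl$u[nx:1, , drop = FALSE])
    sl_v <- rbind(sl$v, sl$v[nx:1, , drop = FALSE])
    sol <- stokes_periodic(2 * L, w, h, 2L * nx, ny, nz, eta,
                           sl_u, sl_v, pin_cell)
    sol$u <- sol$u[1:nx, , , drop = FALSE]
    sol$v <- sol$v[1:nx, , , drop = FALSE]
    sol$w <- sol$w[1:nx, , , drop = FALSE]
    sol$p <- sol$p[1:nx, , , drop = FALSE]
  } else {
    sol <- stokes_periodic(L, w, h, nx, ny, nz, eta, sl$u, sl$v, pin_cell)
  }
  zc <- (seq_len(nz) - 0.5) * h / nz
  out <- structure(list(x = xc, y = yc, z = zc,
                        u = sol$u, v = sol$v, w = sol$w, p = sol$p,
                        divergence = sol$divergence,
                        geometry = geometry, eta = eta, ends = ends,
                        grid = c(nx, ny, nz)),
                   class = "second_order_field")
  out$velocity <- make_trilinear(out)
  out
}

eval_slip <- function(slip, xc, yc) {
  if (inherits(slip, "limiting_velocity_field")) {
    xq <- rep(xc, times = length(yc)); yq <- rep(yc, each = length(xc))
    list(u = matrix(interp2(slip$x, slip$y, slip$uL, xq, yq),
                    length(xc), length(yc)),
         v = matrix(interp2(slip$x, slip$y, slip$vL, xq, yq),
                    length(xc), length(yc)))
  } else if (is.function(slip)) {
    xq <- rep(xc, times = length(yc)); yq <- rep(yc, each = length(xc))
    s <- slip(xq, yq)
    list(u = matrix(s$u, length(xc), length(yc)),
         v = matrix(s$v, length(xc), length(yc)))
  } else stopf("slip must be a limiting_velocity_field or a function(x, y)")
}

# Assemble the kappa-independent pieces of the per-mode saddle system.
# Unknown order: u (ny*nz centers), v ((ny-1)*nz y-faces), w (ny*(nz-1)
# z-faces), p (ny*nz centers). Returns real sparse A0 (viscous + gradient/
# divergence couplings that do not involve kappa), diagonal selector S
# (velocity unknowns, multiplied by -eta*kappa^2) and C (terms multiplied
# by i*kappa). Momentum rows are written as eta*lap(u) - grad(p) = rhs.
stokes_mode_operator <- function(ny, nz, dy, dz, eta) {
  nu <- ny * nz
  nv <- max(ny - 1, 0) * nz
  nw <- ny * (nz - 1)
  np <- ny * nz
  iu <- function(j, k) (k - 1) * ny + j
  iv <- function(jf, k) nu + (k - 1) * (ny - 1) + jf
  iw <- function(j, kf) nu + nv + (kf - 1) * ny + j
  ip <- function(j, k) nu + nv + nw + (k - 1) * ny + j
  n <- nu + nv + nw + np
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  ci <- integer(0); cj <- integer(0); cx <- numeric(0)
  add <- function(i, j, x) {
    ti[[length(ti) + 1]] <<- i; tj[[length(tj) + 1]] <<- j
    tx[[length(tx) + 1]] <<- x
  }
  addc <- function(i, j, x) {
    ci[[length(ci) + 1]] <<- i; cj[[length(cj) + 1]] <<- j
    cx[[length(cx) + 1]] <<- x
  }
  idy2 <- if (ny > 1) 1 / dy^2 else 0   # ny == 1: invariant in y
  idz2 <- 1 / dz^2
  # --- u momentum (centers) ---
  for (k in 1:nz) for (j in 1:ny) {
    row <- iu(j, k); diagv <- 0
    if (ny > 1) {
      if (j > 1) add(row, iu(j - 1, k), eta * idy2) else diagv <- diagv - eta * idy2
      if (j < ny) add(row, iu(j + 1, k), eta * idy2) else diagv <- diagv - eta * idy2
      diagv <- diagv - 2 * eta * idy2
    }
    if (k > 1) add(row, iu(j, k - 1), eta * idz2) else diagv <- diagv - eta * idz2
    if (k < nz) add(row, iu(j, k + 1), eta * idz2) else diagv <- diagv - eta * idz2
    diagv <- diagv - 2 * eta * idz2
    add(row, row, diagv)
    addc(row, ip(j, k), -1)             # -i kappa p
  }
  # --- v momentum (interior y faces) ---
  if (ny > 1) for (k in 1:nz) for (jf in 1:(ny - 1)) {
    row <- iv(jf, k); diagv <- -2 * eta * idy2 - 2 * eta * idz2
    if (jf > 1) add(row, iv(jf - 1, k), eta * idy2)
    if (jf < ny - 1) add(row, iv(jf + 1, k), eta * idy2)
    if (k > 1) add(row, iv(jf, k - 1), eta * idz2) else diagv <- diagv - eta * idz2
    if (k < nz) add(row, iv(jf, k + 1), eta * idz2) else diagv <- diagv - eta * idz2
    add(row, row, diagv)
    add(row, ip(jf + 1, k), -1 / dy)
    add(row, ip(jf, k), 1 / dy)
    addc(row, row, 0)                   # keep pattern identical across modes
  }
  # --- w momentum (interior z faces) ---
  for (kf in 1:(nz - 1)) for (j in 1:ny) {
    row <- iw(j, kf); diagv <- -2 * eta * idz2
    if (ny > 1) {
      if (j > 1) add(row, iw(j - 1, kf), eta * idy2) else diagv <- diagv - eta * idy2
      if (j < ny) add(row, iw(j + 1, kf), eta * idy2) else diagv <- diagv - eta * idy2
      diagv <- diagv - 2 * eta * idy2
    }
    if (kf > 1) add(row, iw(j, kf - 1), eta * idz2)
    if (kf < nz - 1) add(row, iw(j, kf + 1), eta * idz2)
    add(row, row, diagv)
    add(row, ip(j, kf + 1), -1 / dz)
    add(row, ip(j, kf), 1 / dz)
  }
  # --- continuity (centers) ---
  for (k in 1:nz) for (j in 1:ny) {
    row <- ip(j, k)
    addc(row, iu(j, k), 1)              # i kappa u
    if (ny > 1) {
      if (j < ny) add(row, iv(j, k), 1 / dy)
      if (j > 1) add(row, iv(j - 1, k), -1 / dy)
    }
    if (k < nz) add(row, iw(j, k), 1 / dz)      # top face of cell k
    if (k > 1) add(row, iw(j, k - 1), -1 / dz)  # bottom face
    add(row, row, 0)                    # ensure diagonal slot exists
  }
  a0 <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj),
                             x = unlist(tx), dims = c(n, n))
  cm <- Matrix::sparseMatrix(i = unlist(ci), j = unlist(cj),
                             x = unlist(cx), dims = c(n, n))
  svec <- c(rep(1, nu + nv + nw), rep(0, np))
  list(A0 = a0, C = cm, S = svec, n = n, nu = nu, nv = nv, nw = nw,
       iu = iu, iv = iv, iw = iw, ip = ip)
}

stokes_periodic <- function(L, w, h, nx, ny, nz, eta, slip_u, slip_v,
                            pin_cell = c(1L, 1L)) {
  dy <- w / ny; dz <- h / nz
  op <- stokes_mode_operator(ny, nz, dy, dz, eta)
  n <- op$n
  # FFT of the slip along x (columns = y cells)
  su_hat <- stats::mvfft(slip_u)
  sv_hat <- stats::mvfft(slip_v)
  mfreq <- 0:(nx - 1)
  kx <- 2 * pi / L * ifelse(mfreq <= nx / 2, mfreq, mfreq - nx)
  nsolve <- nx %/% 2 + 1
  uhat <- matrix(0i, nx, ny * nz)
  vhat <- matrix(0i, nx, max(ny - 1, 0) * nz)
  what <- matrix(0i, nx, ny * (nz - 1))
  phat <- matrix(0i, nx, ny * nz)
  svec <- op$S
  for (m in seq_len(nsolve)) {
    kap <- kx[m]
    mr <- op$A0 - Matrix::Diagonal(n, eta * kap^2 * svec)
    mi <- kap * op$C
    if (m == 1) {
      # pressure gauge: pin one cell pressure, replacing its continuity row
      row <- op$ip(pin_cell[1], pin_cell[2])
      mr[row, ] <- 0; mi[row, ] <- 0
      mr[row, row] <- 1
    }
    big <- rbind(cbind(mr, -mi), cbind(mi, mr))
    # rhs: slip enters the bottom-ghost elimination of u and v momentum
    b <- complex(length.out = n)
    for (j in 1:ny)
      b[op$iu(j, 1)] <- -2 * eta / dz^2 * su_hat[m, j]
    if (ny > 1) for (jf in 1:(ny - 1))
      b[op$iv(jf, 1)] <- -2 * eta / dz^2 * (sv_hat[m, jf] +
                                              sv_hat[m, jf + 1]) / 2
    if (m == 1) b[op$ip(pin_cell[1], pin_cell[2])] <- 0
    sol <- Matrix::solve(big, c(Re(b), Im(b)))
    zc <- sol[1:n] + 1i * sol[n + 1:n]
    uhat[m, ] <- zc[1:op$nu]
    if (op$nv > 0) vhat[m, ] <- zc[op$nu + 1:op$nv]
    what[m, ] <- zc[op$nu + op$nv + 1:op$nw]
    phat[m, ] <- zc[op$nu + op$nv + op$nw + 1:(ny * nz)]
    mm <- nx - m + 2                    # conjugate mirror
    if (m > 1 && mm <= nx && mm != m) {
      uhat[mm, ] <- Conj(uhat[m, ])
      if (op$nv > 0) vhat[mm, ] <- Conj(vhat[m, ])
      what[mm, ] <- Conj(what[m, ])
      phat[mm, ] <- Conj(phat[m, ])
    }
  }
  inv <- function(mat) Re(stats::mvfft(mat, inverse = TRUE)) / nx
  u_st <- array(inv(uhat), c(nx, ny, nz))          # centers
  v_st <- if (op$nv > 0) array(inv(vhat), c(nx, ny - 1, nz)) else
    array(0, c(nx, max(ny - 1, 0), nz))
  w_st <- array(inv(what), c(nx, ny, nz - 1))      # interior z faces
  p_c <- array(inv(phat), c(nx, ny, nz))
  # relative discrete divergence (staggered), spectral x-derivative
  dudx <- array(Re(stats::mvfft(uhat * (1i * kx), inverse = TRUE)) / nx,
                c(nx, ny, nz))
  div <- dudx
  if (ny > 1) {
    vfull <- array(0, c(nx, ny + 1, nz))
    vfull[, 2:ny, ] <- v_st
    div <- div + (vfull[, 2:(ny + 1), , drop = FALSE] -
                    vfull[, 1:ny, , drop = FALSE]) / dy
  }
  wfull <- array(0, c(nx, ny, nz + 1))
  wfull[, , 2:nz] <- w_st
  div <- div + (wfull[, , 2:(nz + 1), drop = FALSE] -
                  wfull[, , 1:nz, drop = FALSE]) / dz
  vmax <- max(abs(u_st), abs(v_st), abs(w_st), 1e-300)
  divergence <- max(abs(div)) / (vmax / min(if (ny > 1) dy else dz, dz))
  # average staggered components to centers
  v_c <- array(0, c(nx, ny, nz))
  if (ny > 1) {
    vfull <- array(0, c(nx, ny + 1, nz)); vfull[, 2:ny, ] <- v_st
    v_c <- (vfull[, 1:ny, , drop = FALSE] +
              vfull[, 2:(ny + 1), , drop = FALSE]) / 2
  }
  w_c <- (wfull[, , 1:nz, drop = FALSE] +
            wfull[, , 2:(nz + 1), drop = FALSE]) / 2
  list(u = u_st, v = v_c, w = w_c, p = p_c, divergence = divergence)
}

#' @export
print.second_order_field <- function(x, ...) {
  cat(sprintf("<second_order_field> grid %d x %d x %d, max |v2| = %.4g m/s, div = %.2e\n",
              x$grid[1], x$grid[2], x$grid[3],
              max(sqrt(x$u^2 + x$v^2 + x$w^2)), x$divergence))
  invisible(x)
}

# Trilinear interpolator over cell-centered arrays; x wraps periodically,
# y and z clamp to the wall-adjacent cells.
make_trilinear <- function(sof) {
  g <- sof$geometry
  nx <- sof$grid[1]; ny <- sof$grid[2]; nz <- sof$grid[3]
  dx <- g$L / nx; dy <- g$w / ny; dz <- g$h / nz
  function(points) {
    points <- rbind(points)
    xq <- points[, 1] %% g$L
    yq <- pmin(pmax(points[, 2], sof$y[1]), sof$y[ny])
    zq <- pmin(pmax(points[, 3], sof$z[1]), sof$z[nz])
    fi <- xq / dx - 0.5
    i0 <- floor(fi); tx <- fi - i0
    i0 <- (as.integer(i0) %% nx) + 1L; i1 <- (i0 %% nx) + 1L
    fj <- pmin(pmax(yq / dy - 0.5, 0), ny - 1)
    j0 <- pmin(floor(fj), ny - 1); ty <- fj - j0
    j0 <- as.integer(j0) + 1L; j1 <- pmin(j0 + 1L, ny)
    fk <- pmin(pmax(zq / dz - 0.5, 0), nz - 1)
    k0 <- pmin(floor(fk), nz - 1); tz <- fk - k0
    k0 <- as.integer(k0) + 1L; k1 <- pmin(k0 + 1L, nz)
    tri <- function(a) {
      a[cbind(i0, j0, k0)] * (1 - tx) * (1 - ty) * (1 - tz) +
        a[cbind(i1, j0, k0)] * tx * (1 - ty) * (1 - tz) +
        a[cbind(i0, j1, k0)] * (1 - tx) * ty * (1 - tz) +
        a[cbind(i0, j0, k1)] * (1 - tx) * (1 - ty) * tz +
        a[cbind(i1, j1, k0)] * tx * ty * (1 - tz) +
        a[cbind(i1, j0, k1)] * tx * (1 - ty) * tz +
        a[cbind(i0, j1, k1)] * (1 - tx) * ty * tz +
        a[cbind(i1, j1, k1)] * tx * ty * tz
    }
    cbind(tri(sof$u), tri(sof$v), tri(sof$w))
  }
}
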