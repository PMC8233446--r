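# Limiting-velocity slip condition and validity checks.

test_that("interface velocities are fluid-minus-wall differences", {
  f <- small_field(theta = 15)
  iv <- interface_velocities(f)   # wall at rest
  xs <- c(0.1e-3, 0.4e-3, 0.7e-3); ys <- c(0.2e-3, 0.5e-3, 0.9e-3)
  expect_equal(iv$u_a0(xs, ys), f$velocity(xs, ys, 0)[, 1])
  expect_equal(iv$v_a0(xs, ys), f$velocity(xs, ys, 0)[, 2])
  # wall co-moving with the fluid tangentially: zero slip amplitudes
  wall <- function(x, y) f$velocity(x, y, 0)
  iv2 <- interface_velocities(f, wall_velocity = wall)
  expect_equal(max(Mod(iv2$u_a0(xs, ys))), 0, tolerance = 1e-15)
  expect_equal(max(Mod(iv2$v_a0(xs, ys))), 0, tolerance = 1e-15)
})

test_that("rotated interface frames give frame-independent results", {
  f <- small_field(theta = 20)
  # in-plane frame rotation by 30 degrees about the normal
  th <- pi / 6
  axes <- cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0),
                c(0, 0, 1))
  iv_g <- interface_velocities(f)
  iv_r <- interface_velocities(f, frame = list(origin = c(0, 0, 0),
                                               axes = axes))
  # the same physical point expressed in both frames
  pg <- c(0.31e-3, 0.52e-3)
  pr <- as.vector(t(axes[, 1:2]) %*% c(pg, 0))[1:2]
  vg <- c(iv_g$u_a0(pg[1], pg[2]), iv_g$v_a0(pg[1], pg[2]))
  vr <- c(iv_r$u_a0(pr[1], pr[2]), iv_r$v_a0(pr[1], pr[2]))
  # project the global tangential amplitude into the rotated frame
  expect_equal(vr, as.vector(t(axes[, 1:2]) %*% c(vg, 0)),
               tolerance = 1e-12)
  expect_error(interface_velocities(
    f, frame = list(origin = c(0, 0, 0),
                    axes = matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 1), 3))),
    "orthonormal")
})

test_that("limiting velocity reduces to the classical Rayleigh slip", {
  # independent 1D oracle: u_a0 = i v_a sin(kx) over a resting wall gives
  # u_L = -(3/8) (v_a^2 / c0) sin(2kx), with c0 = omega / k
  va <- 0.67; k <- 2 * pi / 200e-6; c0 <- 1497; omega <- k * c0
  iv <- list(u_a0 = function(x, y) 1i * va * sin(k * x),
             v_a0 = function(x, y) 0i * x,
             w_a0 = function(x, y) 0i * x,
             omega = omega)
  xs <- seq(0, 400e-6, length.out = 81)
  lv <- limiting_velocity(iv, list(x = xs, y = c(0, 1e-3)),
                          derivs = "numeric", step = 1e-8)
  expect_equal(lv$uL[, 1], -(3 / 8) * va^2 / c0 * sin(2 * k * xs),
               tolerance = 1e-6)
  expect_equal(max(abs(lv$vL)), 0, tolerance = 1e-15)
  # package path: theta = 0 standing wave across the width, analytic derivs
  f <- small_field(theta = 0)
  lvf <- limiting_velocity(interface_velocities(f),
                           list(x = c(0.2e-3, 0.5e-3),
                                y = seq(0, 1e-3, length.out = 401)))
  va_f <- f$p_a / (f$rho0 * f$c0)
  ks <- f$k_s
  expect_equal(lvf$vL[1, ],
               -(3 / 8) * va_f^2 / f$c0 * sin(2 * ks * lvf$y),
               tolerance = 1e-9)
  # 1 MPa in water: slip amplitude ~1.1e-4 m/s, the order of the FEM's
  # 0.23 mm/s maximum
  expect_equal(max(abs(lvf$vL)), 3 / 8 * va_f^2 / f$c0, tolerance = 1e-3)
  expect_gt(max(abs(lvf$vL)), 0.5e-4)
  expect_lt(max(abs(lvf$vL)), 5e-4)
})

test_that("zero first-order fields give zero slip", {
  f <- small_field(p_a = 0)
  lv <- limiting_velocity(interface_velocities(f),
                          list(x = seq(0, 1e-3, length.out = 11),
                               y = seq(0, 1e-3, length.out = 11)))
  expect_equal(max(abs(lv$uL)), 0)
  expect_equal(max(abs(lv$vL)), 0)
})

test_that("slip magnitude vanishes on node and antinode loci", {
  f <- small_field(theta = 15)
  iv <- interface_velocities(f)
  lv <- limiting_velocity(iv, list(x = seq(0, 1e-3, length.out = 201),
                                   y = seq(0, 1e-3, length.out = 201)))
  mag_max <- max(sqrt(lv$uL^2 + lv$vL^2))
  th <- 15 * pi / 180
  probe <- function(x_r_line) {
    # a point on the locus inside the footprint
    y <- 0.5e-3
    x <- (x_r_line - y * cos(th)) / sin(th)
    if (x < 0 || x > 1e-3) return(NA_real_)
    u <- sawstream:::interp2(lv$x, lv$y, lv$uL, x, y)
    v <- sawstream:::interp2(lv$x, lv$y, lv$vL, x, y)
    sqrt(u^2 + v^2)
  }
  nl <- nodal_lines(f); al <- nodal_lines(f, "antinodes")
  vals <- stats::na.omit(vapply(c(nl$x_r, al$x_r), probe, 0))
  expect_gt(length(vals), 3)
  expect_lt(max(vals), 0.05 * mag_max)
})

test_that("limiting-velocity profile extraction works along a line", {
  f <- small_field(theta = 15)
  lv <- limiting_velocity(interface_velocities(f),
                          list(x = seq(0, 1e-3, length.out = 101),
                               y = seq(0, 1e-3, length.out = 101)))
  pr <- limiting_velocity_profile(lv, c(0, 0.5e-3), c(1e-3, 0.5e-3),
                                  n = 100)
  expect_equal(nrow(pr), 100)
  expect_true(all(pr$magnitude >= 0))
  expect_equal(max(pr$magnitude), max(sqrt(lv$uL^2 + lv$vL^2)),
               tolerance = 0.05)
})

test_that("validity report flags the stated restrictions", {
  ok <- limiting_validity(2 * pi * 9.63e6, WATER$eta, WATER$rho,
                          list(h = 75e-6))
  expect_true(ok$valid)
  expect_lt(ok$delta_nu, 1e-6)           # ~0.17 um << 75 um
  expect_equal(ok$delta_nu, 1.72e-7, tolerance = 0.02)
  expect_gt(ok$womersley, 100)
  bad <- limiting_validity(0, WATER$eta, WATER$rho, list(h = 75e-6))
  expect_false(bad$valid)
  curved <- limiting_validity(2 * pi * 9.63e6, WATER$eta, WATER$rho,
                              list(h = 75e-6, curvature_radius = 1e-6))
  expect_false(curved$valid)
  expect_match(paste(curved$flags, collapse = " "), "curvature")
})
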