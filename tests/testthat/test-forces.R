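# Scattering coefficients, radiation force and drag.

test_that("monopole coefficient f1 = 1 - kappa_tilde", {
  expect_equal(scattering_f1(1), 0 + 0i)
  expect_equal(scattering_f1(0), 1 + 0i)
  expect_equal(Re(scattering_f1(1.72 / 4.48)), 1 - 1.72 / 4.48)
  expect_equal(Re(scattering_f1(1.72 / 4.48)), 0.616, tolerance = 1e-3)
  expect_error(scattering_f1(-0.1), ">= 0")
})

test_that("dipole coefficient f2 matches its definition and limits", {
  # neutrally buoyant: zero for any boundary-layer ratio
  for (d in c(0, 0.05, 0.5)) expect_equal(scattering_f2(1, d), 0 + 0i)
  # inviscid limit is the classical real dipole factor
  for (rt in c(0.5, 1.05, 2.4))
    expect_equal(scattering_f2(rt, 0), 2 * (rt - 1) / (2 * rt + 1) + 0i)
  # independent step-by-step evaluation for 10 um PS in water at 9.63 MHz
  delta <- sqrt(2 * (WATER$eta / WATER$rho) / (2 * pi * 9.63e6))
  dt <- delta / 5e-6
  expect_equal(dt, 0.034, tolerance = 0.02)
  rt <- PS$rho / WATER$rho
  lam <- -3 / 2 * dt - 1i * 3 / 2 * (1 + dt) * dt
  f2_oracle <- (2 * (1 - lam) * (rt - 1)) / (2 * rt + 1 - 3 * lam)
  expect_equal(scattering_f2(rt, dt), f2_oracle, tolerance = 1e-14)
  expect_true(Im(scattering_f2(rt, dt)) != 0)
})

test_that("scattering coefficients assemble from particle, fluid, frequency", {
  co <- scattering_coefficients(ps_particle(10e-6), water_mat(), 9.63e6)
  expect_equal(co$delta_tilde, co$delta_nu / 5e-6)
  expect_equal(co$f1, scattering_f1(1.72e-10 / 4.48e-10))
  expect_equal(co$f2, scattering_f2(1050 / 997, co$delta_tilde))
})

test_that("radiation force matches the standing-wave closed form", {
  # exact-kappa water makes the identity exact
  wex <- water_exact()
  f <- make_tassaw_field(1e6, 200e-6, 0, list(L = 1e-3, w = 1e-3, h = 30e-6),
                         wex, 19.32e6)
  p <- ps_particle(10e-6)
  co <- scattering_coefficients(p, wex, 19.32e6)
  phi_fac <- Re(co$f1) / 3 + Re(scattering_f2(co$rho_tilde, 0)) / 2
  e_ac <- acoustic_energy_density(f)
  ks <- f$k_s
  ys <- seq(10e-6, 190e-6, by = 20e-6)
  for (y in ys) {
    fr <- radiation_force(f, p, c(0.5e-3, y, 15e-6), wex, delta_tilde = 0)
    f_oracle <- 4 * pi * phi_fac * p$radius^3 * ks * e_ac *
      sin(2 * ks * (y - f$x_ref))
    expect_equal(fr[2], f_oracle, tolerance = 1e-10)
    expect_equal(fr[1], 0, tolerance = 1e-22)
    expect_equal(fr[3], 0, tolerance = 1e-22)
  }
  # brute-force numeric evaluation of the definition on a fine stencil
  h <- 1e-9; y0 <- 37e-6
  pv <- function(y) f$pressure(0.5e-3, y)
  vv <- function(y) f$velocity(0.5e-3, y)[2]
  gp <- (pv(y0 + h) - pv(y0 - h)) / (2 * h)
  gv <- (vv(y0 + h) - vv(y0 - h)) / (2 * h)
  fr_num <- -pi * p$radius^3 *
    ((2 * wex$compressibility / 3) * Re(Conj(co$f1) * Conj(pv(y0)) * gp) -
       wex$density * Re(Conj(scattering_f2(co$rho_tilde, 0)) *
                          Conj(vv(y0)) * gv))
  fr_pkg <- radiation_force(f, p, c(0.5e-3, y0, 15e-6), wex,
                            delta_tilde = 0)
  expect_equal(fr_pkg[2], fr_num, tolerance = 1e-6)
})

test_that("3 Phi equals the acoustic contrast factor on a parameter grid", {
  for (rt in c(0.6, 1.02, 1.5, 3)) for (kt in c(0.2, 0.384, 1, 2.1)) {
    phi_eq <- contrast_factor(rt * 1000, kt * 1e-10, 1000, 1e-10)
    phi_f <- Re(scattering_f1(kt)) / 3 + Re(scattering_f2(rt, 0)) / 2
    expect_equal(3 * phi_f, phi_eq, tolerance = 1e-12)
  }
})

test_that("radiation force scales as r^3 and p_a^2", {
  wex <- water_exact()
  p_at <- function(d, pa) {
    f <- make_tassaw_field(pa, 200e-6, 0,
                           list(L = 1e-3, w = 1e-3, h = 30e-6), wex,
                           19.32e6)
    p <- ps_particle(d)
    radiation_force(f, p, c(0.5e-3, 30e-6, 15e-6), wex,
                    delta_tilde = 0.02)[2]   # fixed delta_tilde
  }
  base <- p_at(2e-6, 1e6)
  for (s in c(2, 3, 5))
    expect_equal(p_at(s * 2e-6, 1e6) / base, s^3, tolerance = 1e-9)
  for (s in c(0.5, 2))
    expect_equal(p_at(2e-6, s * 1e6) / base, s^2, tolerance = 1e-9)
})

test_that("zero field gives zero force; nodes are stable traps for phi > 0", {
  w <- water_mat()
  f0 <- make_tassaw_field(0, 200e-6, 0, list(L = 1e-3, w = 1e-3, h = 30e-6),
                          w, 19.32e6)
  p <- ps_particle(10e-6)
  expect_equal(radiation_force(f0, p, c(0.5e-3, 40e-6, 10e-6), w),
               c(0, 0, 0))
  f <- small_field(theta = 0)
  y_node <- 50e-6                      # quarter wavelength: cos = 0
  fr_node <- radiation_force(f, p, c(0.5e-3, y_node, 15e-6), w)
  expect_equal(fr_node[2], 0, tolerance = 1e-18)
  h <- 1e-7
  dfy <- (radiation_force(f, p, c(0.5e-3, y_node + h, 15e-6), w)[2] -
            radiation_force(f, p, c(0.5e-3, y_node - h, 15e-6), w)[2]) /
    (2 * h)
  expect_lt(dfy, 0)                    # restoring
  expect_error(radiation_force(f, p, c(2e-3, 40e-6, 10e-6), w),
               "x = 0.002")
})

test_that("particle validity warning and Stokes drag basics", {
  expect_warning(particle_spec(15e-6, 1050, 1.72e-10, lambda = 200e-6),
                 "r/lambda")
  expect_equal(stokes_drag(c(1, 2, 3) * 1e-3, c(1, 2, 3) * 1e-3, 5e-6,
                           WATER$eta), c(0, 0, 0))
  d1 <- stokes_drag(c(1e-3, 0, 0), c(0, 0, 0), 5e-6, WATER$eta)
  d2 <- stokes_drag(c(1e-3, 0, 0), c(0, 0, 0), 10e-6, WATER$eta)
  expect_equal(d2, 2 * d1)
  expect_equal(d1[1], 6 * pi * WATER$eta * 5e-6 * 1e-3)
  # terminal balance: v_p = v_f + F/(6 pi eta r) makes drag cancel F
  fr <- c(2e-12, -1e-12, 0); r <- 5e-6
  v_term <- c(1e-3, 0, 0) + fr / (6 * pi * WATER$eta * r)
  expect_equal(stokes_drag(c(1e-3, 0, 0), v_term, r, WATER$eta) + fr,
               c(0, 0, 0), tolerance = 1e-20)
})
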