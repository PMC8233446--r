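test_that("compressibility from rho and c matches the tabulated values", {
  # water row: 1/(997 * 1497^2) = 4.4757e-10, printed as 4.48e-10
  expect_equal(signif(compressibility_from_rho_c(997, 1497), 3), 4.48e-10)
  # polystyrene row: 1/(1050 * 2350^2) = 1.7246e-10, printed as 1.72e-10
  expect_equal(signif(compressibility_from_rho_c(1050, 2350), 3), 1.72e-10)
  expect_equal(compressibility_from_rho_c(1, 1), 1)
  expect_error(compressibility_from_rho_c(-1, 10), "positive")
  expect_error(compressibility_from_rho_c(10, 0), "positive")
})

test_that("Landau solid compressibility behaves as the footnote formula", {
  # sigma = 0.5 limit: prefactor 3(1-s)/(1+s) = 1
  expect_equal(compressibility_landau(0.5, 1050, 2350),
               compressibility_from_rho_c(1050, 2350))
  # direct evaluation with the polystyrene constants does NOT reproduce
  # the tabulated 1.72e-10 (which equals 1/(rho c^2) instead)
  k_landau <- compressibility_landau(PS$sigma, PS$rho, PS$c)
  expect_equal(k_landau, 3 * 0.65 / 1.35 / (1050 * 2350^2))  # 2.491e-10
  expect_gt(abs(k_landau - 1.72e-10) / 1.72e-10, 0.40)
  # pole of the prefactor is guarded
  expect_error(compressibility_landau(-1, 1050, 2350), "Poisson")
  expect_error(compressibility_landau(-1.5, 1050, 2350), "Poisson")
  expect_error(compressibility_landau(0.7, 1050, 2350), "Poisson")
  # approaching the pole the prefactor diverges
  expect_gt(compressibility_landau(-1 + 1e-9, 1050, 2350),
            1e8 * compressibility_from_rho_c(1050, 2350))
})

test_that("acoustic contrast factor reproduces the device values", {
  phi_ps <- contrast_factor(PS$rho, PS$kappa, WATER$rho, WATER$kappa)
  # direct arithmetic: 3256/3097 - 1.72/4.48 = 0.66741; the printed value
  # is 0.66 -- agreement at the ~1% level
  expect_equal(phi_ps, (5 * 1050 - 2 * 997) / (2 * 1050 + 997) -
                 1.72 / 4.48)
  expect_equal(phi_ps, 0.66, tolerance = 0.02)
  phi_wbc <- contrast_factor(1019, 3.99e-10, WATER$rho, WATER$kappa)
  phi_mcf <- contrast_factor(1068, 4.22e-10, WATER$rho, WATER$kappa)
  expect_equal(round(phi_wbc, 2), 0.13)
  expect_equal(round(phi_mcf, 2), 0.13)
  # particle identical to fluid: (5-2)/3 - 1 = 0
  expect_equal(contrast_factor(997, 4.48e-10, 997, 4.48e-10), 0)
  # strictly increasing in rho_p over a grid
  rhos <- seq(900, 1300, by = 25)
  phis <- vapply(rhos, contrast_factor, 0, kappa_p = 3e-10,
                 rho_f = 997, kappa_f = 4.48e-10)
  expect_true(all(diff(phis) > 0))
})

test_that("library fluids satisfy kappa = 1/(rho c^2) to 1%", {
  lib <- material_library()
  fluids <- Filter(function(m) m$kind == "fluid", lib)
  expect_gt(length(fluids), 0)
  for (m in fluids) {
    expect_lt(abs(m$compressibility -
                    compressibility_from_rho_c(m$density, m$sound_speed)) /
                m$compressibility, 0.01)
  }
  # a fluid violating the 1% consistency is rejected outright
  expect_error(material("bad", "fluid", density = 1000, sound_speed = 1500,
                        compressibility = 6e-10,
                        dynamic_viscosity = 1e-3),
               "disagrees")
})

test_that("viscous boundary-layer thickness follows sqrt(2 nu / omega)", {
  d <- boundary_layer_thickness(WATER$eta, WATER$rho, 9.63e6)
  expect_equal(d, sqrt(2 * (WATER$eta / WATER$rho) / (2 * pi * 9.63e6)))
  expect_equal(d, 1.7e-7, tolerance = 0.02)
  # quartering under 4x frequency
  expect_equal(boundary_layer_thickness(WATER$eta, WATER$rho, 4 * 9.63e6),
               d / 2)
  expect_equal(boundary_layer_thickness(0, WATER$rho, 9.63e6), 0)
})

test_that("voltage to dBm conversion matches the printed pairs", {
  # validation-device calibration 7.5 V <-> 26.5 dBm
  expect_equal(voltage_to_dbm(10, 7.5, 26.5), 29)
  expect_equal(voltage_to_dbm(5, 7.5, 26.5), 23)
  expect_equal(voltage_to_dbm(7.5, 7.5, 26.5, rounding = "none"), 26.5)
  # sheathless calibration 20 V <-> 26.5 dBm
  expect_equal(voltage_to_dbm(40, 20, 26.5), 33)
  expect_equal(voltage_to_dbm(30, 20, 26.5), 30)
  # differences depend only on voltage ratios
  for (a in c(0.5, 2, 3.7)) {
    expect_equal(voltage_to_dbm(a * 12, 7.5, 26.5, "none") -
                   voltage_to_dbm(12, 7.5, 26.5, "none"),
                 20 * log10(a))
  }
  expect_error(voltage_to_dbm(0, 7.5, 26.5), "positive")
})

test_that("SAW frequency from wavelength brackets the operating band", {
  f <- frequency_from_wavelength(3997, 400e-6)
  expect_gte(f, 9e6); expect_lte(f, 10e6)
  expect_equal(frequency_from_wavelength(3864, 200e-6), 19.32e6)
  expect_equal(frequency_from_wavelength(3997, 800e-6), f / 2)
})

test_that("material records validate and the library resolves by name", {
  w <- material_library("water")
  expect_s3_class(w, "saw_material")
  expect_equal(w$compressibility, 4.48e-10)
  expect_error(material_library("unobtainium"), "unknown material")
  expect_output(print(w), "water")
})
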