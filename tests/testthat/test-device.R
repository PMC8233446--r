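# Multi-stage device assembly and sweeps.

test_that("drive calibration is linear and per-device", {
  cal_v <- list(V_cal = 7.5, p_cal = 1e6)
  expect_equal(calibrate_amplitude(7.5, cal_v), 1e6)
  expect_equal(calibrate_amplitude(15, cal_v), 2e6)
  cal_s <- list(V_cal = 40, p_cal = 1e6)
  expect_equal(calibrate_amplitude(40, cal_s), 1e6)
  expect_error(calibrate_amplitude(10, NULL), "calibration")
})

test_that("composed flow realigns the stream parallel to the sidewall", {
  dv <- device_preset("sheathless", "beads")
  fl <- compose_flow(dv$stages, dv$height)
  # no side flow: direction unchanged
  dv1 <- device_preset("validation")
  fl1 <- compose_flow(dv1$stages, dv1$height)
  expect_equal(fl1[[1]]$flow[2], 0)
  # realignment: downstream flow parallel to the sidewall
  expect_equal(fl[[2]]$angle_deg, 0)
  expect_equal(fl[[2]]$flow[2], 0)
  # transverse momentum balance held by the side-stream direction
  st <- dv$stages
  q_m <- st[[1]]$axial_flow * st[[1]]$width * dv$height
  q_s <- st[[2]]$side_flow * st[[2]]$side_width * dv$height
  phi <- fl[[2]]$side_angle_deg * pi / 180
  expect_equal(q_m * st[[1]]$axial_flow * sin(st[[1]]$incline_deg * pi / 180) +
                 q_s * st[[2]]$side_flow * sin(phi), 0, tolerance = 1e-18)
  # volumetric flux conserved across every junction
  expect_equal(fl[[2]]$Q, q_m + q_s, tolerance = 1e-12 * fl[[2]]$Q)
  expect_equal(fl[[3]]$Q, fl[[2]]$Q, tolerance = 1e-12 * fl[[2]]$Q)
})

test_that("focusing stage of width lambda/2 has exactly one nodal line", {
  dv <- device_preset("sheathless", "beads")
  st <- dv$stages[[1]]
  expect_equal(st$width, dv$lambda / 2)
  f <- make_tassaw_field(0.5e6, dv$lambda, 0,
                         list(L = st$length, w = st$width, h = dv$height),
                         dv$fluid, dv$frequency, node_at = "center")
  expect_equal(nrow(nodal_lines(f)), 1)
})

test_that("sheathless preset focuses both bead species to one nodal line", {
  dv <- device_preset("sheathless", "beads")
  res <- run_device(dv, include_streaming = FALSE)
  st1 <- res$trajectories[[1]]
  # both species end stage 1 at the stage's single node (center, 100 um)
  for (tr in st1) {
    m <- separation_metrics(list(tr), dv$stages[[1]]$length)
    expect_equal(m$positions$y_outlet, 100e-6, tolerance = 0.03)
  }
})

test_that("zero drive gives zero outlet separation", {
  dv <- device_preset("sheathless", "beads")
  for (i in seq_along(dv$stages)) dv$stages[[i]]$drive_voltage <- 0
  res <- run_device(dv, include_streaming = FALSE,
                    release_y = c(100e-6, 100e-6))
  expect_equal(res$outlet$delta, 0, tolerance = 1e-12)
})

test_that("device-level size ordering holds for beads and cells", {
  res_b <- run_device(device_preset("sheathless", "beads"))
  yb <- res_b$outlet$positions
  expect_true(all(yb$crossed))
  disp <- abs(yb$y_outlet - 500e-6)    # entry at the realigned centerline
  expect_gt(disp[yb$particle == "PS 10 um"],
            disp[yb$particle == "PS 4 um"])
  res_c <- run_device(device_preset("sheathless", "cells"))
  yc <- res_c$outlet$positions
  disp_c <- abs(yc$y_outlet - 500e-6)
  expect_gt(disp_c[yc$particle == "mcf7"], disp_c[yc$particle == "wbc"])
})

test_that("tilt sweep covers the grid and matches single runs", {
  dv <- device_preset("sheathless", "beads")
  one <- sweep_tilt_angle(dv, 10, 20, include_streaming = FALSE)
  expect_equal(nrow(one), 1)
  direct <- run_device(device_preset("sheathless", "beads",
                                     drive_voltage = 20),
                       include_streaming = FALSE)
  expect_equal(one$delta, direct$outlet$delta, tolerance = 1e-12)
  # reduced grid keeps the full-cross-product shape and is deterministic
  tab <- sweep_tilt_angle(dv, c(5, 15, 25), c(12, 20),
                          include_streaming = FALSE, tol = 1e-4)
  expect_equal(nrow(tab), 6)
  expect_equal(nrow(unique(attr(tab, "grid")[, 1:2])), 6)
  tab2 <- sweep_tilt_angle(dv, c(5, 15, 25), c(12, 20),
                           include_streaming = FALSE, tol = 1e-4)
  expect_identical(attr(tab, "grid")$delta, attr(tab2, "grid")$delta)
  expect_error(sweep_tilt_angle(dv, c(0, 10), 20), "theta_list")
})

test_that("separation metric is non-decreasing in voltage below saturation", {
  # above ~20 V both species become fully node-trapped in the
  # uniform-amplitude field and the metric saturates; the monotone
  # regime is the sub-trapping range
  deltas <- vapply(c(6, 9, 12, 16), function(v) {
    run_device(device_preset("sheathless", "beads", drive_voltage = v),
               include_streaming = FALSE)$outlet$delta
  }, 0)
  expect_true(all(diff(deltas) > 0))
})

test_that("validation preset reproduces the taSSAW trapping phenomenology", {
  dv <- device_preset("validation")
  expect_equal(dv$frequency, 19.32e6)
  expect_equal(dv$lambda, 200e-6)
  res <- suppressMessages(run_device(dv, include_streaming = FALSE,
                                     release_y = c(5e-4, 5e-4)))
  pos <- res$outlet$positions
  expect_true(all(pos$crossed))
  # both beads migrate along the inclined nodal lines (large lateral
  # displacement), the larger one at least as far
  disp <- abs(pos$y_outlet - 5e-4)
  expect_gt(min(disp), 5e-5)
  expect_gte(disp[pos$particle == "PS 9.9 um"],
             disp[pos$particle == "PS 7.3 um"])
})
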