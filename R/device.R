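# Multi-stage device assembly: focusing -> realignment -> separation,
# drive-amplitude calibration, presets for the two reference devices, and
# the tilt-angle optimization sweep.

#' Stage configuration
#'
#' @param kind `"focusing"`, `"realignment"` or `"separation"`.
#' @param length,width stage dimensions, m.
#' @param tilt_deg nodal-line tilt to the flow axis, degrees (0 for a
#'   conventional SSAW focusing stage; realignment stages carry no field).
#' @param drive_voltage V (0 for realignment).
#' @param calibration list `(V_cal, p_cal)`: voltage-to-pressure-amplitude
#'   calibration pair of this stage (per-device, never global).
#' @param axial_flow axial flow speed, m/s.
#' @param side_flow side-stream speed (realignment only), m/s.
#' @param side_width width of the side-stream channel, m (realignment
#'   only; sets the side flux `side_flow * side_width * h`).
#' @param incline_deg inclination of this stage's channel axis to the
#'   downstream main-channel axis, degrees (a tilted focusing inlet enters
#'   the realignment junction at this angle; its local field tilt stays 0).
#' @return object of class `stage_config`.
#' @export
stage_config <- function(kind = c("focusing", "realignment", "separation"),
                         length, width, tilt_deg = 0, drive_voltage = 0,
                         calibration = NULL, axial_flow = 0,
                         side_flow = NULL, side_width = NULL,
                         incline_deg = 0) {
  kind <- match.arg(kind)
  assert_positive(length, "length"); assert_positive(width, "width")
  structure(list(kind = kind, length = length, width = width,
                 tilt_deg = tilt_deg, drive_voltage = drive_voltage,
                 calibration = calibration, axial_flow = axial_flow,
                 side_flow = side_flow, side_width = side_width,
                 incline_deg = incline_deg),
            class = "stage_config")
}

#' Device configuration
#'
#' @param stages ordered list of [stage_config()]s.
#' @param height channel height, m.
#' @param fluid [material()] fluid record.
#' @param particles list of [particle_spec()].
#' @param frequency drive frequency, Hz.
#' @param lambda SAW wavelength, m.
#' @return object of class `device_config`.
#' @export
device_config <- function(stages, height, fluid, particles, frequency,
                          lambda) {
  assert_positive(height, "height")
  stopifnot(all(vapply(stages, inherits, TRUE, "stage_config")))
  structure(list(stages = stages, height = height, fluid = fluid,
                 particles = particles, frequency = frequency,
                 lambda = lambda),
            class = "device_config")
}

#' Pressure amplitude from drive voltage
#'
#' Linear voltage-amplitude map through a per-stage calibration pair:
#' `p_a = p_cal * V / V_cal`.
#'
#' @param voltage drive voltage, V.
#' @param calibration list with `V_cal` (V) and `p_cal` (Pa).
#' @return pressure amplitude, Pa.
#' @export
calibrate_amplitude <- function(voltage, calibration) {
  if (is.null(calibration) || is.null(calibration$V_cal) ||
      is.null(calibration$p_cal))
    stopf("missing drive calibration: need list(V_cal =, p_cal =)")
  if (voltage < 0) stopf("voltage must be >= 0")
  calibration$p_cal * voltage / calibration$V_cal
}

#' Compose the piecewise background flow through the stages
#'
#' Each stage carries a uniform axial flow. At a realignment junction the
#' entering particle-laden stream arrives at the inclination angle of the
#' upstream (focusing) stage; the side stream's direction is chosen by
#' momentum-flux-weighted vector addition so that the merged stream is
#' parallel to the sidewall, and its magnitude then follows mass
#' conservation into the downstream width.
#'
#' @param stages list of [stage_config()].
#' @param height channel height, m (common to all stages).
#' @return list with per-stage entries: `flow` (3-vector, the uniform
#'   stage velocity in stage-local coordinates), `Q` (volumetric flux,
#'   m^3/s) and `angle_deg` (flow angle to the axis).
#' @export
compose_flow <- function(stages, height) {
  out <- vector("list", length(stages))
  q_prev <- NULL; angle_prev <- 0
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    a_cross <- st$width * height
    if (st$kind == "realignment" && !is.null(st$side_flow) &&
        st$side_flow > 0) {
      # main stream enters at the upstream inclination with flux q_prev
      v_main <- stages[[max(i - 1, 1)]]$axial_flow
      th <- deg2rad(angle_prev)
      q_main <- q_prev %||% (v_main * a_cross)
      # momentum flux of the main stream transverse to the wall must be
      # cancelled by the side stream: rho q_m v_m sin(th) + rho q_s v_s
      # sin(phi) = 0 with v_s = side_flow given
      v_s <- st$side_flow
      # side-stream flux through its own channel cross-section;
      # direction phi from the transverse momentum balance
      q_s <- v_s * (st$side_width %||% st$width) * height
      sin_phi <- -q_main * v_main * sin(th) / (q_s * v_s)
      if (abs(sin_phi) > 1)
        stopf("side flow too weak to realign the stream (needed |sin phi| = %.2f)",
              abs(sin_phi))
      phi <- asin(sin_phi)
      # merged momentum flux is axial by construction; mass conservation
      # rescales into the downstream width
      q_tot <- q_main + q_s
      v_axial <- q_tot / a_cross
      out[[i]] <- list(flow = c(v_axial, 0, 0), Q = q_tot, angle_deg = 0,
                       side_angle_deg = phi * 180 / pi)
      q_prev <- q_tot; angle_prev <- 0
    } else {
      ang <- st$incline_deg %||% 0
      v <- st$axial_flow
      q <- v * a_cross
      if (!is.null(q_prev) && abs(q) < 1e-300) {
        # no stated speed: carry the upstream flux through this width
        v <- q_prev / a_cross
        q <- q_prev
      }
      out[[i]] <- list(flow = c(v, 0, 0), Q = q, angle_deg = ang)
      q_prev <- q; angle_prev <- ang
    }
  }
  out
}

#' Device presets for the two reference configurations
#'
#' `"validation"`: the taSSAW bead-separation device (19.32 MHz, lambda =
#' 200 um, theta = 15 deg, footprint 1000 um x 1000 um working region,
#' h = 75 um, PS beads of 9.9 and 7.3 um diameter, calibration 7.5 V ->
#' 1 MPa). The inlet flow speed is not stated for this device; the preset
#' borrows 6 mm/s from the sheathless design (overridable).
#'
#' `"sheathless"`: the three-stage sheathless separator (lambda = 400 um
#' so 9.63 MHz operation, theta = 10 deg, inlet 6 mm/s, side flow 18 mm/s,
#' focusing width lambda/2, separation width 1000 um; `particles =
#' "beads"` gives PS 4/10 um at 40 V with the 40 V -> 1 MPa separation
#' calibration, `particles = "cells"` gives WBC 12 um / MCF-7 20 um at
#' 30 V). Stage lengths are not fully printed for this design; defaults
#' give each stage a residence time comfortably above the focusing/
#' realignment time at the preset flows.
#'
#' @param name `"validation"` or `"sheathless"`.
#' @param particles for the sheathless preset: `"beads"` or `"cells"`.
#' @param tilt_deg,drive_voltage optional overrides of the separation
#'   stage tilt and voltage.
#' @return [device_config()].
#' @export
device_preset <- function(name = c("validation", "sheathless"),
                          particles = c("beads", "cells"),
                          tilt_deg = NULL, drive_voltage = NULL) {
  name <- match.arg(name)
  particles <- match.arg(particles)
  lib <- material_library()
  water <- lib$water
  if (name == "validation") {
    lam <- 200e-6
    theta <- tilt_deg %||% 15
    volts <- drive_voltage %||% 7.5
    cal <- list(V_cal = 7.5, p_cal = 1e6)
    parts <- list(
      particle_spec(9.9e-6 / 2, lib$polystyrene$density,
                    lib$polystyrene$compressibility, "PS 9.9 um"),
      particle_spec(7.3e-6 / 2, lib$polystyrene$density,
                    lib$polystyrene$compressibility, "PS 7.3 um"))
    stages <- list(stage_config("separation", length = 1000e-6,
                                width = 1000e-6, tilt_deg = theta,
                                drive_voltage = volts, calibration = cal,
                                axial_flow = 6e-3))
    device_config(stages, height = 75e-6, fluid = water,
                  particles = parts,
                  frequency = frequency_from_wavelength(3864, lam),
                  lambda = lam)
  } else {
    lam <- 400e-6
    theta <- tilt_deg %||% 10
    if (particles == "beads") {
      volts <- drive_voltage %||% 40
      parts <- list(
        particle_spec(4e-6 / 2, lib$polystyrene$density,
                      lib$polystyrene$compressibility, "PS 4 um"),
        particle_spec(10e-6 / 2, lib$polystyrene$density,
                      lib$polystyrene$compressibility, "PS 10 um"))
    } else {
      volts <- drive_voltage %||% 30
      parts <- list(particle_from_material(lib$wbc),
                    particle_from_material(lib$mcf7))
    }
    # separation-stage calibration 40 V -> 1 MPa; focusing stage 10 V ->
    # 0.5 MPa (both printed operating points of this design)
    stages <- list(
      stage_config("focusing", length = 5e-3, width = lam / 2,
                   tilt_deg = 0, drive_voltage = 10,
                   calibration = list(V_cal = 10, p_cal = 0.5e6),
                   axial_flow = 6e-3, incline_deg = theta),
      stage_config("realignment", length = 1.5e-3, width = 1000e-6,
                   axial_flow = 0, side_flow = 18e-3,
                   side_width = lam / 2),
      stage_config("separation", length = 2.5e-3, width = 1000e-6,
                   tilt_deg = theta, drive_voltage = volts,
                   calibration = list(V_cal = 40, p_cal = 1e6)))
    device_config(stages, height = 75e-6, fluid = water,
                  particles = parts,
                  frequency = frequency_from_wavelength(3997, lam),
                  lambda = lam)
  }
}

#' Run a device end to end
#'
#' Builds the per-stage fields (conventional SSAW in focusing stages,
#' taSSAW in separation stages, none in realignment), optionally solves
#' the slip-driven streaming per driven stage, traces every particle
#' through the stages in sequence and reports separation metrics at the
#' final outlet.
#'
#' @param d [device_config()].
#' @param include_streaming solve and include the second-order streaming
#'   drag (default TRUE).
#' @param release_y release lateral positions, m (default: evenly spread
#'   over the middle half of the first stage width).
#' @param release_z release height, m; default 20 um above the substrate.
#' @param mode,tol passed to [trace()].
#' @param streaming_grid grid for [solve_stokes()] per stage.
#' @param stall_time flag a particle as trapped when it makes no axial
#'   progress for this long, s.
#' @return list with `trajectories` (per stage, per particle), `outlet`
#'   ([separation_metrics()] at the final outlet), `stages` (per-stage
#'   diagnostics: p_a, flow), `trapped` (logical per particle).
#' @export
run_device <- function(d, include_streaming = TRUE, release_y = NULL,
                       release_z = 20e-6, mode = "overdamped", tol = 1e-6,
                       streaming_grid = c(64, 24, 8), stall_time = 2) {
  stopifnot(inherits(d, "device_config"))
  flows <- compose_flow(d$stages, d$height)
  np <- length(d$particles)
  if (is.null(release_y)) {
    w1 <- d$stages[[1]]$width
    release_y <- seq(0.3 * w1, 0.7 * w1, length.out = max(np, 2))[seq_len(np)]
  }
  if (length(release_y) == 1) release_y <- rep(release_y, np)
  ys <- release_y
  all_traj <- vector("list", length(d$stages))
  trapped <- rep(FALSE, np)
  stage_info <- vector("list", length(d$stages))
  for (si in seq_along(d$stages)) {
    st <- d$stages[[si]]
    geom <- list(L = st$length, w = st$width, h = d$height)
    flow <- flows[[si]]$flow
    p_a <- if (st$kind == "realignment" || st$drive_voltage == 0) 0
    else calibrate_amplitude(st$drive_voltage, st$calibration)
    field <- NULL; sof <- NULL
    if (p_a > 0) {
      field <- make_tassaw_field(p_a, d$lambda, st$tilt_deg, geom,
                                 d$fluid, d$frequency,
                                 node_at = "center")
      if (include_streaming) {
        iv <- interface_velocities(field)
        lx <- seq(0, geom$L, length.out = streaming_grid[1] + 1)
        ly <- seq(0, geom$w, length.out = max(streaming_grid[2], 2) + 1)
        lv <- limiting_velocity(iv, list(x = lx, y = ly))
        sof <- solve_stokes(geom, lv, d$fluid$dynamic_viscosity,
                            grid = streaming_grid)
      }
    } else {
      field <- make_tassaw_field(0, d$lambda, st$tilt_deg, geom, d$fluid,
                                 d$frequency)
    }
    v_ax <- max(abs(flow[1]), 1e-9)
    duration <- min(stall_time, 8 * st$length / v_ax)
    trajs <- trace(d$particles, field, d$fluid, streaming = sof,
                   background_flow = flow, duration = duration,
                   release = cbind(0, ys, release_z), mode = mode,
                   tol = tol)
    all_traj[[si]] <- trajs
    stage_info[[si]] <- list(kind = st$kind, p_a = p_a, flow = flow,
                             length = st$length, width = st$width)
    # hand off lateral positions to the next stage
    new_ys <- numeric(np)
    for (i in seq_len(np)) {
      tr <- trajs[[i]]
      if (!isTRUE(attr(tr, "exit")) && max(tr$x) < st$length - 1e-9) {
        trapped[i] <- TRUE
        new_ys[i] <- tr$y[nrow(tr)]
      } else {
        m <- separation_metrics(trajs[i], st$length)
        new_ys[i] <- if (m$positions$crossed[1]) m$positions$y_outlet[1]
        else tr$y[nrow(tr)]
      }
    }
    # width change between stages: keep the lateral offset from the
    # stage centerline (stages share a sidewall-aligned centerline)
    if (si < length(d$stages)) {
      w_next <- d$stages[[si + 1]]$width
      ys <- new_ys + (w_next - st$width) / 2
      ys <- pmin(pmax(ys, 0.01 * w_next), 0.99 * w_next)
    } else ys <- new_ys
  }
  last <- length(d$stages)
  outlet <- separation_metrics(all_traj[[last]],
                               d$stages[[last]]$length)
  list(trajectories = all_traj, outlet = outlet, stages = stage_info,
       trapped = trapped)
}

#' Tilt-angle and voltage optimization sweep
#'
#' Runs [run_device()] over a grid of separation-stage tilt angles and
#' drive voltages, recording the outlet maximum inter-particle distance,
#' and returns the table ranked by separation.
#'
#' @param d [device_config()] whose last stage is the separation stage.
#' @param theta_list tilt angles, degrees, each in (0, 90).
#' @param voltages drive voltages, V.
#' @param ... passed to [run_device()] (e.g. `include_streaming = FALSE`
#'   for a fast scan).
#' @return data.frame with `theta_deg`, `voltage`, `delta` (m), ordered by
#'   decreasing `delta`; attribute `"grid"` preserves evaluation order.
#' @export
sweep_tilt_angle <- function(d, theta_list, voltages, ...) {
  stopifnot(all(theta_list > 0 & theta_list < 90))
  sep_i <- length(d$stages)
  rows <- list()
  for (v in voltages) for (th in theta_list) {
    d2 <- d
    d2$stages[[sep_i]]$tilt_deg <- th
    d2$stages[[sep_i]]$drive_voltage <- v
    res <- run_device(d2, ...)
    rows[[length(rows) + 1]] <- data.frame(theta_deg = th, voltage = v,
                                           delta = res$outlet$delta)
  }
  tab <- do.call(rbind, rows)
  out <- tab[order(-tab$delta), , drop = FALSE]
  attr(out, "grid") <- tab
  out
}
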