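# Lagrangian acoustophoretic particle tracing.
#
# Newton's law for particle j reduces to m_j dv/dt = F_drag + F_rad
# (inertial mode); buoyancy and gravity are excluded from the in-plane
# equations because the vertical force balance holds them fixed in these
# shallow channels. The overdamped (quasi-static) limit
#   v_p = v_fluid + F_rad / (6 pi eta r)
# is the default: at micrometre scales the velocity relaxation time
# m/(6 pi eta r) is microseconds, far below any trajectory time scale.

#' Trace particles through first- and second-order fields
#'
#' Integrates particle motion under the acoustic radiation force, Stokes
#' drag from the background flow plus streaming, with the vertical
#' coordinate held fixed by default (vertical radiation force and buoyancy
#' are taken as balanced by vertical drag).
#'
#' Modes: `"overdamped"` integrates the quasi-static velocity with an
#' adaptive Dormand-Prince (RK45) scheme; `"inertial"` integrates the full
#' second-order law with an exponential integrator that is exact for the
#' stiff linear drag term.
#'
#' @param particles list of [particle_spec()] (or a single one).
#' @param field `first_order_field` (or `NULL` for no acoustics).
#' @param fluid [material()] fluid record.
#' @param streaming optional `second_order_field` from [solve_stokes()].
#' @param background_flow uniform velocity 3-vector (m/s) or a function
#'   `(points)` returning an `n x 3` matrix.
#' @param duration integration time, s.
#' @param release matrix of release positions (one row per particle) or a
#'   single position recycled to all particles, m.
#' @param mode `"overdamped"` or `"inertial"`.
#' @param tol relative tolerance of the adaptive integrator.
#' @param max_step maximum time step, s.
#' @param full3d logical; FALSE (default) freezes z.
#' @param record_every thin the stored trajectory to roughly this time
#'   interval, s (default: duration/400).
#' @return list of `trajectory` objects: data.frames with `time`,
#'   `x, y, z`, `vx, vy, vz`, force decomposition `Frad_x..` and
#'   `Fdrag_x..`, plus attributes `particle` and `exit` flag.
#' @export
trace <- function(particles, field, fluid, streaming = NULL,
                  background_flow = c(0, 0, 0), duration,
                  release, mode = c("overdamped", "inertial"),
                  tol = 1e-6, max_step = NULL, full3d = FALSE,
                  record_every = NULL) {
  mode <- match.arg(mode)
  assert_positive(duration, "duration")
  if (inherits(particles, "particle_spec")) particles <- list(particles)
  release <- rbind(release)
  if (nrow(release) == 1 && length(particles) > 1)
    release <- release[rep(1, length(particles)), , drop = FALSE]
  stopifnot(nrow(release) == length(particles))
  flow_fun <- if (is.function(background_flow)) background_flow
  else function(pts) {
    pts <- rbind(pts)
    matrix(background_flow, nrow(pts), 3, byrow = TRUE)
  }
  eta <- fluid$dynamic_viscosity
  domain <- if (!is.null(field)) field$geometry else NULL
  lapply(seq_along(particles), function(i) {
    trace_one(particles[[i]], field, fluid, streaming, flow_fun,
              duration, release[i, ], mode, tol, max_step, full3d,
              record_every, eta, domain)
  })
}

trace_one <- function(p, field, fluid, streaming, flow_fun, duration,
                      x0, mode, tol, max_step, full3d, record_every,
                      eta, domain) {
  drag_c <- 6 * pi * eta * p$radius
  mass <- 4 / 3 * pi * p$radius^3 * p$density
  frad <- function(pos) {
    if (is.null(field) || field$p_a == 0) return(c(0, 0, 0))
    radiation_force(field, p, clamp_domain(pos, domain), fluid)
  }
  vfluid <- function(pos) {
    v <- as.vector(flow_fun(rbind(pos)))
    if (!is.null(streaming)) v <- v + as.vector(streaming$velocity(rbind(pos)))
    v
  }
  vquasi <- function(pos) {
    v <- vfluid(pos) + frad(pos) / drag_c
    if (!full3d) v[3] <- 0
    v
  }
  exited <- function(pos) {
    !is.null(domain) && (pos[1] > domain$L + 1e-12 || pos[1] < -1e-12)
  }
  project <- function(pos) {
    # side walls and lid/floor are impenetrable; x stays free so exits
    # through the ends can be detected
    if (is.null(domain)) return(pos)
    pos[2] <- min(max(pos[2], p$radius), domain$w - p$radius)
    pos[3] <- min(max(pos[3], p$radius), domain$h - p$radius)
    pos
  }
  x0 <- project(x0)
  rec_dt <- record_every %||% (duration / 400)
  if (mode == "overdamped") {
    out <- rk45(vquasi, x0, duration, tol = tol,
                max_step = max_step %||% (duration / 20),
                rec_dt = rec_dt, stop_fun = exited, project = project)
  } else {
    out <- expint_inertial(frad, vfluid, drag_c, mass, x0, duration,
                           max_step %||% (duration / 2000), rec_dt,
                           full3d, stop_fun = exited, project = project)
  }
  tr <- out$df
  n <- nrow(tr)
  fr <- t(vapply(seq_len(n), function(i)
    frad(c(tr$x[i], tr$y[i], tr$z[i])), numeric(3)))
  fd <- t(vapply(seq_len(n), function(i)
    stokes_drag(vfluid(c(tr$x[i], tr$y[i], tr$z[i])),
                c(tr$vx[i], tr$vy[i], tr$vz[i]), p$radius, eta),
    numeric(3)))
  tr$Frad_x <- fr[, 1]; tr$Frad_y <- fr[, 2]; tr$Frad_z <- fr[, 3]
  tr$Fdrag_x <- fd[, 1]; tr$Fdrag_y <- fd[, 2]; tr$Fdrag_z <- fd[, 3]
  structure(tr, class = c("trajectory", "data.frame"),
            particle = p, exit = out$exited, mass = mass)
}

clamp_domain <- function(pos, domain) {
  if (is.null(domain)) return(pos)
  c(min(max(pos[1], 0), domain$L), min(max(pos[2], 0), domain$w),
    min(max(pos[3], 0), domain$h))
}

# Adaptive Dormand-Prince 5(4) for dx/dt = f(x) with trajectory recording.
rk45 <- function(f, x0, tend, tol, max_step, rec_dt, stop_fun,
                 project = identity) {
  a <- list(c(1 / 5),
            c(3 / 40, 9 / 40),
            c(44 / 45, -56 / 15, 32 / 9),
            c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
            c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176,
              -5103 / 18656),
            c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)
  t <- 0; x <- x0
  dt <- min(max_step, tend / 10)
  rec_t <- t; rec_x <- list(x); rec_v <- list(f(x))
  last_rec <- 0
  exited <- FALSE
  vel <- f(x)
  nstep <- 0
  while (t < tend) {
    dt <- min(dt, tend - t)
    if (dt < tend * 1e-14)
      stopf("step-size underflow at t = %g s (dt = %g)", t, dt)
    k <- matrix(0, 7, length(x))
    k[1, ] <- vel
    for (s in 1:6) {
      xs <- x + dt * as.vector(t(k[1:s, , drop = FALSE]) %*% a[[s]])
      k[s + 1, ] <- f(xs)
      if (s == 6) x5 <- xs                 # FSAL: stage 7 value is x5
    }
    x4 <- x + dt * as.vector(t(k) %*% b4)
    err <- sqrt(sum((x5 - x4)^2)) /
      (tol * max(sqrt(sum(x^2)), 1e-9))
    if (err <= 1) {
      t <- t + dt; x <- project(x5)
      vel <- if (identical(x, x5)) k[7, ] else f(x)
      if (t - last_rec >= rec_dt || t >= tend) {
        rec_t <- c(rec_t, t); rec_x[[length(rec_x) + 1]] <- x
        rec_v[[length(rec_v) + 1]] <- vel
        last_rec <- t
      }
      if (stop_fun(x)) { exited <- TRUE; break }
    }
    dt <- dt * min(5, max(0.2, 0.9 * err^(-0.2)))
    dt <- min(dt, max_step)
    nstep <- nstep + 1
    if (nstep > 2e6) stopf("integrator exceeded 2e6 steps")
  }
  if (rec_t[length(rec_t)] < t) {      # always keep the final state
    rec_t <- c(rec_t, t); rec_x[[length(rec_x) + 1]] <- x
    rec_v[[length(rec_v) + 1]] <- vel
  }
  xm <- do.call(rbind, rec_x); vm <- do.call(rbind, rec_v)
  list(df = data.frame(time = rec_t, x = xm[, 1], y = xm[, 2], z = xm[, 3],
                       vx = vm[, 1], vy = vm[, 2], vz = vm[, 3]),
       exited = exited)
}

# Exponential (exact-drag) integrator for m dv/dt = -c (v - v_f) + F_rad.
expint_inertial <- function(frad, vfluid, drag_c, mass, x0, tend, dt0,
                            rec_dt, full3d, stop_fun,
                            project = identity) {
  tau <- mass / drag_c
  t <- 0; x <- x0
  v <- vfluid(x) + frad(x) / drag_c      # start on the slow manifold
  if (!full3d) v[3] <- 0
  rec_t <- t; rec_x <- list(x); rec_v <- list(v)
  last_rec <- 0; exited <- FALSE
  dt <- dt0
  while (t < tend) {
    dt_s <- min(dt, tend - t)
    vt <- vfluid(x) + frad(x) / drag_c   # local terminal velocity
    if (!full3d) vt[3] <- 0
    ef <- exp(-dt_s / tau)
    xn <- x + vt * dt_s + (v - vt) * tau * (1 - ef)
    vn <- vt + (v - vt) * ef
    if (!full3d) { xn[3] <- x0[3]; vn[3] <- 0 }
    t <- t + dt_s; x <- project(xn); v <- vn
    if (t - last_rec >= rec_dt || t >= tend) {
      rec_t <- c(rec_t, t); rec_x[[length(rec_x) + 1]] <- x
      rec_v[[length(rec_v) + 1]] <- v
      last_rec <- t
    }
    if (stop_fun(x)) { exited <- TRUE; break }
  }
  if (rec_t[length(rec_t)] < t) {
    rec_t <- c(rec_t, t); rec_x[[length(rec_x) + 1]] <- x
    rec_v[[length(rec_v) + 1]] <- v
  }
  xm <- do.call(rbind, rec_x); vm <- do.call(rbind, rec_v)
  list(df = data.frame(time = rec_t, x = xm[, 1], y = xm[, 2], z = xm[, 3],
                       vx = vm[, 1], vy = vm[, 2], vz = vm[, 3]),
       exited = exited)
}

#' Separation metrics at an outlet cross-section
#'
#' Reports each particle's lateral (y) position where its trajectory
#' crosses `x = outlet_x` (linearly interpolated), and the maximum
#' pairwise lateral distance `delta` over all particles that crossed.
#'
#' @param trajectories list of `trajectory` objects from [trace()].
#' @param outlet_x outlet coordinate along the flow axis, m.
#' @return list with `positions` (data.frame: particle label, `y_outlet`,
#'   `t_outlet`, `crossed`) and `delta` (m; `NA` if fewer than two
#'   crossings).
#' @export
separation_metrics <- function(trajectories, outlet_x) {
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    p <- attr(tr, "particle")
    ix <- which(tr$x[-1] >= outlet_x & tr$x[-nrow(tr)] < outlet_x)
    if (length(ix) == 0) {
      if (tr$x[1] >= outlet_x) ix <- 0
      else return(data.frame(particle = p$label, y_outlet = NA_real_,
                             t_outlet = NA_real_, crossed = FALSE))
    }
    j <- ix[1]
    if (j == 0) {
      y <- tr$y[1]; tt <- tr$time[1]
    } else {
      tt <- cross_interp(tr$time[j], tr$time[j + 1], tr$x[j], tr$x[j + 1],
                         outlet_x)
      y <- tr$y[j] + (tr$y[j + 1] - tr$y[j]) *
        (tt - tr$time[j]) / max(tr$time[j + 1] - tr$time[j], 1e-300)
    }
    data.frame(particle = p$label, y_outlet = y, t_outlet = tt,
               crossed = TRUE)
  })
  pos <- do.call(rbind, rows)
  yc <- pos$y_outlet[pos$crossed]
  delta <- if (length(yc) >= 2) max(dist(yc)) else NA_real_
  list(positions = pos, delta = delta)
}
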