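# Shared fixtures, built in code.

# Table-style constants used across tests (water / polystyrene rows).
WATER <- list(rho = 997, c = 1497, eta = 0.89e-3, eta_b = 2.47e-3,
              kappa = 4.48e-10)
PS <- list(rho = 1050, c = 2350, kappa = 1.72e-10, sigma = 0.35)

water_mat <- function() material_library("water")

# A water-like fluid whose compressibility is exactly 1/(rho c^2); closed
# -form identities (force oracle, contrast identity) hold exactly with it.
water_exact <- function()
  material("water_exact", "fluid", density = WATER$rho,
           sound_speed = WATER$c, dynamic_viscosity = WATER$eta,
           bulk_viscosity = WATER$eta_b)

ps_particle <- function(d = 10e-6, label = sprintf("PS %g um", d * 1e6))
  particle_spec(d / 2, PS$rho, PS$kappa, label)

small_field <- function(p_a = 1e6, lambda = 200e-6, theta = 0,
                        L = 1e-3, w = 1e-3, h = 30e-6, ...)
  make_tassaw_field(p_a, lambda, theta, list(L = L, w = w, h = h),
                    water_mat(), 19.32e6, ...)

# Rayleigh's characteristic equation for an isotropic half space:
# (2 - xi^2)^2 = 4 sqrt(1 - xi^2 ct^2/cl^2) sqrt(1 - xi^2), xi = v/ct.
rayleigh_sextic_root <- function(ct, cl) {
  f <- function(xi) (2 - xi^2)^2 -
    4 * sqrt(1 - xi^2 * ct^2 / cl^2) * sqrt(1 - xi^2)
  stats::uniroot(f, c(0.5, 0.999), tol = 1e-14)$root * ct
}

iso_speeds <- function(young, poisson, rho) {
  mu <- young / (2 * (1 + poisson))
  lam <- young * poisson / ((1 + poisson) * (1 - 2 * poisson))
  list(ct = sqrt(mu / rho), cl = sqrt((lam + 2 * mu) / rho))
}

# Independent full fourth-rank tensor rotation (oracle for the Bond route).
rotate_stiffness_full <- function(cv, a) {
  vi <- function(i, j) if (i == j) i else 9 - i - j + 0  # (2,3)=4,(1,3)=5,(1,2)=6
  # note: 9 - i - j gives 4, 5, 6 for (2,3), (1,3), (1,2)
  cf <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
    cf[i, j, k, l] <- cv[vi(i, j), vi(k, l)]
  cr <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- 0
    for (p in 1:3) for (q in 1:3) for (r in 1:3) for (t in 1:3)
      s <- s + a[i, p] * a[j, q] * a[k, r] * a[l, t] * cf[p, q, r, t]
    cr[i, j, k, l] <- s
  }
  out <- matrix(0, 6, 6)
  pairs <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  for (m in 1:6) for (n in 1:6)
    out[m, n] <- cr[pairs[m, 1], pairs[m, 2], pairs[n, 1], pairs[n, 2]]
  out
}

rotate_piezo_full <- function(ev, a) {
  vi <- function(i, j) if (i == j) i else 9 - i - j
  ef <- array(0, c(3, 3, 3))
  for (i in 1:3) for (k in 1:3) for (l in 1:3)
    ef[i, k, l] <- ev[i, vi(k, l)]
  er <- array(0, c(3, 3, 3))
  for (i in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- 0
    for (p in 1:3) for (q in 1:3) for (r in 1:3)
      s <- s + a[i, p] * a[k, q] * a[l, r] * ef[p, q, r]
    er[i, k, l] <- s
  }
  out <- matrix(0, 3, 6)
  pairs <- rbind(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  for (i in 1:3) for (m in 1:6)
    out[i, m] <- er[i, pairs[m, 1], pairs[m, 2]]
  out
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
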