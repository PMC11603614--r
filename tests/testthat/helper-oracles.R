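# Independent oracles and shared fixtures. Oracles are deliberately written
# against base R (dnorm sums, stats::cor/lm, explicit quadrature) and never
# call the code paths they check.

kT298 <- oneopes::kBT(298)

# relative finite-difference gradient error of a toy potential at x
fd_gradient_error <- function(pot, x, h = 1e-5) {
  f <- pot$force(x)
  fd <- vapply(seq_along(x), function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
    -(pot$energy(xp) - pot$energy(xm)) / (2 * h)
  }, numeric(1))
  max(abs(f - fd) / pmax(abs(fd), 1))
}

# bin-integrated Boltzmann free energy of a 1-D potential (min-shifted)
quad_profile_1d <- function(pot, grid, T = 298) {
  kT <- oneopes::kBT(T)
  dz <- diff(grid[1:2])
  Fq <- vapply(grid, function(zc) {
    -kT * log(integrate(function(x) exp(-vapply(x, pot$energy, numeric(1)) / kT),
                        zc - dz / 2, zc + dz / 2)$value / dz)
  }, numeric(1))
  Fq - min(Fq)
}

# brute-force weighted KDE (wrapped for periodic dims), plain R loops
kde_brute <- function(S, centers, weights, sigma, period) {
  out <- numeric(nrow(S))
  for (i in seq_len(nrow(S))) {
    acc <- 0
    for (q in seq_len(nrow(centers))) {
      e <- 0
      for (j in seq_len(ncol(S))) {
        d <- S[i, j] - centers[q, j]
        if (period[j] > 0) d <- d - period[j] * round(d / period[j])
        e <- e + d^2 / (2 * sigma[j]^2)
      }
      if (e < 30) acc <- acc + weights[q] * exp(-e)
    }
    out[i] <- acc
  }
  out
}

# independent dihedral via explicit plane normals + signed angle through
# a rotation construction (distinct from the atan2 route in the package)
dihedral_oracle <- function(p) {
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  n1 <- n1 / sqrt(sum(n1^2)); n2 <- n2 / sqrt(sum(n2^2))
  cosphi <- max(-1, min(1, sum(n1 * n2)))
  phi <- acos(cosphi)
  if (sum(cross(n1, n2) * b2) < 0) phi <- -phi
  if (phi <= -pi) phi <- phi + 2 * pi
  phi
}

# toy binding-system quadrature machinery, parameterized by wall stiffness
binding_quadrature <- function(D = 20, w = 0.25, cc = 8, Bq = 20,
                               Rcyl = 0.2, alpha = 0.6, zcc = 0.4,
                               kwall = 1000, T = 298) {
  kT <- oneopes::kBT(T)
  Zq <- function(b) integrate(function(q)
    exp(-(Bq * (q^2 - 1)^2 + cc * q * b) / kT), -3, 3,
    rel.tol = 1e-10)$value
  Ra <- function(z) Rcyl + tan(alpha) * pmax(0, zcc - z)
  slice <- function(z, rel = FALSE) {
    # cross-section integral at fixed z (optionally divided by Zq(0))
    f <- function(rho) {
      b <- exp(-(rho^2 + z^2) / (2 * w^2))
      wall <- ifelse(rho > Ra(z), 0.5 * kwall * (rho - Ra(z))^2, 0)
      den <- if (rel) Zq(0) else 1
      vapply(seq_along(rho), function(i)
        exp(-(-D * b[i] + wall[i]) / kT) * Zq(b[i]) / den, numeric(1)) *
        2 * pi * rho
    }
    integrate(f, 0, Ra(z) + 6 * sqrt(kT / max(kwall, 1)), rel.tol = 1e-9)$value
  }
  G_of_z <- function(zs) vapply(zs, function(z) -kT * log(slice(z)), numeric(1))
  dG_direct <- function(bound_window, dz = 0.0125) {
    zf <- seq(bound_window[1] + dz / 2, bound_window[2] - dz / 2 + 1e-12,
              by = dz)
    site <- sum(vapply(zf, function(z) slice(z, rel = TRUE), numeric(1))) * dz
    -kT * log(oneopes:::C0_nm3 * site)
  }
  list(Zq = Zq, G_of_z = G_of_z, dG_direct = dG_direct, kT = kT, Rcyl = Rcyl)
}

# session-level cache for expensive shared runs
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_env)) assign(name, fn(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# short double-well OPES run shared by several module tests
dw_short_run <- function() {
  fixture("dw_short", function() {
    setup <- oneopes::toy_double_well_setup(steps = 150000L, seed = 11)
    trs <- do.call(oneopes::run_oneopes, setup$run_args)
    list(setup = setup, trs = trs, traj = trs[[1]],
         main = attr(trs, "runtime")[[1]]$bias$main)
  })
}

expected_table1 <- function() {
  # the published 8-replica bias roster: replica k carries auxiliary biases
  # 1..k in the order WL4, WH1, WL1, WH3, WH8, WH5, WH10; MultiThermal tops
  # 310/330/350/370 K on replicas 4-7; main CVs (z, COS) everywhere
  aux <- c("WL4", "WH1", "WL1", "WH3", "WH8", "WH5", "WH10")
  m <- matrix("", nrow = 9, ncol = 8,
              dimnames = list(c("OPES Explore", paste("OPES MultiCV", 1:7),
                                "OPES MultiT"),
                              paste0("replica", 0:7)))
  m[1, ] <- "z,COS"
  for (k in 1:7) for (i in seq_len(k)) m[1 + i, k + 1] <- aux[i]
  m[9, 5:8] <- c("310 K", "330 K", "350 K", "370 K")
  m
}

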