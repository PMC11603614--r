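mk_traj <- function(z, bias = 0, extra = list()) {
  df <- data.frame(time = seq_along(z) * 0.01, z = z,
                   bias = rep_len(bias, length(z)))
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  colvar_trajectory(df)
}

test_that("reweighted profile: uniform sampling gives a flat G, G_U ~ 0", {
  # a free particle in the funnel cylinder samples z uniformly
  sys <- toy_system(flat_potential(3),
                    funnel = funnel_geometry(cylinder_radius = 0.2,
                                             cone_to_cylinder_z = 0),
                    z_range = c(0, 1), z_wall_k = 2000)
  set.seed(91)
  r <- run_langevin(sys, c(0, 0, 0.5), 6e5, dt = 5e-4, record_stride = 10)
  traj <- mk_traj(r$coords[, 3])
  grid <- seq(0.075, 0.925, by = 0.05)
  prof <- reweighted_profile(traj, grid = grid, discard_fraction = 0.1,
                             plateau_window = c(0.6, 0.9))
  expect_true(all(is.finite(prof$G)))
  # z diffuses freely (relaxation ~ L^2/2D ~ 400 steps), so ~750 effective
  # samples spread over 18 bins: the profile is flat to ~0.4 kJ/mol
  expect_lt(diff(range(prof$G)), 0.45)
  expect_lt(abs(prof$G_U - mean(prof$G)), 0.15)
})

test_that("reweighted profile: gauge invariance and error contracts", {
  set.seed(92)
  z <- runif(5000, 0, 1)
  V <- rnorm(5000, 10, 2)
  grid <- seq(0.05, 0.95, by = 0.1)
  p1 <- reweighted_profile(mk_traj(z, V), grid = grid, discard_fraction = 0,
                           plateau_window = c(0.5, 0.9))
  p2 <- reweighted_profile(mk_traj(z, V + 7.3), grid = grid,
                           discard_fraction = 0, plateau_window = c(0.5, 0.9))
  expect_equal(p1$G, p2$G, tolerance = 1e-10)  # constant bias renormalizes away
  expect_equal(p1$G_U, p2$G_U, tolerance = 1e-10)
  expect_error(reweighted_profile(mk_traj(numeric(0)), grid = grid),
               "no frames")
  expect_error(reweighted_profile(mk_traj(z, V), grid = grid,
                                  discard_fraction = 0,
                                  plateau_window = c(5, 6)),
               "plateau")
  expect_error(reweighted_profile(mk_traj(z), z_label = "zz", grid = grid),
               "zz")
})

test_that("binding free energy: closed form, R_cyl scaling, gauge, errors", {
  kT <- kT298
  geom <- funnel_geometry(cylinder_radius = 0.2)
  grid <- seq(0.025, 1.975, by = 0.05)
  L <- 1.0
  # flat G = G_U over a bound window of length L reduces to the closed form
  prof <- free_energy_profile(grid, rep(5, length(grid)), G_U = 5)
  got <- binding_free_energy(prof, c(0.475, 1.425), geom)
  # the discrete window [0.475, 1.425] holds exactly 20 bins x 0.05 = L
  expect_equal(got, kj_to_kcal(-kT * log(C0_nm3 * pi * 0.2^2 * L)),
               tolerance = 1e-10)
  # doubling R_cyl shifts dG by exactly -kT ln 4
  geom2 <- funnel_geometry(cylinder_radius = 0.4)
  expect_equal(binding_free_energy(prof, c(0.475, 1.425), geom2) - got,
               kj_to_kcal(-kT * log(4)), tolerance = 1e-10)
  # gauge invariance: G and G_U shifted together
  prof2 <- free_energy_profile(grid, rep(12, length(grid)), G_U = 12)
  expect_equal(binding_free_energy(prof2, c(0.475, 1.425), geom), got,
               tolerance = 1e-12)
  expect_error(binding_free_energy(
    free_energy_profile(grid, rep(1, length(grid)), G_U = NA_real_),
    c(0.475, 1.425), geom), "G_U")
  expect_error(binding_free_energy(prof, c(5, 6), geom), "outside")
  expect_error(binding_free_energy(
    free_energy_profile(grid, rep(NA_real_, length(grid)), G_U = 0),
    c(0.475, 1.425), geom), "unsampled")
})

test_that("Eq-3 route equals direct standard-state quadrature (stiff wall)", {
  # quadrature vs quadrature: with a stiff wall the funnel assumptions hold
  # and the profile formula must reproduce the direct 3+1-D Boltzmann result
  qd <- binding_quadrature(kwall = 1e6)
  dz <- 0.0125
  grid <- seq(-0.5 + dz / 2, 1.2, by = dz)
  G <- qd$G_of_z(grid)
  # plateau beyond z ~ 0.9: the basin tail (-D exp(-z^2/2w^2) ~ -0.4 kJ/mol
  # at z = 0.7) has decayed below 0.05 kJ/mol there
  GU <- mean(G[grid >= 0.9 & grid <= 1.15])
  prof <- free_energy_profile(grid, G - min(G), G_U = GU - min(G))
  geom <- funnel_geometry(cylinder_radius = qd$Rcyl)
  dG_eq3 <- kcal_to_kj(binding_free_energy(prof, c(-0.5, 0.5), geom))
  dG_dir <- qd$dG_direct(c(-0.5, 0.5))
  expect_lt(abs(dG_eq3 - dG_dir), 0.1)
})

test_that("dual-funnel combination and the undersampled-side rule", {
  a <- c(-3.1, -3.3, -2.9); b <- c(-3.5, -3.2, -3.0)
  both <- dual_funnel_combine(a, b)
  expect_equal(both$per_block, (a + b) / 2)
  expect_equal(both$value, mean((a + b) / 2))
  expect_equal(both$std, sd((a + b) / 2))
  expect_identical(both$sides_used, "both")
  # identical sides collapse to either one
  same <- dual_funnel_combine(a, a)
  expect_equal(same$per_block, a)
  # x + delta and x - delta average to x exactly
  x <- c(-4, -5, -6); delta <- c(0.3, -0.2, 0.7)
  expect_equal(dual_funnel_combine(x + delta, x - delta)$per_block, x)
  # pass-through with the side flag when one side is starved
  ab <- dual_funnel_combine(a, b, sampling_ok = c(TRUE, FALSE))
  expect_identical(ab$sides_used, "above_only")
  expect_equal(ab$per_block, a)
  ba <- dual_funnel_combine(a, b, sampling_ok = c(FALSE, TRUE))
  expect_identical(ba$sides_used, "below_only")
  expect_error(dual_funnel_combine(a, b, sampling_ok = c(FALSE, FALSE)),
               "neither")
  # occupancy rule on a fixture with one empty side
  z <- c(runif(500, -0.2, 0.2), runif(495, 0.8, 1.1), runif(5, -1.1, -0.8))
  traj <- mk_traj(z)
  expect_true(funnel_side_sampled(traj, window = c(0.7, 1.2),
                                  discard_fraction = 0))
  expect_false(funnel_side_sampled(traj, window = c(-1.2, -0.7),
                                   discard_fraction = 0))
})

test_that("block errors: exact hand values, CLT scaling, triplicate mode", {
  est_mean <- function(tr) mean(tr$z)
  z <- c(1, 2, 3, 4, 5, 6)
  bfe <- block_error(mk_traj(z), est_mean, n_blocks = 3, discard_fraction = 0)
  expect_equal(bfe$per_block, c(1.5, 3.5, 5.5))
  expect_equal(bfe$value, 3.5)
  expect_equal(bfe$std, sd(c(1.5, 3.5, 5.5)))  # n-1 denominator
  # three identical blocks: zero spread
  z3 <- rep(c(2, 7, 4, 1), 3)
  expect_equal(block_error(mk_traj(z3), est_mean, n_blocks = 3,
                           discard_fraction = 0)$std, 0)
  # stationary series: block std shrinks like 1/sqrt(block length)
  set.seed(93)
  ratio <- replicate(40, {
    s1 <- block_error(mk_traj(rnorm(600)), est_mean, n_blocks = 3,
                      discard_fraction = 0)$std
    s2 <- block_error(mk_traj(rnorm(9600)), est_mean, n_blocks = 3,
                      discard_fraction = 0)$std
    s1 / s2
  })
  expect_equal(median(ratio), 4, tolerance = 0.35)
  # triplicate-run mode: each independent trajectory is one block
  runs <- list(mk_traj(c(1, 1)), mk_traj(c(2, 2)), mk_traj(c(4, 4)))
  tri <- block_error(runs, est_mean)
  expect_equal(tri$per_block, c(1, 2, 4))
  expect_equal(tri$std, sd(c(1, 2, 4)))
  expect_error(block_error(mk_traj(c(1, 2)), est_mean, n_blocks = 3,
                           discard_fraction = 0), "fewer frames")
})

test_that("unit conversions round-trip", {
  x <- c(-13.06, 0, 2.5, 1e6)
  expect_equal(kcal_to_kj(kj_to_kcal(x)), x, tolerance = 1e-12)
  expect_equal(kj_to_kcal(4.184), 1)
})
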