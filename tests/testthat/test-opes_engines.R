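test_that("explore bias: empty state, single kernel, eps floor, gauge", {
  st <- opes_explore_new(sigma = 0.1, barrier = 20, pace = 10)
  g <- seq(-2, 2, by = 0.01)
  expect_identical(opes_explore_bias(st, matrix(g, ncol = 1)), numeric(length(g)))
  st <- opes_explore_deposit(st, 0.3)
  V <- opes_explore_bias(st, matrix(g, ncol = 1))
  expect_equal(g[which.max(V)], 0.3, tolerance = 0.011)
  # strictly decreasing away from the kernel until the floor
  right <- V[g >= 0.31 & g <= 0.8]
  expect_true(all(diff(right) < 0))
  # far away the bias sits at the constant eps floor, which is -BARRIER
  expect_equal(V[1], -20, tolerance = 1e-6)
  expect_equal(max(V), 0, tolerance = 1e-12)
  # two points with identical estimated density get identical bias
  expect_equal(opes_explore_bias(st, 0.3 - 0.07), opes_explore_bias(st, 0.3 + 0.07),
               tolerance = 1e-12)
  # deposit honors PACE
  st2 <- opes_explore_deposit(st, 1, step = 7L)
  expect_identical(st2$deposit_count, st$deposit_count)
  expect_error(opes_explore_deposit(st, NaN), "non-finite CV")
  expect_error(opes_explore_new(sigma = 0.1, barrier = 1), "gamma")
})

test_that("explore bias matches a brute-force weighted KDE oracle", {
  set.seed(31)
  for (case in 1:3) {
    k <- sample(1:2, 1)
    period <- if (case == 3) rep(2 * pi, k) else rep(0, k)
    st <- opes_explore_new(sigma = runif(k, 0.05, 0.3), barrier = 15,
                           pace = 1, period = period,
                           merge_threshold = if (case == 2) 1 else NULL)
    for (i in 1:40) st <- opes_explore_deposit(st, runif(k, -1, 1) * pi)
    S <- matrix(runif(30 * k, -1, 1) * pi, ncol = k)
    dens <- kde_brute(S, st$centers, st$weights, st$sigma, st$period)
    Vexp <- st$pref * (log(pmin(dens / st$Z, 1) + st$eps) - log1p(st$eps))
    expect_equal(opes_explore_bias(st, S), Vexp, tolerance = 1e-12)
    # Z is the sup of the same KDE over centers
    expect_equal(st$Z, max(kde_brute(st$centers, st$centers, st$weights,
                                     st$sigma, st$period)), tolerance = 1e-12)
  }
})

test_that("engine-recorded bias values equal the R-side evaluation", {
  set.seed(41)
  pot <- double_well_1d(10, 2)
  sys <- toy_system(pot)
  st <- opes_explore_new(sigma = 0.12, barrier = 12, pace = 1)
  for (i in 1:25) st <- opes_explore_deposit(st, runif(1, -1.2, 1.2))
  seg <- oneopes:::engine_run_segment(
    -0.5, 200L, 1e-3, kT298, 1, pot$pot_id, pot$pot_par, numeric(0),
    list(oneopes:::explore_to_engine(st, 1L)), NULL, 10L, 0L, rnorm(1))
  n <- seg$nrec
  xs <- seg$records[seq_len(n), 1, drop = FALSE]
  expect_equal(seg$records[seq_len(n), 4], opes_explore_bias(st, xs),
               tolerance = 1e-12)
  expect_equal(seg$records[seq_len(n), 3], seg$records[seq_len(n), 4])
})

test_that("BARRIER contract holds exactly for random kernel configurations", {
  set.seed(51)
  for (barrier in c(3, 15, 100)) {
    st <- opes_explore_new(sigma = 0.1, barrier = barrier, pace = 1)
    for (i in 1:60) {
      st <- opes_explore_deposit(st, rnorm(1))
      V <- opes_explore_bias(st, matrix(seq(-4, 4, by = 0.005), ncol = 1))
      expect_lte(max(V) - min(V), barrier * (1 + 1e-6))
    }
  }
})

test_that("converged double-well run: KDE near target, V + (1-1/g)F flat", {
  run <- dw_short_run()
  main <- run$main
  pot <- run$setup$system$potential
  gamma <- main$gamma
  grid <- seq(-1.55, 1.55, by = 0.05)
  ptg <- vapply(grid, function(zc)
    integrate(function(u) exp(-vapply(u, pot$energy, numeric(1)) /
                                (gamma * kT298)),
              zc - 0.025, zc + 0.025)$value, numeric(1))
  ptg <- ptg / sum(ptg)
  dens <- oneopes:::engine_kernel_sum(matrix(grid, ncol = 1), main$centers,
                                      main$weights, main$sigma, main$period)
  dens <- dens / sum(dens)
  expect_lt(sum(abs(dens - ptg)) / 2, 0.1)
  # flat-histogram-like residual: V(s) + (1-1/gamma) F(s) ~ constant over the
  # well-populated region, to within a (1-1/gamma)-scaled tolerance
  Fg <- vapply(grid, pot$energy, numeric(1))
  Vg <- opes_explore_bias(main, matrix(grid, ncol = 1))
  resid <- Vg + (1 - 1 / gamma) * Fg
  sel <- Fg < 25
  expect_lt(diff(range(resid[sel])), 0.1 * (1 - 1 / gamma) * main$barrier)
})

test_that("multithermal: null limit, closed-form oracle, gauge, monotone", {
  # T_max = T_min is a single-member ensemble: bias identically zero
  st0 <- opes_multithermal_new(T_min = 298, T_max = 298)
  st0 <- opes_multithermal_update(st0, rnorm(100, 50, 5))
  expect_identical(opes_multithermal_bias(st0, c(0, 50, 100)), rep(0, 3))

  # harmonic-oscillator closed form: U ~ Gamma(d/2, kT) at T0 gives
  # c_l = ln <exp(-(b_l - b0) U)>_T0 = -(d/2) ln(b_l / b0) exactly; feed the
  # estimator Gauss-Legendre quadrature "samples" so it reproduces it to
  # high precision, then the bias must match the brute-force log-sum-exp
  d <- 2
  st <- opes_multithermal_new(T_min = 298, T_max = 370, n_temps = 8)
  h <- 0.01
  nodes <- seq(h / 2, 80, by = h)  # midpoint rule on a dense U grid, kJ/mol
  logw <- (d / 2 - 1) * log(nodes) - nodes / kT298  # Gamma(1, kT) density
  st <- opes_multithermal_update(st, nodes, logw = logw)
  c_exact <- -(d / 2) * log(st$beta / st$beta[1])
  expect_equal(st$clam, c_exact, tolerance = 1e-3)
  expect_equal(opes_multithermal_deltaF(st)[1], 0)
  # bias values match an independent high-precision log-sum-exp
  U <- c(1, 10, 30, 55)
  brute <- vapply(U, function(u) {
    terms <- exp(-(st$beta - st$beta[1]) * u - c_exact)
    -kT298 * log(mean(terms))
  }, numeric(1))
  expect_equal(opes_multithermal_bias(st, U), brute, tolerance = 2e-3)
  # gauge property: shifting all c by a constant shifts the bias rigidly,
  # so bias differences are invariant
  st2 <- st
  st2$clam <- st$clam + 1.23
  d1 <- diff(opes_multithermal_bias(st, U))
  d2 <- diff(opes_multithermal_bias(st2, U))
  expect_equal(d1, d2, tolerance = 1e-12)
  # degenerate (constant-U) record: bias stays zero, with a warning
  stc <- opes_multithermal_new(T_min = 298, T_max = 350)
  expect_warning(stc <- opes_multithermal_update(stc, rep(5, 50)),
                 "constant potential energy")
  expect_identical(opes_multithermal_bias(stc, c(1, 5)), rep(0, 2))
})

test_that("multithermal reweighting recovers the canonical mean energy", {
  # biased run on a 2-D harmonic well with a MultiThermal bias; reweighting
  # with exp(+V/kT) must recover the T_min canonical <U> = d/2 kT
  pot <- harmonic_potential(c(80, 80))
  sys <- toy_system(pot)
  lad <- ladder_config(list(replica_spec(0L, main_cvs = "x")),
                       steps = 0L, seed = 3)
  set.seed(3)
  st <- opes_multithermal_new(T_min = 298, T_max = 500, n_temps = 8)
  x <- c(0.1, 0)
  noise <- rnorm(2)
  U_all <- c(); V_all <- c()
  for (seg in 1:100) {
    out <- oneopes:::engine_run_segment(
      x, 500L, 5e-4, kT298, 1, pot$pot_id, pot$pot_par, numeric(0), list(),
      oneopes:::mt_to_engine(st), 10L, 0L, noise)
    x <- out$x; noise <- out$noise_prev
    n <- out$nrec
    U <- out$records[seq_len(n), 3]
    V <- out$records[seq_len(n), 4]
    st <- opes_multithermal_update(st, U, logw = V / kT298)
    if (seg > 20) { U_all <- c(U_all, U); V_all <- c(V_all, V) }
  }
  expect_true(st$active)
  w <- exp((V_all - max(V_all)) / kT298)
  Uhat <- sum(w * U_all) / sum(w)
  # block standard error on the reweighted mean
  nb <- 20
  bl <- split(seq_along(U_all), cut(seq_along(U_all), nb))
  bm <- vapply(bl, function(i) sum(w[i] * U_all[i]) / sum(w[i]), numeric(1))
  se <- sd(bm) / sqrt(nb)
  expect_lt(abs(Uhat - kT298), 3 * se + 0.02)
  # sanity: the biased (unweighted) mean energy is visibly hotter
  expect_gt(mean(U_all), kT298 * 1.05)
})

test_that("total_bias sums the roster and rejects mismatches", {
  spec0 <- replica_spec(0L, main_cvs = "z")
  spec2 <- replica_spec(2L, main_cvs = "z",
                        aux_rosters = list("q", c("q", "t1")),
                        multithermal_Tmax = NULL)
  set.seed(61)
  main <- opes_explore_new(0.1, barrier = 20, pace = 1)
  main <- opes_explore_deposit(main, 0.2)
  a1 <- opes_explore_new(0.2, barrier = 3, pace = 1, labels = "q")
  a1 <- opes_explore_deposit(a1, -0.5)
  a2 <- opes_explore_new(c(0.2, 0.4), barrier = 3, pace = 1,
                         labels = c("q", "t1"), period = c(0, 2 * pi))
  a2 <- opes_explore_deposit(a2, c(-0.5, 3))
  cvv <- c(z = 0.1, q = -0.4, t1 = 3.1)
  # replica 0: main term alone
  expect_equal(total_bias(spec0, list(main = main, aux = list(), mt = NULL),
                          cvv, U = 5),
               as.numeric(opes_explore_bias(main, 0.1)))
  # additivity against term-by-term recomputation
  got <- total_bias(spec2, list(main = main, aux = list(a1, a2), mt = NULL),
                    cvv, U = 5)
  expect_equal(got, as.numeric(opes_explore_bias(main, 0.1) +
                                 opes_explore_bias(a1, -0.4) +
                                 opes_explore_bias(a2, c(-0.4, 3.1))),
               tolerance = 1e-12)
  # zeroed biases sum to zero
  z1 <- opes_explore_new(0.1, barrier = 0); z2 <- opes_explore_new(0.2, barrier = 0,
                                                                   labels = "q")
  spec1 <- replica_spec(1L, main_cvs = "z", aux_rosters = list("q"))
  expect_identical(total_bias(spec1, list(main = z1, aux = list(z2), mt = NULL),
                              cvv, U = 5), 0)
  expect_error(total_bias(spec2, list(main = main, aux = list(a1), mt = NULL),
                          cvv, U = 5), "mismatch")
  expect_error(total_bias(spec0, list(main = main, aux = list(),
                                      mt = opes_multithermal_new(298, 350)),
                          cvv, U = 5), "mismatch|MultiThermal")
})
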