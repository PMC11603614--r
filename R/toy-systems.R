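# Analytic model potentials, synthetic solvent, funnel restraint and an
# overdamped Langevin integrator. These stand in for the MD engine and the
# host-guest Hamiltonian so that every free energy the sampling machinery
# estimates can also be computed exactly by quadrature.

#' Construct a toy potential
#'
#' A `toy_potential` bundles an energy function, its (negative-gradient) force
#' and the metadata the compiled engine needs. Energies are kJ/mol, lengths nm.
#'
#' @param dimensionality number of coordinates
#' @param energy_fn function(x) -> energy, x a numeric vector of length
#'   `dimensionality`
#' @param force_fn function(x) -> force vector (-dU/dx)
#' @param descriptor identifier string
#' @param pot_id,pot_par compiled-engine dispatch id and parameter vector
#' @return object of class `toy_potential`
#' @export
toy_potential <- function(dimensionality, energy_fn, force_fn, descriptor,
                          pot_id = NA_integer_, pot_par = numeric(0)) {
  stopifnot(dimensionality >= 1, is.function(energy_fn), is.function(force_fn))
  structure(list(dim = as.integer(dimensionality), energy = energy_fn,
                 force = force_fn, descriptor = descriptor,
                 pot_id = as.integer(pot_id), pot_par = as.numeric(pot_par)),
            class = "toy_potential")
}

#' @export
print.toy_potential <- function(x, ...) {
  cat("<toy_potential>", x$descriptor, "dim:", x$dim, "\n")
  invisible(x)
}

#' Symmetric quartic double well in one dimension
#'
#' \eqn{U(x) = B\,[(2x/a)^2 - 1]^2} with equal minima of zero at
#' \eqn{x = \pm a/2} and a barrier of height `barrier_height` at the origin.
#'
#' @param barrier_height barrier B in kJ/mol (> 0)
#' @param minima_sep distance a between the two minima in nm (> 0)
#' @return a [toy_potential()] of dimensionality 1
#' @export
double_well_1d <- function(barrier_height, minima_sep) {
  stopifnot(barrier_height > 0, minima_sep > 0)
  B <- barrier_height
  h <- minima_sep / 2
  toy_potential(
    1L,
    energy_fn = function(x) {
      t2 <- (x[1] / h)^2
      B * (t2 - 1)^2
    },
    force_fn = function(x) -4 * B * (x[1] / h) * ((x[1] / h)^2 - 1) / h,
    descriptor = sprintf("double_well_1d(B=%g,a=%g)", B, minima_sep),
    pot_id = 1L, pot_par = c(B, h))
}

#' Toy host-guest binding potential
#'
#' A single attractive Gaussian basin of depth `well_depth` at the origin with
#' a flat far field. With `solvent_coupling > 0` a fourth coordinate q, a
#' synthetic solvent-occupancy degree of freedom, is added: q lives in a
#' symmetric double well of barrier `solvent_barrier` and couples to the bound
#' state through `solvent_coupling * q * exp(-|r|^2 / 2w^2)`, so binding
#' requires crossing a slow barrier orthogonal to the binding axis - the
#' classic hidden-degree-of-freedom trap for a bias applied on z alone.
#'
#' @param well_depth basin depth D in kJ/mol (> 0)
#' @param well_width Gaussian width w in nm
#' @param solvent_coupling coupling c in kJ/mol; 0 disables the q coordinate
#' @param solvent_barrier double-well barrier for q in kJ/mol
#' @return a [toy_potential()] of dimensionality 3 (or 4 when coupled)
#' @export
toy_binding_potential <- function(well_depth, well_width = 0.25,
                                  solvent_coupling = 0,
                                  solvent_barrier = 20) {
  stopifnot(well_depth > 0, well_width > 0, solvent_coupling >= 0)
  D <- well_depth; w <- well_width; cc <- solvent_coupling; Bq <- solvent_barrier
  has_q <- cc > 0
  d <- if (has_q) 4L else 3L
  toy_potential(
    d,
    energy_fn = function(x) {
      b <- exp(-sum(x[1:3]^2) / (2 * w^2))
      U <- -D * b
      if (has_q) {
        q <- x[4]
        U <- U + Bq * (q^2 - 1)^2 + cc * q * b
      }
      U
    },
    force_fn = function(x) {
      b <- exp(-sum(x[1:3]^2) / (2 * w^2))
      dUdb <- -D
      f <- numeric(d)
      if (has_q) {
        q <- x[4]
        dUdb <- dUdb + cc * q
        f[4] <- -(4 * Bq * q * (q^2 - 1) + cc * b)
      }
      f[1:3] <- dUdb * b * x[1:3] / w^2
      f
    },
    descriptor = sprintf("toy_binding(D=%g,w=%g,c=%g,Bq=%g)", D, w, cc, Bq),
    pot_id = 2L, pot_par = c(D, w, cc, Bq, as.numeric(has_q)))
}

#' Harmonic well (diagnostic potential)
#'
#' @param spring per-dimension spring constants, kJ/mol/nm^2
#' @return a [toy_potential()]
#' @export
harmonic_potential <- function(spring) {
  stopifnot(all(spring > 0))
  k <- as.numeric(spring)
  toy_potential(
    length(k),
    energy_fn = function(x) sum(0.5 * k * x^2),
    force_fn = function(x) -k * x,
    descriptor = sprintf("harmonic(k=%s)", paste(k, collapse = ",")),
    pot_id = 3L, pot_par = k)
}

#' Flat potential (funnel walls only)
#'
#' Zero energy everywhere; useful with a funnel restraint to test that a free
#' particle samples the restrained volume uniformly.
#'
#' @param dimensionality number of coordinates (>= 3 to combine with a funnel)
#' @return a [toy_potential()]
#' @export
flat_potential <- function(dimensionality = 3L) {
  d <- as.integer(dimensionality)
  toy_potential(d, energy_fn = function(x) 0,
                force_fn = function(x) numeric(d),
                descriptor = "flat", pot_id = 4L, pot_par = numeric(0))
}

#' Funnel restraint geometry
#'
#' Cone-plus-cylinder confining region: within axial distance
#' `cone_to_cylinder_z` of the origin plane the allowed radius opens linearly
#' with `cone_half_angle`; beyond it the guest is confined to a cylinder of
#' radius `cylinder_radius`, which makes the unbound-state volume analytic and
#' enables the standard-state correction. With `dual = TRUE` the allowed
#' region is the union of two funnels mirror-symmetric about the origin plane
#' (hosts open at both ends); otherwise the single funnel extends toward +z.
#'
#' @param origin 3-vector, nm
#' @param axis 3-vector, normalized internally
#' @param cylinder_radius R_cyl in nm (> 0)
#' @param cone_half_angle radians in [0, pi/2)
#' @param cone_to_cylinder_z axial length of the cone section, nm (>= 0)
#' @param wall_spring_constant kJ/mol/nm^2 (>= 0)
#' @param dual logical; two mirror-symmetric funnels
#' @return object of class `funnel_geometry`
#' @export
funnel_geometry <- function(origin = c(0, 0, 0), axis = c(0, 0, 1),
                            cylinder_radius, cone_half_angle = 0.6,
                            cone_to_cylinder_z = 0.4,
                            wall_spring_constant = 1000, dual = FALSE) {
  stopifnot(length(origin) == 3, length(axis) == 3,
            cylinder_radius > 0, cone_half_angle >= 0, cone_half_angle < pi / 2,
            cone_to_cylinder_z >= 0, wall_spring_constant >= 0)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("funnel axis must be non-zero")
  structure(list(origin = as.numeric(origin), axis = as.numeric(axis) / nrm,
                 cylinder_radius = cylinder_radius,
                 cone_half_angle = cone_half_angle,
                 cone_to_cylinder_z = cone_to_cylinder_z,
                 wall_spring_constant = wall_spring_constant,
                 dual = isTRUE(dual)),
            class = "funnel_geometry")
}

funnel_allowed_radius <- function(geom, z) {
  zz <- if (geom$dual) abs(z) else z
  geom$cylinder_radius +
    tan(geom$cone_half_angle) * pmax(0, geom$cone_to_cylinder_z - zz)
}

#' Funnel restraint energy
#'
#' Zero inside the allowed cone-plus-cylinder region; half-harmonic penalty
#' `0.5 * k * (rho - R(z))^2` on the radial excess outside. Continuous
#' everywhere, and exactly zero (zero force) in the interior.
#'
#' @param r 3-vector position (nm), or an n x 3 matrix of positions
#' @param geom a [funnel_geometry()]
#' @return energy in kJ/mol (vectorized over rows of a matrix input)
#' @export
funnel_restraint_energy <- function(r, geom) {
  stopifnot(inherits(geom, "funnel_geometry"))
  R <- if (is.matrix(r)) r else matrix(r, nrow = 1)
  rel <- sweep(R, 2, geom$origin)
  z <- as.numeric(rel %*% geom$axis)
  radial <- rel - outer(z, geom$axis)
  rho <- sqrt(rowSums(radial^2))
  excess <- pmax(0, rho - funnel_allowed_radius(geom, z))
  e <- 0.5 * geom$wall_spring_constant * excess^2
  if (is.matrix(r)) e else e[1]
}

#' Simulation state for the toy integrator
#'
#' @param coordinates numeric vector of coordinates (single-particle toy
#'   systems) in nm
#' @param step integer step counter
#' @param noise_prev previous-step Gaussian draws (the BAOAB-limit integrator
#'   averages consecutive noises); defaults to a fresh draw
#' @return object of class `simulation_state`
#' @export
simulation_state <- function(coordinates, step = 0L, noise_prev = NULL) {
  x <- as.numeric(coordinates)
  if (is.null(noise_prev)) noise_prev <- rnorm(length(x))
  stopifnot(length(noise_prev) == length(x))
  structure(list(coordinates = x, step = as.integer(step),
                 noise_prev = as.numeric(noise_prev)),
            class = "simulation_state")
}

#' One overdamped Langevin step (BAOAB limit)
#'
#' \deqn{x' = x + (\Delta t/\gamma) F + \sqrt{2 k_B T \Delta t/\gamma}\,
#'       (\xi_n + \xi_{n+1})/2}
#' The averaged consecutive noises give the BAOAB-limit method, whose
#' configurational sampling error is O(dt^2) rather than Euler-Maruyama's
#' O(dt). Randomness comes from R's RNG stream, so a fixed seed gives a
#' bit-identical trajectory (and matches the compiled engine draw-for-draw).
#'
#' @param state a [simulation_state()]
#' @param total_force force vector at `state$coordinates`, kJ/mol/nm
#' @param dt time step, ps (> 0)
#' @param T temperature, K (> 0)
#' @param friction friction coefficient gamma, kJ mol^-1 ps nm^-2 (> 0)
#' @return the advanced `simulation_state`
#' @export
langevin_step <- function(state, total_force, dt, T = 298, friction = 1) {
  stopifnot(inherits(state, "simulation_state"), dt > 0, T > 0, friction > 0)
  f <- as.numeric(total_force)
  if (!all(is.finite(f))) {
    bad <- which(!is.finite(f))[1]
    stop(sprintf("non-finite force on coordinate %d at step %d",
                 bad, state$step + 1L))
  }
  xi <- rnorm(length(state$coordinates))
  sq <- sqrt(2 * kBT(T) * dt / friction) * 0.5
  x <- state$coordinates + (dt / friction) * f + sq * (xi + state$noise_prev)
  simulation_state(x, step = state$step + 1L, noise_prev = xi)
}

#' Synthetic solvent shell
#'
#' Uniform pseudo-random tracer positions (synthetic "water oxygens") in a box,
#' reproducible from `seed`. The tracers are non-interacting: they only feed
#' coordination-number collective variables with realistic fluctuation
#' statistics. The caller's RNG state is left untouched.
#'
#' @param n_solvent number of tracers (>= 0)
#' @param box lengths of the box sides, nm (length 3, recycled if scalar)
#' @param seed integer seed
#' @return `n_solvent` x 3 matrix of coordinates
#' @export
generate_solvent_shell <- function(n_solvent, box = c(2, 2, 2), seed = 1L) {
  stopifnot(n_solvent >= 0)
  box <- rep_len(as.numeric(box), 3)
  if (n_solvent == 0) return(matrix(numeric(0), 0, 3))
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  m <- matrix(runif(3 * n_solvent), ncol = 3)
  sweep(m, 2, box, `*`)
}

#' Diffusive refresh of solvent tracers
#'
#' Adds Gaussian displacements (reflected at the box walls) so coordination
#' CVs fluctuate with a realistic diffusive time scale.
#'
#' @param solvent n x 3 coordinate matrix
#' @param box box side lengths, nm
#' @param sd displacement standard deviation, nm
#' @return refreshed n x 3 matrix
#' @export
refresh_solvent <- function(solvent, box = c(2, 2, 2), sd = 0.05) {
  if (nrow(solvent) == 0) return(solvent)
  box <- rep_len(as.numeric(box), 3)
  m <- solvent + matrix(rnorm(length(solvent), sd = sd), ncol = 3)
  for (j in 1:3) {  # reflect into [0, box]
    m[, j] <- abs(m[, j])
    over <- m[, j] > box[j]
    m[over, j] <- 2 * box[j] - m[over, j]
  }
  m
}

# wall spec vector consumed by the compiled engine
wall_vector <- function(funnel = NULL, z_range = NULL, z_wall_k = 500) {
  if (is.null(funnel) && is.null(z_range)) return(numeric(0))
  if (is.null(funnel)) {
    funnel <- list(cylinder_radius = Inf, cone_half_angle = 0,
                   cone_to_cylinder_z = 0, wall_spring_constant = 0,
                   dual = FALSE)
  }
  if (is.null(z_range)) z_range <- c(-Inf, Inf)
  c(funnel$cylinder_radius, tan(funnel$cone_half_angle),
    funnel$cone_to_cylinder_z, funnel$wall_spring_constant,
    as.numeric(isTRUE(funnel$dual)), z_range[1], z_range[2], z_wall_k)
}

#' Toy system: potential plus confining restraints
#'
#' Combines a base [toy_potential()] with an optional [funnel_geometry()]
#' (engine requires origin at 0 and axis +z) and optional axial half-harmonic
#' walls `z_range` that bound the sampled stretch of the funnel axis.
#'
#' @param potential a [toy_potential()]
#' @param funnel optional [funnel_geometry()]
#' @param z_range optional `c(zlo, zhi)` axial walls, nm
#' @param z_wall_k spring constant of the axial walls, kJ/mol/nm^2
#' @return object of class `toy_system` with `$energy(x)` / `$force(x)`
#'   including all restraints
#' @export
toy_system <- function(potential, funnel = NULL, z_range = NULL,
                       z_wall_k = 500) {
  stopifnot(inherits(potential, "toy_potential"))
  if (!is.null(funnel)) {
    stopifnot(inherits(funnel, "funnel_geometry"))
    if (any(abs(funnel$origin) > 1e-12) ||
        any(abs(funnel$axis - c(0, 0, 1)) > 1e-12))
      stop("toy engine requires a funnel with origin 0 and axis +z")
    if (potential$dim < 3) stop("funnel needs >= 3 coordinates")
  }
  wall <- wall_vector(funnel, z_range, z_wall_k)
  energy <- function(x) {
    e <- potential$energy(x)
    if (!is.null(funnel)) e <- e + funnel_restraint_energy(x[1:3], funnel)
    if (!is.null(z_range)) {
      z <- x[3]
      if (z < z_range[1]) e <- e + 0.5 * z_wall_k * (z - z_range[1])^2
      if (z > z_range[2]) e <- e + 0.5 * z_wall_k * (z - z_range[2])^2
    }
    e
  }
  structure(list(potential = potential, funnel = funnel, z_range = z_range,
                 z_wall_k = z_wall_k, wall = wall, dim = potential$dim,
                 energy = energy),
            class = "toy_system")
}

#' Unbiased Langevin run through the compiled engine
#'
#' @param system a [toy_system()] (or bare [toy_potential()])
#' @param x0 initial coordinates
#' @param nsteps number of steps
#' @param dt,T,friction integrator parameters, see [langevin_step()]
#' @param record_stride record every this many steps
#' @return list with `coords` (matrix), `U` (potential energies), `x` (final
#'   coordinates), `noise_prev`
#' @export
run_langevin <- function(system, x0, nsteps, dt = 1e-3, T = 298, friction = 1,
                         record_stride = 1L) {
  if (inherits(system, "toy_potential")) system <- toy_system(system)
  stopifnot(inherits(system, "toy_system"), length(x0) == system$dim)
  seg <- engine_run_segment(as.numeric(x0), as.integer(nsteps), dt, kBT(T),
                            friction, system$potential$pot_id,
                            system$potential$pot_par, system$wall,
                            list(), NULL, as.integer(record_stride), 0L,
                            rnorm(system$dim))
  n <- seg$nrec
  d <- system$dim
  list(coords = seg$records[seq_len(n), seq_len(d), drop = FALSE],
       U = seg$records[seq_len(n), d + 1],
       step = seg$rec_step[seq_len(n)],
       x = seg$x, noise_prev = seg$noise_prev)
}
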