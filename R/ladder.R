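# The OneOPES replica ladder: a convergence-dedicated replica 0 carrying only
# the main OPES Explore bias, and exploration replicas 1-7 that add weak
# auxiliary multi-CV biases and (on replicas 4-7) a MultiThermal bias.
# Configurations are exchanged between neighbors with a Metropolis rule on
# the bias difference; bias potentials are owned by the replica slot and
# never swap, matching replica-exchange semantics in PLUMED.

#' Replica specification
#'
#' @param index replica index (0 = convergence replica)
#' @param main_cvs ordered labels of the main OPES Explore CVs
#' @param aux_rosters list of character vectors: the CV roster of each
#'   auxiliary (multi-CV) bias this replica carries
#' @param multithermal_Tmax highest MultiThermal temperature in K, or NULL
#' @return object of class `replica_spec`
#' @export
replica_spec <- function(index, main_cvs = c("z", "COS"),
                         aux_rosters = list(), multithermal_Tmax = NULL) {
  stopifnot(index >= 0, length(main_cvs) >= 1)
  if (index == 0 && (length(aux_rosters) > 0 || !is.null(multithermal_Tmax)))
    stop("replica 0 is convergence-dedicated: no auxiliary or thermal bias")
  structure(list(index = as.integer(index), main_cvs = main_cvs,
                 aux_rosters = aux_rosters,
                 multithermal_Tmax = multithermal_Tmax),
            class = "replica_spec")
}

#' Ladder configuration
#'
#' @param replicas list of [replica_spec()] (8 by default order)
#' @param exchange_stride steps between exchange attempts
#' @param steps total integration steps of a run
#' @param seed RNG seed of a run
#' @param thermostat_T thermostat temperature, K
#' @return object of class `ladder_config`
#' @export
ladder_config <- function(replicas, exchange_stride = 1000L, steps = 0L,
                          seed = 1L, thermostat_T = 298) {
  stopifnot(length(replicas) >= 1, exchange_stride >= 1)
  idx <- vapply(replicas, function(r) r$index, integer(1))
  if (!identical(idx, seq_along(replicas) - 1L))
    stop("replica indices must be 0..n-1 in order")
  naux <- vapply(replicas, function(r) length(r$aux_rosters), integer(1))
  if (any(diff(naux) < 0))
    stop("auxiliary bias count must be non-decreasing with replica index")
  for (r in replicas) {
    if (!is.null(r$multithermal_Tmax) && r$index < 4)
      stop("MultiThermal biases are restricted to replicas 4 and above")
  }
  structure(list(replicas = replicas,
                 exchange_stride = as.integer(exchange_stride),
                 steps = as.integer(steps), seed = as.integer(seed),
                 thermostat_T = thermostat_T),
            class = "ladder_config")
}

#' Build the default 8-replica ladder
#'
#' Replica k (k = 1..7) carries auxiliary biases 1..k in the order given by
#' `aux_cv_order` (default: the hydration CVs WL4, WH1, WL1, WH3, WH8, WH5,
#' WH10). Torsions, when present, join every auxiliary roster: with up to two
#' torsions each roster takes all of them; with three, roster j takes the
#' cycling pair `{j mod 3, (j+1) mod 3}` (0-based) so every unordered torsion
#' pair occurs across rosters and every roster has exactly 3 CVs. Replicas
#' 4-7 additionally carry MultiThermal biases with `Tmax_list` (default
#' 310, 330, 350, 370 K) above the 298 K thermostat floor.
#'
#' @param aux_cv_order 7 hydration-CV labels
#' @param torsions 0-3 torsion CV labels
#' @param Tmax_list 4 MultiThermal maximum temperatures, K
#' @param main_cvs main OPES Explore CV labels
#' @param exchange_stride,steps,seed,thermostat_T see [ladder_config()]
#' @return a [ladder_config()] with 8 replicas
#' @export
build_default_ladder <- function(aux_cv_order = c("WL4", "WH1", "WL1", "WH3",
                                                  "WH8", "WH5", "WH10"),
                                 torsions = character(0),
                                 Tmax_list = c(310, 330, 350, 370),
                                 main_cvs = c("z", "COS"),
                                 exchange_stride = 1000L, steps = 0L,
                                 seed = 1L, thermostat_T = 298) {
  stopifnot(length(aux_cv_order) == 7, length(Tmax_list) == 4)
  nt <- length(torsions)
  if (nt > 3) stop("unsupported configuration: more than 3 torsion CVs")
  roster <- function(j) {
    hyd <- aux_cv_order[j]
    if (nt <= 2) c(hyd, torsions)
    else c(hyd, torsions[(j %% 3) + 1], torsions[((j + 1) %% 3) + 1])
  }
  reps <- vector("list", 8)
  reps[[1]] <- replica_spec(0L, main_cvs = main_cvs)
  for (k in 1:7) {
    reps[[k + 1]] <- replica_spec(
      k, main_cvs = main_cvs,
      aux_rosters = lapply(seq_len(k), roster),
      multithermal_Tmax = if (k >= 4) Tmax_list[k - 3] else NULL)
  }
  ladder_config(reps, exchange_stride = exchange_stride, steps = steps,
                seed = seed, thermostat_T = thermostat_T)
}

#' Bias-roster matrix of a ladder
#'
#' Rows are bias slots (main, auxiliary 1..max, MultiThermal), columns are
#' replicas; cells hold comma-joined CV labels (or the MultiThermal Tmax),
#' empty where a replica does not carry the bias.
#'
#' @param ladder a [ladder_config()]
#' @return character matrix
#' @export
ladder_roster_matrix <- function(ladder) {
  nrep <- length(ladder$replicas)
  naux <- max(vapply(ladder$replicas, function(r) length(r$aux_rosters),
                     integer(1)))
  m <- matrix("", nrow = naux + 2, ncol = nrep,
              dimnames = list(c("OPES Explore",
                                if (naux > 0) paste("OPES MultiCV", seq_len(naux)),
                                "OPES MultiT"),
                              paste0("replica", seq_len(nrep) - 1L)))
  for (r in ladder$replicas) {
    j <- r$index + 1L
    m[1, j] <- paste(r$main_cvs, collapse = ",")
    for (i in seq_along(r$aux_rosters))
      m[1 + i, j] <- paste(r$aux_rosters[[i]], collapse = ",")
    if (!is.null(r$multithermal_Tmax))
      m[naux + 2, j] <- sprintf("%g K", r$multithermal_Tmax)
  }
  m
}

#' Metropolis exchange attempt between two replicas
#'
#' Standard Hamiltonian-replica-exchange rule at the common thermostat
#' temperature: with V_r the full bias stack of replica r, the configuration
#' swap i <-> j is accepted with probability
#' `min(1, exp(beta * ((V_i(x_i) + V_j(x_j)) - (V_i(x_j) + V_j(x_i))))`.
#' Configurations swap; bias states never do. Uses R's RNG stream.
#'
#' @param i,j replica indices (0-based, adjacent in the ladder)
#' @param states per-replica runtime states: each a list with `x`
#'   (coordinates), `spec` (a [replica_spec()]) and `bias` (states consumed
#'   by [total_bias()])
#' @param evaluator function(x) -> list(cv = named CV values, U = potential
#'   energy)
#' @param T temperature, K
#' @return list(accepted = logical, states = possibly swapped states)
#' @export
attempt_exchange <- function(i, j, states, evaluator, T = 298) {
  if (abs(i - j) != 1L) stop("exchange attempts are between ladder neighbors")
  si <- states[[i + 1L]]; sj <- states[[j + 1L]]
  ei <- evaluator(si$x); ej <- evaluator(sj$x)
  Vii <- total_bias(si$spec, si$bias, ei$cv, ei$U)
  Vjj <- total_bias(sj$spec, sj$bias, ej$cv, ej$U)
  Vij <- total_bias(si$spec, si$bias, ej$cv, ej$U)  # bias i on config j
  Vji <- total_bias(sj$spec, sj$bias, ei$cv, ei$U)
  delta <- ((Vii + Vjj) - (Vij + Vji)) / kBT(T)
  accepted <- log(runif(1)) < delta
  if (accepted) {
    swp <- si$x; si$x <- sj$x; sj$x <- swp
    swp <- si$noise_prev; si$noise_prev <- sj$noise_prev; sj$noise_prev <- swp
    states[[i + 1L]] <- si; states[[j + 1L]] <- sj
  }
  list(accepted = accepted, states = states)
}

#' Run OneOPES on a toy system
#'
#' Advances every replica with overdamped Langevin dynamics under its total
#' bias, deposits kernels at each bias's PACE, refreshes MultiThermal
#' estimators, and attempts neighbor exchanges (alternating even/odd pairs)
#' every `ladder$exchange_stride` steps. Replicas run sequentially at desk
#' scale; the whole run is reproducible from `ladder$seed`.
#'
#' CV labels are resolved on the toy system through `cv_map`, a named integer
#' vector mapping each label to a coordinate index (a point guest on the
#' canonical funnel makes "z" coordinate 3 and the solvent-occupancy CV "q"
#' coordinate 4). Resolution failures abort before any dynamics.
#'
#' The BARRIER/PACE defaults here are the desk-scale presets; the real
#' protocol values (BARRIER 100/3 kJ/mol, PACE 10000/20000/100, exchange
#' stride 1000) live in [protocol_config()] and scale PACE down with run
#' length as documented in the vignette.
#'
#' @param system a [toy_system()]
#' @param ladder a [ladder_config()]
#' @param cv_map named integer vector: CV label -> coordinate index
#' @param x0 initial coordinates (single vector shared by all replicas, or a
#'   list of per-replica vectors)
#' @param dt,friction integrator parameters ([langevin_step()])
#' @param main_barrier,main_pace main OPES Explore BARRIER (kJ/mol) and PACE
#' @param aux_barrier,aux_pace auxiliary multi-CV BARRIER and PACE
#' @param mt_pace,n_temps MultiThermal refresh stride and temperature-grid
#'   size
#' @param sigma named per-CV kernel widths; NULL estimates them from a short
#'   unbiased run of `sigma_steps` steps (the protocol's procedure)
#' @param merge_threshold kernel-compression threshold passed to
#'   [opes_explore_new()] (NULL = exact KDE)
#' @param sigma_steps length of the sigma-estimation run
#' @param record_stride thinning stride of the output time series
#' @return list of per-replica [colvar_trajectory()] objects, with the
#'   runtime states attached as attribute `"runtime"`
#' @export
run_oneopes <- function(system, ladder, cv_map, x0,
                        dt = 1e-3, friction = 1,
                        main_barrier = 50, main_pace = 500L,
                        aux_barrier = 3, aux_pace = 1000L,
                        mt_pace = 100L, n_temps = 8L,
                        sigma = NULL, sigma_steps = 2000L,
                        record_stride = 10L, merge_threshold = 1) {
  stopifnot(inherits(system, "toy_system"), inherits(ladder, "ladder_config"))
  T <- ladder$thermostat_T
  kT <- kBT(T)
  d <- system$dim
  labels_used <- unique(unlist(c(lapply(ladder$replicas, function(r)
    c(r$main_cvs, unlist(r$aux_rosters))))))
  missing_lab <- setdiff(labels_used, names(cv_map))
  if (length(missing_lab))
    stop("cannot resolve CV label(s) on this system: ",
         paste(missing_lab, collapse = ", "))
  if (any(cv_map > d)) stop("cv_map points beyond the system dimensionality")

  set.seed(ladder$seed)
  nrep <- length(ladder$replicas)

  if (is.null(sigma)) {
    pre <- run_langevin(system, if (is.list(x0)) x0[[1]] else x0,
                        nsteps = sigma_steps, dt = dt, T = T,
                        friction = friction, record_stride = 1L)
    sigma <- vapply(names(cv_map),
                    function(l) sd(pre$coords[, cv_map[[l]]]), numeric(1))
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("invalid kernel width sigma (constant CV in the unbiased run?)")

  states <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    spec <- ladder$replicas[[r]]
    x <- if (is.list(x0)) as.numeric(x0[[r]]) else as.numeric(x0)
    stopifnot(length(x) == d)
    main <- opes_explore_new(sigma[spec$main_cvs], barrier = main_barrier,
                             T = T, pace = main_pace, labels = spec$main_cvs,
                             merge_threshold = merge_threshold)
    aux <- lapply(spec$aux_rosters, function(ro)
      opes_explore_new(sigma[ro], barrier = aux_barrier, T = T,
                       pace = aux_pace, labels = ro,
                       merge_threshold = merge_threshold))
    mt <- if (!is.null(spec$multithermal_Tmax))
      opes_multithermal_new(T_min = T, T_max = spec$multithermal_Tmax,
                            n_temps = n_temps, pace = mt_pace)
    states[[r]] <- list(spec = spec, x = x, noise_prev = rnorm(d),
                        bias = list(main = main, aux = aux, mt = mt),
                        rec = list(), rec_steps = list())
  }

  evaluator <- function(x) {
    list(cv = setNames(x[cv_map], names(cv_map)), U = system$energy(x))
  }

  strides <- c(main_pace, aux_pace, ladder$exchange_stride)
  if (any(vapply(ladder$replicas,
                 function(r) !is.null(r$multithermal_Tmax), logical(1))))
    strides <- c(strides, mt_pace)
  seg_len <- Reduce(gcd2, strides)
  total <- ladder$steps
  global <- 0L
  n_exch_attempt <- 0L; n_exch_accept <- 0L

  while (global < total) {
    seg <- min(seg_len, total - global)
    for (r in seq_len(nrep)) {
      st <- states[[r]]
      engine_biases <- c(
        list(explore_to_engine(st$bias$main, cv_map[st$spec$main_cvs])),
        lapply(st$bias$aux, function(b) explore_to_engine(b, cv_map[b$labels])))
      engine_mt <- if (!is.null(st$bias$mt)) mt_to_engine(st$bias$mt)
      out <- engine_run_segment(st$x, as.integer(seg), dt, kT, friction,
                                system$potential$pot_id,
                                system$potential$pot_par, system$wall,
                                engine_biases, engine_mt,
                                as.integer(record_stride),
                                as.integer(global %% record_stride),
                                st$noise_prev)
      st$x <- out$x
      st$noise_prev <- out$noise_prev
      if (out$nrec > 0) {
        rows <- seq_len(out$nrec)
        st$rec[[length(st$rec) + 1L]] <- out$records[rows, , drop = FALSE]
        st$rec_steps[[length(st$rec_steps) + 1L]] <-
          out$rec_step[rows] + global
        if (!is.null(st$bias$mt)) {
          U <- out$records[rows, d + 1]
          Vt <- out$records[rows, d + 2]
          st$bias$mt <- opes_multithermal_update(st$bias$mt, U,
                                                 step = global + seg,
                                                 logw = Vt / kT)
        }
      }
      states[[r]] <- st
    }
    global <- global + seg

    for (r in seq_len(nrep)) {  # kernel deposits at PACE boundaries
      st <- states[[r]]
      if (global %% main_pace == 0L) {
        s_now <- st$x[cv_map[st$spec$main_cvs]]
        st$bias$main <- opes_explore_deposit(st$bias$main, s_now)
      }
      if (length(st$bias$aux) && global %% aux_pace == 0L) {
        for (a in seq_along(st$bias$aux)) {
          ro <- st$spec$aux_rosters[[a]]
          st$bias$aux[[a]] <-
            opes_explore_deposit(st$bias$aux[[a]], st$x[cv_map[ro]])
        }
      }
      states[[r]] <- st
    }

    if (nrep > 1 && global %% ladder$exchange_stride == 0L && global < total) {
      sweep_id <- global %/% ladder$exchange_stride
      first <- if (sweep_id %% 2L == 1L) 0L else 1L
      ii <- seq.int(first, nrep - 2L, by = 2L)
      for (i in ii) {
        res <- attempt_exchange(i, i + 1L, states, evaluator, T = T)
        states <- res$states
        n_exch_attempt <- n_exch_attempt + 1L
        n_exch_accept <- n_exch_accept + res$accepted
      }
    }
  }

  trajs <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    st <- states[[r]]
    if (length(st$rec)) {
      recs <- do.call(rbind, st$rec)
      steps <- unlist(st$rec_steps)
    } else {
      nb <- 1L + length(st$bias$aux)
      recs <- matrix(numeric(0), 0, d + 2L + nb +
                       as.integer(!is.null(st$bias$mt)))
      steps <- integer(0)
    }
    nb <- 1L + length(st$bias$aux)
    df <- data.frame(time = steps * dt)
    for (l in names(cv_map)) df[[l]] <- recs[, cv_map[[l]]][seq_len(nrow(recs))]
    df[["ene"]] <- recs[, d + 1][seq_len(nrow(recs))]
    df[["opes.bias"]] <- recs[, d + 3][seq_len(nrow(recs))]
    if (length(st$bias$aux))
      for (a in seq_along(st$bias$aux))
        df[[paste0("aux", a, ".bias")]] <- recs[, d + 3 + a][seq_len(nrow(recs))]
    if (!is.null(st$bias$mt))
      df[["mt.bias"]] <- recs[, d + 3 + nb][seq_len(nrow(recs))]
    df[["bias"]] <- recs[, d + 2][seq_len(nrow(recs))]
    trajs[[r]] <- colvar_trajectory(df, metadata = list(
      replica = st$spec$index, thermostat_T = T, dt = dt,
      record_stride = record_stride, seed = ladder$seed,
      descriptor = system$potential$descriptor))
  }
  attr(trajs, "runtime") <- states
  attr(trajs, "exchange") <- c(attempted = n_exch_attempt,
                               accepted = n_exch_accept)
  trajs
}

gcd2 <- function(a, b) if (b == 0) a else Recall(b, a %% b)
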