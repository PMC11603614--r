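# Bias engines. OPES Explore iteratively builds
#   V(s) = (gamma - 1) kB T ln( p_tg(s)/Z + eps )
# where p_tg is the on-the-fly kernel-density estimate of the sampled
# target (well-tempered) distribution, gamma = dE/(kB T) the bias factor and
# eps the regularizer that caps the bias range at the BARRIER dE. (With the
# KDE estimating the broadened target p_tg = P^(1/gamma), the exponent that
# turns it into the bias is gamma - 1; the familiar 1 - 1/gamma prefactor
# belongs to the original variant whose KDE estimates the unbiased P.) The
# normalization Z is maintained as the running supremum of the kernel density
# over deposited centers, with the density ratio clamped to [0, 1]; together
# with eps = 1/expm1(dE / ((1-1/gamma) kB T)) this makes
#   max V - min V <= dE
# an exact algebraic guarantee rather than an asymptotic one (bias gauge:
# V in [-dE, 0], so untouched regions sit at the eps floor -dE).

#' Create an OPES Explore bias state
#'
#' @param sigma per-CV kernel width(s); in the protocol these come from the
#'   CV standard deviations of a short unbiased run
#' @param barrier BARRIER dE in kJ/mol: cap on the bias range (0 disables the
#'   bias, giving the unbiased limit)
#' @param T temperature in K (the thermostat temperature)
#' @param gamma bias factor; default dE/(kB*T) as the protocol defines it
#'   (must exceed 1)
#' @param pace deposition stride in integration steps
#' @param period per-CV period for wrapped (minimum-image) kernels; 0 means
#'   aperiodic, torsions use 2*pi
#' @param labels CV labels (length gives the CV-space dimension)
#' @param merge_threshold on-the-fly kernel compression: a new kernel landing
#'   within this many sigmas (scaled Euclidean distance) of an existing
#'   center is merged into it (weight + 1, weight-averaged center) instead of
#'   appended. NULL keeps the exact KDE (every deposit its own kernel);
#'   long runs use a threshold (1 is a good default) to keep the kernel list
#'   compact, exactly as production OPES codes compress their kernels
#' @return object of class `opes_explore`
#' @export
opes_explore_new <- function(sigma, barrier, T = 298, gamma = NULL,
                             pace = 500L, period = NULL,
                             labels = paste0("cv", seq_along(sigma)),
                             merge_threshold = NULL) {
  k <- length(sigma)
  stopifnot(k >= 1, all(sigma > 0), barrier >= 0, pace >= 1)
  if (is.null(period)) period <- rep(0, k)
  stopifnot(length(period) == k)
  kT <- kBT(T)
  if (barrier == 0) {
    gamma <- Inf; pref <- 0; eps <- 1
  } else {
    if (is.null(gamma)) gamma <- barrier / kT
    if (gamma <= 1)
      stop("bias factor gamma must exceed 1 (BARRIER must exceed kB*T ",
           "under the default gamma = BARRIER/(kB*T))")
    pref <- (gamma - 1) * kT
    eps <- 1 / expm1(barrier / pref)
  }
  structure(list(labels = labels, k = k, sigma = as.numeric(sigma),
                 period = as.numeric(period), barrier = barrier,
                 gamma = gamma, T = T, kT = kT, pref = pref, eps = eps,
                 pace = as.integer(pace),
                 centers = matrix(numeric(0), 0, k),
                 weights = numeric(0),
                 dens_at_centers = numeric(0), Z = 0,
                 deposit_count = 0L,
                 merge_threshold = merge_threshold),
            class = "opes_explore")
}

#' @export
print.opes_explore <- function(x, ...) {
  cat(sprintf("<opes_explore> %d CV(s) [%s], BARRIER %g kJ/mol, gamma %.3g, pace %d, %d kernels\n",
              x$k, paste(x$labels, collapse = ","), x$barrier, x$gamma,
              x$pace, x$deposit_count))
  invisible(x)
}

#' Deposit a Gaussian kernel
#'
#' Call at every step; a kernel is appended only when `step %% pace == 0`.
#' Appends a unit-weight Gaussian at the current CV point and refreshes the
#' sup-normalization Z (the maximum kernel-density value over all deposited
#' centers). Deterministic.
#'
#' @param state an [opes_explore_new()] state
#' @param s_now CV-space point (length k)
#' @param step integer step count; `NULL` forces a deposit
#' @return the updated state
#' @export
opes_explore_deposit <- function(state, s_now, step = NULL) {
  if (!is.null(step) && (step %% state$pace) != 0L) return(state)
  s_now <- as.numeric(s_now)
  stopifnot(length(s_now) == state$k)
  if (!all(is.finite(s_now)))
    stop(sprintf("non-finite CV value at step %s",
                 if (is.null(step)) "<forced>" else step))
  K <- nrow(state$centers)
  merged <- FALSE
  if (!is.null(state$merge_threshold) && K > 0) {
    dz <- sweep(state$centers, 2, s_now)
    for (j in seq_along(state$period)) {
      if (state$period[j] > 0)
        dz[, j] <- dz[, j] -
          state$period[j] * floor(dz[, j] / state$period[j] + 0.5)
    }
    d2 <- rowSums(sweep(dz, 2, state$sigma, `/`)^2)
    i <- which.min(d2)
    if (d2[i] <= state$merge_threshold^2) {
      w <- state$weights[i]
      state$centers[i, ] <- (w * state$centers[i, ] + s_now) / (w + 1)
      state$weights[i] <- w + 1
      merged <- TRUE
    }
  }
  if (merged) {
    # centers moved: refresh all center densities (kernel list is compact
    # whenever merging is on, so the O(K^2) refresh stays cheap)
    state$dens_at_centers <- as.numeric(
      engine_kernel_sum(state$centers, state$centers, state$weights,
                        state$sigma, state$period))
  } else {
    if (K > 0) {
      g_new <- kernel_gauss(state$centers, s_now, state$sigma, state$period)
      state$dens_at_centers <- state$dens_at_centers + g_new
      dens_new <- sum(g_new) + 1
    } else {
      dens_new <- 1
    }
    state$centers <- rbind(state$centers, s_now)
    dimnames(state$centers) <- NULL
    state$weights <- c(state$weights, 1)
    state$dens_at_centers <- c(state$dens_at_centers, dens_new)
  }
  state$Z <- max(state$dens_at_centers)
  state$deposit_count <- state$deposit_count + 1L
  state
}

# unnormalized Gaussian kernel values of point s at each row of centers
kernel_gauss <- function(centers, s, sigma, period) {
  dz <- sweep(centers, 2, s)
  for (j in seq_along(period)) {
    if (period[j] > 0)
      dz[, j] <- dz[, j] - period[j] * floor(dz[, j] / period[j] + 0.5)
  }
  exp(-rowSums(sweep(dz^2, 2, 2 * sigma^2, `/`)))
}

#' Evaluate the OPES Explore bias
#'
#' Before the first deposit the bias is identically zero. Afterwards
#' `V(s) = pref * (log(min(1, p(s)/Z) + eps) - log1p(eps))`, bounded in
#' `[-BARRIER, 0]`.
#'
#' @param state an [opes_explore_new()] state
#' @param s CV point (length k) or an n x k matrix of points
#' @return bias energies in kJ/mol
#' @export
opes_explore_bias <- function(state, s) {
  S <- if (is.matrix(s)) s else matrix(s, ncol = state$k)
  if (state$deposit_count == 0L || state$pref == 0) return(numeric(nrow(S)))
  dens <- engine_kernel_sum(S, state$centers, state$weights,
                            state$sigma, state$period)
  ratio <- pmin(dens / state$Z, 1)
  state$pref * (log(ratio + state$eps) - log1p(state$eps))
}

# engine-facing compact description of an explore bias
explore_to_engine <- function(state, cv_idx) {
  list(cv = as.integer(cv_idx - 1L), centers = state$centers,
       weights = state$weights, sigma = state$sigma, period = state$period,
       pref = state$pref, eps = state$eps, M = state$Z)
}

#' Create an OPES MultiThermal bias state
#'
#' Expanded-temperature-ensemble bias on the potential energy U. The target is
#' the uniform mixture of canonical ensembles on a temperature grid between
#' `T_min` (the thermostat) and `T_max`, realized by the bias
#' \deqn{V(U) = -k_B T_{min} \ln \frac{1}{N_T} \sum_\lambda
#'       e^{-(\beta_\lambda - \beta_{min}) U - c_\lambda}}
#' with per-rung constants \eqn{c_\lambda = \ln\langle
#' e^{-(\beta_\lambda-\beta_{min}) U}\rangle_{T_{min}}}
#' (gauge \eqn{c_{min} = 0}) estimated on the fly from reweighted energy
#' statistics via a running log-sum-exp. The grid is geometric with
#' `n_temps` rungs.
#'
#' @param T_min thermostat temperature, K
#' @param T_max highest sampled temperature, K (equal to `T_min` disables)
#' @param n_temps temperature-grid size
#' @param pace refresh stride in integration steps
#' @return object of class `opes_multithermal`
#' @export
opes_multithermal_new <- function(T_min = 298, T_max, n_temps = 8L,
                                  pace = 100L) {
  stopifnot(T_max >= T_min, n_temps >= 1, pace >= 1)
  temps <- if (T_max == T_min) rep(T_min, n_temps)
           else exp(seq(log(T_min), log(T_max), length.out = n_temps))
  beta <- 1 / (kB_kj * temps)
  structure(list(T_min = T_min, T_max = T_max, n_temps = as.integer(n_temps),
                 temps = temps, beta = beta, dbeta = beta - beta[1],
                 kT0 = kBT(T_min), pace = as.integer(pace),
                 clam = numeric(n_temps),
                 lse_num = rep(-Inf, n_temps), lse_den = -Inf,
                 n_samples = 0L, sumU = 0, sumU2 = 0,
                 active = FALSE, degenerate_warned = FALSE),
            class = "opes_multithermal")
}

logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Feed energies to the MultiThermal estimator and refresh the bias
#'
#' Accumulates (optionally reweighted) potential-energy samples into running
#' log-sum-exp statistics; when `step %% pace == 0` (or `step` is `NULL`) the
#' per-rung constants are refreshed from them. With `T_max == T_min`, or a
#' degenerate (constant) energy record, the bias stays zero (a warning is
#' given once in the degenerate case).
#'
#' @param state an [opes_multithermal_new()] state
#' @param U_now potential energy sample(s), kJ/mol
#' @param step integer step, `NULL` forces a refresh
#' @param logw log-weights of the samples relative to the unbiased `T_min`
#'   ensemble (e.g. `+beta*V_total` from a biased run); recycled
#' @return the updated state
#' @export
opes_multithermal_update <- function(state, U_now, step = NULL, logw = 0) {
  U_now <- as.numeric(U_now)
  if (length(U_now)) {
    logw <- rep_len(as.numeric(logw), length(U_now))
    for (l in seq_len(state$n_temps)) {
      a <- logw - state$dbeta[l] * U_now
      state$lse_num[l] <- logaddexp(state$lse_num[l], lse_vec(a))
    }
    state$lse_den <- logaddexp(state$lse_den, lse_vec(logw))
    state$n_samples <- state$n_samples + length(U_now)
    state$sumU <- state$sumU + sum(U_now)
    state$sumU2 <- state$sumU2 + sum(U_now^2)
  }
  if (!is.null(step) && (step %% state$pace) != 0L) return(state)
  if (state$T_max == state$T_min || state$n_samples < 2L) return(state)
  varU <- state$sumU2 / state$n_samples -
    (state$sumU / state$n_samples)^2
  if (varU <= 1e-12) {
    if (!state$degenerate_warned) {
      warning("constant potential energy record: MultiThermal bias stays 0")
      state$degenerate_warned <- TRUE
    }
    state$active <- FALSE
    return(state)
  }
  state$clam <- state$lse_num - state$lse_den
  state$clam <- state$clam - state$clam[1]  # gauge: c at T_min is exactly 0
  state$active <- TRUE
  state
}

lse_vec <- function(a) {
  m <- max(a)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(a - m)))
}

#' Per-rung free-energy offsets of the MultiThermal estimator
#'
#' \eqn{\Delta F_\lambda = -c_\lambda / \beta_\lambda} with the gauge
#' \eqn{\Delta F = 0} at `T_min`.
#'
#' @param state an [opes_multithermal_new()] state
#' @return numeric vector, kJ/mol
#' @export
opes_multithermal_deltaF <- function(state) {
  -state$clam / state$beta
}

#' Evaluate the MultiThermal bias at potential energy U
#'
#' @param state an [opes_multithermal_new()] state
#' @param U energies, kJ/mol (vectorized)
#' @return bias energies, kJ/mol
#' @export
opes_multithermal_bias <- function(state, U) {
  if (!state$active || state$T_max == state$T_min) return(numeric(length(U)) * 0)
  A <- outer(U, state$dbeta, function(u, db) -db * u)
  A <- sweep(A, 2, state$clam)
  m <- apply(A, 1, max)
  -state$kT0 * (m + log(rowMeans(exp(A - m))))
}

mt_to_engine <- function(state) {
  list(dbeta = state$dbeta, clam = state$clam, kT0 = state$kT0,
       active = isTRUE(state$active) && state$T_max > state$T_min)
}

#' Total bias of a replica
#'
#' Sums the replica's main OPES Explore bias, its auxiliary multi-CV biases
#' and its MultiThermal contribution. Replica 0 carries the main bias only.
#'
#' @param replica a [replica_spec()]
#' @param states list with `main` (an `opes_explore`), `aux` (list of
#'   `opes_explore`, one per roster) and `mt` (an `opes_multithermal` or NULL)
#' @param cv_values named numeric vector of CV values (names = CV labels)
#' @param U potential energy, kJ/mol
#' @return total bias energy in kJ/mol
#' @export
total_bias <- function(replica, states, cv_values, U) {
  if (length(states$aux) != length(replica$aux_rosters))
    stop("bias roster/state mismatch: replica declares ",
         length(replica$aux_rosters), " auxiliary biases, got ",
         length(states$aux), " states")
  v <- opes_explore_bias(states$main, cv_values[replica$main_cvs])
  for (i in seq_along(states$aux)) {
    roster <- replica$aux_rosters[[i]]
    if (!identical(states$aux[[i]]$labels, roster))
      stop("bias roster/state mismatch on auxiliary bias ", i)
    v <- v + opes_explore_bias(states$aux[[i]], cv_values[roster])
  }
  if (!is.null(states$mt)) {
    if (is.null(replica$multithermal_Tmax))
      stop("bias roster/state mismatch: replica has no MultiThermal slot")
    v <- v + opes_multithermal_bias(states$mt, U)
  } else if (!is.null(replica$multithermal_Tmax)) {
    stop("bias roster/state mismatch: missing MultiThermal state")
  }
  as.numeric(v)
}
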