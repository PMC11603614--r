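# Post-processing of replica-0 time series: reweighted free-energy profiles
# G(z) along the funnel axis and the funnel-corrected absolute binding free
# energy
#   dG_B = -kB T ln[ C0 pi Rcyl^2 sum_bound exp(-(G(z)-G_U)/(kB T)) dz ]
# where C0 = 1/1660 A^-3 is the standard concentration, Rcyl the funnel
# cylinder radius and G_U the unbound plateau reference. Errors come from
# contiguous block averages (or one block per independent run).

#' Free-energy profile along the funnel axis
#'
#' @param z_grid ordered bin centers, nm
#' @param G free energy per bin, kJ/mol (NA on unsampled bins)
#' @param G_U unbound-plateau reference value, kJ/mol
#' @param T temperature, K
#' @param funnel_side one of "above", "below", "single"
#' @param gauge either "min" (min over sampled bins shifted to 0) or "G_U"
#' @return object of class `free_energy_profile`
#' @export
free_energy_profile <- function(z_grid, G, G_U, T = 298,
                                funnel_side = "single", gauge = "min") {
  stopifnot(length(z_grid) == length(G), !is.unsorted(z_grid))
  funnel_side <- match.arg(funnel_side, c("above", "below", "single"))
  structure(list(z_grid = z_grid, G = G, G_U = G_U, T = T,
                 funnel_side = funnel_side, gauge = gauge),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("<free_energy_profile> %d bins on [%.3g, %.3g] nm, G_U = %.3g kJ/mol (%s side)\n",
              length(x$z_grid), min(x$z_grid), max(x$z_grid), x$G_U,
              x$funnel_side))
  invisible(x)
}

#' Binding free-energy estimate with block statistics
#'
#' @param value point estimate, kcal/mol (block mean)
#' @param per_block per-block estimates, kcal/mol
#' @param sides_used "both", "above_only" or "below_only"
#' @return object of class `binding_free_energy`; `$std` is the sample
#'   (n-1 denominator) standard deviation over blocks
#' @export
binding_free_energy_estimate <- function(value, per_block,
                                         sides_used = "both") {
  std <- if (length(per_block) >= 2) sd(per_block) else NA_real_
  structure(list(value = value, per_block = per_block, std = std,
                 sides_used = sides_used),
            class = "binding_free_energy")
}

#' @export
print.binding_free_energy <- function(x, ...) {
  cat(sprintf("dG_B = %.3f +/- %.3f kcal/mol  (blocks: %s; sides: %s)\n",
              x$value, x$std, paste(sprintf("%.3f", x$per_block),
                                    collapse = ", "), x$sides_used))
  invisible(x)
}

#' Reweighted free-energy profile over z
#'
#' Discards the leading `discard_fraction` of frames as equilibration (the
#' real-system protocol discards 50 ns for TEMOA and 100 ns for CB8), weights
#' each remaining frame by `exp(+V_total/(kB T))`, histograms z with the
#' given grid and sets `G = -kB T log(weighted histogram)`. `G_U` is the
#' weighted mean of G over the unbound plateau window.
#'
#' @param traj a [colvar_trajectory()] (replica 0)
#' @param z_label name of the z column
#' @param grid bin-center grid (uniform spacing), nm
#' @param T temperature, K
#' @param discard_fraction fraction of initial frames dropped, in [0, 1)
#' @param plateau_window `c(lo, hi)` z-window defining the unbound reference;
#'   default the outer 20% of the grid
#' @param bias_label column holding the total bias (V = 0 everywhere if the
#'   column is absent)
#' @param funnel_side recorded side tag, see [free_energy_profile()]
#' @return a [free_energy_profile()]
#' @export
reweighted_profile <- function(traj, z_label = "z", grid, T = 298,
                               discard_fraction = 0.2,
                               plateau_window = NULL,
                               bias_label = "bias",
                               funnel_side = "single") {
  stopifnot(discard_fraction >= 0, discard_fraction < 1)
  n <- nrow(traj)
  keep <- seq.int(floor(discard_fraction * n) + 1L, length.out = n -
                    floor(discard_fraction * n))
  if (n == 0 || length(keep) == 0) stop("no frames left after discard")
  z <- traj[[z_label]][keep]
  if (is.null(z)) stop("no such z column: ", z_label)
  V <- if (bias_label %in% names(traj)) traj[[bias_label]][keep] else 0 * z
  kT <- kBT(T)
  logw <- V / kT
  logw <- logw - max(logw)
  w <- exp(logw)
  dz <- diff(grid[1:2])
  edges <- c(grid - dz / 2, grid[length(grid)] + dz / 2)
  bin <- findInterval(z, edges, rightmost.closed = TRUE)
  inside <- bin >= 1 & bin <= length(grid)
  hist_w <- vapply(seq_along(grid),
                   function(b) sum(w[inside & bin == b]), numeric(1))
  G <- -kT * log(hist_w / sum(w) / dz)
  G[!is.finite(G)] <- NA_real_
  if (is.null(plateau_window)) {
    span <- range(grid)
    plateau_window <- c(span[2] - 0.2 * diff(span), span[2])
  }
  pl <- grid >= plateau_window[1] & grid <= plateau_window[2] & !is.na(G)
  if (!any(pl)) stop("empty unbound plateau window: no sampled bins in [",
                     plateau_window[1], ", ", plateau_window[2], "]")
  G_U <- mean(G[pl])
  shift <- min(G, na.rm = TRUE)
  free_energy_profile(grid, G - shift, G_U - shift, T = T,
                      funnel_side = funnel_side, gauge = "min")
}

#' Funnel-corrected absolute binding free energy
#'
#' Applies the standard-state funnel correction to a profile: the Boltzmann
#' integral of `G(z) - G_U` over the bound window times the entropic volume
#' factor `C0 pi Rcyl^2` of the unbound cylinder. Adding any constant to G
#' (and hence to G_U) leaves the result unchanged.
#'
#' @param profile a [free_energy_profile()]
#' @param bound_window `c(lo, hi)` z-interval of the bound basin, nm
#' @param geom a [funnel_geometry()] (supplies R_cyl)
#' @param C0 standard concentration, nm^-3 (default 1/1.660 = 1/1660 A^-3)
#' @return dG_B in kcal/mol (negative = favorable binding)
#' @export
binding_free_energy <- function(profile, bound_window, geom, C0 = C0_nm3) {
  stopifnot(inherits(profile, "free_energy_profile"))
  if (!is.finite(profile$G_U)) stop("profile has no valid unbound reference G_U")
  kT <- kBT(profile$T)
  z <- profile$z_grid
  dz <- diff(z[1:2])
  sel <- z >= bound_window[1] & z <= bound_window[2]
  if (!any(sel)) stop("bound window lies outside the profile grid")
  G <- profile$G[sel]
  if (all(is.na(G))) stop("bound window is unsampled")
  integ <- sum(exp(-(G[!is.na(G)] - profile$G_U) / kT)) * dz
  dG_kj <- -kT * log(C0 * pi * geom$cylinder_radius^2 * integ)
  kj_to_kcal(dG_kj)
}

#' Combine the two funnel-side estimates
#'
#' With both unbound sides well sampled, the per-block estimates of the two
#' sides are first averaged block-by-block and the block statistics are taken
#' on the averaged values. When one side is flagged as undersampled (the
#' guest barely visits it), the other side's estimate passes through and the
#' `sides_used` field records which.
#'
#' @param above,below [binding_free_energy_estimate()]s (or vectors of
#'   per-block values, kcal/mol) for the two unbound sides
#' @param sampling_ok logical 2-vector: is (above, below) well sampled?
#' @return a [binding_free_energy_estimate()]
#' @export
dual_funnel_combine <- function(above, below, sampling_ok = c(TRUE, TRUE)) {
  blocks <- function(x) if (inherits(x, "binding_free_energy")) x$per_block
                        else as.numeric(x)
  if (!any(sampling_ok)) stop("neither funnel side is sampled")
  if (all(sampling_ok)) {
    a <- blocks(above); b <- blocks(below)
    stopifnot(length(a) == length(b))
    per <- (a + b) / 2
    binding_free_energy_estimate(mean(per), per, sides_used = "both")
  } else if (sampling_ok[1]) {
    a <- blocks(above)
    binding_free_energy_estimate(mean(a), a, sides_used = "above_only")
  } else {
    b <- blocks(below)
    binding_free_energy_estimate(mean(b), b, sides_used = "below_only")
  }
}

#' Undersampling check for a funnel side
#'
#' A side counts as undersampled when fewer than `min_fraction` of the
#' post-discard frames fall in its unbound window.
#'
#' @param traj a [colvar_trajectory()]
#' @param z_label z column name
#' @param window `c(lo, hi)` unbound z-window of the side
#' @param discard_fraction equilibration fraction dropped first
#' @param min_fraction occupancy threshold (default 1%)
#' @return logical: TRUE when the side is adequately sampled
#' @export
funnel_side_sampled <- function(traj, z_label = "z", window,
                                discard_fraction = 0.2, min_fraction = 0.01) {
  n <- nrow(traj)
  keep <- seq.int(floor(discard_fraction * n) + 1L, n)
  z <- traj[[z_label]][keep]
  mean(z >= window[1] & z <= window[2]) >= min_fraction
}

#' Block-average binding free energy
#'
#' Splits the post-discard trajectory into `n_blocks` equal contiguous blocks
#' (default 3), applies the profile-to-dG estimator to each, and reports the
#' block mean and sample standard deviation. In triplicate-run mode pass a
#' list of trajectories: each independent run is one block.
#'
#' @param traj a [colvar_trajectory()], or a list of them (one per block)
#' @param estimator function(traj) -> dG in kcal/mol
#' @param n_blocks number of blocks (>= 2; ignored for a list input)
#' @param discard_fraction equilibration fraction dropped before blocking
#' @return a [binding_free_energy_estimate()]
#' @export
block_error <- function(traj, estimator, n_blocks = 3L,
                        discard_fraction = 0.2) {
  if (is.list(traj) && !is.data.frame(traj)) {
    per <- vapply(traj, estimator, numeric(1))
    return(binding_free_energy_estimate(mean(per), per,
                                        sides_used = "single"))
  }
  stopifnot(n_blocks >= 2)
  n <- nrow(traj)
  keep <- seq.int(floor(discard_fraction * n) + 1L, n)
  if (length(keep) < n_blocks) stop("fewer frames than blocks")
  cuts <- floor(seq(0, length(keep), length.out = n_blocks + 1))
  per <- vapply(seq_len(n_blocks), function(b) {
    idx <- keep[(cuts[b] + 1):cuts[b + 1]]
    sub <- traj[idx, , drop = FALSE]
    class(sub) <- class(traj)
    attr(sub, "metadata") <- attr(traj, "metadata")
    estimator(sub)
  }, numeric(1))
  binding_free_energy_estimate(mean(per), per, sides_used = "single")
}
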