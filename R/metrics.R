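# Experiment-vs-prediction scoreboard: Kendall tau-b, linear fit (R^2 and
# slope), MAE/ME/RMSE, and percentile-bootstrap confidence intervals that
# resample systems with replacement and (optionally) perturb predictions by
# their reported per-system uncertainties.

#' Affinity table
#'
#' @param system_ids unique labels
#' @param predicted predicted affinities, kcal/mol
#' @param experimental experimental affinities, kcal/mol
#' @param uncertainty per-system predicted uncertainty (1 sd), kcal/mol
#' @return object of class `affinity_table` (a data.frame)
#' @export
affinity_table <- function(system_ids, predicted, experimental,
                           uncertainty = rep(0, length(predicted))) {
  stopifnot(length(system_ids) == length(predicted),
            length(predicted) == length(experimental),
            length(uncertainty) == length(predicted))
  if (anyDuplicated(system_ids)) stop("duplicate system ids")
  structure(data.frame(id = as.character(system_ids), predicted = predicted,
                       uncertainty = uncertainty,
                       experimental = experimental,
                       stringsAsFactors = FALSE),
            class = c("affinity_table", "data.frame"))
}

#' Read an affinity table from CSV
#'
#' Columns: id, predicted, uncertainty, experimental (kcal/mol); a missing
#' uncertainty column is taken as zero.
#'
#' @param path CSV path
#' @return an [affinity_table()]
#' @export
read_affinity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "predicted", "experimental")
  if (!all(need %in% names(df)))
    stop("affinity CSV must have columns id, predicted, experimental")
  if (!"uncertainty" %in% names(df)) df$uncertainty <- 0
  affinity_table(df$id, df$predicted, df$experimental, df$uncertainty)
}

#' Kendall rank correlation (tau-b)
#'
#' Concordant-minus-discordant pair statistic with tie correction:
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))` over all pairs. Invariant
#' under strictly monotone transforms of either axis.
#'
#' @param x,y numeric vectors of equal length (n >= 2)
#' @return tau in [-1, 1]; `NA` when either vector is all-tied
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2)
  dx <- sign(outer(x, x, `-`))
  dy <- sign(outer(y, y, `-`))
  up <- upper.tri(dx)
  s <- sum(dx[up] * dy[up])
  n0 <- n * (n - 1) / 2
  n1 <- sum(dx[up] == 0)
  n2 <- sum(dy[up] == 0)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) return(NA_real_)
  s / den
}

#' Ordinary least squares of predicted on experimental
#'
#' Slope/intercept from the normal equations; `r_squared` is the squared
#' Pearson correlation. The axis convention (predicted regressed on
#' experimental) can be flipped with `predicted_on_experimental = FALSE`.
#'
#' @param pred,exp predicted and experimental values (n >= 3)
#' @param predicted_on_experimental axis convention switch
#' @return list(slope, intercept, r_squared); all `NA` under zero variance
#' @export
linear_fit_metrics <- function(pred, exp, predicted_on_experimental = TRUE) {
  stopifnot(length(pred) == length(exp), length(pred) >= 3)
  x <- if (predicted_on_experimental) exp else pred
  y <- if (predicted_on_experimental) pred else exp
  vx <- sum((x - mean(x))^2)
  vy <- sum((y - mean(y))^2)
  if (vx == 0 || vy == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_))
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / vx
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r_squared = sxy^2 / (vx * vy))
}

#' Error metrics
#'
#' ME = mean(pred - exp), MAE = mean |pred - exp|,
#' RMSE = sqrt(mean (pred - exp)^2).
#'
#' @param pred,exp predicted and experimental values (n >= 1)
#' @return list(mae, me, rmse)
#' @export
error_metrics <- function(pred, exp) {
  stopifnot(length(pred) == length(exp), length(pred) >= 1)
  d <- pred - exp
  list(mae = mean(abs(d)), me = mean(d), rmse = sqrt(mean(d^2)))
}

compute_all_metrics <- function(pred, exp, which = NULL) {
  out <- c(list(tau = kendall_tau(pred, exp)),
           linear_fit_metrics(pred, exp),
           error_metrics(pred, exp))
  if (!is.null(which)) out <- out[which]
  out
}

#' Bootstrap confidence intervals for the benchmark metrics
#'
#' Each iteration resamples the (predicted, experimental) pairs with
#' replacement and, when `noise = TRUE`, perturbs every resampled prediction
#' by Gaussian noise with its per-system uncertainty; percentile intervals at
#' the given confidence are reported. Iterations whose resample is degenerate
#' for a metric (e.g. a single repeated system) are excluded for that metric
#' and counted. Reproducible from `seed`.
#'
#' @param table an [affinity_table()]
#' @param n_iter bootstrap iterations (protocol default 100000; >= 1000
#'   recommended for reported CIs)
#' @param confidence interval mass (default 0.95)
#' @param seed RNG seed
#' @param noise inject per-system uncertainty noise (default TRUE)
#' @param metrics subset of c("tau","slope","intercept","r_squared","mae",
#'   "me","rmse") to bootstrap (all by default)
#' @return object of class `metrics_report`: point estimates, per-metric
#'   `ci` (low, high), excluded-iteration counts, `n_boot`, `seed`
#' @export
bootstrap_ci <- function(table, n_iter = 100000L, confidence = 0.95,
                         seed = 1L, noise = TRUE, metrics = NULL) {
  stopifnot(inherits(table, "data.frame"), n_iter >= 1)
  n <- nrow(table)
  if (n < 3) stop("need at least 3 systems")
  point <- compute_all_metrics(table$predicted, table$experimental, metrics)
  mnames <- names(point)
  set.seed(seed)
  draws <- matrix(NA_real_, n_iter, length(mnames),
                  dimnames = list(NULL, mnames))
  pred0 <- table$predicted; exp0 <- table$experimental
  unc0 <- table$uncertainty
  for (it in seq_len(n_iter)) {
    idx <- sample.int(n, n, replace = TRUE)
    p <- pred0[idx]
    if (noise) p <- p + rnorm(n, sd = unc0[idx])
    e <- exp0[idx]
    m <- compute_all_metrics(p, e, metrics)
    draws[it, ] <- unlist(m)[mnames]
  }
  alpha <- (1 - confidence) / 2
  ci <- t(apply(draws, 2, function(col)
    quantile(col, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)))
  colnames(ci) <- c("low", "high")
  excluded <- colSums(is.na(draws))
  structure(list(point = point, ci = ci, excluded = excluded,
                 n_boot = as.integer(n_iter), confidence = confidence,
                 seed = as.integer(seed), noise = noise),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics over bootstrap (%d iterations, %.0f%% CI):\n",
              x$n_boot, 100 * x$confidence))
  for (m in names(x$point)) {
    cat(sprintf("  %-10s %8.4f  [%8.4f, %8.4f]\n", m, x$point[[m]],
                x$ci[m, "low"], x$ci[m, "high"]))
  }
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report a `metrics_report`
#' @param path output path (NULL returns the JSON string)
#' @return path or JSON string
#' @export
write_metrics_json <- function(report, path = NULL) {
  obj <- list(point = report$point,
              ci = apply(report$ci, 1, as.list, simplify = FALSE),
              excluded = as.list(report$excluded),
              n_boot = report$n_boot, confidence = report$confidence,
              seed = report$seed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
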