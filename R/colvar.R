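# COLVAR-dialect tabular time series: "#! FIELDS time cv1 cv2 ..." header,
# whitespace-separated numeric rows. This is the lingua franca between the
# sampling engine(s) and the post-processing.

#' COLVAR trajectory container
#'
#' A data frame of time-stamped CV values and bias energies plus provenance
#' metadata. The first column must be `time`, strictly increasing; all
#' columns have equal length by construction.
#'
#' @param data data.frame whose first column is `time`
#' @param metadata named list of provenance (replica, ladder, units, ...)
#' @return object of class `colvar_trajectory` (also a data.frame)
#' @export
colvar_trajectory <- function(data, metadata = list()) {
  stopifnot(is.data.frame(data), ncol(data) >= 1,
            names(data)[1] == "time")
  if (nrow(data) > 1 && any(diff(data$time) <= 0))
    stop("time stamps must be strictly increasing")
  structure(data, metadata = metadata,
            class = c("colvar_trajectory", "data.frame"))
}

#' @export
print.colvar_trajectory <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("<colvar_trajectory> %d frames, fields: %s\n", nrow(x),
              paste(names(x), collapse = " ")))
  if (!is.null(md$replica)) cat("  replica:", md$replica, "\n")
  invisible(x)
}

#' Read a COLVAR-dialect file
#'
#' Requires a leading `#! FIELDS ...` header; columns are mapped by name.
#' Ragged rows abort with the offending line number; additional `#!` metadata
#' lines are skipped.
#'
#' @param path file path
#' @return a [colvar_trajectory()]
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#! FIELDS"))
    stop("not a COLVAR file: missing '#! FIELDS' header in ", path)
  fields <- strsplit(trimws(sub("^#! FIELDS", "", lines[1])), "\\s+")[[1]]
  body_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  n <- length(body_idx)
  mat <- matrix(NA_real_, n, length(fields))
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[body_idx[i]]), "\\s+")[[1]]
    if (length(tok) != length(fields))
      stop(sprintf("ragged COLVAR row at line %d of %s: %d tokens, %d fields",
                   body_idx[i], path, length(tok), length(fields)))
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v))
      stop(sprintf("non-numeric COLVAR entry at line %d of %s", body_idx[i],
                   path))
    mat[i, ] <- v
  }
  df <- as.data.frame(mat)
  names(df) <- fields
  colvar_trajectory(df, metadata = list(source = path))
}

#' Write a COLVAR-dialect file
#'
#' Deterministic formatting (17 significant digits, fixed column order from
#' the trajectory) so golden-file comparisons and byte-stable round trips
#' work: write -> read -> write reproduces identical bytes.
#'
#' @param traj a [colvar_trajectory()] (or plain data.frame led by `time`)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_colvar <- function(traj, path) {
  stopifnot(is.data.frame(traj))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(traj), collapse = " ")), con)
  if (nrow(traj) > 0) {
    cols <- lapply(traj, function(x) sprintf("%.17g", as.numeric(x)))
    writeLines(do.call(paste, cols), con)
  }
  invisible(path)
}

#' Kernel widths from an unbiased run
#'
#' Per-CV sample standard deviations of an unbiased trajectory, the
#' protocol's source for the SIGMA parameter. Periodic CVs use the circular
#' standard deviation `sqrt(-2 log R)` (R the mean resultant length), which
#' is immune to the wrap-around inflation of the naive estimate.
#'
#' @param traj a [colvar_trajectory()]
#' @param cv_labels columns to estimate
#' @param period named (or recycled) periods; 0/absent = aperiodic
#' @return named numeric vector of widths
#' @export
compute_sigma_from_unbiased <- function(traj, cv_labels,
                                        period = setNames(rep(0, length(cv_labels)),
                                                          cv_labels)) {
  bias_cols <- grep("bias", names(traj), value = TRUE)
  if (length(bias_cols)) {
    bmax <- max(vapply(bias_cols, function(cl) max(abs(traj[[cl]]), 0),
                       numeric(1)), 0)
    if (bmax > 1e-10)
      stop("trajectory carries non-zero bias energies: SIGMA must come from ",
           "an unbiased run")
  }
  out <- numeric(length(cv_labels))
  names(out) <- cv_labels
  for (l in cv_labels) {
    x <- traj[[l]]
    if (is.null(x)) stop("no such CV column: ", l)
    per <- if (l %in% names(period)) period[[l]] else 0
    if (per > 0) {
      th <- x * 2 * pi / per
      R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
      out[l] <- sqrt(-2 * log(R)) * per / (2 * pi)
    } else {
      out[l] <- sd(x)
    }
    if (!is.finite(out[l]) || out[l] <= 0)
      stop("CV '", l, "' is constant: kernel width would be degenerate")
  }
  out
}
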