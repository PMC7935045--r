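#' Expand confound regressors
#'
#' Augments each base confound column with its temporal derivative (backward
#' first difference, first frame zero-padded), its square, and the square of
#' the derivative, yielding 4x the base column count.
#'
#' @param confounds Numeric matrix or data.frame, timepoints x regressors.
#' @return Numeric matrix with `4 * ncol(confounds)` columns, named
#'   `<base>`, `<base>_dt`, `<base>_sq`, `<base>_dt_sq`.
#' @export
expand_confounds <- function(confounds) {
  C <- as.matrix(confounds)
  stop_if(ncol(C) < 1, "need at least one base regressor")
  check_finite(C, "confounds")
  d <- rbind(0, diff(C))
  nm <- colnames(C)
  if (is.null(nm)) nm <- paste0("c", seq_len(ncol(C)))
  out <- cbind(C, d, C^2, d^2)
  colnames(out) <- c(nm, paste0(nm, "_dt"), paste0(nm, "_sq"),
                     paste0(nm, "_dt_sq"))
  out
}

#' Regress confounds out of a node time series
#'
#' Least-squares projection of every node signal onto the orthogonal
#' complement of the confound design (an intercept is always included, so
#' residuals are demeaned). Linearly dependent design columns are dropped
#' with a message.
#'
#' @param ts A [node_timeseries()] or timepoints x nodes matrix.
#' @param design Confound design matrix (timepoints x regressors), e.g. from
#'   [expand_confounds()]; `NULL` or zero columns demeans only.
#' @return Same type as `ts`, residual signals.
#' @export
regress_confounds <- function(ts, design = NULL) {
  x <- if (inherits(ts, "node_timeseries")) ts$data else as.matrix(ts)
  n <- nrow(x)
  if (is.null(design) || NCOL(design) == 0L || length(design) == 0L) {
    X <- matrix(1, n, 1)
  } else {
    D <- as.matrix(design)
    stop_if(nrow(D) != n, "design rows must match time series rows")
    check_finite(D, "design")
    X <- cbind(1, D)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    message("dropping ", ncol(X) - qx$rank,
            " linearly dependent confound column(s)")
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  res <- qr.resid(qx, x)
  if (inherits(ts, "node_timeseries"))
    node_timeseries(res, ts$subject, ts$session, ts$run, ts$tr)
  else res
}

#' Zero-phase bandpass filter
#'
#' 4th-order Butterworth bandpass applied forward and backward
#' (`signal::filtfilt`), so the output is band-limited with zero phase
#' shift. The default 0.01-0.1 Hz band is the conventional resting-state
#' fluctuation band.
#'
#' @param ts A [node_timeseries()], or a matrix together with `tr`.
#' @param low,high Band edges in Hz; `high` must be below Nyquist
#'   `1 / (2 tr)`.
#' @param tr Repetition time in seconds (taken from `ts` when it is a
#'   `node_timeseries`).
#' @param order Filter order.
#' @return Same type as `ts`.
#' @export
bandpass <- function(ts, low = 0.01, high = 0.1, tr = NULL, order = 4) {
  x <- if (inherits(ts, "node_timeseries")) ts$data else as.matrix(ts)
  if (inherits(ts, "node_timeseries")) tr <- ts$tr
  stop_if(is.null(tr), "tr must be supplied for matrix input")
  nyquist <- 1 / (2 * tr)
  stop_if(low <= 0 || high <= low,
          "band edges must satisfy 0 < low < high")
  stop_if(high >= nyquist,
          sprintf("high edge %g Hz is not below the Nyquist frequency %g Hz",
                  high, nyquist))
  check_finite(x, "time series")
  bf <- signal::butter(order, c(low, high) / nyquist, type = "pass")
  # demean first: DC lies outside the passband anyway, and a nonzero mean
  # produces large start-up transients in the recursive filter
  out <- apply(x, 2, function(col) signal::filtfilt(bf, col - mean(col)))
  if (inherits(ts, "node_timeseries"))
    node_timeseries(out, ts$subject, ts$session, ts$run, ts$tr)
  else out
}

#' Concatenate runs into standardized session blocks
#'
#' Runs are concatenated within each subject-session (in run order), each
#' session block is standardized per node (mean 0, SD 1), and blocks are
#' stacked session-by-session across subjects (all subjects' session 1,
#' then session 2, ...), mirroring the session-grouped concatenation used
#' for group-level state inference.
#'
#' @param ts_list List of [node_timeseries()] objects.
#' @return An object of class `concat_timeseries`: `data` (rows x nodes
#'   matrix), `subject` and `session` (per-row identifiers), and `block`
#'   (per-row subject-session factor, contiguous).
#' @export
standardize_concat <- function(ts_list) {
  stopifnot(length(ts_list) > 0,
            all(vapply(ts_list, inherits, TRUE, "node_timeseries")))
  p <- ncol(ts_list[[1]]$data)
  stop_if(!all(vapply(ts_list, function(t) ncol(t$data), 1L) == p),
          "node columns must align across all runs")
  sub <- vapply(ts_list, function(t) t$subject, "")
  ses <- vapply(ts_list, function(t) t$session, 1L)
  run <- vapply(ts_list, function(t) t$run, 1L)
  ord <- order(ses, sub, run)
  key <- block_label(sub, ses)[ord]
  pieces <- list()
  ids <- list()
  for (b in unique(key)) {
    sel <- ord[key == b]
    block <- do.call(rbind, lapply(ts_list[sel], function(t) t$data))
    mu <- colMeans(block)
    sdv <- apply(block, 2, stats::sd)
    if (any(sdv == 0))
      stop("zero-variance node(s) in block ", b, ": ",
           paste(which(sdv == 0), collapse = ", "), call. = FALSE)
    pieces[[b]] <- sweep(sweep(block, 2, mu), 2, sdv, `/`)
    ids[[b]] <- data.frame(subject = ts_list[[sel[1]]]$subject,
                           session = ts_list[[sel[1]]]$session)[
                             rep(1, nrow(block)), ]
  }
  id <- do.call(rbind, ids)
  structure(list(
    data = do.call(rbind, pieces),
    subject = id$subject,
    session = id$session,
    block = as_blocks(block_label(id$subject, id$session), nrow(id),
                      contiguous = TRUE)
  ), class = "concat_timeseries")
}

#' @export
print.concat_timeseries <- function(x, ...) {
  cat(sprintf("concat_timeseries: %d rows x %d nodes, %d subject-session blocks\n",
              nrow(x$data), ncol(x$data), nlevels(x$block)))
  invisible(x)
}

#' Framewise displacement
#'
#' Scalar head-motion index per frame: the sum of absolute frame-to-frame
#' changes in the three translations (mm) plus `radius` times the sum of
#' absolute changes in the three rotations (radians), i.e. rotations are
#' converted to arc length on a sphere of the given radius. The first frame
#' is defined as 0.
#'
#' @param motion Timepoints x 6 matrix: 3 translations (mm) then 3
#'   rotations (radians).
#' @param radius Sphere radius in mm.
#' @return Numeric vector of per-frame FD values (mm).
#' @export
framewise_displacement <- function(motion, radius = 50) {
  m <- as.matrix(motion)
  stop_if(ncol(m) != 6,
          "motion table must have exactly 6 columns (3 translations, 3 rotations)")
  check_finite(m, "motion parameters")
  d <- abs(diff(m))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      radius * rowSums(d[, 4:6, drop = FALSE]))
}

#' Mean framewise displacement per subject-session
#'
#' Convenience QC summary: averages FD over all frames of all runs belonging
#' to each subject-session.
#'
#' @param motion_list List of motion matrices as from [generate_motion()].
#' @param radius Sphere radius in mm.
#' @return data.frame with `subject`, `session`, `mean_fd`.
#' @export
mean_fd_by_session <- function(motion_list, radius = 50) {
  sub <- vapply(motion_list, attr, "", "subject")
  ses <- vapply(motion_list, function(m) as.integer(attr(m, "session")), 1L)
  fd <- lapply(motion_list, framewise_displacement, radius = radius)
  key <- block_label(sub, ses)
  out <- lapply(unique(key), function(b) {
    i <- which(key == b)
    data.frame(subject = sub[i[1]], session = ses[i[1]],
               mean_fd = mean(unlist(fd[i])))
  })
  do.call(rbind, out)
}
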