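#' ROI time-series container
#'
#' @param data numeric matrix, volumes x ROIs; no missing values.
#' @param tr_seconds sampling interval (repetition time), seconds.
#' @param subject_id id string.
#' @return object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, tr_seconds, subject_id = "subject") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time series must be numeric")
  if (anyNA(data)) stop("time series contains missing values")
  stopifnot(tr_seconds > 0, nrow(data) >= 1, ncol(data) >= 1)
  structure(list(data = data, tr_seconds = tr_seconds,
                 subject_id = subject_id, R = ncol(data)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %s: %d volumes x %d ROIs, TR = %g s\n",
              x$subject_id, nrow(x$data), x$R, x$tr_seconds))
  invisible(x)
}

#' Sliding-window specification
#'
#' Defaults follow the protocol of a 48 s window with a 16 s stride and
#' exclusion of the first eight volumes.  Window and stride must convert to
#' whole numbers of volumes at the series' TR.
#'
#' @param window_seconds window length, seconds.
#' @param stride_seconds stride between window starts, seconds.
#' @param drop_initial_volumes leading volumes discarded before windowing.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(window_seconds = 48, stride_seconds = 16,
                        drop_initial_volumes = 8L) {
  stopifnot(window_seconds > 0, stride_seconds > 0, drop_initial_volumes >= 0)
  structure(list(window_seconds = window_seconds,
                 stride_seconds = stride_seconds,
                 drop_initial_volumes = as.integer(drop_initial_volumes)),
            class = "window_spec")
}

# Convert a duration to a whole number of volumes; error if not integral.
volumes_from_seconds <- function(seconds, tr) {
  v <- seconds / tr
  if (abs(v - round(v)) > 1e-8)
    stop(sprintf("%g s is not a whole number of volumes at TR = %g s", seconds, tr))
  as.integer(round(v))
}

#' Number of sliding windows
#'
#' `T = floor((n_volumes - w) / s) + 1` with `w`, `s` the window and stride
#' in volumes.  `n_volumes` is the retained series length (after any initial
#' volumes have been dropped); 480 volumes at TR 0.8 s with the default
#' 48 s / 16 s windows give T = 22.
#'
#' @param n_volumes retained volumes.
#' @param spec a [window_spec()].
#' @param tr sampling interval, seconds.
#' @return integer window count.
#' @export
count_windows <- function(n_volumes, spec = window_spec(), tr = 0.8) {
  w <- volumes_from_seconds(spec$window_seconds, tr)
  s <- volumes_from_seconds(spec$stride_seconds, tr)
  if (n_volumes < w)
    stop(sprintf("series of %d volumes is shorter than one %d-volume window",
                 n_volumes, w))
  as.integer((n_volumes - w) %/% s + 1L)
}

#' Split a time series into sliding-window segments
#'
#' Drops the initial volumes, then cuts segments
#' `[t * s, t * s + w)` (0-based, half-open, volumes) for `t = 0..T-1`.
#'
#' @param ts a [roi_timeseries()].
#' @param spec a [window_spec()].
#' @return list of T numeric matrices (w_vol x R).
#' @export
window_segments <- function(ts, spec = window_spec()) {
  stopifnot(inherits(ts, "roi_timeseries"))
  X <- ts$data
  if (spec$drop_initial_volumes > 0) {
    if (nrow(X) <= spec$drop_initial_volumes)
      stop("series shorter than drop_initial_volumes")
    X <- X[-seq_len(spec$drop_initial_volumes), , drop = FALSE]
  }
  w <- volumes_from_seconds(spec$window_seconds, ts$tr_seconds)
  s <- volumes_from_seconds(spec$stride_seconds, ts$tr_seconds)
  T_n <- count_windows(nrow(X), spec, ts$tr_seconds)
  lapply(seq_len(T_n) - 1L, function(t) {
    X[t * s + seq_len(w), , drop = FALSE]
  })
}

#' Windowed Pearson functional connectivity
#'
#' Pairwise Pearson correlations between ROI signals within one segment:
#' a symmetric matrix with unit diagonal and entries in [-1, 1].
#'
#' @param segment numeric matrix, volumes x R.
#' @param zero_variance policy for constant columns: `"error"` (default) or
#'   `"zero"` (set the offending rows/columns to 0 with a warning).
#' @return R x R correlation matrix.
#' @export
pearson_fc <- function(segment, zero_variance = c("error", "zero")) {
  zero_variance <- match.arg(zero_variance)
  v <- apply(segment, 2, stats::var)
  bad <- which(v == 0 | !is.finite(v))
  if (length(bad) > 0) {
    if (zero_variance == "error")
      stop(sprintf("zero-variance ROI column(s) in segment: %s",
                   paste(bad, collapse = ", ")))
    A <- suppressWarnings(stats::cor(segment))
    A[bad, ] <- 0; A[, bad] <- 0
    warning(sprintf("%d zero-variance ROI(s) set to 0 connectivity", length(bad)))
  } else {
    A <- stats::cor(segment)
  }
  diag(A) <- 1
  A[A > 1] <- 1; A[A < -1] <- -1
  A
}

#' Build a dynamic functional connectivity tensor
#'
#' Applies [window_segments()] and [pearson_fc()] to obtain the R x R x T
#' stack of windowed correlation matrices (the dFCN states A_t).
#'
#' @inheritParams window_segments
#' @param zero_variance passed to [pearson_fc()].
#' @return object of class `dfcn_tensor`: list with 3-d array `A`
#'   (R x R x T), `R`, `T`, `subject_id`, `spec`.
#' @export
build_dfcn <- function(ts, spec = window_spec(), zero_variance = "error") {
  segs <- window_segments(ts, spec)
  A <- vapply(segs, pearson_fc, zero_variance = zero_variance,
              FUN.VALUE = matrix(0, ts$R, ts$R))
  structure(list(A = A, R = ts$R, T = length(segs),
                 subject_id = ts$subject_id, spec = spec),
            class = "dfcn_tensor")
}

#' @export
print.dfcn_tensor <- function(x, ...) {
  cat(sprintf("<dfcn_tensor> %s: R = %d, T = %d\n", x$subject_id, x$R, x$T))
  invisible(x)
}
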