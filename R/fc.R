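#' Validate a functional-connectivity matrix
#'
#' An FC matrix is square, symmetric (within `tol`), has diagonal exactly 1
#' (correlation convention) and off-diagonal entries in `[-1, 1]`.
#'
#' @param fc matrix to validate.
#' @param tol symmetry tolerance (default 1e-10).
#' @return invisibly, `fc`; errors if any invariant fails.
#' @export
assert_fc <- function(fc, tol = 1e-10) {
  if (!is.matrix(fc) || !is.numeric(fc) || nrow(fc) != ncol(fc))
    stop("FC must be a square numeric matrix")
  if (any(!is.finite(fc)))
    stop("FC contains non-finite values")
  if (max(abs(fc - t(fc))) > tol)
    stop(sprintf("FC matrix is not symmetric within %g", tol))
  if (any(diag(fc) != 1))
    stop("FC diagonal must be exactly 1")
  off <- fc[upper.tri(fc)]
  if (length(off) && (min(off) < -1 || max(off) > 1))
    stop("off-diagonal FC values must lie in [-1, 1]")
  invisible(fc)
}

#' Pearson functional connectivity from ROI time series
#'
#' Computes the node-by-node Pearson correlation matrix of regional time
#' series: entry (i, j) is the correlation of series i and j over time.
#' The diagonal is forced to exactly 1 to absorb floating-point drift.
#'
#' @param ts numeric node-by-time matrix (rows = nodes/ROIs, columns =
#'   time points); at least 3 time points, every row with nonzero variance.
#' @return an FC matrix satisfying [assert_fc()].
#' @examples
#' ts <- matrix(rnorm(5 * 50), 5, 50)
#' fc <- fc_from_timeseries(ts)
#' @export
fc_from_timeseries <- function(ts) {
  if (!is.matrix(ts) || !is.numeric(ts))
    stop("ts must be a numeric node-by-time matrix")
  if (ncol(ts) < 3)
    stop("at least 3 time points are required")
  v <- apply(ts, 1, stats::var)
  bad <- which(v == 0 | !is.finite(v))
  if (length(bad))
    stop(sprintf("constant or non-finite time series at node(s): %s",
                 paste(bad - 1L, collapse = ", ")))
  fc <- stats::cor(t(ts))
  fc[fc > 1] <- 1
  fc[fc < -1] <- -1
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  fc
}
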