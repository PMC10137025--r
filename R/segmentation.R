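#' Euclidean distances between adjacent dFCS time slices
#'
#' Element `t` is the Euclidean distance between window columns `t` and
#' `t+1` of the dFCS matrix; large values mark transitions between
#' quasi-stable connectivity regimes.
#'
#' @param d an N x W `dfcs_matrix` (or plain matrix), W >= 2.
#' @return numeric vector of length W - 1.
#' @export
adjacent_distances <- function(d) {
  d <- unclass(d)
  W <- ncol(d)
  if (W < 2L)
    dfcp_error("need at least 2 windows for adjacent distances",
               "dfcp_validation_error")
  sqrt(colSums((d[, -1L, drop = FALSE] - d[, -W, drop = FALSE])^2))
}

#' Segment a dFCS matrix into quasi-stable spans
#'
#' Places a boundary after window `t` whenever the adjacent-slice
#' Euclidean distance exceeds `mean(dist) + alpha * sd(dist)`, then
#' merges any segment shorter than `min_segment_windows` into the
#' neighbouring segment whose shared-boundary distance is smaller (ties
#' merge left).  Spans are half-open 0-based `[start, end)` window
#' intervals partitioning `[0, W)`.
#'
#' Because the threshold is affine in the distance distribution,
#' segmentation is invariant to uniform rescaling of the dFCS matrix.
#' When all distances are equal (sd = 0) nothing exceeds the threshold
#' strictly and a single span is returned.
#'
#' @param d an N x W `dfcs_matrix`.
#' @param alpha nonnegative threshold multiplier (default 1).
#' @param min_segment_windows minimum windows per segment (default 2).
#' @return data.frame with 0-based columns `start`, `end` (half-open).
#' @export
segment_dfcs <- function(d, alpha = 1, min_segment_windows = 2L) {
  W <- ncol(d)
  if (alpha < 0)
    dfcp_error("alpha must be nonnegative", "dfcp_config_error")
  min_segment_windows <- max(1L, as.integer(min_segment_windows))
  if (W <= min_segment_windows || W < 2L)
    return(data.frame(start = 0L, end = W))
  dd <- adjacent_distances(d)
  thr <- mean(dd) + alpha * sd(dd)
  cuts <- which(dd > thr)            # boundary after window t (1-based t)
  bounds <- c(0L, cuts, W)           # span k = [bounds[k], bounds[k+1])

  # merge short segments into the neighbour with the weaker boundary
  repeat {
    len <- diff(bounds)
    short <- which(len < min_segment_windows)
    if (length(short) == 0L || length(bounds) == 2L) break
    k <- short[1L]
    left_b <- if (k > 1L) bounds[k] else NA_integer_
    right_b <- if (k < length(len)) bounds[k + 1L] else NA_integer_
    drop_b <- if (is.na(left_b)) right_b
              else if (is.na(right_b)) left_b
              else if (dd[left_b] <= dd[right_b]) left_b else right_b
    bounds <- bounds[bounds != drop_b]
  }
  data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
}

#' Whole-brain quasi-stable connectome patterns (WQCPs) from spans
#'
#' Each WQCP is the columnwise mean of the dFCS windows inside one
#' quasi-stable span, giving one length-N pattern vector per segment.
#'
#' @param d an N x W `dfcs_matrix`.
#' @param spans data.frame from [segment_dfcs()].
#' @return a `wqcp_set`: list with `values` (n_segments x N matrix, one
#'   WQCP per row), `spans`, and `subject_id`.
#' @export
wqcps_from_segments <- function(d, spans) {
  W <- ncol(d)
  if (nrow(spans) == 0L)
    dfcp_error("empty span list", "dfcp_internal_error")
  if (any(spans$end <= spans$start) || any(spans$start < 0L) ||
      any(spans$end > W))
    dfcp_error("invalid span for this dFCS matrix", "dfcp_internal_error")
  vals <- t(vapply(seq_len(nrow(spans)), function(k) {
    idx <- (spans$start[k] + 1L):spans$end[k]
    rowMeans(unclass(d)[, idx, drop = FALSE])
  }, numeric(nrow(d))))
  structure(list(values = vals, spans = spans,
                 subject_id = attr(d, "subject_id")),
            class = "wqcp_set")
}

#' Segment and extract WQCPs in one call
#'
#' @inheritParams segment_dfcs
#' @return a `wqcp_set` (see [wqcps_from_segments()]).
#' @export
extract_wqcps <- function(d, alpha = 1, min_segment_windows = 2L) {
  wqcps_from_segments(d, segment_dfcs(d, alpha, min_segment_windows))
}

#' @export
print.wqcp_set <- function(x, ...) {
  cat(sprintf("WQCP set: %d pattern(s) x %d ROIs (subject %s)\n",
              nrow(x$values), ncol(x$values), x$subject_id))
  invisible(x)
}
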