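#' Static functional connectivity matrix
#'
#' Pearson correlation between every pair of ROI time series over all
#' time points, with the diagonal set exactly to zero (self-connections
#' are not counted as connectivity).  An ROI whose series has zero
#' variance within the correlation span gets zero correlation to every
#' other ROI, with a warning, rather than propagating `NaN`.
#'
#' @param ts an [roi_ts()] object, or a plain T x N numeric matrix.
#' @return an N x N `fc_matrix` (symmetric, zero diagonal, entries in
#'   \[-1, 1\]) with attribute `kind = "static"`.
#' @export
static_fc <- function(ts) {
  m <- if (inherits(ts, "roi_ts")) ts$values else as.matrix(ts)
  if (nrow(m) < 3L)
    dfcp_error("need at least 3 time points for a correlation estimate",
               "dfcp_validation_error")
  .fc_from_block(m, warn_context = "static FC")
}

# correlation of a T x N block with zero-variance policy and zero diagonal
.fc_from_block <- function(m, warn_context = "windowed FC") {
  sds <- apply(m, 2L, sd)
  degenerate <- sds == 0 | !is.finite(sds)
  C <- suppressWarnings(cor(m))
  if (any(degenerate)) {
    dfcp_warn(sprintf(
      "%s: %d zero-variance ROI column(s); correlations set to 0",
      warn_context, sum(degenerate)), "dfcp_degenerate_warning")
    C[degenerate, ] <- 0
    C[, degenerate] <- 0
  }
  # guard against numerically |r| marginally above 1
  C[C > 1] <- 1
  C[C < -1] <- -1
  diag(C) <- 0
  structure(C, kind = "static", class = c("fc_matrix", "matrix", "array"))
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("%s FC matrix, %d x %d ROIs\n", attr(x, "kind"),
              nrow(x), ncol(x)))
  invisible(x)
}

#' Static connectivity strength per ROI
#'
#' Per-ROI sum of its correlations to all other ROIs.  The default mode
#' `"positive_sum"` adds only positive correlations (negative
#' connections are discarded as physiologically contentious);
#' `"absolute_sum"` adds absolute values.  The diagonal contributes 0.
#'
#' @param fc an N x N connectivity matrix (see [static_fc()]).
#' @param mode `"positive_sum"` (default) or `"absolute_sum"`.
#' @return numeric vector of length N with attribute `mode`; entries lie
#'   in \[0, N-1\].
#' @examples
#' fc <- matrix(0, 3, 3); fc[1,2] <- fc[2,1] <- 0.5
#' fc[1,3] <- fc[3,1] <- -0.2; fc[2,3] <- fc[3,2] <- 0.3
#' sfc_strength(fc)                   # 0.5 0.8 0.3
#' sfc_strength(fc, "absolute_sum")   # 0.7 0.8 0.5
#' @export
sfc_strength <- function(fc, mode = c("positive_sum", "absolute_sum")) {
  mode <- match.arg(mode)
  m <- unclass(fc)
  v <- if (mode == "positive_sum") rowSums(pmax(m, 0)) else rowSums(abs(m))
  structure(as.numeric(v), mode = mode)
}

#' Convert a window length in seconds to samples
#'
#' `round(window_seconds / tr_seconds)`, floored at 2 samples, so that
#' cohorts scanned with different repetition times share the same nominal
#' window duration.
#'
#' @param window_seconds window length in seconds (at least 2 TRs).
#' @param tr_seconds repetition time in seconds.
#' @return integer number of samples.
#' @export
window_samples <- function(window_seconds, tr_seconds) {
  if (window_seconds < 2 * tr_seconds)
    dfcp_error("window must span at least two repetition times",
               "dfcp_validation_error")
  max(2L, as.integer(round(window_seconds / tr_seconds)))
}

#' Sliding-window dynamic functional connectivity
#'
#' Pearson correlation computed on each sliding window of `w` samples,
#' advanced by `step` samples.  Window `t` (0-based) covers samples
#' `[t*step, t*step + w)`; there are `floor((T - w)/step) + 1` windows.
#'
#' @param ts an [roi_ts()] object or T x N matrix.
#' @param w window length in samples (2..T).
#' @param step step length in samples (default 1).
#' @return list of windowed `fc_matrix` objects.
#' @export
sliding_dfc <- function(ts, w, step = 1L) {
  m <- if (inherits(ts, "roi_ts")) ts$values else as.matrix(ts)
  Tn <- nrow(m)
  w <- as.integer(w); step <- as.integer(step)
  if (w < 2L || w > Tn)
    dfcp_error(sprintf("window length %d outside [2, T=%d]", w, Tn),
               "dfcp_config_error")
  if (step < 1L)
    dfcp_error("step must be >= 1", "dfcp_config_error")
  n_win <- (Tn - w) %/% step + 1L
  lapply(seq_len(n_win) - 1L, function(t) {
    C <- .fc_from_block(m[(t * step + 1L):(t * step + w), , drop = FALSE],
                        warn_context = sprintf("window %d", t))
    attr(C, "kind") <- "windowed"
    C
  })
}

#' Dynamic functional connectivity strength (dFCS) matrix
#'
#' Collapses a sequence of windowed connectivity matrices into an
#' N x W matrix whose entry (i, t) is the sum of absolute windowed
#' correlations of ROI i in window t (diagonal excluded).  Columns are
#' ordered by window index.
#'
#' @param windows list of N x N windowed connectivity matrices
#'   ([sliding_dfc()] output).
#' @param window_length_samples,step_samples,window_length_seconds,subject_id
#'   metadata stored as attributes on the result.
#' @return an N x W `dfcs_matrix` (entries in \[0, N-1\]).
#' @export
dfcs_matrix <- function(windows, window_length_samples = NA_integer_,
                        step_samples = 1L,
                        window_length_seconds = NA_real_,
                        subject_id = NA_character_) {
  if (length(windows) == 0L)
    dfcp_error("empty window sequence", "dfcp_shape_error")
  ns <- vapply(windows, nrow, integer(1))
  if (any(ns != ns[1L]))
    dfcp_error("inconsistent ROI count across windows", "dfcp_shape_error")
  d <- vapply(windows, function(C) rowSums(abs(unclass(C))),
              numeric(ns[1L]))
  d <- matrix(d, nrow = ns[1L])  # keep matrix shape when W == 1
  structure(d, class = c("dfcs_matrix", "matrix", "array"),
            window_length_samples = window_length_samples,
            step_samples = step_samples,
            window_length_seconds = window_length_seconds,
            subject_id = subject_id)
}

#' One-call dFCS matrix for a subject
#'
#' Convenience wrapper: converts the window length from seconds to
#' samples using the subject's TR, runs [sliding_dfc()] and
#' [dfcs_matrix()].
#'
#' @param ts an [roi_ts()] object.
#' @param window_seconds window length in seconds.
#' @param step step in samples (default 1).
#' @return an N x W `dfcs_matrix`.
#' @export
subject_dfcs <- function(ts, window_seconds, step = 1L) {
  w <- window_samples(window_seconds, ts$tr_seconds)
  if (w > nrow(ts$values))
    dfcp_error(sprintf(
      "window of %g s (%d samples) exceeds series length %d for subject %s",
      window_seconds, w, nrow(ts$values), ts$subject_id),
      "dfcp_config_error")
  dfcs_matrix(sliding_dfc(ts, w, step),
              window_length_samples = w, step_samples = as.integer(step),
              window_length_seconds = window_seconds,
              subject_id = ts$subject_id)
}

#' @export
print.dfcs_matrix <- function(x, ...) {
  cat(sprintf("dFCS matrix: %d ROIs x %d windows (w = %s samples, step %s)\n",
              nrow(x), ncol(x), attr(x, "window_length_samples"),
              attr(x, "step_samples")))
  invisible(x)
}
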