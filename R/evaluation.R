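#' Per-run metric values of a cross-validation result
#'
#' @param cv a `dfcp_cv` object (or its `runs` data.frame).
#' @return data.frame with one row per run and columns `accuracy`,
#'   `precision`, `recall`, `specificity`, `f1`.
#' @export
cv_metric_values <- function(cv) {
  runs <- if (inherits(cv, "dfcp_cv")) cv$runs else cv
  out <- t(apply(runs[, c("TP", "FP", "TN", "FN")], 1L,
                 function(r) classification_metrics(r)))
  as.data.frame(out)
}

#' Aggregate cross-validation runs into a summary row
#'
#' Per metric: mean, sample standard deviation and the 95% confidence
#' interval `mean +/- t(0.975, n-1) * sd / sqrt(n)`.  With a single run
#' the CI is undefined and reported as the mean.
#'
#' @param runs a `dfcp_cv` object, its `runs` data.frame, or a
#'   data.frame of per-run metric values.
#' @return data.frame with one row per metric: `mean`, `sd`,
#'   `ci_lower`, `ci_upper`, `n`.
#' @export
aggregate_metrics <- function(runs) {
  vals <- if (inherits(runs, "dfcp_cv") || "TP" %in% names(runs))
    cv_metric_values(runs) else runs
  n <- nrow(vals)
  out <- do.call(rbind, lapply(names(vals), function(m) {
    x <- vals[[m]]
    mu <- mean(x)
    if (n < 2L)
      return(data.frame(metric = m, mean = mu, sd = NA_real_,
                        ci_lower = mu, ci_upper = mu, n = n))
    s <- sd(x)
    half <- qt(0.975, n - 1L) * s / sqrt(n)
    data.frame(metric = m, mean = mu, sd = s,
               ci_lower = mu - half, ci_upper = mu + half, n = n)
  }))
  rownames(out) <- NULL
  out
}

#' @export
summary.dfcp_cv <- function(object, ...) {
  out <- aggregate_metrics(object)
  attr(out, "approach") <- object$approach
  attr(out, "window_seconds") <- object$window_seconds
  class(out) <- c("summary.dfcp_cv", "data.frame")
  out
}

#' @export
print.summary.dfcp_cv <- function(x, ...) {
  cat(sprintf("Cross-validation summary (%s approach, %g s window):\n",
              attr(x, "approach"), attr(x, "window_seconds")))
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], function(v) if (is.numeric(v)) round(v, 4) else v)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.dfcp_cv <- function(x, ...) {
  cat(sprintf(
    "Repeated stratified CV: %s approach, %g s window, %d x %d = %d runs\n",
    x$approach, x$window_seconds, x$params$repeats, x$params$outer_folds,
    nrow(x$runs)))
  agg <- aggregate_metrics(x)
  acc <- agg[agg$metric == "accuracy", ]
  cat(sprintf("  mean accuracy %.4f (sd %.4f, 95%% CI [%.4f, %.4f])\n",
              acc$mean, acc$sd, acc$ci_lower, acc$ci_upper))
  invisible(x)
}

#' @export
plot.dfcp_cv <- function(x, ...) {
  vals <- cv_metric_values(x)
  boxplot(vals, ylim = c(0, 1), las = 1,
          main = sprintf("%s approach, %g s window", x$approach,
                         x$window_seconds),
          ylab = "per-run value", ...)
  invisible(x)
}

#' Two-sample t-test between two sets of CV runs
#'
#' Compares per-run values of one metric between two protocols (e.g.
#' static-only vs combined features).  Pooled-variance t-test by
#' default; Welch optionally.  When both sets are constant, the p-value
#' is 1 for equal means and 0 otherwise (degenerate, flagged).
#'
#' @param runsA,runsB `dfcp_cv` objects or per-run metric data.frames.
#' @param metric metric name (default `"accuracy"`).
#' @param welch use Welch's correction (default `FALSE`).
#' @return list with `p_value`, `statistic`, `significant` (at 0.05).
#' @export
compare_approaches <- function(runsA, runsB, metric = "accuracy",
                               welch = FALSE) {
  get <- function(r) {
    v <- if (inherits(r, "dfcp_cv") || "TP" %in% names(r))
      cv_metric_values(r) else r
    v[[metric]]
  }
  a <- get(runsA); b <- get(runsB)
  if (sd(a) == 0 && sd(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(list(p_value = p, statistic = NA_real_,
                significant = p < 0.05))
  }
  tt <- t.test(a, b, var.equal = !welch)
  list(p_value = tt$p.value, statistic = unname(tt$statistic),
       significant = tt$p.value < 0.05)
}

#' Correlation between window length and a metric's per-window means
#'
#' Plain Pearson correlation between the vector of window lengths and
#' the vector of per-window mean metric values (one mean per window
#' length), quantifying how performance trends with the sliding-window
#' duration.
#'
#' @param window_lengths numeric vector (seconds), length >= 3.
#' @param metric_means numeric vector of per-window means, same length.
#' @return Pearson r; `NaN` with a warning if either input has zero
#'   variance.
#' @export
window_correlation <- function(window_lengths, metric_means) {
  if (length(window_lengths) != length(metric_means) ||
      length(window_lengths) < 3L)
    dfcp_error("need equal-length vectors of at least 3 windows",
               "dfcp_validation_error")
  if (sd(window_lengths) == 0 || sd(metric_means) == 0) {
    dfcp_warn("zero variance: window correlation undefined")
    return(NaN)
  }
  cor(window_lengths, metric_means)
}

#' Intersection of selected-feature sets across folds
#'
#' Features retained by SVM-RFE in every fold and repetition; the
#' stable core of the selection.
#'
#' @param selected_sets list of index (or name) vectors, e.g. the
#'   `selected_features` element of a `dfcp_cv` object.
#' @return vector of features common to all sets.
#' @export
feature_intersection <- function(selected_sets) {
  if (length(selected_sets) == 0L)
    dfcp_error("no feature sets to intersect", "dfcp_validation_error")
  Reduce(intersect, selected_sets)
}

#' Published benchmark per-window metric means
#'
#' Summary classification metrics (per-window means over 100 CV runs)
#' reported by a published resting-state fMRI migraine-vs-control
#' benchmark for the two dynamic feature sets at five sliding-window
#' lengths, shipped as a plain-text reference table.  Used to
#' cross-check [window_correlation()] against that study's printed
#' window-length correlation coefficients.
#'
#' @return data.frame with columns `approach`, `window_seconds`,
#'   `accuracy`, `precision`, `recall`, `specificity`, `f1`.
#' @export
reference_window_metrics <- function() {
  read.table(system.file("extdata", "reference_window_metrics.tsv",
                         package = "dfcp"),
             sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Window-length correlations of the benchmark reference metrics
#'
#' Computes [window_correlation()] for every metric of both dynamic
#' approaches in [reference_window_metrics()].
#'
#' @return data.frame with columns `approach`, `metric`, `r`.
#' @export
reference_window_correlations <- function() {
  ref <- reference_window_metrics()
  metrics <- c("accuracy", "precision", "recall", "specificity", "f1")
  out <- do.call(rbind, lapply(unique(ref$approach), function(a) {
    sub <- ref[ref$approach == a, ]
    data.frame(approach = a, metric = metrics,
               r = vapply(metrics, function(m)
                 window_correlation(sub$window_seconds, sub[[m]]),
                 numeric(1)))
  }))
  rownames(out) <- NULL
  out
}
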