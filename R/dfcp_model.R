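#' Fit dynamic functional connectome patterns by twice-clustering
#'
#' Clusters pooled training WQCPs into K recurring connectivity states
#' (DFCPs) in two stages: K-means overclustering with `kmeans_k0`
#' centers (several restarts, best inertia kept), followed by
#' agglomerative merging of the stage-1 centroids (Euclidean metric,
#' Ward linkage by default).  Candidate partitions over `k_candidates`
#' are scored by the total within-cluster sum of squares of the WQCPs
#' themselves, and K is chosen by the elbow (maximum-knee) criterion.
#' Final centroids are the means of member WQCPs.
#'
#' @param wqcps a `wqcp_set`, a list of `wqcp_set`s (pooled), or a
#'   numeric matrix with one WQCP per row.
#' @param k_candidates integer vector of candidate pattern counts
#'   (default `1:12`, truncated to the overclustering size; including 1
#'   lets the elbow rule see the full drop of the dispersion curve, and
#'   the knee can never fall on an endpoint except for flat curves).
#' @param kmeans_k0 stage-1 center count; default
#'   `min(2 * ceiling(sqrt(n)), n)` for n WQCPs.
#' @param linkage `"ward"` (default), `"average"` or `"complete"`.
#' @param n_init K-means restarts (default 10).
#' @param seed integer seed controlling the K-means initialisation.
#' @return object of class `dfcp_model`: `centroids` (N x K, column k is
#'   pattern k), `K`, `labels` (training assignments), `elbow_curve`,
#'   `k_candidates`, `kmeans_k0`, `linkage`, `seed`.
#' @examples
#' set.seed(1)
#' blobs <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 10), 20))
#' m <- dfcp_model(blobs, k_candidates = 2:6, seed = 1)
#' m$K
#' @export
dfcp_model <- function(wqcps, k_candidates = 1:12, kmeans_k0 = NULL,
                       linkage = c("ward", "average", "complete"),
                       n_init = 10L, seed = 1L) {
  X <- pool_wqcps(wqcps)
  linkage <- match.arg(linkage)
  n <- nrow(X)
  if (n < 1L) dfcp_error("no WQCPs to cluster", "dfcp_validation_error")
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (is.null(kmeans_k0))
    kmeans_k0 <- min(2L * ceiling(sqrt(n)), n)
  if (kmeans_k0 > n) {
    dfcp_warn(sprintf("kmeans_k0 lowered from %d to the %d available WQCPs",
                      kmeans_k0, n))
    kmeans_k0 <- n
  }
  n_distinct <- nrow(unique(X))
  k0 <- min(kmeans_k0, n_distinct)

  if (n_distinct == 1L) {
    # all WQCPs identical: no structure to find; smallest candidate K,
    # every centroid the common point
    K <- min(k_candidates)
    centroids <- matrix(rep(X[1L, ], K), ncol = K)
    return(new_dfcp_model(centroids, K, rep(1L, n),
                          elbow_curve = rep(0, length(k_candidates)),
                          k_candidates, kmeans_k0, linkage, seed))
  }

  set.seed(seed)
  if (k0 >= n_distinct) {
    # one center per distinct point: K-means is the identity partition
    centers <- unique(X)
    cluster <- match(apply(X, 1L, paste, collapse = "\r"),
                     apply(centers, 1L, paste, collapse = "\r"))
    km <- list(centers = centers, cluster = cluster)
  } else {
    km <- suppressWarnings(
      kmeans(X, centers = k0, nstart = n_init, iter.max = 100L))
  }
  hc <- hclust(dist(km$centers),
               method = switch(linkage, ward = "ward.D2", linkage))
  ks <- k_candidates[k_candidates <= k0]
  if (length(ks) == 0L) ks <- k0
  curve <- vapply(ks, function(k) {
    lab <- cutree(hc, k)[km$cluster]
    total_wss(X, lab)
  }, numeric(1))
  K <- elbow_select(curve, ks)
  labels <- cutree(hc, K)[km$cluster]
  centroids <- vapply(seq_len(K), function(k)
    colMeans(X[labels == k, , drop = FALSE]), numeric(ncol(X)))
  new_dfcp_model(matrix(centroids, ncol = K), K, labels, curve, ks,
                 kmeans_k0, linkage, seed)
}

new_dfcp_model <- function(centroids, K, labels, elbow_curve,
                           k_candidates, kmeans_k0, linkage, seed) {
  structure(list(centroids = centroids, K = K, labels = labels,
                 elbow_curve = elbow_curve, k_candidates = k_candidates,
                 kmeans_k0 = kmeans_k0, linkage = linkage, seed = seed),
            class = "dfcp_model")
}

pool_wqcps <- function(wqcps) {
  if (inherits(wqcps, "wqcp_set")) return(wqcps$values)
  if (is.matrix(wqcps)) return(wqcps)
  if (is.list(wqcps))
    return(do.call(rbind, lapply(wqcps, function(w)
      if (inherits(w, "wqcp_set")) w$values else as.matrix(w))))
  dfcp_error("cannot interpret WQCP input", "dfcp_validation_error")
}

total_wss <- function(X, labels) {
  sum(vapply(unique(labels), function(k) {
    Xi <- X[labels == k, , drop = FALSE]
    sum(scale(Xi, scale = FALSE)^2)
  }, numeric(1)))
}

#' @export
print.dfcp_model <- function(x, ...) {
  cat(sprintf(
    "DFCP model: K = %d patterns x %d ROIs (kmeans_k0 = %d, %s linkage)\n",
    x$K, nrow(x$centroids), x$kmeans_k0, x$linkage))
  cat(sprintf("  fitted on %d WQCPs; candidate K: %s; seed %d\n",
              length(x$labels),
              paste(range(x$k_candidates), collapse = ".."), x$seed))
  invisible(x)
}

#' @export
coef.dfcp_model <- function(object, ...) object$centroids

#' Elbow (knee) selection of cluster count
#'
#' Picks the candidate K whose point on the dispersion curve lies
#' farthest (perpendicular distance) from the straight line joining the
#' curve's endpoints.  Ties favour the smaller K, so a perfectly linear
#' curve returns the smallest candidate.  With fewer than 3 candidates
#' the argmin of the curve is returned.
#'
#' @param curve within-cluster dispersion per candidate K.
#' @param k_values candidate K values (default `seq_along(curve)`).
#' @return the selected K.
#' @examples
#' elbow_select(c(100, 20, 18, 17, 16), 1:5)  # 2
#' @export
elbow_select <- function(curve, k_values = seq_along(curve)) {
  stopifnot(length(curve) == length(k_values))
  if (length(curve) < 3L) return(k_values[which.min(curve)])
  x1 <- k_values[1L]; y1 <- curve[1L]
  x2 <- k_values[length(k_values)]; y2 <- curve[length(curve)]
  dx <- x2 - x1; dy <- y2 - y1
  dist <- abs(dx * (curve - y1) - dy * (k_values - x1)) / sqrt(dx^2 + dy^2)
  k_values[which.max(dist)]   # which.max takes the first (smaller K) on ties
}

#' Nearest-pattern assignment for a WQCP
#'
#' Returns the index of the centroid with minimal Euclidean distance to
#' the WQCP (ties resolved to the lowest index).
#'
#' @param wqcp numeric vector of length N, or matrix with WQCPs as rows.
#' @param model a fitted [dfcp_model()].
#' @return integer pattern index (vector if `wqcp` is a matrix).
#' @export
assign_pattern <- function(wqcp, model) {
  R <- model$centroids
  if (is.matrix(wqcp) && (nrow(wqcp) > 1L || ncol(wqcp) == nrow(R)))
    return(apply(wqcp, 1L, function(y)
      which.min(colSums((R - y)^2))))
  y <- as.numeric(wqcp)
  which.min(colSums((R - y)^2))
}

#' @export
predict.dfcp_model <- function(object, newdata, ...) {
  X <- pool_wqcps(newdata)
  assign_pattern(X, object)
}

#' Pattern occupancy ratio features
#'
#' Fraction of a subject's WQCPs assigned to each pattern; a length-K
#' probability vector (state occupancy distribution).  A subject with
#' zero WQCPs yields a zero vector with attribute `flagged = TRUE` and a
#' warning.
#'
#' @param assignments integer pattern indices for one subject's WQCPs.
#' @param K number of patterns.
#' @return numeric vector of length K summing to 1.
#' @examples
#' ratio_features(c(1, 1, 2, 3), 3)  # 0.50 0.25 0.25
#' @export
ratio_features <- function(assignments, K) {
  if (length(assignments) == 0L) {
    dfcp_warn("subject has no WQCPs; ratio features flagged zero")
    return(structure(numeric(K), flagged = TRUE))
  }
  tabulate(assignments, nbins = K) / length(assignments)
}

#' Least-squares loadings of a WQCP on the pattern centroids
#'
#' Treats a WQCP as a linear combination of the K pattern centroids
#' (no intercept) and returns the coefficient vector minimising the
#' squared reconstruction error; the minimum-norm solution is returned
#' when the centroids are rank-deficient (SVD pseudoinverse).
#'
#' @param wqcp numeric vector of length N.
#' @param model a fitted [dfcp_model()].
#' @return numeric vector of length K.
#' @export
beta_regress <- function(wqcp, model) {
  R <- model$centroids
  y <- as.numeric(wqcp)
  sv <- svd(R)
  pos <- sv$d > max(sv$d[1L], 0) * 1e-12
  if (!any(pos)) return(numeric(ncol(R)))
  as.numeric(sv$v[, pos, drop = FALSE] %*%
               ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
}

#' Mean regression coefficients over a subject's WQCPs
#'
#' @param betas list (or matrix rows) of per-WQCP coefficient vectors.
#' @return elementwise mean vector; zeros with a warning when empty.
#' @export
mean_beta <- function(betas) {
  if (is.list(betas)) betas <- do.call(rbind, betas)
  if (is.null(betas) || nrow(betas) == 0L) {
    dfcp_warn("subject has no regression coefficients; flagged zero")
    return(structure(numeric(0), flagged = TRUE))
  }
  colMeans(betas)
}

#' DFCP feature vector for one subject
#'
#' Concatenates the K occupancy ratio features and K mean regression
#' coefficient features (2K DFCP features).  Assignment uses the
#' nearest-centroid rule uniformly, for training and test subjects
#' alike, so held-out subjects follow exactly the same code path.
#'
#' @param wqcps the subject's `wqcp_set` (or matrix of WQCP rows).
#' @param model a fitted [dfcp_model()] (trained without this subject
#'   when the subject is held out).
#' @param sfc_strength optional length-N static strength vector to carry
#'   alongside (for the combined feature set).
#' @param subject_id,group metadata (defaulted from the `wqcp_set`).
#' @return list with `ratios`, `mean_betas`, `sfc_strength`,
#'   `subject_id`, `group`; class `dfcp_features`.
#' @export
dfcp_features <- function(wqcps, model, sfc_strength = NULL,
                          subject_id = NULL, group = NA_character_) {
  X <- pool_wqcps(wqcps)
  if (is.null(subject_id) && inherits(wqcps, "wqcp_set"))
    subject_id <- wqcps$subject_id
  if (nrow(X) == 0L) {
    dfcp_warn("subject has no WQCPs; DFCP features flagged zero")
    ratios <- structure(numeric(model$K), flagged = TRUE)
    mbetas <- numeric(model$K)
  } else {
    ratios <- ratio_features(assign_pattern(X, model), model$K)
    betas <- matrix(NA_real_, nrow(X), model$K)
    for (i in seq_len(nrow(X))) betas[i, ] <- beta_regress(X[i, ], model)
    mbetas <- mean_beta(betas)
  }
  structure(list(ratios = ratios, mean_betas = mbetas,
                 sfc_strength = sfc_strength,
                 subject_id = subject_id, group = group),
            class = "dfcp_features")
}
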