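#' Protocol parameters for feature selection and classification
#'
#' Bundles every tunable of the repeated stratified cross-validation
#' protocol with its default.  The classifier is an SVM; by default an
#' RBF kernel is tuned over log2-spaced grids of the cost C and kernel
#' width gamma by inner stratified cross-validation (a linear kernel
#' tunes C only).  SVM-RFE ranks features with a linear SVM and the
#' retained subset size is the rank prefix maximising inner-CV accuracy
#' (configurable to a fixed count via `rfe_n_features`).
#'
#' @param outer_folds outer CV folds (default 5).
#' @param repeats protocol repetitions (default 20; 20 x 5 = 100 runs).
#' @param inner_folds inner CV folds for RFE subset choice and
#'   hyperparameter tuning (default 5).
#' @param rfe_step features eliminated per RFE iteration (default 1).
#' @param rfe_n_features optional fixed subset size; `NULL` (default)
#'   selects the size by inner-CV accuracy.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param C_grid cost grid (default `2^(-5:5)`).
#' @param gamma_grid RBF width grid (default `2^(-7:1)`).
#' @param seed master integer seed; every random draw in the protocol
#'   derives from it.
#' @param alpha,min_segment_windows segmentation parameters (see
#'   [segment_dfcs()]).
#' @param sfc_mode static strength mode (see [sfc_strength()]).
#' @param k_candidates,kmeans_k0,n_init,linkage clustering parameters
#'   (see [dfcp_model()]).
#' @return list of class `protocol_params`.
#' @export
protocol_params <- function(outer_folds = 5L, repeats = 20L,
                            inner_folds = 5L, rfe_step = 1L,
                            rfe_n_features = NULL,
                            kernel = c("rbf", "linear"),
                            C_grid = 2^(-5:5), gamma_grid = 2^(-7:1),
                            seed = 1L, alpha = 1,
                            min_segment_windows = 2L,
                            sfc_mode = "positive_sum",
                            k_candidates = 1:12, kmeans_k0 = NULL,
                            n_init = 10L, linkage = "ward") {
  kernel <- match.arg(kernel)
  if (length(C_grid) == 0L || any(C_grid <= 0))
    dfcp_error("C_grid must be nonempty and positive", "dfcp_config_error")
  if (kernel == "rbf" && (length(gamma_grid) == 0L || any(gamma_grid <= 0)))
    dfcp_error("gamma_grid must be nonempty and positive",
               "dfcp_config_error")
  if (outer_folds < 2L || inner_folds < 2L)
    dfcp_error("folds must be >= 2", "dfcp_config_error")
  structure(list(outer_folds = as.integer(outer_folds),
                 repeats = as.integer(repeats),
                 inner_folds = as.integer(inner_folds),
                 rfe_step = as.integer(rfe_step),
                 rfe_n_features = rfe_n_features,
                 kernel = kernel, C_grid = sort(C_grid),
                 gamma_grid = sort(gamma_grid), seed = as.integer(seed),
                 alpha = alpha,
                 min_segment_windows = as.integer(min_segment_windows),
                 sfc_mode = sfc_mode, k_candidates = k_candidates,
                 kmeans_k0 = kmeans_k0, n_init = as.integer(n_init),
                 linkage = linkage),
            class = "protocol_params")
}

#' Stratified fold assignment
#'
#' Assigns subjects to `k` folds so that per-group fold sizes differ by
#' at most one; deterministic given the seed.
#'
#' @param groups factor/character vector of group labels per subject.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k) per subject.
#' @export
stratified_folds <- function(groups, k, seed) {
  groups <- as.character(groups)
  k <- as.integer(k)
  folds <- integer(length(groups))
  set.seed(seed)
  offset <- 0L  # continue cyclic assignment across groups so the
                # per-group remainders land on different folds and total
                # fold sizes also differ by at most one
  for (g in sort(unique(groups))) {
    idx <- which(groups == g)
    if (length(idx) < k)
      dfcp_error(sprintf("group '%s' has %d subjects, fewer than %d folds",
                         g, length(idx), k), "dfcp_validation_error")
    folds[sample(idx)] <- (offset + seq_along(idx) - 1L) %% k + 1L
    offset <- (offset + length(idx)) %% k
  }
  folds
}

# weight vector of a fitted linear SVM: w = t(coefs) %*% SV
.linear_svm_weights <- function(X, y, C = 1) {
  fit <- e1071::svm(X, y, kernel = "linear", cost = C, scale = FALSE)
  w <- crossprod(fit$coefs, fit$SV)
  as.numeric(w)
}

# e1071 names the RBF kernel "radial"
.svm_kernel <- function(kernel) if (kernel == "rbf") "radial" else kernel

# stratified inner-CV accuracy of an SVM spec on (X, y); with very small
# groups the fold count drops to the group size (resubstitution as the
# degenerate floor)
.inner_cv_accuracy <- function(X, y, kernel, C, gamma, inner_folds, seed) {
  inner_folds <- min(inner_folds, min(table(y)))
  if (inner_folds < 2L) {
    fit <- e1071::svm(X, y, kernel = .svm_kernel(kernel), cost = C,
                      gamma = gamma, scale = FALSE)
    return(mean(predict(fit, X) == y))
  }
  folds <- stratified_folds(y, inner_folds, seed)
  correct <- 0L
  for (f in seq_len(inner_folds)) {
    tr <- folds != f
    fit <- e1071::svm(X[tr, , drop = FALSE], y[tr],
                      kernel = .svm_kernel(kernel),
                      cost = C, gamma = gamma, scale = FALSE)
    pred <- predict(fit, X[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' SVM-RFE feature ranking and subset selection
#'
#' Recursive feature elimination: repeatedly fits a linear SVM and
#' removes the `rfe_step` features with the smallest squared weights,
#' recording the elimination order (survivors rank first).  The retained
#' subset is the rank prefix maximising inner stratified CV accuracy
#' (ties favour the smaller subset), unless a fixed size is requested.
#' Columns are used as given: standardize with training statistics
#' before calling.  Constant columns are retained in the ranking but
#' flagged.
#'
#' @param X numeric feature matrix (subjects x features), training rows
#'   only.
#' @param y factor of class labels (levels `control`, `case`).
#' @param params a [protocol_params()] list.
#' @param seed integer seed for the inner folds.
#' @return list with `ranking` (all features, best first), `selected`
#'   (chosen indices, in ranking order), `subset_accuracy` (inner-CV
#'   accuracy per prefix size) and `flagged_constant`.
#' @export
svm_rfe <- function(X, y, params = protocol_params(), seed = params$seed) {
  p <- ncol(X)
  if (p < 1L) dfcp_error("no features", "dfcp_validation_error")
  if (nlevels(droplevels(as.factor(y))) < 2L)
    dfcp_error("both classes must be present", "dfcp_validation_error")
  y <- factor(y, levels = c("control", "case"))
  flagged <- which(apply(X, 2L, function(col) sd(col) == 0))
  if (p == 1L)
    return(list(ranking = 1L, selected = 1L, subset_accuracy = NA_real_,
                flagged_constant = flagged))

  remaining <- seq_len(p)
  eliminated <- integer(0)
  while (length(remaining) > 1L) {
    w2 <- .linear_svm_weights(X[, remaining, drop = FALSE], y)^2
    k <- min(params$rfe_step, length(remaining) - 1L)
    drop <- remaining[order(w2)[seq_len(k)]]
    eliminated <- c(drop, eliminated)   # worst eliminated first overall
    remaining <- setdiff(remaining, drop)
  }
  ranking <- c(remaining, eliminated)

  if (!is.null(params$rfe_n_features)) {
    s <- min(params$rfe_n_features, p)
    return(list(ranking = ranking, selected = ranking[seq_len(s)],
                subset_accuracy = NA_real_, flagged_constant = flagged))
  }
  acc <- vapply(seq_len(p), function(s)
    .inner_cv_accuracy(X[, ranking[seq_len(s)], drop = FALSE], y,
                       kernel = "linear", C = 1, gamma = 1,
                       inner_folds = params$inner_folds, seed = seed),
    numeric(1))
  s_best <- which.max(acc)    # first maximum: smallest subset on ties
  list(ranking = ranking, selected = ranking[seq_len(s_best)],
       subset_accuracy = acc, flagged_constant = flagged)
}

#' Train an SVM with inner-CV hyperparameter search
#'
#' Grid search over the cost C (and gamma for the RBF kernel) scored by
#' inner stratified CV accuracy; the winning combination (ties: smallest
#' C, then smallest gamma) is refit on the full training split.
#'
#' @param X training feature matrix (selected, standardized columns).
#' @param y factor of labels (levels `control`, `case`).
#' @param params a [protocol_params()] list.
#' @param seed seed for the inner folds.
#' @return list with the fitted `model`, tuned `C`, `gamma`, and
#'   `inner_accuracy`.
#' @export
train_svm <- function(X, y, params = protocol_params(),
                      seed = params$seed) {
  y <- factor(y, levels = c("control", "case"))
  if (nlevels(droplevels(y)) < 2L)
    dfcp_error("degenerate single-class training split",
               "dfcp_validation_error")
  gammas <- if (params$kernel == "rbf") params$gamma_grid else 1 / ncol(X)
  grid <- expand.grid(gamma = gammas, C = params$C_grid)
  grid <- grid[order(grid$C, grid$gamma), ]
  acc <- vapply(seq_len(nrow(grid)), function(i)
    .inner_cv_accuracy(X, y, params$kernel, grid$C[i], grid$gamma[i],
                       params$inner_folds, seed), numeric(1))
  best <- which.max(acc)   # grid sorted ascending: ties take smallest C, gamma
  fit <- e1071::svm(X, y, kernel = .svm_kernel(params$kernel),
                    cost = grid$C[best],
                    gamma = grid$gamma[best], scale = FALSE)
  list(model = fit, C = grid$C[best], gamma = grid$gamma[best],
       inner_accuracy = acc[best])
}

#' Confusion counts on a held-out fold
#'
#' The case (patient) group is the positive class.
#'
#' @param fit fitted SVM (from [train_svm()], `$model`).
#' @param X_test test feature matrix (same columns as training).
#' @param y_test factor of test labels.
#' @return named integer vector `TP`, `FP`, `TN`, `FN`.
#' @export
evaluate_fold <- function(fit, X_test, y_test) {
  if (ncol(X_test) != ncol(fit$SV))
    dfcp_error("feature dimension mismatch between training and test",
               "dfcp_shape_error")
  y_test <- factor(y_test, levels = c("control", "case"))
  pred <- predict(fit, X_test)
  c(TP = sum(pred == "case" & y_test == "case"),
    FP = sum(pred == "case" & y_test == "control"),
    TN = sum(pred == "control" & y_test == "control"),
    FN = sum(pred == "control" & y_test == "case"))
}

#' Classification performance metrics from confusion counts
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1, with
#' the case group as positive.  A zero denominator yields 0 for that
#' metric and sets the `flagged` attribute.
#'
#' @param counts named vector with `TP`, `FP`, `TN`, `FN`.
#' @return named numeric vector of the five metrics.
#' @examples
#' classification_metrics(c(TP = 9, FP = 2, TN = 8, FN = 1))
#' @export
classification_metrics <- function(counts) {
  TP <- counts[["TP"]]; FP <- counts[["FP"]]
  TN <- counts[["TN"]]; FN <- counts[["FN"]]
  flagged <- FALSE
  safe <- function(num, den) {
    if (den == 0) { flagged <<- TRUE; return(0) }
    num / den
  }
  precision <- safe(TP, TP + FP)
  recall <- safe(TP, TP + FN)
  out <- c(accuracy = safe(TP + TN, TP + FP + TN + FN),
           precision = precision, recall = recall,
           specificity = safe(TN, TN + FP),
           f1 = if (precision + recall == 0) { flagged <- TRUE; 0 }
                else 2 * precision * recall / (precision + recall))
  attr(out, "flagged") <- flagged
  out
}

# ---- feature construction shared by dfcp_fit and dfcp_crossval ----------

# per-subject, split-independent raw material for a given window length
.prepare_subjects <- function(cohort, approach, window_seconds, params) {
  need_sfc <- approach %in% c("sfc", "combined")
  need_dyn <- approach %in% c("dfcp", "combined")
  lapply(cohort, function(ts) {
    out <- list(subject_id = ts$subject_id, group = ts$group)
    if (need_sfc)
      out$sfc <- sfc_strength(static_fc(ts), params$sfc_mode)
    if (need_dyn)
      out$wqcps <- extract_wqcps(subject_dfcs(ts, window_seconds),
                                 params$alpha, params$min_segment_windows)
    out
  })
}

# feature matrix for a subject subset given a (possibly NULL) DFCP model
.feature_matrix <- function(subjects, approach, model) {
  rows <- lapply(subjects, function(s) {
    dyn <- if (!is.null(model))
      dfcp_features(s$wqcps, model, subject_id = s$subject_id,
                    group = s$group)
    c(if (!is.null(model)) c(dyn$ratios, dyn$mean_betas),
      if (approach %in% c("sfc", "combined")) as.numeric(s$sfc))
  })
  X <- do.call(rbind, rows)
  K <- if (is.null(model)) 0L else model$K
  nm <- c(if (K > 0) c(paste0("ratio_", 1:K), paste0("mbeta_", 1:K)),
          if (approach %in% c("sfc", "combined"))
            paste0("sfcs_", seq_len(ncol(X) - 2L * K)))
  colnames(X) <- nm
  X
}

# z-scoring with training statistics; zero-sd columns pass through
.fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}
.apply_scaler <- function(X, sc) scale(X, center = sc$mu, scale = sc$sd)

# ---- single-split fit (the classic modelling entry point) ---------------

#' Fit the full classifier on a cohort
#'
#' Fits every stage on the given subjects — DFCP model (for the
#' `"dfcp"` and `"combined"` approaches), feature construction,
#' standardization, SVM-RFE feature selection and the tuned SVM — and
#' returns a classifier applicable to new subjects via [predict()].
#' This is the single-split counterpart of [dfcp_crossval()]; use the
#' latter for unbiased performance estimates.
#'
#' @param cohort list of [roi_ts()] objects containing both groups.
#' @param approach `"dfcp"` (dynamic features), `"sfc"` (static strength
#'   features) or `"combined"`.
#' @param window_seconds sliding-window length in seconds (ignored for
#'   `"sfc"`).
#' @param params a [protocol_params()] list.
#' @return object of class `dfcp_classifier`.
#' @export
dfcp_fit <- function(cohort, approach = c("combined", "dfcp", "sfc"),
                     window_seconds = 24, params = protocol_params()) {
  approach <- match.arg(approach)
  subjects <- .prepare_subjects(cohort, approach, window_seconds, params)
  y <- factor(vapply(subjects, `[[`, "", "group"),
              levels = c("control", "case"))
  model <- NULL
  if (approach != "sfc")
    model <- dfcp_model(lapply(subjects, `[[`, "wqcps"),
                        k_candidates = params$k_candidates,
                        kmeans_k0 = params$kmeans_k0,
                        linkage = params$linkage,
                        n_init = params$n_init, seed = params$seed)
  X <- .feature_matrix(subjects, approach, model)
  scaler <- .fit_scaler(X)
  Xs <- .apply_scaler(X, scaler)
  rfe <- svm_rfe(Xs, y, params, seed = params$seed)
  sel <- rfe$selected
  tuned <- train_svm(Xs[, sel, drop = FALSE], y, params,
                     seed = params$seed)
  structure(list(approach = approach, window_seconds = window_seconds,
                 params = params, pattern_model = model, scaler = scaler,
                 feature_names = colnames(X), rfe = rfe,
                 selected = sel, svm = tuned$model,
                 C = tuned$C, gamma = tuned$gamma),
            class = "dfcp_classifier")
}

#' @export
print.dfcp_classifier <- function(x, ...) {
  cat(sprintf("DFCP classifier (%s approach", x$approach))
  if (x$approach != "sfc")
    cat(sprintf(", %g s window, K = %d patterns", x$window_seconds,
                x$pattern_model$K))
  cat(")\n")
  cat(sprintf("  %d/%d features selected by SVM-RFE; %s SVM, C = %g%s\n",
              length(x$selected), length(x$feature_names),
              x$params$kernel, x$C,
              if (x$params$kernel == "rbf")
                sprintf(", gamma = %g", x$gamma) else ""))
  invisible(x)
}

#' @export
predict.dfcp_classifier <- function(object, newdata, ...) {
  subjects <- .prepare_subjects(newdata, object$approach,
                                object$window_seconds, object$params)
  X <- .feature_matrix(subjects, object$approach, object$pattern_model)
  Xs <- .apply_scaler(X, object$scaler)
  pred <- predict(object$svm, Xs[, object$selected, drop = FALSE])
  names(pred) <- vapply(subjects, `[[`, "", "subject_id")
  pred
}

# ---- repeated stratified cross-validation protocol ----------------------

#' Repeated stratified cross-validation of the classification framework
#'
#' Runs the full protocol: for each of `repeats` repetitions, subjects
#' are split into `outer_folds` stratified folds; within each fold the
#' DFCP model (when dynamic features are used) is fitted on training
#' subjects' WQCPs only, features are built and standardized with
#' training statistics, SVM-RFE selects a feature subset once per fold,
#' the SVM is tuned by inner CV and evaluated on the held-out fold.
#' With the defaults this yields 20 x 5 = 100 runs per approach.
#' Held-out subjects contribute nothing to clustering, scaling, ranking
#' or tuning.
#'
#' @inheritParams dfcp_fit
#' @param extra_test optional fully held-out second cohort (list of
#'   [roi_ts()]); each fold's trained classifier is also evaluated on it
#'   and recorded in `extra_runs`.
#' @return object of class `dfcp_cv`: data.frame `runs` (one row per
#'   repeat x fold with confusion counts, tuned parameters, K and
#'   selected-feature count), list `selected_features`, `feature_names`,
#'   optional `extra_runs`, plus the call metadata.
#' @export
dfcp_crossval <- function(cohort, approach = c("combined", "dfcp", "sfc"),
                          window_seconds = 24,
                          params = protocol_params(),
                          extra_test = NULL) {
  approach <- match.arg(approach)
  subjects <- .prepare_subjects(cohort, approach, window_seconds, params)
  groups <- vapply(subjects, `[[`, "", "group")
  if (length(unique(groups)) < 2L)
    dfcp_error("cohort must contain both groups", "dfcp_validation_error")
  extra <- if (!is.null(extra_test))
    .prepare_subjects(extra_test, approach, window_seconds, params)

  runs <- list(); extra_runs <- list(); sel_log <- list()
  feature_names <- NULL
  row <- 0L
  for (r in seq_len(params$repeats)) {
    fold_seed <- params$seed + 101L * r
    folds <- stratified_folds(groups, params$outer_folds, fold_seed)
    for (f in seq_len(params$outer_folds)) {
      split_seed <- fold_seed + 13L * f
      tr <- which(folds != f); te <- which(folds == f)
      model <- NULL
      if (approach != "sfc")
        model <- dfcp_model(lapply(subjects[tr], `[[`, "wqcps"),
                            k_candidates = params$k_candidates,
                            kmeans_k0 = params$kmeans_k0,
                            linkage = params$linkage,
                            n_init = params$n_init, seed = split_seed)
      Xtr <- .feature_matrix(subjects[tr], approach, model)
      Xte <- .feature_matrix(subjects[te], approach, model)
      ytr <- factor(groups[tr], levels = c("control", "case"))
      yte <- factor(groups[te], levels = c("control", "case"))
      scaler <- .fit_scaler(Xtr)
      Xtr_s <- .apply_scaler(Xtr, scaler)
      Xte_s <- .apply_scaler(Xte, scaler)
      rfe <- svm_rfe(Xtr_s, ytr, params, seed = split_seed)
      sel <- rfe$selected
      feature_names <- colnames(Xtr)
      tuned <- train_svm(Xtr_s[, sel, drop = FALSE], ytr, params,
                         seed = split_seed)
      counts <- evaluate_fold(tuned$model, Xte_s[, sel, drop = FALSE], yte)
      row <- row + 1L
      runs[[row]] <- data.frame(repeat_idx = r, fold = f,
                                TP = counts[["TP"]], FP = counts[["FP"]],
                                TN = counts[["TN"]], FN = counts[["FN"]],
                                K = if (is.null(model)) NA_integer_
                                    else model$K,
                                n_selected = length(sel),
                                C = tuned$C, gamma = tuned$gamma)
      sel_log[[row]] <- colnames(Xtr)[sel]
      if (!is.null(extra)) {
        Xe <- .feature_matrix(extra, approach, model)
        ye <- factor(vapply(extra, `[[`, "", "group"),
                     levels = c("control", "case"))
        ce <- evaluate_fold(tuned$model,
                            .apply_scaler(Xe, scaler)[, sel, drop = FALSE],
                            ye)
        extra_runs[[row]] <- data.frame(repeat_idx = r, fold = f,
                                        TP = ce[["TP"]], FP = ce[["FP"]],
                                        TN = ce[["TN"]], FN = ce[["FN"]])
      }
    }
  }
  structure(list(runs = do.call(rbind, runs),
                 selected_features = sel_log,
                 feature_names = feature_names,
                 extra_runs = if (length(extra_runs))
                   do.call(rbind, extra_runs),
                 approach = approach, window_seconds = window_seconds,
                 params = params),
            class = "dfcp_cv")
}
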