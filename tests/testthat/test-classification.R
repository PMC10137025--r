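test_that("stratified folds balance groups and are seed-deterministic", {
  g <- rep(c("case", "control"), c(34, 34))
  f <- stratified_folds(g, 5, seed = 1)
  for (k in 1:5) {
    expect_true(sum(f == k & g == "case") %in% 6:7)
    expect_true(sum(f == k & g == "control") %in% 6:7)
    expect_true(sum(f == k) %in% 13:14)
  }
  expect_identical(f, stratified_folds(g, 5, seed = 1))
  expect_false(identical(f, stratified_folds(g, 5, seed = 2)))

  g2 <- rep(c("case", "control"), each = 10)
  f2 <- stratified_folds(g2, 5, seed = 3)
  expect_true(all(table(f2, g2) == 2))

  expect_error(stratified_folds(rep(c("case", "control"), c(3, 10)), 5, 1),
               class = "dfcp_validation_error")
})

test_that("confusion metrics match hand-computed values and handle zeros", {
  m <- classification_metrics(c(TP = 9, FP = 2, TN = 8, FN = 1))
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["precision"]), 9 / 11, tolerance = 1e-12)
  expect_equal(unname(m["recall"]), 0.9)
  expect_equal(unname(m["specificity"]), 0.8)
  expect_equal(unname(m["f1"]), 2 * (9/11) * 0.9 / (9/11 + 0.9),
               tolerance = 1e-12)

  perfect <- classification_metrics(c(TP = 7, FP = 0, TN = 7, FN = 0))
  expect_true(all(perfect == 1))

  # classifier that never predicts case: precision flagged 0, specificity 1
  deg <- classification_metrics(c(TP = 0, FP = 0, TN = 8, FN = 6))
  expect_equal(unname(deg["precision"]), 0)
  expect_equal(unname(deg["recall"]), 0)
  expect_equal(unname(deg["specificity"]), 1)
  expect_true(attr(deg, "flagged"))
})

test_that("evaluate_fold counts with case as the positive class", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40, 3), 10), matrix(rnorm(40, -3), 10))
  y <- factor(rep(c("case", "control"), each = 10),
              levels = c("control", "case"))
  fit <- e1071::svm(X, y, kernel = "linear", scale = FALSE)
  expect_equal(evaluate_fold(fit, X, y),
               c(TP = 10L, FP = 0L, TN = 10L, FN = 0L))
  # inverted labels: everything lands in FP/FN
  expect_equal(evaluate_fold(fit, X, rev(y)),
               c(TP = 0L, FP = 10L, TN = 0L, FN = 10L))
  expect_error(evaluate_fold(fit, X[, 1:2], y), class = "dfcp_shape_error")
})

test_that("SVM-RFE performs the expected elimination rounds and ranks planted signal", {
  set.seed(2)
  n <- 60
  y <- factor(rep(c("control", "case"), each = n / 2),
              levels = c("control", "case"))
  X <- matrix(rnorm(n * 5), n)
  p <- protocol_params(rfe_step = 1, rfe_n_features = 2, seed = 1)
  r <- svm_rfe(scale(X), y, p)
  expect_setequal(r$ranking, 1:5)  # every feature ranked once

  # 2 informative of 22: informative features rank near the top
  hits <- 0L
  for (s in 1:25) {
    set.seed(s)
    X <- matrix(rnorm(n * 22), n)
    X[y == "case", 1:2] <- X[y == "case", 1:2] + 2.0
    r <- svm_rfe(scale(X), y, p, seed = s)
    if (all(c(1, 2) %in% r$ranking[1:5])) hits <- hits + 1L
  }
  expect_gte(hits, 24L)

  # single feature: trivially selected
  r1 <- svm_rfe(matrix(rnorm(n), n), y, p)
  expect_equal(r1$selected, 1L)
})

test_that("inner-CV subset choice keeps informative features and drops noise", {
  set.seed(3)
  n <- 60
  y <- factor(rep(c("control", "case"), each = n / 2),
              levels = c("control", "case"))
  X <- matrix(rnorm(n * 10), n)
  X[y == "case", 1:2] <- X[y == "case", 1:2] + 3
  r <- svm_rfe(scale(X), y, protocol_params(seed = 4), seed = 4)
  expect_true(all(c(1, 2) %in% r$selected))
  expect_lt(length(r$selected), 10L)
})

test_that("hyperparameter search is deterministic and favours rbf on XOR data", {
  set.seed(5)
  n <- 80
  X <- matrix(runif(n * 2, -1, 1), n)
  y <- factor(ifelse(X[, 1] * X[, 2] > 0, "case", "control"),
              levels = c("control", "case"))
  p_lin <- protocol_params(kernel = "linear", seed = 6)
  p_rbf <- protocol_params(kernel = "rbf", seed = 6)
  fit_lin <- train_svm(X, y, p_lin)
  fit_rbf <- train_svm(X, y, p_rbf)
  expect_gt(fit_rbf$inner_accuracy, fit_lin$inner_accuracy)

  fit2 <- train_svm(X, y, p_rbf)
  expect_identical(fit_rbf$C, fit2$C)
  expect_identical(fit_rbf$gamma, fit2$gamma)

  # linearly separable toy set trains to perfect training accuracy
  Xs <- rbind(matrix(rnorm(20, 4), 10), matrix(rnorm(20, -4), 10))
  ys <- factor(rep(c("case", "control"), each = 10),
               levels = c("control", "case"))
  fit3 <- train_svm(Xs, ys, protocol_params(kernel = "linear",
                                            inner_folds = 2, seed = 1))
  expect_equal(sum(predict(fit3$model, Xs) == ys), 20L)

  expect_error(train_svm(Xs, factor(rep("case", 20),
                                    levels = c("control", "case")),
                         p_lin),
               class = "dfcp_validation_error")
})

test_that("the protocol yields repeats x folds runs and is fully seed-deterministic", {
  sim <- tiny_cohort(n_per_group = 5, seed = 21)
  p <- protocol_params(repeats = 2, outer_folds = 5, seed = 31,
                       k_candidates = 2:4)
  cv1 <- dfcp_crossval(sim$cohort, "dfcp", 24, p)
  expect_equal(nrow(cv1$runs), 10L)
  expect_true(all(cv1$runs$TP + cv1$runs$FP + cv1$runs$TN +
                    cv1$runs$FN == 2L))
  cv2 <- dfcp_crossval(sim$cohort, "dfcp", 24, p)
  expect_identical(cv1$runs, cv2$runs)
  expect_identical(cv1$selected_features, cv2$selected_features)
})

test_that("combined features stack static strengths on the 2K dynamic features", {
  sim <- tiny_cohort(n_per_group = 5, seed = 22)
  p <- protocol_params(repeats = 1, seed = 7, k_candidates = 2:4)
  cv <- dfcp_crossval(sim$cohort, "combined", 24, p)
  n_rois <- ncol(sim$cohort[[1]]$values)
  K <- cv$runs$K[1]
  expect_length(cv$feature_names, n_rois + 2 * K)
  expect_true(all(grepl("^(ratio|mbeta|sfcs)_", cv$feature_names)))
})

test_that("held-out subjects cannot influence their fold's fitted pipeline", {
  sim <- tiny_cohort(n_per_group = 5, seed = 23)
  p <- protocol_params(repeats = 1, seed = 41, k_candidates = 2:4)
  cv1 <- dfcp_crossval(sim$cohort, "dfcp", 24, p)

  # replace one subject's series with unrelated noise and rerun
  groups <- vapply(sim$cohort, `[[`, "", "group")
  folds <- stratified_folds(groups, p$outer_folds, p$seed + 101L)
  victim <- 3L
  cohort2 <- sim$cohort
  set.seed(999)
  cohort2[[victim]] <- roi_ts(
    matrix(rnorm(length(cohort2[[victim]]$values)),
           nrow(cohort2[[victim]]$values)),
    cohort2[[victim]]$tr_seconds, cohort2[[victim]]$subject_id,
    cohort2[[victim]]$group)
  cv2 <- dfcp_crossval(cohort2, "dfcp", 24, p)

  f <- folds[victim]  # the fold where the victim is a test subject
  r1 <- cv1$runs[cv1$runs$fold == f, ]
  r2 <- cv2$runs[cv2$runs$fold == f, ]
  expect_identical(r1$K, r2$K)
  expect_identical(r1$C, r2$C)
  expect_identical(r1$gamma, r2$gamma)
  expect_identical(cv1$selected_features[[which(cv1$runs$fold == f)]],
                   cv2$selected_features[[which(cv2$runs$fold == f)]])
})

test_that("a second fully held-out cohort is scored with each fold's classifier", {
  sim <- tiny_cohort(n_per_group = 5, seed = 24)
  extra <- simulate_cohort(synthetic_spec(n_subjects_per_group = 3,
                                          n_timepoints = 120,
                                          seed = 77))$cohort
  p <- protocol_params(repeats = 1, seed = 8, k_candidates = 2:4)
  cv <- dfcp_crossval(sim$cohort, "dfcp", 24, p, extra_test = extra)
  expect_equal(nrow(cv$extra_runs), 5L)
  expect_true(all(cv$extra_runs$TP + cv$extra_runs$FP +
                    cv$extra_runs$TN + cv$extra_runs$FN == 6L))
})

test_that("single-split classifier fits and predicts new subjects", {
  sim <- tiny_cohort(n_per_group = 6, seed = 25)
  fit <- dfcp_fit(sim$cohort, "combined", 24,
                  protocol_params(seed = 9, k_candidates = 2:4))
  expect_s3_class(fit, "dfcp_classifier")
  pred <- predict(fit, sim$cohort[1:4])
  expect_s3_class(pred, "factor")
  expect_length(pred, 4L)
  expect_true(all(levels(pred) == c("control", "case")))
})
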