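# shared fixture builders (all data generated in code)

random_roi_ts <- function(T = 30, N = 5, seed = 1, tr = 2,
                          group = "control", id = "s1") {
  set.seed(seed)
  roi_ts(matrix(rnorm(T * N), T, N), tr_seconds = tr, subject_id = id,
         group = group)
}

# piecewise-constant dFCS matrix with planted boundaries; noise_sd scales
# within-level jitter, jump the between-level step size
planted_dfcs <- function(n_rois = 6, seg_lengths = c(10, 10, 10),
                         jump = 3, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  levels <- matrix(runif(n_rois * length(seg_lengths), 1, 2), n_rois)
  for (k in seq_along(seg_lengths)[-1])
    levels[, k] <- levels[, k - 1] + jump * rnorm(n_rois) / sqrt(n_rois)
  cols <- do.call(cbind, lapply(seq_along(seg_lengths), function(k)
    levels[, k] + matrix(rnorm(n_rois * seg_lengths[k], sd = noise_sd),
                         n_rois)))
  cols
}

# tiny two-group cohort for protocol-level tests
tiny_cohort <- function(n_per_group = 8, seed = 5) {
  spec <- synthetic_spec(n_subjects_per_group = n_per_group,
                         n_timepoints = 120, seed = seed)
  simulate_cohort(spec)
}

# adjusted Rand index via e1071 (independent of the clustering code)
ari <- function(a, b) e1071::classAgreement(table(a, b))$crand
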