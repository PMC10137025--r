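#' Specification of a synthetic two-group cohort
#'
#' Defines the generative model used to validate the pipeline: each
#' subject's ROI series follows a latent switching-state process.  K
#' latent connectivity states are correlation matrices built from random
#' low-rank factor loadings plus diagonal noise; within a state dwell,
#' observations are zero-mean Gaussian with that state's correlation,
#' plus isotropic measurement noise.  Groups differ in (a) expected
#' state occupancy (dwell durations are sampled so that expected
#' occupancy equals the group's target) and (b) a static connectivity
#' shift: a designated ROI subset of the case group gets an offset added
#' to its factor loadings, raising those ROIs' connectivity strength in
#' every state.
#'
#' Defaults are the package's reference study conditions: 20 ROIs,
#' 34 subjects per group, 150 time points at TR 2 s, 2 states with
#' occupancy 0.7/0.3 (case) vs 0.3/0.7 (control), static shift 0.3 on
#' 4 ROIs, mean state dwell 25 samples with a 14-sample minimum,
#' observation noise sd 0.2.
#'
#' @param n_rois number of ROIs.
#' @param n_subjects_per_group subjects per group.
#' @param n_timepoints time points per subject.
#' @param tr_seconds repetition time (seconds).
#' @param n_states number of latent connectivity states.
#' @param factor_rank rank of the state loading matrices.
#' @param loading_scale sd of the random loadings.
#' @param diag_noise diagonal variance added before rescaling to unit
#'   diagonal.
#' @param occupancy_case,occupancy_control length-`n_states` target
#'   occupancy vectors (sum to 1).
#' @param dwell_min minimum state dwell in samples.
#' @param dwell_mean mean state dwell in samples (expected dwells are
#'   set proportional to target occupancy around this mean).
#' @param static_strength_shift loading offset applied to the case
#'   group's designated ROIs.
#' @param shift_rois indices of the designated ROIs.
#' @param noise_sd isotropic observation noise sd.
#' @param min_state_distance minimum pairwise Frobenius distance between
#'   state correlation matrices (resampled until met).
#' @param seed master seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_rois = 20L, n_subjects_per_group = 34L,
                           n_timepoints = 150L, tr_seconds = 2,
                           n_states = 2L, factor_rank = 2L,
                           loading_scale = 1, diag_noise = 0.5,
                           occupancy_case = c(0.7, 0.3),
                           occupancy_control = c(0.3, 0.7),
                           dwell_min = 14L, dwell_mean = 25,
                           static_strength_shift = 0.3,
                           shift_rois = 1:4, noise_sd = 0.2,
                           min_state_distance = NULL, seed = 1L) {
  stopifnot(length(occupancy_case) == n_states,
            length(occupancy_control) == n_states,
            factor_rank < n_rois, dwell_min >= 1)
  if (abs(sum(occupancy_case) - 1) > 1e-8 ||
      abs(sum(occupancy_control) - 1) > 1e-8)
    dfcp_error("occupancy vectors must sum to 1", "dfcp_config_error")
  if (is.null(min_state_distance))
    min_state_distance <- 0.15 * n_rois
  structure(list(n_rois = as.integer(n_rois),
                 n_subjects_per_group = as.integer(n_subjects_per_group),
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, n_states = as.integer(n_states),
                 factor_rank = as.integer(factor_rank),
                 loading_scale = loading_scale, diag_noise = diag_noise,
                 occupancy_case = occupancy_case,
                 occupancy_control = occupancy_control,
                 dwell_min = as.integer(dwell_min),
                 dwell_mean = dwell_mean,
                 static_strength_shift = static_strength_shift,
                 shift_rois = as.integer(shift_rois),
                 noise_sd = noise_sd,
                 min_state_distance = min_state_distance,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Named presets of the synthetic cohort specification
#'
#' `"strong-effect"`: the defaults of [synthetic_spec()] (clear
#' occupancy and static group differences).  `"null"`: identical
#' occupancy (0.5/0.5) in both groups and zero static shift, so any
#' downstream classification accuracy above chance indicates leakage.
#' `"paper-shaped"`: 246 ROIs with the cohort geometry of the motivating
#' study design (cases: 150 points at TR 3 s; controls simulated at the
#' same length at TR 2 s); computationally heavy, intended for full-scale
#' runs rather than tests.
#'
#' @param preset preset name.
#' @param seed master seed.
#' @return a [synthetic_spec()].
#' @export
synthetic_preset <- function(preset = c("strong-effect", "null",
                                        "paper-shaped"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    "strong-effect" = synthetic_spec(seed = seed),
    "null" = synthetic_spec(occupancy_case = c(0.5, 0.5),
                            occupancy_control = c(0.5, 0.5),
                            static_strength_shift = 0, seed = seed),
    "paper-shaped" = synthetic_spec(n_rois = 246L, n_timepoints = 150L,
                                    tr_seconds = 3, shift_rois = 1:20,
                                    seed = seed))
}

# loadings for one state; the case group's designated ROIs get the
# static offset added to the first factor column
.state_loadings <- function(spec) {
  lapply(seq_len(spec$n_states), function(k)
    matrix(rnorm(spec$n_rois * spec$factor_rank, sd = spec$loading_scale),
           spec$n_rois, spec$factor_rank))
}

.loadings_to_corr <- function(L, diag_noise) {
  S <- tcrossprod(L) + diag(diag_noise, nrow(L))
  stats::cov2cor(S)
}

#' Generate the latent state correlation matrices
#'
#' Each state is a valid correlation matrix built from random low-rank
#' loadings plus diagonal noise, rescaled to unit diagonal.  The set is
#' resampled (bounded retries) until every pairwise Frobenius distance
#' exceeds the spec's floor, so states are distinguishable.
#'
#' @param spec a [synthetic_spec()].
#' @param group `"case"` or `"control"`: the case group's designated
#'   ROIs carry the static loading shift.
#' @param max_retries resampling attempts (default 50).
#' @return list with `corr` (list of K correlation matrices), `chol`
#'   (their Cholesky factors) and `loadings`.
#' @export
make_states <- function(spec, group = "control", max_retries = 50L) {
  set.seed(spec$seed)
  for (attempt in seq_len(max_retries)) {
    loadings <- .state_loadings(spec)
    if (group == "case" && spec$static_strength_shift != 0)
      loadings <- lapply(loadings, function(L) {
        # amplify the designated ROIs' factor participation in the
        # direction they already load, so their |correlation| to the
        # rest of the factor rises regardless of loading sign
        sgn <- ifelse(L[spec$shift_rois, 1L] >= 0, 1, -1)
        L[spec$shift_rois, 1L] <- L[spec$shift_rois, 1L] +
          sgn * spec$static_strength_shift
        L
      })
    corr <- lapply(loadings, .loadings_to_corr, spec$diag_noise)
    ok <- TRUE
    if (spec$n_states > 1L) {
      for (a in seq_len(spec$n_states - 1L))
        for (b in (a + 1L):spec$n_states)
          if (norm(corr[[a]] - corr[[b]], "F") < spec$min_state_distance)
            ok <- FALSE
    }
    if (ok)
      return(list(corr = corr, chol = lapply(corr, chol),
                  loadings = loadings))
  }
  dfcp_error("could not generate sufficiently separated states",
             "dfcp_config_error")
}

#' Sample a latent state sequence with target occupancy
#'
#' Semi-Markov sampling: state dwells are `dwell_min` plus a geometric
#' tail, with expected dwell in state k proportional to the target
#' occupancy (`dwell_mean * n_states * occupancy_k`), floored at
#' `dwell_min + 1`.  Successor states are drawn uniformly among the
#' other states, so expected time-occupancy equals the target.
#'
#' @param occupancy target occupancy vector (sums to 1).
#' @param n_timepoints sequence length.
#' @param dwell_min,dwell_mean dwell parameters in samples.
#' @return integer state sequence of length `n_timepoints`.
#' @export
state_sequence <- function(occupancy, n_timepoints, dwell_min = 14L,
                           dwell_mean = 25) {
  K <- length(occupancy)
  target_dwell <- pmax(dwell_mean * K * occupancy, dwell_min + 1)
  s <- sample.int(K, 1L, prob = occupancy)
  seqv <- integer(0)
  while (length(seqv) < n_timepoints) {
    extra_mean <- target_dwell[s] - dwell_min
    dwell <- dwell_min + rgeom(1L, prob = 1 / (1 + extra_mean))
    seqv <- c(seqv, rep(s, dwell))
    if (K > 1L) {
      others <- setdiff(seq_len(K), s)
      s <- others[sample.int(length(others), 1L)]
    }
  }
  seqv[seq_len(n_timepoints)]
}

#' Simulate one subject's ROI time series
#'
#' @param spec a [synthetic_spec()].
#' @param group `"case"` or `"control"`.
#' @param seed per-subject seed.
#' @param subject_id subject identifier.
#' @param states precomputed [make_states()] output for this group
#'   (generated from the spec seed when omitted).
#' @return an [roi_ts()] with attribute `ground_truth`: list with the
#'   latent `states` sequence and empirical `occupancy`.
#' @export
simulate_subject <- function(spec, group, seed,
                             subject_id = sprintf("%s_%d", group, seed),
                             states = NULL) {
  if (is.null(states)) states <- make_states(spec, group)
  set.seed(seed)
  sq <- state_sequence(
    if (group == "case") spec$occupancy_case else spec$occupancy_control,
    spec$n_timepoints, spec$dwell_min, spec$dwell_mean)
  N <- spec$n_rois
  X <- matrix(0, spec$n_timepoints, N)
  for (k in seq_len(spec$n_states)) {
    idx <- which(sq == k)
    if (length(idx))
      X[idx, ] <- matrix(rnorm(length(idx) * N), length(idx), N) %*%
        states$chol[[k]]
  }
  if (spec$noise_sd > 0)
    X <- X + matrix(rnorm(length(X), sd = spec$noise_sd), nrow(X))
  ts <- roi_ts(X, spec$tr_seconds, subject_id, group, cohort = "synthetic")
  attr(ts, "ground_truth") <- list(
    states = sq, occupancy = tabulate(sq, spec$n_states) / length(sq))
  ts
}

#' Simulate a two-group cohort
#'
#' Generates `n_subjects_per_group` subjects per group with per-subject
#' seeds derived from the master seed (fully reproducible).
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_cohort`: `cohort` (list of
#'   [roi_ts()]), `ground_truth` (per-subject latent occupancy, state
#'   matrices per group, designated shift ROIs) and `spec`.
#' @export
simulate_cohort <- function(spec = synthetic_spec()) {
  states <- list(case = make_states(spec, "case"),
                 control = make_states(spec, "control"))
  n <- spec$n_subjects_per_group
  cohort <- list(); occ <- list()
  i <- 0L
  for (group in c("case", "control")) {
    for (j in seq_len(n)) {
      i <- i + 1L
      sid <- sprintf("%s_%02d", group, j)
      ts <- simulate_subject(spec, group, seed = spec$seed + 977L * i,
                             subject_id = sid, states = states[[group]])
      cohort[[i]] <- ts
      occ[[i]] <- data.frame(subject_id = sid, group = group,
                             t(attr(ts, "ground_truth")$occupancy))
    }
  }
  occ <- do.call(rbind, occ)
  names(occ)[-(1:2)] <- paste0("occupancy_", seq_len(spec$n_states))
  structure(list(cohort = cohort,
                 ground_truth = list(occupancy = occ,
                                     states = states,
                                     shift_rois = spec$shift_rois),
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "Synthetic cohort: %d + %d subjects, %d ROIs, T = %d (TR %g s), %d states\n",
    s$n_subjects_per_group, s$n_subjects_per_group, s$n_rois,
    s$n_timepoints, s$tr_seconds, s$n_states))
  cat(sprintf("  occupancy case %s vs control %s; static shift %g on %d ROIs\n",
              paste(s$occupancy_case, collapse = "/"),
              paste(s$occupancy_control, collapse = "/"),
              s$static_strength_shift, length(s$shift_rois)))
  invisible(x)
}

#' Write a synthetic cohort to disk in the package's exchange format
#'
#' Per-subject TSV matrix + JSON sidecar, a manifest TSV, and a ground
#' truth JSON (latent occupancies, shift ROIs, spec).
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(sim$cohort, function(ts) {
    f <- paste0(ts$subject_id, ".tsv")
    write_roi_timeseries(ts, file.path(dir, f))
    data.frame(subject_id = ts$subject_id, group = ts$group,
               timeseries = f, sidecar = paste0(ts$subject_id, ".json"))
  })
  manifest <- file.path(dir, "manifest.tsv")
  write.table(do.call(rbind, rows), manifest, sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(occupancy = sim$ground_truth$occupancy,
         shift_rois = sim$ground_truth$shift_rois,
         spec = unclass(sim$spec)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
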