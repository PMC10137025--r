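#' Construct a validated ROI time-series object
#'
#' An `roi_ts` object holds one subject's ROI-averaged resting-state
#' time series as a T x N numeric matrix (rows are time points, columns
#' are regions of interest), together with the repetition time and
#' subject metadata.
#'
#' @param values numeric matrix, T time points x N ROIs; no missing values.
#' @param tr_seconds positive repetition time in seconds.
#' @param subject_id subject identifier string.
#' @param group `"case"` or `"control"`.
#' @param cohort optional cohort label (e.g. scanner/site).
#' @return an object of class `roi_ts`.
#' @examples
#' ts <- roi_ts(matrix(rnorm(60), 20, 3), tr_seconds = 2, subject_id = "s1",
#'              group = "control")
#' dim(ts$values)
#' @export
roi_ts <- function(values, tr_seconds, subject_id, group,
                   cohort = "default") {
  values <- as.matrix(values)
  if (!is.numeric(values))
    dfcp_error("time-series values must be numeric", "dfcp_parse_error")
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    dfcp_error(sprintf(
      "non-finite value in time series at row %d, column %d",
      bad[1L], bad[2L]), "dfcp_parse_error")
  }
  if (nrow(values) < 2L)
    dfcp_error("time series needs at least 2 time points",
               "dfcp_validation_error")
  if (ncol(values) < 2L)
    dfcp_error("time series needs at least 2 ROIs", "dfcp_validation_error")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L ||
      !is.finite(tr_seconds) || tr_seconds <= 0)
    dfcp_error("tr_seconds must be a single positive number",
               "dfcp_metadata_error")
  group <- match.arg(group, c("case", "control"))
  structure(list(values = values, tr_seconds = as.numeric(tr_seconds),
                 subject_id = as.character(subject_id), group = group,
                 cohort = as.character(cohort)),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("ROI time series: subject %s (%s, cohort %s)\n",
              x$subject_id, x$group, x$cohort))
  cat(sprintf("  %d time points x %d ROIs, TR = %g s (%.1f s scan)\n",
              nrow(x$values), ncol(x$values), x$tr_seconds,
              nrow(x$values) * x$tr_seconds))
  invisible(x)
}

#' Read an ROI time series from a delimited matrix plus JSON sidecar
#'
#' The matrix file is whitespace/tab-delimited with rows as time points
#' and columns as ROIs (time-major).  The sidecar is a JSON object with
#' at least `tr_seconds`, `subject_id` and `group`; it may also carry
#' `cohort` and `orientation` (`"time_by_roi"`, the default, or
#' `"roi_by_time"` to declare a transposed matrix).  Square matrices are
#' rejected as ambiguous unless the sidecar declares the orientation.
#'
#' @param path path to the numeric matrix (TSV/CSV; delimiter sniffed).
#' @param metadata path to the JSON sidecar.  Defaults to `path` with the
#'   extension replaced by `.json`.
#' @return an [roi_ts()] object.
#' @export
read_roi_timeseries <- function(path, metadata = NULL) {
  if (is.null(metadata))
    metadata <- paste0(sub("\\.[^.]+$", "", path), ".json")
  if (!file.exists(path))
    dfcp_error(sprintf("time-series file not found: %s", path),
               "dfcp_parse_error")
  if (!file.exists(metadata))
    dfcp_error(sprintf("metadata sidecar not found: %s", metadata),
               "dfcp_metadata_error")
  meta <- jsonlite::read_json(metadata, simplifyVector = TRUE)
  if (is.null(meta$tr_seconds))
    dfcp_error("sidecar lacks tr_seconds", "dfcp_metadata_error")
  if (is.null(meta$subject_id) || is.null(meta$group))
    dfcp_error("sidecar lacks subject_id or group", "dfcp_metadata_error")

  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- tryCatch(
    read.table(path, sep = sep, header = FALSE,
               colClasses = "numeric", comment.char = ""),
    error = function(e) dfcp_error(
      sprintf("cannot parse %s as a numeric matrix: %s",
              path, conditionMessage(e)), "dfcp_parse_error"))
  m <- as.matrix(df)
  dimnames(m) <- NULL
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    dfcp_error(sprintf("missing/non-numeric cell at row %d, column %d of %s",
                       bad[1L], bad[2L], path), "dfcp_parse_error")
  }
  orientation <- meta$orientation
  if (nrow(m) == ncol(m) && is.null(orientation))
    dfcp_error(paste0("square matrix is ambiguous: declare 'orientation' ",
                      "(time_by_roi or roi_by_time) in the sidecar"),
               "dfcp_metadata_error")
  if (!is.null(orientation)) {
    orientation <- match.arg(orientation, c("time_by_roi", "roi_by_time"))
    if (orientation == "roi_by_time") m <- t(m)
  }
  roi_ts(m, tr_seconds = meta$tr_seconds, subject_id = meta$subject_id,
         group = meta$group,
         cohort = if (is.null(meta$cohort)) "default" else meta$cohort)
}

#' Write an ROI time series (matrix + JSON sidecar)
#'
#' @param ts an [roi_ts()] object.
#' @param path output path for the TSV matrix; the sidecar is written next
#'   to it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_ts"))
  # 17 significant digits so the double round-trips bit-identically
  chr <- matrix(sprintf("%.17g", ts$values), nrow(ts$values))
  write.table(chr, path, sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  meta <- list(tr_seconds = ts$tr_seconds, subject_id = ts$subject_id,
               group = ts$group, cohort = ts$cohort,
               orientation = "time_by_roi")
  jsonlite::write_json(meta, paste0(sub("\\.[^.]+$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-subject feature vectors to TSV
#'
#' One row per subject, with stable column names `ratio_1..K`,
#' `mbeta_1..K`, optionally `sfcs_1..N`, plus `subject_id` and `group`.
#'
#' @param vectors list of feature vectors as produced by [dfcp_features()]
#'   (each a list with `ratios`, `mean_betas`, optional `sfc_strength`,
#'   `subject_id`, `group`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(vectors, path) {
  if (length(vectors) == 0L) {
    writeLines("subject_id\tgroup", path)
    return(invisible(path))
  }
  dims <- vapply(vectors, function(v)
    c(length(v$ratios), length(v$mean_betas), length(v$sfc_strength)),
    integer(3))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]) ||
      any(dims[3, ] != dims[3, 1]))
    dfcp_error("feature vectors have mixed dimensionality",
               "dfcp_shape_error")
  K <- dims[1, 1]; N <- dims[3, 1]
  rows <- lapply(vectors, function(v) {
    num <- c(v$ratios, v$mean_betas, v$sfc_strength)
    data.frame(subject_id = v$subject_id, group = v$group,
               t(sprintf("%.17g", num)))
  })
  df <- do.call(rbind, rows)
  nm <- c("subject_id", "group",
          if (K > 0) paste0("ratio_", seq_len(K)),
          if (K > 0) paste0("mbeta_", seq_len(K)),
          if (N > 0) paste0("sfcs_", seq_len(N)))
  names(df) <- nm
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read feature vectors written by [write_features()]
#'
#' @param path TSV path.
#' @return a data.frame with subject_id, group and feature columns.
#' @export
read_features <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Read a cohort from a manifest
#'
#' The manifest is a TSV with columns `timeseries` and `sidecar` holding
#' paths (absolute, or relative to the manifest's directory).
#'
#' @param manifest path to the manifest TSV.
#' @return list of [roi_ts()] objects.
#' @export
read_cohort <- function(manifest) {
  mf <- read.table(manifest, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  if (!all(c("timeseries", "sidecar") %in% names(mf)))
    dfcp_error("manifest needs 'timeseries' and 'sidecar' columns",
               "dfcp_parse_error")
  base <- dirname(manifest)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  lapply(seq_len(nrow(mf)), function(i)
    read_roi_timeseries(resolve(mf$timeseries[i]), resolve(mf$sidecar[i])))
}
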