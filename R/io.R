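#' Read and write the pipeline's delimited text formats
#'
#' Plain CSV with unit-bearing column names: IPD tables
#' (\code{subject_id,arm,endpoint,time_days,event}), digitised curves
#' (\code{time_days,survival}) and number-at-risk tables
#' (\code{time_days,n_at_risk}).
#'
#' @param x object to write.
#' @param path file path.
#' @return readers return a \code{data.frame}; writers return \code{path}
#'   invisibly.
#' @name pipeline-io
NULL

write_table_checked <- function(x, path, cols) {
  stopifnot(all(cols %in% names(x)))
  utils::write.csv(x[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

read_table_checked <- function(path, cols) {
  x <- utils::read.csv(path)
  if (!all(cols %in% names(x))) {
    stop("file ", path, " lacks required columns: ",
         paste(setdiff(cols, names(x)), collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname pipeline-io
#' @export
write_ipd <- function(x, path) {
  write_table_checked(x, path,
                      c("subject_id", "arm", "endpoint", "time_days",
                        "event"))
}

#' @rdname pipeline-io
#' @export
read_ipd <- function(path) {
  read_table_checked(path, c("subject_id", "arm", "endpoint", "time_days",
                             "event"))
}

#' @rdname pipeline-io
#' @export
write_curve <- function(x, path) {
  write_table_checked(x, path, c("time_days", "survival"))
}

#' @rdname pipeline-io
#' @export
read_curve <- function(path) {
  read_table_checked(path, c("time_days", "survival"))
}

#' @rdname pipeline-io
#' @export
write_risk_table <- function(x, path) {
  write_table_checked(x, path, c("time_days", "n_at_risk"))
}

#' @rdname pipeline-io
#' @export
read_risk_table <- function(path) {
  read_table_checked(path, c("time_days", "n_at_risk"))
}

#' Emit synthetic trial artefacts to a directory
#'
#' Writes, for each arm and endpoint of a simulated trial, the IPD slice,
#' the digitised Kaplan-Meier curve and the number-at-risk table — the
#' three file kinds the reconstruction stage consumes.
#'
#' @param ipd IPD table from \code{\link{simulate_trial}}.
#' @param out_dir output directory (created if needed).
#' @param grid_step digitisation grid in days.
#' @param jitter_sd digitisation noise SD.
#' @param risk_interval_days risk-table spacing in days.
#' @return named list of written file paths, invisibly.
#' @export
write_trial_artifacts <- function(ipd, out_dir, grid_step = 7,
                                  jitter_sd = 0,
                                  risk_interval_days = months_to_days(6)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (arm in unique(ipd$arm)) {
    for (ep in unique(ipd$endpoint)) {
      tag <- paste0(arm, "_", ep)
      km <- km_estimate(ipd, arm, ep)
      paths[[paste0("ipd_", tag)]] <- write_ipd(
        ipd[ipd$arm == arm & ipd$endpoint == ep, ],
        file.path(out_dir, paste0("ipd_", tag, ".csv")))
      paths[[paste0("curve_", tag)]] <- write_curve(
        digitize_curve(km, grid_step, jitter_sd),
        file.path(out_dir, paste0("curve_", tag, ".csv")))
      paths[[paste0("risk_", tag)]] <- write_risk_table(
        make_risk_table(ipd, arm, ep, risk_interval_days),
        file.path(out_dir, paste0("risk_", tag, ".csv")))
    }
  }
  invisible(paths)
}
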