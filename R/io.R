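# Delimited-text I/O for ROI timeseries, FC tables and posterior ensembles.
# All files are tab-separated with a mandatory header row; ensembles carry a
# JSON sidecar with priors and provenance.

#' Read ROI-averaged timeseries
#'
#' Expects a tab-separated file with a `time` column (seconds) followed by
#' one column per region.
#'
#' @param path file path.
#' @return list with `times` and `series` (matrix, named columns).
#' @export
read_roi_timeseries <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  if (!"time" %in% names(d)) stop("missing 'time' column in ", path)
  series <- as.matrix(d[, setdiff(names(d), "time"), drop = FALSE])
  if (anyNA(series)) stop("NaN/NA values in ROI timeseries ", path)
  list(times = d$time, series = series)
}

#' Write ROI-averaged timeseries
#' @param times numeric vector, seconds.
#' @param series matrix with region column names.
#' @param path file path.
#' @export
write_roi_timeseries <- function(times, series, path) {
  d <- data.frame(time = times, series, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an FC table
#'
#' One row per subject or simulation, columns in the canonical edge order.
#'
#' @param fc matrix with edge column names.
#' @param path file path.
#' @export
write_fc_table <- function(fc, path) {
  fc <- as.matrix(fc)
  if (is.null(colnames(fc))) stop("fc must carry edge column names")
  utils::write.table(as.data.frame(fc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an FC table
#'
#' Validates the header against the expected canonical edge set.
#'
#' @param path file path.
#' @param regions optional region labels; when given, the file must contain
#'   exactly the canonical edges of those regions, in order.
#' @return numeric matrix.
#' @export
read_fc_table <- function(path, regions = NULL) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d)
  if (!is.null(regions)) {
    want <- canonical_edge_order(regions)
    if (!identical(colnames(m), want)) {
      bad <- c(setdiff(colnames(m), want), setdiff(want, colnames(m)))
      stop("FC table header mismatch in ", path, ": expected ",
           length(want), " canonical edges; offending column(s): ",
           paste(bad, collapse = ", "))
    }
  }
  if (anyNA(m)) stop("NaN/NA values in FC table ", path)
  m
}

#' Write a posterior ensemble
#'
#' Particles (and their fitness values) as a delimited table plus a JSON
#' metadata sidecar (`<path>.json`) holding the priors, seeds, generations
#' and threshold schedule.
#'
#' @param ensemble a `posterior_ensemble`.
#' @param path table path.
#' @export
write_posterior <- function(ensemble, path) {
  d <- data.frame(ensemble$theta, eps = ensemble$eps, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(priors = ensemble$priors[, c("name", "lower", "upper")],
               seed = ensemble$seed, generations = ensemble$generations,
               eps_schedule = ensemble$eps_schedule,
               converged = ensemble$converged, n_failed = ensemble$n_failed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a posterior ensemble written by [write_posterior()]
#' @param path table path (the sidecar `<path>.json` must exist).
#' @return a `posterior_ensemble`.
#' @export
read_posterior <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  theta <- as.matrix(d[, setdiff(names(d), "eps"), drop = FALSE])
  priors <- prior_specification(meta$priors$name, meta$priors$lower,
                                meta$priors$upper)
  ens <- posterior_ensemble(theta, priors, eps = d$eps)
  ens$seed <- meta$seed
  ens$generations <- meta$generations
  ens$eps_schedule <- as.numeric(meta$eps_schedule)
  ens$converged <- meta$converged
  ens
}
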