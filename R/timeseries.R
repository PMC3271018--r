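#' ROI time-series container
#'
#' A numeric matrix (time x region) with region names, sampling interval and
#' subject/group metadata.
#'
#' @param values numeric matrix, one column per region, no missing values
#' @param region_names unique region labels (defaults to column names)
#' @param TR sampling interval in seconds
#' @param subject_id subject identifier
#' @param group_label group identifier
#' @return an object of class `roi_timeseries`
#' @export
roi_timeseries <- function(values, region_names = colnames(values), TR = 2,
                           subject_id = NA_character_,
                           group_label = NA_character_) {
  values <- as.matrix(values)
  if (is.null(region_names)) {
    region_names <- paste0("R", seq_len(ncol(values)))
  }
  if (ncol(values) < 2) stopf("at least 2 regions are required")
  if (anyDuplicated(region_names)) stopf("region names must be unique")
  if (length(region_names) != ncol(values)) {
    stopf("length(region_names) must equal ncol(values)")
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stopf("time series must be finite with no missing samples")
  }
  colnames(values) <- region_names
  structure(list(values = values, region_names = region_names, TR = TR,
                 subject_id = subject_id, group_label = group_label),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d samples x %d regions, TR %g s (%s, %s)\n",
              nrow(x$values), ncol(x$values), x$TR,
              x$subject_id, x$group_label))
  invisible(x)
}

#' Detrend and demean ROI time series
#'
#' Removes, per region, a linear trend and the temporal mean (the residual
#' of an ordinary least-squares fit on time). This is the standard
#' preparation step before any causal or connectivity estimation in the
#' package; it is idempotent up to numerical tolerance.
#'
#' @param ts an `roi_timeseries` (or plain matrix)
#' @return object of the same type with detrended, zero-mean columns
#' @export
preprocess_timeseries <- function(ts) {
  mat <- if (inherits(ts, "roi_timeseries")) ts$values else as.matrix(ts)
  n <- nrow(mat)
  tt <- seq_len(n)
  X <- cbind(1, tt - mean(tt))
  const <- apply(mat, 2, function(col) var(col) < .Machine$double.eps)
  if (any(const)) {
    warnf("constant region series detrended to zero: %s",
          paste(colnames(mat)[const], collapse = ", "))
  }
  beta <- solve(crossprod(X), crossprod(X, mat))
  out <- mat - X %*% beta
  if (inherits(ts, "roi_timeseries")) {
    ts$values <- out
    ts
  } else {
    out
  }
}

#' Read / write ROI time-series tables
#'
#' Tab-delimited text: header row of region names, one row per TR sample.
#'
#' @param ts an `roi_timeseries`
#' @param path file path
#' @param TR,subject_id,group_label metadata applied when reading
#' @return `read_timeseries` returns an `roi_timeseries`
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  df <- as.data.frame(ts$values)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path, TR = 2, subject_id = NA_character_,
                            group_label = NA_character_) {
  df <- read.delim(path, check.names = FALSE)
  roi_timeseries(as.matrix(df), TR = TR, subject_id = subject_id,
                 group_label = group_label)
}
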