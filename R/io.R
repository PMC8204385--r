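# Sensorgram container and plain-text I/O.  Biacore exports are delimited
# text; no vendor binary formats are read.

#' Construct a sensorgram
#'
#' @param time sampling times in s, strictly increasing, no NAs.
#' @param signal response in instrument units (RU), no NAs.
#' @param metadata optional list (conditions, flow-cell label,
#'   reference-subtracted flag, ground truth for synthetic traces, ...).
#' @return data.frame of class \code{"spr_trace"}.
#' @export
spr_trace <- function(time, signal, metadata = list()) {
  time <- as.double(time); signal <- as.double(signal)
  if (length(time) != length(signal))
    stop("time and signal must have equal length")
  if (anyNA(time) || anyNA(signal)) {
    bad <- which(is.na(time) | is.na(signal))[1]
    stop("NA in sensorgram at row ", bad)
  }
  if (is.unsorted(time, strictly = TRUE)) {
    bad <- which(diff(time) <= 0)[1] + 1L
    stop("times must be strictly increasing (violated at row ", bad, ")")
  }
  structure(data.frame(time = time, signal = signal),
            metadata = metadata, class = c("spr_trace", "data.frame"))
}

#' Read a sensorgram from delimited text
#'
#' Accepts a headerless two-column CSV or a tab-separated export with a
#' header line; the two dialects parse to identical traces.  The first
#' column is time in seconds, the second the SPR response.
#'
#' @param path file path.
#' @param dialect \code{"csv"} (headerless, comma) or \code{"tsv"}
#'   (tab-separated, header).
#' @return an [spr_trace()].
#' @export
read_sensorgram <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  d <- switch(dialect,
              csv = read.table(path, sep = ",", header = FALSE),
              tsv = read.table(path, sep = "\t", header = TRUE))
  if (ncol(d) < 2) stop("expected two columns (time, signal) in ", path)
  spr_trace(d[[1]], d[[2]], metadata = list(source = path))
}

#' Write a sensorgram as delimited text
#'
#' @param trace an [spr_trace()].
#' @param path output path.
#' @param dialect see [read_sensorgram()].
#' @return \code{path}, invisibly.
#' @export
write_sensorgram <- function(trace, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         csv = write.table(trace[, c("time", "signal")], path, sep = ",",
                           row.names = FALSE, col.names = FALSE),
         tsv = write.table(trace[, c("time", "signal")], path, sep = "\t",
                           row.names = FALSE, col.names = TRUE, quote = FALSE))
  invisible(path)
}
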