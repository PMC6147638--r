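#' Multichannel time-series set
#'
#' Container for a channels x samples matrix of simultaneously recorded
#' signals plus its sampling rate. Band-filtered sets carry the band they
#' were filtered to; surrogate sets are flagged as such.
#'
#' @param values Numeric matrix, rows = channels, columns = samples; all
#'   values must be finite.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_ids Optional character vector of channel labels; defaults
#'   to `ch01, ch02, ...`.
#' @param band Optional [frequency_band()] the set has been filtered to.
#' @return An object of class `"ts_set"`.
#' @examples
#' ts_set(matrix(rnorm(40), 4), sampling_rate = 100)
#' @export
ts_set <- function(values, sampling_rate, channel_ids = NULL, band = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix (channels x samples)")
  if (!all(is.finite(values)))
    stopf("`values` contains non-finite entries")
  sampling_rate <- check_scalar(sampling_rate, "sampling_rate")
  if (sampling_rate <= 0) stopf("`sampling_rate` must be > 0")
  n <- nrow(values)
  if (is.null(channel_ids))
    channel_ids <- sprintf("ch%02d", seq_len(n))
  if (length(channel_ids) != n)
    stopf("`channel_ids` length must equal the number of channels")
  if (!is.null(band) && !inherits(band, "freq_band"))
    stopf("`band` must be a freq_band or NULL")
  rownames(values) <- channel_ids
  structure(
    list(values = values, sampling_rate = sampling_rate,
         channel_ids = channel_ids, band = band),
    class = "ts_set")
}

#' @export
print.ts_set <- function(x, ...) {
  cat(sprintf("<ts_set> %d channels x %d samples @ %.4g Hz%s\n",
              nrow(x$values), ncol(x$values), x$sampling_rate,
              if (is.null(x$band)) "" else paste0(" [", x$band$name, "]")))
  invisible(x)
}

n_samples <- function(ts) ncol(ts$values)
n_channels <- function(ts) nrow(ts$values)

#' Write signals to delimited text plus a JSON sidecar
#'
#' Writes `<prefix>.tsv` (rows = channels, tab-separated, no header) and
#' `<prefix>.json` holding the sampling rate, channel names and any extra
#' metadata, so a signal set round-trips losslessly through text files.
#'
#' @param ts A [ts_set()].
#' @param prefix Output path prefix (without extension).
#' @param extra Optional list of additional metadata stored in the sidecar.
#' @return Invisibly, the two file paths.
#' @seealso [read_signals()]
#' @export
write_signals <- function(ts, prefix, extra = list()) {
  stopifnot(inherits(ts, "ts_set"))
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".json")
  utils::write.table(format(ts$values, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- c(list(sampling_rate = ts$sampling_rate,
                 channel_ids = ts$channel_ids,
                 band = if (!is.null(ts$band))
                   list(name = ts$band$name, low = ts$band$low,
                        high = ts$band$high)),
            extra)
  jsonlite::write_json(meta, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' Read signals written by [write_signals()]
#'
#' @param prefix Path prefix used when writing.
#' @return A [ts_set()]; extra sidecar metadata is attached as the
#'   `"meta"` attribute.
#' @export
read_signals <- function(prefix) {
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".json")
  if (!file.exists(tsv) || !file.exists(js))
    stopf("missing %s or %s", tsv, js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(tsv, sep = "\t", header = FALSE))
  dimnames(vals) <- NULL
  band <- NULL
  if (is.character(meta$band$name))
    band <- frequency_band(meta$band$name, meta$band$low, meta$band$high)
  out <- ts_set(vals, meta$sampling_rate, meta$channel_ids, band)
  attr(out, "meta") <- meta
  out
}
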