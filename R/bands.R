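#' Frequency band
#'
#' A named frequency interval in Hz. The canonical bands of resting-state
#' M/EEG work are provided by [default_bands()]: theta \[3, 8\] Hz,
#' alpha \[8, 12\] Hz, beta \[12, 30\] Hz and gamma \[30, 100\] Hz.
#'
#' @param name Band label, e.g. `"alpha"`.
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return An object of class `"freq_band"` with fields `name`, `low`, `high`.
#' @examples
#' frequency_band("alpha", 8, 12)
#' @export
frequency_band <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  low <- check_scalar(low, "low")
  high <- check_scalar(high, "high")
  if (!(0 < low && low < high))
    stopf("band '%s': need 0 < low < high (got [%g, %g])", name, low, high)
  structure(list(name = name, low = low, high = high), class = "freq_band")
}

#' @export
print.freq_band <- function(x, ...) {
  cat(sprintf("<freq_band> %s [%g, %g] Hz\n", x$name, x$low, x$high))
  invisible(x)
}

#' Canonical frequency bands
#'
#' @param which Optional character vector selecting a subset (in the given
#'   order), e.g. `c("alpha", "beta")`.
#' @return Named list of [frequency_band()] objects.
#' @examples
#' default_bands(c("alpha", "beta"))
#' @export
default_bands <- function(which = NULL) {
  bands <- list(
    theta = frequency_band("theta", 3, 8),
    alpha = frequency_band("alpha", 8, 12),
    beta  = frequency_band("beta", 12, 30),
    gamma = frequency_band("gamma", 30, 100)
  )
  if (is.null(which)) return(bands)
  unknown <- setdiff(which, names(bands))
  if (length(unknown))
    stopf("unknown band(s): %s", paste(unknown, collapse = ", "))
  bands[which]
}
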