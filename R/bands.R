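#' The seven canonical analysis bands
#'
#' Returns the standard frequency decomposition used throughout the package:
#' slow wave (0.1--1 Hz), delta (1--4 Hz), theta (4--8 Hz), alpha (8--12 Hz),
#' beta (12--30 Hz), gamma (30--80 Hz) and ripple (80--250 Hz).  Band edges
#' are contiguous above the 0.1 Hz floor; the ripple band requires a
#' sampling rate above 500 Hz.
#'
#' @return A data frame with columns `name`, `lo`, `hi` (Hz), one row per
#'   band, in ascending frequency order.
#' @examples
#' default_bands()
#' @export
default_bands <- function() {
  data.frame(
    name = c("slow", "delta", "theta", "alpha", "beta", "gamma", "ripple"),
    lo   = c(0.1, 1, 4, 8, 12, 30, 80),
    hi   = c(1, 4, 8, 12, 30, 80, 250),
    stringsAsFactors = FALSE
  )
}

#' Construct or coerce a band specification
#'
#' @param x A band name from [default_bands()], a list with `name`, `lo`,
#'   `hi`, or a one-row data frame with those columns.
#' @param lo,hi Optional band edges in Hz when `x` is a new band name.
#' @return A one-row data frame with columns `name`, `lo`, `hi`.
#' @export
as_band <- function(x, lo = NULL, hi = NULL) {
  if (is.character(x) && length(x) == 1L && is.null(lo)) {
    bands <- default_bands()
    idx <- match(x, bands$name)
    if (is.na(idx)) stop("unknown band name: ", x)
    return(bands[idx, , drop = FALSE])
  }
  if (is.character(x) && length(x) == 1L) {
    band <- data.frame(name = x, lo = lo, hi = hi, stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("band must be a single row")
    band <- x[, c("name", "lo", "hi")]
  } else if (is.list(x)) {
    band <- data.frame(name = x$name, lo = x$lo, hi = x$hi,
                       stringsAsFactors = FALSE)
  } else {
    stop("cannot interpret band specification")
  }
  if (!is.finite(band$lo) || !is.finite(band$hi) ||
      band$lo <= 0 || band$hi <= band$lo)
    stop("band edges must satisfy 0 < lo < hi")
  band
}

# Nyquist validity of a set of bands at a given sampling rate.
check_bands_nyquist <- function(bands, sampling_rate) {
  bad <- bands$hi >= sampling_rate / 2
  if (any(bad))
    stop("band(s) ", paste(bands$name[bad], collapse = ", "),
         " violate the Nyquist limit at sampling rate ", sampling_rate,
         " Hz (need hi < ", sampling_rate / 2, " Hz)")
  invisible(TRUE)
}
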