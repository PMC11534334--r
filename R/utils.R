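#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal of a real vector (the signal plus i
#' times its Hilbert transform), computed by zeroing negative frequencies of
#' the FFT. Its modulus is the instantaneous amplitude envelope used for
#' spindle thresholding.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  if (!is.numeric(x)) stopf("analytic_signal() expects a numeric vector")
  n <- length(x)
  if (n == 0L) return(complex(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Local extrema of a sampled signal
#'
#' Locates strict local maxima and minima from sign changes of the first
#' difference; plateaus (runs of equal samples between opposite slopes) are
#' resolved to their midpoint sample.
#'
#' @param x numeric vector.
#' @return list with integer index vectors `maxima` and `minima`.
#' @export
local_extrema <- function(x) {
  n <- length(x)
  out <- list(maxima = integer(0), minima = integer(0))
  if (n < 3L) return(out)
  s <- sign(diff(x))
  r <- rle(s)
  ends <- cumsum(r$lengths)          # index into s; sample index = ends + 1
  starts <- ends - r$lengths + 1L
  last_val <- 0
  last_end <- 0L
  maxima <- integer(0)
  minima <- integer(0)
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    if (v == 0) next
    if (last_val != 0 && v != last_val) {
      # extremum between sample (last_end + 1) and sample starts[k]
      idx <- as.integer(floor((last_end + 1L + starts[k]) / 2))
      if (last_val > 0) maxima <- c(maxima, idx) else minima <- c(minima, idx)
    }
    last_val <- v
    last_end <- ends[k]
  }
  list(maxima = maxima, minima = minima)
}

#' Linear detrend of a vector
#'
#' Removes the least-squares straight line; used per channel when epoching.
#' @param x numeric vector.
#' @return detrended vector.
#' @keywords internal
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2L) return(x - mean(x))
  t <- seq_len(n) - (n + 1) / 2
  x - mean(x) - t * (sum(t * x) / sum(t * t))
}

# derive a reproducible 32-bit sub-seed from a base seed and a stream index
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2017L + as.integer(stream) * 7919L
}
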