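# Copy-number preparation: the logR -> absolute copy-number transform and
# running-median smoothing applied to segment input before deletion matching.

#' Convert logR to absolute total copy number
#'
#' Transforms a relative coverage logR value into copy-number space given
#' tumor purity \eqn{\rho} and ploidy \eqn{\psi}:
#' \deqn{n = \frac{(2(1-\rho) + \psi\rho)\,2^{logR} - 2(1-\rho)}{\rho}}
#' Negative results (possible for noisy logR at high purity) are floored at
#' zero with a warning.
#'
#' @param logR numeric vector of logR values.
#' @param rho tumor purity in (0, 1].
#' @param psi tumor ploidy (> 0).
#' @return numeric vector of total copy numbers.
#' @examples
#' logr_to_cn(0, rho = 1, psi = 2)   # 2: diploid identity
#' logr_to_cn(1, rho = 0.5, psi = 2) # 6
#' @export
logr_to_cn <- function(logR, rho, psi) {
  if (length(rho) != 1 || is.na(rho) || rho <= 0 || rho > 1)
    stop("rho must be a single value in (0, 1]")
  if (length(psi) != 1 || is.na(psi) || psi <= 0)
    stop("psi must be a single positive value")
  n <- ((2 * (1 - rho) + psi * rho) * 2^logR - 2 * (1 - rho)) / rho
  if (any(n < 0, na.rm = TRUE)) {
    warning(sum(n < 0, na.rm = TRUE), " negative copy-number value(s) floored at 0")
    n[!is.na(n) & n < 0] <- 0
  }
  n
}

#' Invert the copy-number transform back to logR
#'
#' @param n total copy number (>= 0).
#' @inheritParams logr_to_cn
#' @return numeric vector of logR values.
#' @export
cn_to_logr <- function(n, rho, psi) {
  log2((n * rho + 2 * (1 - rho)) / (2 * (1 - rho) + psi * rho))
}

#' Running-median smoothing of a logR (or any) series
#'
#' Centered running median with edge shrinkage (the window shrinks near the
#' series ends); length-preserving. Window must be odd.
#'
#' @param values numeric vector.
#' @param window odd positive integer window width (default 11 bins).
#' @return numeric vector of the same length.
#' @export
running_median <- function(values, window = 11L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be a positive odd integer")
  n <- length(values)
  if (window == 1L || n <= 2L) return(values)
  k <- min(window, if (n %% 2L == 1L) n else n - 1L)
  as.numeric(runmed(values, k = k, endrule = "median"))
}
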