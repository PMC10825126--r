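# Internal numeric helpers shared across modules.

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Trapezoidal integral over an ordered grid.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# log(1 + exp(x)) without overflow; log of the logistic normalizer.
#' @keywords internal
log1pexp <- function(x) {
  out <- numeric(length(x))
  big <- x > 35
  out[big] <- x[big]
  out[!big] <- log1p(exp(x[!big]))
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
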