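# von Mises distribution: density, random generation and mixtures.
# These are the circular building blocks for both the activity-overlap
# estimator (kernel and smoothed bootstrap) and the synthetic diel generator.

#' von Mises density
#'
#' Density of the von Mises distribution with mean direction `mu` and
#' concentration `kappa`, evaluated at angles in radians. Uses the
#' exponentially scaled Bessel function so large concentrations do not
#' overflow.
#'
#' @param theta numeric vector of angles (radians).
#' @param mu mean direction (radians).
#' @param kappa concentration, `kappa >= 0`; `kappa = 0` is the circular
#'   uniform density `1 / (2 * pi)`.
#' @return numeric vector of densities.
#' @export
dvonmises <- function(theta, mu, kappa) {
  stopifnot_scalar_number(mu, "mu")
  stopifnot_scalar_number(kappa, "kappa")
  if (kappa < 0) stop("'kappa' must be non-negative")
  if (kappa == 0) return(rep(1 / (2 * pi), length(theta)))
  # exp(kappa*cos(d)) / (2*pi*I0(kappa)) written with I0 scaled by exp(-kappa)
  exp(kappa * (cos(theta - mu) - 1)) /
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' von Mises random deviates
#'
#' Draws from the von Mises distribution by the Best-Fisher rejection
#' algorithm. Reproducible under `set.seed()`.
#'
#' @inheritParams dvonmises
#' @param n number of deviates.
#' @return numeric vector of angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot_scalar_number(mu, "mu")
  stopifnot_scalar_number(kappa, "kappa")
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0L) {
      theta <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      out[(got + 1L):(got + k)] <- (theta + mu) %% (2 * pi)
      got <- got + k
    }
  }
  out
}

#' Specify a von Mises mixture
#'
#' A finite mixture of von Mises components, used to describe diel activity
#' patterns (e.g. a bimodal nocturnal cycle).
#'
#' @param weight,mu,kappa equal-length numeric vectors: component weights
#'   (must sum to 1), mean directions (radians) and concentrations (> 0
#'   unless the component is circular-uniform with `kappa = 0`).
#' @return an object of class `vm_mixture`.
#' @export
vm_mixture <- function(weight, mu, kappa) {
  if (length(weight) != length(mu) || length(mu) != length(kappa))
    stop("'weight', 'mu' and 'kappa' must have the same length")
  if (any(weight < 0) || abs(sum(weight) - 1) > 1e-8)
    stop("mixture weights must be non-negative and sum to 1")
  if (any(kappa < 0)) stop("'kappa' must be non-negative")
  structure(list(weight = weight, mu = mu %% (2 * pi), kappa = kappa),
            class = "vm_mixture")
}

#' @export
print.vm_mixture <- function(x, ...) {
  cat("von Mises mixture with", length(x$weight), "component(s)\n")
  print(data.frame(weight = x$weight, mu = x$mu, kappa = x$kappa))
  invisible(x)
}

#' Density of a von Mises mixture
#'
#' @param theta angles in radians.
#' @param mixture a [vm_mixture()].
#' @return numeric vector of densities.
#' @export
dvm_mixture <- function(theta, mixture) {
  stopifnot(inherits(mixture, "vm_mixture"))
  dens <- numeric(length(theta))
  for (k in seq_along(mixture$weight))
    dens <- dens + mixture$weight[k] *
      dvonmises(theta, mixture$mu[k], mixture$kappa[k])
  dens
}

#' Random deviates from a von Mises mixture
#'
#' @inheritParams dvm_mixture
#' @param n number of deviates.
#' @return angles in `[0, 2*pi)`.
#' @export
rvm_mixture <- function(n, mixture) {
  stopifnot(inherits(mixture, "vm_mixture"))
  comp <- sample.int(length(mixture$weight), n, replace = TRUE,
                     prob = mixture$weight)
  out <- numeric(n)
  for (k in unique(comp)) {
    idx <- comp == k
    out[idx] <- rvonmises(sum(idx), mixture$mu[k], mixture$kappa[k])
  }
  out
}

# ML estimate of the von Mises concentration from the mean resultant length,
# by solving A1(kappa) = Rbar. Capped at kmax (the smoothing convention for
# activity data caps the pilot estimate at 3).
#' @keywords internal
fit_kappa_ml <- function(theta, kmax = 3) {
  rbar <- sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
  a1 <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  if (rbar >= a1(kmax)) return(kmax)
  if (rbar < 1e-12) return(1e-12)
  stats::uniroot(function(k) a1(k) - rbar, c(1e-10, kmax),
                 tol = 1e-10)$root
}
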