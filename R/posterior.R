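# Posterior summaries: moments, credible intervals, split-chain Rhat,
# autocorrelation ESS, and the derived per-site psi/p quantities.

# Split-chain Gelman-Rubin potential scale reduction for one parameter.
# Each chain is halved; Rhat = sqrt(((L-1)/L * W + B/L) / W). Identical
# constant chains give 1 by convention.
#' @keywords internal
rhat_split <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    L <- floor(length(x) / 2)
    list(x[seq_len(L)], x[L + seq_len(L)])
  }), recursive = FALSE)
  L <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- L * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((L - 1) / L * W + B / L) / W)
}

# Effective sample size by the initial-positive-sequence truncation of the
# chain-averaged autocorrelation function (Geyer-style), capped at the total
# draw count.
#' @keywords internal
ess_ips <- function(chains) {
  M <- length(chains)
  N <- length(chains[[1]])
  total <- M * N
  if (all(vapply(chains, stats::sd, 0) == 0)) return(total)
  lag_max <- min(N - 1L, 2000L)
  rho <- rowMeans(vapply(chains, function(x) {
    if (stats::sd(x) == 0) rep(0, lag_max + 1)
    else drop(stats::acf(x, lag.max = lag_max, plot = FALSE,
                         demean = TRUE)$acf)
  }, numeric(lag_max + 1)))
  # pair consecutive lags (1,2), (3,4), ...; stop before the first
  # non-positive pair sum
  s <- 0
  k <- 1L
  while (k + 1L <= lag_max) {
    g <- rho[k + 1L] + rho[k + 2L]   # rho at lags k, k+1 (rho[1] is lag 0)
    if (g <= 0) break
    s <- s + g
    k <- k + 2L
  }
  min(total, total / (1 + 2 * s))
}

#' Summarize posterior draws
#'
#' Produces the standard coefficient summary table: posterior mean, SD,
#' equal-tailed 95% credible interval (2.5/97.5 percentiles), split-chain
#' Gelman-Rubin Rhat (convergence requires Rhat < 1.1), effective sample
#' size from the truncated autocorrelation sum, `overlap0` (1 iff the
#' credible interval contains 0 — the non-significance flag), and `f`, the
#' fraction of draws sharing the posterior mean's sign.
#'
#' @param fit an `occu_fit`, or a list of per-chain draw matrices with
#'   common column names.
#' @param prob credible-interval mass (default 0.95).
#' @return data.frame with one row per parameter and columns
#'   `parameter, mean, sd, lci, uci, rhat, ess, overlap0, f`.
#' @export
summarize_posterior <- function(fit, prob = 0.95) {
  chains <- if (inherits(fit, "occu_fit")) fit$draws else fit
  if (!is.list(chains) || !all(vapply(chains, is.matrix, TRUE)))
    stop("'fit' must be an occu_fit or a list of draw matrices")
  single <- length(chains) == 1L
  if (single)
    warning("single chain: Rhat cannot be computed, reported as NA")
  pars <- colnames(chains[[1]])
  a <- (1 - prob) / 2
  rows <- lapply(pars, function(pn) {
    per_chain <- lapply(chains, function(m) m[, pn])
    x <- unlist(per_chain, use.names = FALSE)
    mu <- mean(x)
    qs <- unname(stats::quantile(x, c(a, 1 - a), type = 7))
    f <- if (mu > 0) mean(x > 0) else if (mu < 0) mean(x < 0) else 0.5
    data.frame(parameter = pn,
               mean = mu,
               sd = stats::sd(x),
               lci = qs[1], uci = qs[2],
               rhat = if (single) NA_real_ else rhat_split(per_chain),
               ess = ess_ips(per_chain),
               overlap0 = as.integer(qs[1] <= 0 && qs[2] >= 0),
               f = f,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-site occupancy and detection probabilities
#'
#' Applies the inverse-logit link to every posterior draw and averages:
#' `psi_i = plogis(x_i' beta)`, `p_i = plogis(w_i' alpha)` per draw, then
#' per-site posterior means and SDs.
#'
#' @param fit an `occu_fit`.
#' @return data.frame with columns
#'   `site, psi_mean, psi_sd, p_mean, p_sd`.
#' @export
derive_site_probabilities <- function(fit) {
  stopifnot(inherits(fit, "occu_fit"))
  draws <- do.call(rbind, fit$draws)
  bcols <- grep("^beta_", colnames(draws))
  acols <- grep("^alpha_", colnames(draws))
  psi <- stats::plogis(fit$X_psi %*% t(draws[, bcols, drop = FALSE]))
  p <- stats::plogis(fit$X_p %*% t(draws[, acols, drop = FALSE]))
  data.frame(site = fit$sites,
             psi_mean = rowMeans(psi),
             psi_sd = apply(psi, 1, stats::sd),
             p_mean = rowMeans(p),
             p_sd = apply(p, 1, stats::sd),
             stringsAsFactors = FALSE)
}

#' Compare two species' per-site probabilities
#'
#' Welch two-sample t-test on per-site posterior means (occupancy or
#' detection), the test used to contrast the two cats' mean probabilities.
#' If both samples are constant the convention is `t = 0, p = 1` for equal
#' means and `t = +/-Inf, p = 0` otherwise.
#'
#' @param psi_a,psi_b numeric vectors of per-site values, one per site.
#' @return object of class `species_comparison`: list with `t_statistic`,
#'   `p_value`, `df`, `mean_a`, `sd_a`, `mean_b`, `sd_b`.
#' @export
compare_species <- function(psi_a, psi_b) {
  if (!length(psi_a) || !length(psi_b))
    stop("empty input to compare_species")
  sa <- stats::sd(psi_a); sb <- stats::sd(psi_b)
  if (sa == 0 && sb == 0) {
    d <- mean(psi_a) - mean(psi_b)
    tt <- list(statistic = if (d == 0) 0 else sign(d) * Inf,
               p.value = if (d == 0) 1 else 0,
               parameter = NA_real_)
  } else {
    ht <- stats::t.test(psi_a, psi_b, var.equal = FALSE)
    tt <- list(statistic = unname(ht$statistic),
               p.value = ht$p.value,
               parameter = unname(ht$parameter))
  }
  structure(list(t_statistic = tt$statistic,
                 p_value = tt$p.value,
                 df = tt$parameter,
                 mean_a = mean(psi_a), sd_a = sa,
                 mean_b = mean(psi_b), sd_b = sb,
                 n_a = length(psi_a), n_b = length(psi_b)),
            class = "species_comparison")
}

#' @export
print.species_comparison <- function(x, ...) {
  cat(sprintf(
    "Welch t-test: t = %.3f, p = %.4g\n  a: %.3f +/- %.3f (n=%d)\n  b: %.3f +/- %.3f (n=%d)\n",
    x$t_statistic, x$p_value, x$mean_a, x$sd_a, x$n_a,
    x$mean_b, x$sd_b, x$n_b))
  invisible(x)
}
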