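# Bayesian single-season occupancy model.
#
# Hierarchy: z_i ~ Bernoulli(psi_i), logit(psi_i) = x_i' beta (site factors);
# y_i ~ Binomial(n_i, p_i * z_i), logit(p_i) = w_i' alpha (distance factors);
# y_i counts the occasions with >= 1 detection. Independent Normal priors on
# all coefficients. Fitted by Metropolis-within-Gibbs: the latent z_i are
# drawn from their exact Bernoulli full conditional and each coefficient gets
# an adaptive univariate random-walk update.

#' Specify an occupancy model
#'
#' Names the covariates entering the occupancy (space-use) and detection
#' submodels and sets the common Normal prior on all coefficients (intercepts
#' included). The default prior SD of 3.16 (precision 0.1) is the usual
#' weakly-informative choice on the logit scale.
#'
#' @param psi_covariates covariate names for `logit(psi)`; site-based factors.
#' @param p_covariates covariate names for `logit(p)`; distance-based factors.
#' @param prior_mean,prior_sd Normal prior on every coefficient.
#' @return object of class `occu_spec`.
#' @export
occu_spec <- function(psi_covariates = c("canopycover", "predators",
                                         "livestock", "human", "othercat"),
                      p_covariates = c("dist_water", "dist_road",
                                       "dist_settlement"),
                      prior_mean = 0, prior_sd = 3.16) {
  stopifnot_scalar_number(prior_mean, "prior_mean")
  stopifnot_scalar_number(prior_sd, "prior_sd", positive = TRUE)
  structure(list(psi_covariates = psi_covariates,
                 p_covariates = p_covariates,
                 prior_mean = prior_mean, prior_sd = prior_sd),
            class = "occu_spec")
}

#' MCMC settings
#'
#' Defaults follow the survey analysis convention: three chains, 1000
#' adaptation iterations (proposal tuning), 1000 burn-in, 15,000 retained
#' iterations per chain. Chain `c` is seeded with `seed + c` so runs are
#' reproducible and chains independent.
#'
#' @param chains,adapt,burn,iterations positive integers.
#' @param seed base RNG seed.
#' @return object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 3, adapt = 1000, burn = 1000,
                          iterations = 15000, seed = 1) {
  for (nm in c("chains", "adapt", "burn", "iterations"))
    stopifnot_scalar_number(get(nm), nm, positive = TRUE)
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 burn = as.integer(burn), iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

# Build the two design matrices (leading intercept column) from a std_design.
#' @keywords internal
occu_design_matrices <- function(design, spec) {
  X <- if (inherits(design, "std_design")) design$X else as.matrix(design)
  miss <- setdiff(c(spec$psi_covariates, spec$p_covariates), colnames(X))
  if (length(miss))
    stop("covariate(s) not in design: ", paste(miss, collapse = ", "))
  ones <- rep(1, nrow(X))
  list(X_psi = cbind(`(Intercept)` = ones,
                     X[, spec$psi_covariates, drop = FALSE]),
       X_p   = cbind(`(Intercept)` = ones,
                     X[, spec$p_covariates, drop = FALSE]))
}

# Data log-likelihood of (beta, alpha, z); -Inf when z = 0 at a detected site.
#' @keywords internal
occu_loglik <- function(beta, alpha, z, y_total, n, X_psi, X_p) {
  if (any(z == 0 & y_total > 0)) return(-Inf)
  eta_psi <- drop(X_psi %*% beta)
  ll <- sum(z * (-log1pexp(-eta_psi)) + (1 - z) * (-log1pexp(eta_psi)))
  occ <- z == 1
  if (any(occ)) {
    eta_p <- drop(X_p[occ, , drop = FALSE] %*% alpha)
    yo <- y_total[occ]; no <- n[occ]
    ll <- ll + sum(lchoose(no, yo) + yo * (-log1pexp(-eta_p)) +
                     (no - yo) * (-log1pexp(eta_p)))
  }
  ll
}

#' Joint log density of the occupancy model
#'
#' Log of the joint density of data, latent states and coefficients:
#' Bernoulli occupancy terms, Binomial detection terms for occupied sites, a
#' point mass at zero detections for unoccupied sites (so any `z_i = 0` with
#' `y_total[i] > 0` gives `-Inf`), and Normal log-priors on all coefficients.
#'
#' @param beta occupancy coefficients (intercept first).
#' @param alpha detection coefficients (intercept first).
#' @param z 0/1 latent occupancy vector.
#' @param history a [build_detection_history()] result.
#' @param design a `std_design`.
#' @param spec an [occu_spec()].
#' @return scalar log density (possibly `-Inf`).
#' @export
joint_log_density <- function(beta, alpha, z, history, design, spec) {
  dm <- occu_design_matrices(design, spec)
  if (length(beta) != ncol(dm$X_psi) || length(alpha) != ncol(dm$X_p))
    stop("coefficient length does not match the model design")
  if (length(z) != length(history$y_total))
    stop("'z' length does not match the number of sites")
  occu_loglik(beta, alpha, z, history$y_total, history$n,
              dm$X_psi, dm$X_p) +
    sum(stats::dnorm(c(beta, alpha), spec$prior_mean, spec$prior_sd,
                     log = TRUE))
}

#' Full-conditional occupancy probability of an undetected site
#'
#' `Pr(z = 1 | y = 0)` for a site with occupancy probability `psi`, detection
#' probability `p` and `n` occasions:
#' `psi * (1 - p)^n / (psi * (1 - p)^n + 1 - psi)`.
#'
#' @param psi,p probabilities in (0, 1); vectorized.
#' @param n number of occasions.
#' @return conditional probability vector.
#' @export
latent_occupancy_prob <- function(psi, p, n) {
  q <- psi * (1 - p)^n
  q / (q + 1 - psi)
}

#' Draw the latent occupancy states from their full conditional
#'
#' Sites with at least one detection get `z = 1` deterministically; sites
#' with none draw `z ~ Bernoulli(Pr(z = 1 | y = 0))` via
#' [latent_occupancy_prob()]. Uses the current R RNG stream.
#'
#' @inheritParams joint_log_density
#' @return integer 0/1 vector, one per site.
#' @export
update_latent_z <- function(beta, alpha, history, design, spec) {
  dm <- occu_design_matrices(design, spec)
  psi <- stats::plogis(drop(dm$X_psi %*% beta))
  p <- stats::plogis(drop(dm$X_p %*% alpha))
  pr <- latent_occupancy_prob(psi, p, history$n)
  z <- as.integer(stats::runif(length(pr)) < pr)
  z[history$y_total > 0] <- 1L
  z
}

# One chain of the Metropolis-within-Gibbs sampler. Proposal log-scales are
# tuned in batches of 50 during the adaptation phase toward 0.44 acceptance.
#' @keywords internal
run_one_chain <- function(y_total, n, X_psi, X_p, spec, n_adapt, n_burn,
                          n_iter, seed) {
  set.seed(seed)
  kb <- ncol(X_psi); ka <- ncol(X_p)
  nsite <- length(y_total)
  pm <- spec$prior_mean; psd <- spec$prior_sd

  # initial values: coefficients ~ N(0, 1); z = 1 at detected sites else
  # Bernoulli(0.5); re-draw on a non-finite start (bounded attempts)
  for (attempt in 1:100) {
    beta <- stats::rnorm(kb); alpha <- stats::rnorm(ka)
    z <- ifelse(y_total > 0, 1L, as.integer(stats::runif(nsite) < 0.5))
    if (is.finite(occu_loglik(beta, alpha, z, y_total, n, X_psi, X_p))) break
    if (attempt == 100) stop("could not find finite starting values")
  }

  # one extra slot: a joint "ridge" proposal moving the two intercepts in
  # opposite directions (psi up / p down leaves expected detections nearly
  # unchanged, so univariate walks alone mix slowly along that direction)
  ls <- rep(log(0.5), kb + ka + 1L)    # log proposal SDs
  acc_batch <- numeric(kb + ka + 1L)
  # warmup draws feed an empirical-covariance joint proposal used while
  # sampling; weakly identified fits leave strong cross-coefficient
  # correlation that coordinatewise walks traverse slowly
  warm <- matrix(NA_real_, n_adapt + n_burn, kb + ka)
  Lprop <- NULL
  batch_len <- 50L
  total <- n_adapt + n_burn + n_iter
  draws <- matrix(NA_real_, n_iter, kb + ka)
  zmean <- numeric(nsite)
  eta_psi <- drop(X_psi %*% beta)
  eta_p <- drop(X_p %*% alpha)
  detected <- y_total > 0

  for (it in seq_len(total)) {
    # --- latent states: exact Bernoulli full conditional
    psi <- stats::plogis(eta_psi)
    p <- stats::plogis(eta_p)
    pr <- latent_occupancy_prob(psi, p, n)
    z <- as.integer(stats::runif(nsite) < pr)
    z[detected] <- 1L

    # --- occupancy coefficients: only the Bernoulli(psi) terms move
    ll_psi <- sum(z * (-log1pexp(-eta_psi)) + (1 - z) * (-log1pexp(eta_psi)))
    for (j in seq_len(kb)) {
      d <- stats::rnorm(1, 0, exp(ls[j]))
      cand <- beta[j] + d
      eta_new <- eta_psi + X_psi[, j] * d
      ll_new <- sum(z * (-log1pexp(-eta_new)) + (1 - z) * (-log1pexp(eta_new)))
      lr <- ll_new - ll_psi +
        stats::dnorm(cand, pm, psd, log = TRUE) -
        stats::dnorm(beta[j], pm, psd, log = TRUE)
      if (log(stats::runif(1)) < lr) {
        beta[j] <- cand; eta_psi <- eta_new; ll_psi <- ll_new
        acc_batch[j] <- acc_batch[j] + 1
      }
    }

    # --- detection coefficients: Binomial terms at currently occupied sites
    occ <- z == 1L
    yo <- y_total[occ]; no <- n[occ]
    eta_po <- eta_p[occ]
    ll_p <- sum(yo * (-log1pexp(-eta_po)) + (no - yo) * (-log1pexp(eta_po)))
    for (j in seq_len(ka)) {
      d <- stats::rnorm(1, 0, exp(ls[kb + j]))
      cand <- alpha[j] + d
      eta_new <- eta_po + X_p[occ, j] * d
      ll_new <- sum(yo * (-log1pexp(-eta_new)) + (no - yo) * (-log1pexp(eta_new)))
      lr <- ll_new - ll_p +
        stats::dnorm(cand, pm, psd, log = TRUE) -
        stats::dnorm(alpha[j], pm, psd, log = TRUE)
      if (log(stats::runif(1)) < lr) {
        alpha[j] <- cand; eta_po <- eta_new; ll_p <- ll_new
        eta_p <- eta_p + X_p[, j] * d
        acc_batch[kb + j] <- acc_batch[kb + j] + 1
      }
    }

    # --- ridge update: intercepts move together along (+d, -d)
    d <- stats::rnorm(1, 0, exp(ls[kb + ka + 1L]))
    eta_psi_new <- eta_psi + d
    eta_po_new <- eta_po - d
    ll_psi_new <- sum(z * (-log1pexp(-eta_psi_new)) +
                        (1 - z) * (-log1pexp(eta_psi_new)))
    ll_p_new <- sum(yo * (-log1pexp(-eta_po_new)) +
                      (no - yo) * (-log1pexp(eta_po_new)))
    lr <- ll_psi_new + ll_p_new - ll_psi - ll_p +
      stats::dnorm(beta[1] + d, pm, psd, log = TRUE) +
      stats::dnorm(alpha[1] - d, pm, psd, log = TRUE) -
      stats::dnorm(beta[1], pm, psd, log = TRUE) -
      stats::dnorm(alpha[1], pm, psd, log = TRUE)
    if (log(stats::runif(1)) < lr) {
      beta[1] <- beta[1] + d
      alpha[1] <- alpha[1] - d
      eta_psi <- eta_psi_new
      eta_p <- eta_p - d
      eta_po <- eta_po_new
      ll_psi <- ll_psi_new
      ll_p <- ll_p_new
      acc_batch[kb + ka + 1L] <- acc_batch[kb + ka + 1L] + 1
    }

    # --- joint update: full-coefficient random walk shaped by the warmup
    # covariance (scale 2.38/sqrt(d)); active once warmup has finished
    if (!is.null(Lprop)) {
      step <- drop(stats::rnorm(kb + ka) %*% Lprop) * (2.38 / sqrt(kb + ka))
      beta_new <- beta + step[seq_len(kb)]
      alpha_new <- alpha + step[kb + seq_len(ka)]
      eta_psi_new <- drop(X_psi %*% beta_new)
      eta_po_new <- drop(X_p[occ, , drop = FALSE] %*% alpha_new)
      ll_psi_new <- sum(z * (-log1pexp(-eta_psi_new)) +
                          (1 - z) * (-log1pexp(eta_psi_new)))
      ll_p_new <- sum(yo * (-log1pexp(-eta_po_new)) +
                        (no - yo) * (-log1pexp(eta_po_new)))
      lr <- ll_psi_new + ll_p_new - ll_psi - ll_p +
        sum(stats::dnorm(c(beta_new, alpha_new), pm, psd, log = TRUE)) -
        sum(stats::dnorm(c(beta, alpha), pm, psd, log = TRUE))
      if (log(stats::runif(1)) < lr) {
        beta <- beta_new; alpha <- alpha_new
        eta_psi <- eta_psi_new
        eta_p <- drop(X_p %*% alpha)
        eta_po <- eta_po_new
        ll_psi <- ll_psi_new; ll_p <- ll_p_new
      }
    }

    # --- adaptation: Robbins-Monro batch tuning toward 0.44 acceptance
    if (it <= n_adapt && it %% batch_len == 0L) {
      b <- it %/% batch_len
      delta <- min(0.1, 1 / sqrt(b))
      ls <- ls + ifelse(acc_batch / batch_len > 0.44, delta, -delta)
      acc_batch[] <- 0
    }

    if (it <= n_adapt + n_burn) {
      warm[it, ] <- c(beta, alpha)
      if (it == n_adapt + n_burn) {
        half <- warm[seq(floor(it / 2) + 1L, it), , drop = FALSE]
        S <- stats::cov(half) + diag(1e-8, kb + ka)
        Lprop <- tryCatch(chol(S), error = function(e) NULL)
      }
    }

    keep <- it - n_adapt - n_burn
    if (keep >= 1L) {
      draws[keep, ] <- c(beta, alpha)
      zmean <- zmean + z
    }
  }
  colnames(draws) <- c(paste0("beta_", colnames(X_psi)),
                       paste0("alpha_", colnames(X_p)))
  list(draws = draws, z_mean = zmean / n_iter, prop_sd = exp(ls))
}

#' Fit the occupancy model by MCMC
#'
#' Runs `settings$chains` independent Metropolis-within-Gibbs chains
#' (adaptive random-walk coefficient updates, exact latent-state Gibbs draws)
#' and retains the post-burn-in coefficient draws. Deterministic given
#' `settings$seed`.
#'
#' @param history a [build_detection_history()] result.
#' @param design a `std_design` from [standardize_covariates()].
#' @param spec an [occu_spec()].
#' @param settings an [mcmc_settings()].
#' @return object of class `occu_fit`: per-chain draw matrices (named
#'   columns `beta_*`, `alpha_*`), per-chain posterior means of `z`,
#'   the spec/settings, and the design matrices used.
#' @export
fit_occupancy <- function(history, design, spec = occu_spec(),
                          settings = mcmc_settings()) {
  stopifnot(inherits(history, "detection_history"))
  dm <- occu_design_matrices(design, spec)
  chains <- lapply(seq_len(settings$chains), function(ch)
    run_one_chain(history$y_total, history$n, dm$X_psi, dm$X_p, spec,
                  settings$adapt, settings$burn, settings$iterations,
                  seed = settings$seed + ch))
  structure(list(draws = lapply(chains, `[[`, "draws"),
                 z_mean = lapply(chains, `[[`, "z_mean"),
                 prop_sd = lapply(chains, `[[`, "prop_sd"),
                 spec = spec, settings = settings,
                 species = history$species,
                 sites = history$sites,
                 X_psi = dm$X_psi, X_p = dm$X_p),
            class = "occu_fit")
}

#' @export
print.occu_fit <- function(x, ...) {
  cat(sprintf("occu_fit ('%s'): %d chains x %d draws, %d parameters\n",
              x$species %||% "?", length(x$draws), nrow(x$draws[[1]]),
              ncol(x$draws[[1]])))
  print(summarize_posterior(x))
  invisible(x)
}
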