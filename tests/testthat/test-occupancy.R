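test_that("joint log density matches closed forms and detection logic", {
  spec <- occu_spec(character(0), character(0))
  h <- make_history(matrix(0L, 1, 3))
  X <- make_design_matrix(1, "dummy")
  # intercept-only, beta = alpha = 0: psi = p = 0.5, z = 1, y = 0:
  # Bernoulli term log 0.5 plus three Binomial zero terms log 0.5 each
  expected <- 4 * log(0.5) + 2 * dnorm(0, 0, 3.16, log = TRUE)
  expect_equal(joint_log_density(0, 0, 1L, h, X, spec), expected,
               tolerance = 1e-12)

  # detection implies occupancy: z = 0 with y > 0 is impossible
  h2 <- make_history(matrix(c(1L, 1L, 0L), 1, 3))
  expect_identical(joint_log_density(0, 0, 0L, h2, X, spec), -Inf)
  # but z = 1 is finite
  expect_true(is.finite(joint_log_density(0, 0, 1L, h2, X, spec)))

  # degenerate: no sites -> priors only
  h0 <- make_history(matrix(0L, 0, 3))
  X0 <- matrix(numeric(0), 0, 1, dimnames = list(NULL, "dummy"))
  expect_equal(joint_log_density(0.7, -0.2, integer(0), h0, X0, spec),
               sum(dnorm(c(0.7, -0.2), 0, 3.16, log = TRUE)))

  expect_error(joint_log_density(c(0, 0), 0, 1L, h, X, spec), "length")
})

test_that("latent-state marginalization matches brute-force enumeration", {
  spec <- occu_spec(c("c1", "c2"), "d1")
  for (case_seed in 1:3) {
    set.seed(case_seed)
    S <- 6
    X <- make_design_matrix(S, c("c1", "c2", "d1"), seed = case_seed)
    beta <- rnorm(3, 0, 0.8); alpha <- rnorm(2, 0, 0.8)
    y <- matrix(rbinom(S * 3, 1, 0.4), S, 3)
    h <- make_history(y)
    X_psi <- cbind(1, X[, c("c1", "c2")])
    X_p <- cbind(1, X[, "d1", drop = FALSE])
    log_prior <- sum(dnorm(c(beta, alpha), 0, 3.16, log = TRUE))
    zs <- as.matrix(expand.grid(rep(list(0:1), S)))
    lp <- apply(zs, 1, function(z)
      joint_log_density(beta, alpha, as.integer(z), h, X, spec))
    lse <- max(lp[is.finite(lp)]) +
      log(sum(exp(lp[is.finite(lp)] - max(lp[is.finite(lp)]))))
    oracle <- marginal_likelihood(beta, alpha, h$y_total, h$n, X_psi, X_p)
    expect_equal(exp(lse - log_prior), oracle, tolerance = 1e-10)
  }
})

test_that("latent full conditional is exact and respects detections", {
  # psi = p = 0.5, three occasions, no detections:
  # 0.5 * 0.125 / (0.5 * 0.125 + 0.5) = 1/9
  expect_equal(latent_occupancy_prob(0.5, 0.5, 3), 1 / 9,
               tolerance = 1e-12)
  # perfect detection with no detections rules occupancy out
  expect_equal(latent_occupancy_prob(0.5, 1 - 1e-12, 3), 0,
               tolerance = 1e-9)
  # detected sites are always occupied in the Gibbs draw
  spec <- occu_spec(character(0), character(0))
  h <- make_history(rbind(c(1L, 0L, 0L), c(0L, 0L, 0L)))
  X <- make_design_matrix(2, "dummy")
  set.seed(1)
  z <- replicate(200, update_latent_z(0, 0, h, X, spec)[1])
  expect_true(all(z == 1L))
  # Monte Carlo frequency of the undetected site matches the closed form
  set.seed(2)
  z2 <- replicate(20000, update_latent_z(0, 0, h, X, spec)[2])
  expect_lt(abs(mean(z2) - 1 / 9), 0.01)
})

test_that("the sampler is reproducible and seed-sensitive", {
  set.seed(30)
  y <- matrix(rbinom(60, 1, 0.3), 20, 3)
  h <- make_history(y)
  X <- make_design_matrix(20, c("c1", "d1"), seed = 30)
  spec <- occu_spec("c1", "d1")
  st <- mcmc_settings(2, 100, 100, 200, seed = 9)
  f1 <- fit_occupancy(h, X, spec, st)
  f2 <- fit_occupancy(h, X, spec, st)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_occupancy(h, X, spec, mcmc_settings(2, 100, 100, 200, seed = 10))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("posterior summaries match a known sampling distribution", {
  set.seed(77)
  chains <- lapply(1:3, function(i)
    matrix(rnorm(15000), ncol = 1, dimnames = list(NULL, "theta")))
  s <- summarize_posterior(chains)
  expect_lt(abs(s$mean), 0.02)
  expect_equal(s$lci, -1.96, tolerance = 0.05)
  expect_equal(s$uci, 1.96, tolerance = 0.05)
  expect_lt(s$rhat, 1.01)
  expect_gt(s$ess, 10000)
  expect_equal(s$overlap0, 1L)
  expect_equal(s$f, 0.5, tolerance = 0.02)
})

test_that("posterior summaries handle degenerate and signed draws", {
  const <- lapply(1:3, function(i)
    matrix(2, 100, 1, dimnames = list(NULL, "c")))
  s <- summarize_posterior(const)
  expect_equal(s$sd, 0)
  expect_equal(s$rhat, 1)      # identical chains converged by convention
  expect_equal(s$overlap0, 0L) # strictly positive
  expect_equal(s$f, 1)

  pos <- lapply(1:2, function(i)
    matrix(rexp(500) + 0.01, ncol = 1, dimnames = list(NULL, "p")))
  sp <- summarize_posterior(pos)
  expect_equal(sp$overlap0, 0L)
  expect_equal(sp$f, 1)

  expect_warning(s1 <- summarize_posterior(pos[1]), "single chain")
  expect_true(is.na(s1$rhat))
})

test_that("per-site probabilities apply the logistic link to the draws", {
  # hand-built fit: all draws at fixed coefficients
  X_psi <- cbind(`(Intercept)` = 1, cov = c(-1, 0, 1))
  X_p <- cbind(`(Intercept)` = 1)
  draws <- matrix(rep(c(-1.117, 0.5, 0.3), each = 50), 50, 3,
                  dimnames = list(NULL, c("beta_(Intercept)", "beta_cov",
                                          "alpha_(Intercept)")))
  fit <- structure(list(draws = list(draws), sites = c("A", "B", "C"),
                        X_psi = X_psi, X_p = X_p),
                   class = "occu_fit")
  pr <- derive_site_probabilities(fit)
  # at covariate 0 the intercept alone drives psi: plogis(-1.117) ~ 0.247
  expect_equal(pr$psi_mean[2], 0.247, tolerance = 0.005)
  # logistic monotonicity in a positive coefficient
  expect_true(all(diff(pr$psi_mean) > 0))
  expect_true(all(pr$psi_mean > 0 & pr$psi_mean < 1))
  expect_equal(pr$p_mean, rep(plogis(0.3), 3))
  expect_equal(pr$psi_sd, rep(0, 3))
})

test_that("species comparison reproduces the Welch statistic", {
  expect_equal(compare_species(1:5, 1:5)$t_statistic, 0)
  expect_equal(compare_species(1:5, 1:5)$p_value, 1)
  # constant shift drives the sign
  a <- c(0.2, 0.3, 0.25, 0.28)
  expect_gt(compare_species(a + 0.07, a)$t_statistic, 0)
  expect_lt(compare_species(a, a + 0.07)$t_statistic, 0)
  # swapping species negates t
  set.seed(5)
  x <- rnorm(154, 0.247, 0.02); y <- rnorm(154, 0.178, 0.02)
  cmp <- compare_species(x, y)
  expect_equal(compare_species(y, x)$t_statistic, -cmp$t_statistic)
  # independent Welch formula
  t_hand <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(cmp$t_statistic, t_hand, tolerance = 1e-12)
  expect_gt(abs(cmp$t_statistic), 20)
  expect_lt(cmp$p_value, 1e-6)
  # both constant, unequal means
  expect_equal(compare_species(rep(1, 3), rep(0, 3))$p_value, 0)
})

test_that("intercept-only fit recovers known occupancy and detection", {
  cfg <- sim_config(n_sites = 500, seed = 60)
  cov <- simulate_covariates(cfg)
  sim <- simulate_occupancy_data(cov,
                                 c(`(Intercept)` = qlogis(0.6)),
                                 c(`(Intercept)` = qlogis(0.4)),
                                 cfg, seed = 61)
  spec <- occu_spec(character(0), character(0))
  fit <- fit_occupancy(sim$history, sim$design, spec,
                       mcmc_settings(2, 500, 500, 2000, seed = 62))
  s <- summarize_posterior(fit)
  expect_true(all(s$rhat < 1.1))
  psi_hat <- plogis(s$mean[s$parameter == "beta_(Intercept)"])
  p_hat <- plogis(s$mean[s$parameter == "alpha_(Intercept)"])
  expect_equal(psi_hat, 0.6, tolerance = 0.07)
  expect_equal(p_hat, 0.4, tolerance = 0.07)
  # credible intervals contain the generating values
  b <- s[s$parameter == "beta_(Intercept)", ]
  expect_true(b$lci <= qlogis(0.6) && qlogis(0.6) <= b$uci)
})
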