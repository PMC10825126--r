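test_that("clock times map onto the circle", {
  ts <- as.POSIXct(c("2023-01-05 00:00:00", "2023-01-05 12:00:00",
                     "2023-01-05 18:00:00"), tz = "UTC")
  expect_equal(to_radians(ts), c(0, pi, 3 * pi / 2))
  # date component is irrelevant
  ts2 <- as.POSIXct("1999-06-01 06:00:00", tz = "UTC")
  expect_equal(to_radians(ts2), pi / 2)
})

test_that("circular KDE integrates to one and recovers known densities", {
  set.seed(9)
  x <- rvonmises(1000, pi, 2)
  f <- fit_kernel_density(x)
  integral <- camcooccur:::circular_trapz(f$grid, f$values)
  expect_equal(integral, 1, tolerance = 1e-6)
  expect_true(all(f$values >= 0))
  # density at the mode within 10% of the generating von Mises
  at_pi <- f$values[which.min(abs(f$grid - pi))]
  expect_equal(at_pi, dvonmises(pi, pi, 2), tolerance = 0.1)

  # circular-uniform sample: flat within 0.02 everywhere
  set.seed(10)
  u <- runif(2000, 0, 2 * pi)
  fu <- fit_kernel_density(u)
  expect_lt(max(abs(fu$values - 1 / (2 * pi))), 0.02)
  expect_equal(camcooccur:::circular_trapz(fu$grid, fu$values), 1,
               tolerance = 1e-6)

  expect_error(fit_kernel_density(1), "at least 2")
  expect_warning(fd <- fit_kernel_density(rep(1.3, 40)), "clipped")
  expect_equal(fd$kappa, 500)
})

test_that("Dhat1 is symmetric, bounded, and exact for identical samples", {
  set.seed(12)
  a <- rvm_mixture(200, diel_preset("junglecat"))
  b <- rvm_mixture(150, diel_preset("leopardcat"))
  expect_equal(dhat1(a, a), 1, tolerance = 1e-9)
  expect_identical(dhat1(a, b), dhat1(b, a))
  for (s in 1:5) {
    set.seed(100 + s)
    x <- runif(30 + 10 * s, 0, 2 * pi)
    y <- rvonmises(25, runif(1, 0, 2 * pi), runif(1, 0.2, 6))
    d <- dhat1(x, y)
    expect_true(d >= 0 && d <= 1)
  }
  # rotating both samples by a common shift leaves the overlap unchanged
  d0 <- dhat1(a, b)
  for (shift in c(0.7, pi, 5.1))
    expect_equal(dhat1((a + shift) %% (2 * pi), (b + shift) %% (2 * pi)),
                 d0, tolerance = 0.01)
})

test_that("Dhat1 recovers the exact overlap of known mixtures", {
  jc <- diel_preset("junglecat"); lc <- diel_preset("leopardcat")
  tr <- true_overlap(jc, lc)
  set.seed(101); a <- rvm_mixture(500, jc)
  set.seed(102); b <- rvm_mixture(500, lc)
  expect_lt(abs(dhat1(a, b) - tr), 0.05)

  # near-disjoint concentrated case
  set.seed(21); x <- rvonmises(500, pi / 2, 4)
  set.seed(22); y <- rvonmises(500, 3 * pi / 2, 4)
  tr2 <- true_overlap(vm_mixture(1, pi / 2, 4), vm_mixture(1, 3 * pi / 2, 4))
  expect_lt(abs(dhat1(x, y) - tr2), 0.05)
})

test_that("Dhat1 error shrinks with sample size", {
  jc <- diel_preset("junglecat"); lc <- diel_preset("leopardcat")
  tr <- true_overlap(jc, lc)
  med_err <- sapply(c(50, 200, 1000), function(n) {
    errs <- sapply(1:7, function(s) {
      set.seed(1000 * n + s)
      abs(dhat1(rvm_mixture(n, jc), rvm_mixture(n, lc)) - tr)
    })
    median(errs)
  })
  expect_lt(med_err[3], med_err[1])
})

test_that("smoothed bootstrap gives reproducible norm0 intervals", {
  set.seed(14)
  a <- rvm_mixture(120, diel_preset("junglecat"))
  b <- rvm_mixture(120, diel_preset("leopardcat"))
  r1 <- bootstrap_ci(a, b, reps = 99, seed = 3)
  r2 <- bootstrap_ci(a, b, reps = 99, seed = 3)
  expect_identical(unclass(r1), unclass(r2))
  expect_gt(r1$boot_sd, 0)
  expect_true(r1$ci_low >= 0 && r1$ci_high <= 1)
  expect_true(r1$ci_low < r1$ci_high)

  # identical samples: estimate 1, upper bound truncated at 1
  ri <- bootstrap_ci(a, a, reps = 49, seed = 4)
  expect_equal(ri$dhat1, 1, tolerance = 1e-9)
  expect_equal(ri$ci_high, 1)

  expect_error(bootstrap_ci(a, b, reps = 1), "at least 2")
})

test_that("stratified overlap splits by site and skips thin strata", {
  cfg <- sim_config(n_sites = 60, seed = 33)
  study <- simulate_study(cfg)
  rec <- study$records
  sites <- study$covariates$site_id

  # single stratum: same Dhat1 as the pooled estimate
  one <- setNames(rep("all", length(sites)), sites)
  res <- stratified_overlap(rec, one, "junglecat", "leopardcat",
                            reps = 49, seed = 2)
  ta <- to_radians(rec$timestamp[rec$species == "junglecat"])
  tb <- to_radians(rec$timestamp[rec$species == "leopardcat"])
  expect_equal(res$dhat1, dhat1(ta, tb))
  expect_false(res$skipped)

  # a stratum holding too few events is skipped, the other computed
  few <- setNames(rep("big", length(sites)), sites)
  few[sites %in% unique(rec$site_id)[1]] <- "tiny"
  expect_message(
    res2 <- stratified_overlap(rec, few, "junglecat", "leopardcat",
                               min_n = 10, reps = 49, seed = 2),
    "skipped")
  expect_true(res2$skipped[res2$stratum == "tiny"])
  expect_true(is.na(res2$dhat1[res2$stratum == "tiny"]))
  expect_false(res2$skipped[res2$stratum == "big"])

  # unmapped sites are an error
  missing_one <- one[setdiff(names(one), rec$site_id[1])]
  expect_error(
    stratified_overlap(rec, missing_one, "junglecat", "leopardcat"),
    "no stratum")
})

test_that("von Mises mixture sampling matches its target moments", {
  set.seed(50)
  x <- rvonmises(10000, 3 * pi / 2, 2)
  cm <- atan2(mean(sin(x)), mean(cos(x))) %% (2 * pi)
  expect_equal(cm, 3 * pi / 2, tolerance = 0.05)
  # equal-weight antipodal mixture: resultant length near zero
  mx <- vm_mixture(c(0.5, 0.5), c(0, pi), c(3, 3))
  y <- rvm_mixture(10000, mx)
  expect_lt(sqrt(mean(cos(y))^2 + mean(sin(y))^2), 0.05)
  # mixture density integrates to 1
  g <- seq(0, 2 * pi, length.out = 2001)
  expect_equal(camcooccur:::trapz(g, dvm_mixture(g, mx)), 1,
               tolerance = 1e-8)
  expect_error(vm_mixture(c(0.5, 0.4), c(0, 1), c(1, 1)), "sum to 1")
})
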