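test_that("occasion construction and effort follow the survey design", {
  d <- survey_design(paste0("S", 1:10), "2023-01-01",
                     deployment_days = 10, occasion_days = 3)
  expect_equal(d$occasions_per_site, 3L)  # trailing partial occasion dropped
  expect_equal(trap_days(d), 100L)

  # effort conservation when occasions divide the deployment evenly
  d2 <- survey_design(paste0("S", 1:6), "2023-01-01", 21, 7)
  h <- build_detection_history(
    make_records(character(0), as.POSIXct(character(0), tz = "UTC")),
    d2, "cat")
  expect_equal(sum(h$n) * d2$occasion_days,
               length(d2$site_id) * d2$deployment_days)
  expect_error(survey_design(c("A", "A"), "2023-01-01"), "duplicated")
  expect_error(survey_design("A", "2023-01-01", deployment_days = 3,
                             occasion_days = 7), "shorter")
})

test_that("detection history collapses records to per-occasion indicators", {
  d <- survey_design(c("A", "B"), "2023-01-01")
  # five events at one site, all inside occasion 2 (days 8-14)
  r <- make_records(rep("A", 5),
                    paste0("2023-01-", 9:13, " 03:00"))
  h <- build_detection_history(r, d, "cat")
  expect_equal(unname(h$y["A", ]), c(0L, 1L, 0L))
  expect_equal(h$y_total, c(1L, 0L))
  expect_equal(h$n, c(3L, 3L))

  # empty record set: all-zero history
  h0 <- build_detection_history(r[0, ], d, "cat")
  expect_true(all(h0$y == 0L))
  expect_equal(h0$y_total, c(0L, 0L))

  # duplicating records changes nothing (idempotence)
  h2 <- build_detection_history(rbind(r, r), d, "cat")
  expect_identical(h2$y, h$y)

  # other species ignored; unknown site is a hard error
  r$species <- "dog"
  expect_true(all(build_detection_history(r, d, "cat")$y == 0L))
  expect_error(
    build_detection_history(make_records("Z", "2023-01-02 10:00"), d, "cat"),
    "not in the design")
})

test_that("records outside the deployment window are excluded with warning", {
  d <- survey_design("A", "2023-01-01")
  r <- make_records(c("A", "A"),
                    c("2022-12-30 10:00", "2023-01-05 10:00"))
  expect_warning(h <- build_detection_history(r, d, "cat"),
                 "1 record")
  expect_equal(unname(h$y["A", ]), c(1L, 0L, 0L))
  # day 21 is past the 21-day window (days 0..20)
  r2 <- make_records("A", "2023-01-22 10:00")
  expect_warning(h2 <- build_detection_history(r2, d, "cat"), "outside")
  expect_equal(sum(h2$y), 0L)
})

test_that("independence rule collapses photo bursts into single events", {
  r <- make_records(rep("A", 4),
                    c("2023-01-02 10:00", "2023-01-02 10:10",
                      "2023-01-02 10:25", "2023-01-02 11:30"),
                    count = c(1L, 3L, 1L, 2L))
  out <- collapse_independent_events(r, minutes = 30)
  # 10:00/10:10/10:25 chain collapses (gaps < 30 min); 11:30 stands alone
  expect_equal(nrow(out), 2L)
  expect_equal(out$count, c(3L, 2L))
  # events exactly at the window survive
  r2 <- make_records(rep("A", 2), c("2023-01-02 10:00", "2023-01-02 10:30"))
  expect_equal(nrow(collapse_independent_events(r2, 30)), 2L)
  # different species never collapse together
  r3 <- r[1:2, ]; r3$species <- c("cat", "dog")
  expect_equal(nrow(collapse_independent_events(r3, 30)), 2L)
})

test_that("standardization centres, scales, projects and inverts exactly", {
  tab <- data.frame(site_id = c("A", "B", "C"), v = c(0, 10, 20),
                    w = c(5, 5, 6))
  std <- standardize_covariates(tab, c("v", "w"))
  expect_equal(unname(std$X[, "v"]), c(-1, 0, 1))  # sample SD = 10
  expect_equal(unname(std$center["v"]), 10)
  expect_equal(unname(std$scale["v"]), 10)

  # invariants on arbitrary data + idempotence + exact inversion
  set.seed(4)
  big <- data.frame(a = rnorm(60, 5, 3), b = runif(60, 0, 100))
  s1 <- standardize_covariates(big, c("a", "b"))
  expect_true(all(abs(colMeans(s1$X)) < 1e-10))
  expect_true(all(abs(apply(s1$X, 2, sd) - 1) < 1e-10))
  s2 <- standardize_covariates(as.data.frame(s1$X), c("a", "b"))
  expect_true(max(abs(s2$X - s1$X)) < 1e-10)
  back <- unstandardize(s1)
  expect_true(max(abs(back - as.matrix(big))) < 1e-10)

  # projection of new sites uses the stored transform
  new <- data.frame(a = 5, b = 50)
  expect_equal(drop(predict(s1, new)),
               c(a = (5 - mean(big$a)) / sd(big$a),
                 b = (50 - mean(big$b)) / sd(big$b)))

  expect_error(standardize_covariates(data.frame(k = rep(2, 5)), "k"),
               "constant covariate")
  expect_error(standardize_covariates(tab, "missing"), "unknown")
})

test_that("collinearity screen flags |r| above threshold and only those", {
  set.seed(11)
  x <- rnorm(154)
  d <- cbind(a = x, b = x, c = -x, e = rnorm(154))
  rep_ <- screen_collinearity(d, 0.7)
  expect_false(rep_$passed)
  ab <- rep_$flagged[rep_$flagged$var_a == "a" & rep_$flagged$var_b == "b", ]
  expect_equal(ab$r, 1.0)
  ac <- rep_$flagged[rep_$flagged$var_a == "a" & rep_$flagged$var_b == "c", ]
  expect_equal(ac$r, -1.0)

  # independent standard normals at the survey's site count: nothing flagged
  set.seed(42)
  ind <- matrix(rnorm(154 * 6), 154, 6,
                dimnames = list(NULL, letters[1:6]))
  expect_true(screen_collinearity(ind, 0.7)$passed)
  expect_error(screen_collinearity(ind[, 1, drop = FALSE]), "2 covariates")
  expect_error(screen_collinearity(ind[1:2, ]), "3 sites")
})

test_that("CSV ingest validates schema and invariants", {
  td <- tempfile(); dir.create(td)
  rec <- data.frame(site_id = "A", species = "cat",
                    timestamp = "2023-01-02T10:30:00", count = 2)
  write.csv(rec, file.path(td, "r.csv"), row.names = FALSE)
  got <- read_detection_records(file.path(td, "r.csv"))
  expect_s3_class(got$timestamp, "POSIXct")
  expect_equal(got$count, 2L)

  rec$count <- 0
  write.csv(rec, file.path(td, "bad.csv"), row.names = FALSE)
  expect_error(read_detection_records(file.path(td, "bad.csv")), ">= 1")

  cov <- data.frame(site_id = "A", x = 0, y = 0, canopycover = 50,
                    dist_water = 100, dist_road = 100,
                    dist_settlement = 100, human = 0, livestock = 0,
                    predators = 1)
  write.csv(cov, file.path(td, "c.csv"), row.names = FALSE)
  expect_silent(read_site_covariates(file.path(td, "c.csv")))
  cov$canopycover <- 150
  write.csv(cov, file.path(td, "c2.csv"), row.names = FALSE)
  expect_error(read_site_covariates(file.path(td, "c2.csv")), "canopycover")
  cov$canopycover <- 50; cov$predators <- 2
  write.csv(cov, file.path(td, "c3.csv"), row.names = FALSE)
  expect_error(read_site_covariates(file.path(td, "c3.csv")), "predators")
})
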