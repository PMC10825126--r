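# Ingest: detection records -> detection histories, covariates -> design
# matrices, collinearity screen.

#' Define a camera-trap survey design
#'
#' Describes the deployment: which sites were surveyed, when each camera went
#' out, how long it stayed, and how the deployment is cut into replicate
#' sampling occasions. Occasions are consecutive site-relative blocks of
#' `occasion_days` days counted from each site's own deployment start (cameras
#' were checked weekly per site, not on calendar weeks); trailing partial
#' occasions are dropped.
#'
#' @param site_id vector of unique site identifiers.
#' @param deploy_start deployment start per site (`Date`, or anything
#'   `as.Date()` accepts); a scalar is recycled to all sites.
#' @param deployment_days days each camera stayed out (default 21).
#' @param occasion_days days per sampling occasion (default 7).
#' @return an object of class `survey_design` with fields `site_id`,
#'   `deploy_start`, `deployment_days`, `occasion_days`, `occasions_per_site`.
#' @examples
#' d <- survey_design(paste0("S", 1:154), "2022-12-01")
#' d$occasions_per_site  # 3
#' trap_days(d)          # 3234
#' @export
survey_design <- function(site_id, deploy_start,
                          deployment_days = 21, occasion_days = 7) {
  site_id <- as.character(site_id)
  if (anyDuplicated(site_id)) stop("duplicated site ids in design")
  stopifnot_scalar_number(deployment_days, "deployment_days", positive = TRUE)
  stopifnot_scalar_number(occasion_days, "occasion_days", positive = TRUE)
  deploy_start <- as.Date(deploy_start)
  if (length(deploy_start) == 1L)
    deploy_start <- rep(deploy_start, length(site_id))
  if (length(deploy_start) != length(site_id))
    stop("'deploy_start' must be scalar or one date per site")
  occ <- floor(deployment_days / occasion_days)
  if (occ < 1) stop("deployment shorter than one occasion")
  structure(list(site_id = site_id,
                 deploy_start = deploy_start,
                 deployment_days = deployment_days,
                 occasion_days = occasion_days,
                 occasions_per_site = as.integer(occ)),
            class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf(
    "survey_design: %d sites x %d days (%d-day occasions, %d per site), %d trap-days\n",
    length(x$site_id), x$deployment_days, x$occasion_days,
    x$occasions_per_site, trap_days(x)))
  invisible(x)
}

#' Total survey effort in trap-days
#'
#' One trap-day is one camera operating for one day, the standard camera-trap
#' effort unit; a full design contributes `n_sites * deployment_days`.
#'
#' @param design a [survey_design()].
#' @return integer number of trap-days.
#' @export
trap_days <- function(design) {
  stopifnot(inherits(design, "survey_design"))
  td <- length(design$site_id) * design$deployment_days
  if (isTRUE(all.equal(td, round(td)))) td <- as.integer(round(td))
  td
}

#' Read camera-trap detection records
#'
#' Reads a CSV with columns `site_id,species,timestamp,count` (ISO-8601 local
#' timestamps to minute precision) and validates the record invariants:
#' parseable timestamps and `count >= 1`.
#'
#' @param path CSV file path.
#' @param tz timezone for timestamp parsing (default `"UTC"`).
#' @return data.frame with columns `site_id` (character), `species`
#'   (character), `timestamp` (`POSIXct`), `count` (integer).
#' @export
read_detection_records <- function(path, tz = "UTC") {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "species", "timestamp", "count")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("records file missing column(s): ", paste(miss, collapse = ", "))
  rec$site_id <- as.character(rec$site_id)
  rec$species <- as.character(rec$species)
  rec$timestamp <- as.POSIXct(rec$timestamp, tz = tz,
                              tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                             "%Y-%m-%dT%H:%M",
                                             "%Y-%m-%d %H:%M:%OS",
                                             "%Y-%m-%d %H:%M"))
  if (anyNA(rec$timestamp)) stop("unparseable timestamps in records file")
  rec$count <- as.integer(rec$count)
  if (anyNA(rec$count) || any(rec$count < 1))
    stop("record counts must be integers >= 1")
  rec[need]
}

#' Read the site covariate table
#'
#' Reads a CSV with columns
#' `site_id,x,y,canopycover,dist_water,dist_road,dist_settlement,human,livestock,predators`
#' (an optional `othercat` column is kept if present) and validates: one row
#' per site, no missing values, canopy cover within \[0, 100\], distances
#' non-negative, `predators` coded 0/1.
#'
#' @param path CSV file path.
#' @return data.frame of per-site covariates.
#' @export
read_site_covariates <- function(path) {
  cov <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "x", "y", "canopycover", "dist_water", "dist_road",
            "dist_settlement", "human", "livestock", "predators")
  miss <- setdiff(need, names(cov))
  if (length(miss))
    stop("covariates file missing column(s): ", paste(miss, collapse = ", "))
  cov$site_id <- as.character(cov$site_id)
  if (anyDuplicated(cov$site_id)) stop("duplicated site ids in covariates")
  if (anyNA(cov)) stop("missing values in covariates")
  if (any(cov$canopycover < 0 | cov$canopycover > 100))
    stop("'canopycover' must be within [0, 100]")
  if (any(cov$dist_water < 0 | cov$dist_road < 0 | cov$dist_settlement < 0))
    stop("distances must be non-negative")
  if (!all(cov$predators %in% c(0, 1)))
    stop("'predators' must be coded 0/1")
  if (any(cov$human < 0 | cov$livestock < 0))
    stop("'human' and 'livestock' counts must be non-negative")
  cov
}

#' Collapse photo events into independent detection records
#'
#' Consecutive records of the same species at the same site closer than
#' `minutes` apart are treated as one detection event (the standard
#' independence rule for camera-trap data). The first record of each run is
#' kept; its count becomes the maximum count observed in the run.
#'
#' @param records data.frame as returned by [read_detection_records()].
#' @param minutes independence window in minutes (default 30).
#' @return data.frame of independent records, sorted by site, species, time.
#' @export
collapse_independent_events <- function(records, minutes = 30) {
  stopifnot_scalar_number(minutes, "minutes", positive = TRUE)
  if (nrow(records) == 0L) return(records)
  ord <- order(records$site_id, records$species, records$timestamp)
  rec <- records[ord, , drop = FALSE]
  key <- paste(rec$site_id, rec$species, sep = "\r")
  gap <- c(Inf, as.numeric(difftime(rec$timestamp[-1],
                                    rec$timestamp[-nrow(rec)],
                                    units = "mins")))
  new_run <- key != c("", key[-length(key)]) | gap >= minutes
  run <- cumsum(new_run)
  keep <- rec[new_run, , drop = FALSE]
  keep$count <- as.integer(tapply(rec$count, run, max))
  rownames(keep) <- NULL
  keep
}

#' Build a detection history
#'
#' Collapses detection records of one species into the site-by-occasion 0/1
#' detection matrix of a single-season occupancy model. `y[i, j] = 1` iff the
#' species was recorded at least once at site `i` during occasion `j`'s
#' site-relative date window; `y_total[i]` is the binomial detection count
#' and `n[i]` the number of complete occasions surveyed.
#'
#' Records at sites absent from the design are a hard error; records outside
#' a site's deployment window are excluded with a warning stating how many.
#'
#' @param records data.frame of detection records (see
#'   [read_detection_records()]).
#' @param design a [survey_design()].
#' @param species species label to extract.
#' @return object of class `detection_history`: list with `sites`, `y`
#'   (matrix), `y_total`, `n`, `species`, `design`.
#' @examples
#' d <- survey_design(c("A", "B"), "2023-01-01")
#' r <- data.frame(site_id = "A", species = "cat",
#'                 timestamp = as.POSIXct("2023-01-09 03:00", tz = "UTC"),
#'                 count = 1L)
#' h <- build_detection_history(r, d, "cat")
#' h$y  # site A: occasion 2 only
#' @export
build_detection_history <- function(records, design, species) {
  stopifnot(inherits(design, "survey_design"))
  sites <- design$site_id
  n_occ <- design$occasions_per_site
  rec <- records[records$species == species, , drop = FALSE]
  y <- matrix(0L, nrow = length(sites), ncol = n_occ,
              dimnames = list(sites, paste0("occ", seq_len(n_occ))))
  if (nrow(rec) > 0L) {
    idx <- match(rec$site_id, sites)
    if (anyNA(idx))
      stop("records at site(s) not in the design: ",
           paste(unique(rec$site_id[is.na(idx)]), collapse = ", "))
    start <- design$deploy_start[idx]
    tzone <- attr(rec$timestamp, "tzone") %||% "UTC"
    day <- as.numeric(as.Date(rec$timestamp, tz = tzone) - start)  # 0-based
    occ <- floor(day / design$occasion_days) + 1
    in_window <- day >= 0 & day < design$deployment_days & occ <= n_occ
    if (any(!in_window))
      warning(sprintf("%d record(s) outside deployment windows excluded",
                      sum(!in_window)))
    idx <- idx[in_window]
    occ <- occ[in_window]
    y[cbind(idx, occ)] <- 1L
  }
  structure(list(sites = sites,
                 y = y,
                 y_total = as.integer(rowSums(y)),
                 n = rep(as.integer(n_occ), length(sites)),
                 species = species,
                 design = design),
            class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  cat(sprintf(
    "detection_history for '%s': %d sites x %d occasions, %d detections at %d sites (naive occupancy %.3f)\n",
    x$species, length(x$sites), ncol(x$y), sum(x$y_total),
    sum(x$y_total > 0), mean(x$y_total > 0)))
  invisible(x)
}

#' Standardize site covariates
#'
#' Centres and scales the named covariates to mean 0 and (sample, n-1
#' denominator) standard deviation 1, keeping the transform parameters so new
#' sites can be projected onto the same scale and values can be mapped back.
#' A constant column is an error.
#'
#' @param table data.frame of site covariates (see [read_site_covariates()]).
#' @param covariates character vector of column names to standardize.
#' @return object of class `std_design`: list with `X` (standardized matrix,
#'   rownames = site ids if present), `center`, `scale`.
#' @export
standardize_covariates <- function(table, covariates) {
  miss <- setdiff(covariates, names(table))
  if (length(miss))
    stop("unknown covariate(s): ", paste(miss, collapse = ", "))
  if (length(covariates) == 0L) {  # intercept-only models standardize nothing
    X0 <- matrix(numeric(0), nrow(table), 0)
    if ("site_id" %in% names(table)) rownames(X0) <- table$site_id
    return(structure(list(X = X0, center = numeric(0), scale = numeric(0)),
                     class = "std_design"))
  }
  X <- as.matrix(table[covariates])
  if (!is.numeric(X)) stop("covariates must be numeric")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0))
    stop("constant covariate(s): ",
         paste(covariates[scl == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if ("site_id" %in% names(table)) rownames(Xs) <- table$site_id
  structure(list(X = Xs, center = ctr, scale = scl), class = "std_design")
}

#' @export
print.std_design <- function(x, ...) {
  cat(sprintf("std_design: %d sites x %d standardized covariates\n",
              nrow(x$X), ncol(x$X)))
  print(data.frame(center = x$center, scale = x$scale))
  invisible(x)
}

#' Project new covariate values onto a standardized scale
#'
#' @param object a `std_design`.
#' @param newdata data.frame holding the same covariate columns.
#' @param ... unused.
#' @return standardized matrix.
#' @export
predict.std_design <- function(object, newdata, ...) {
  X <- as.matrix(newdata[colnames(object$X)])
  sweep(sweep(X, 2, object$center), 2, object$scale, "/")
}

#' Invert a standardization
#'
#' Maps standardized values back to the original covariate scale; composing
#' with [standardize_covariates()] is the identity.
#'
#' @param design a `std_design`.
#' @param X standardized matrix (defaults to the design's own).
#' @return matrix on the original scale.
#' @export
unstandardize <- function(design, X = design$X) {
  stopifnot(inherits(design, "std_design"))
  sweep(sweep(X, 2, design$scale, "*"), 2, design$center, "+")
}

#' Screen covariates for collinearity
#'
#' Reports all covariate pairs whose absolute Pearson correlation exceeds the
#' threshold; the analysis convention is to drop one of any pair with
#' `|r| > 0.7` before model fitting.
#'
#' @param design a `std_design` (or any numeric matrix/data.frame).
#' @param threshold flag pairs with `|r|` above this (default 0.7).
#' @return object of class `collinearity_report`: list with the full
#'   correlation matrix `r`, data.frame `flagged` (var_a, var_b, r), and
#'   `threshold`. `passed(report)` via `$passed` is `TRUE` when nothing is
#'   flagged.
#' @export
screen_collinearity <- function(design, threshold = 0.7) {
  X <- if (inherits(design, "std_design")) design$X else as.matrix(design)
  if (ncol(X) < 2) stop("need at least 2 covariates to screen")
  if (nrow(X) < 3) stop("need at least 3 sites to screen")
  r <- stats::cor(X)
  ut <- upper.tri(r)
  hit <- which(ut & abs(r) > threshold, arr.ind = TRUE)
  flagged <- data.frame(var_a = colnames(r)[hit[, 1]],
                        var_b = colnames(r)[hit[, 2]],
                        r = r[hit],
                        stringsAsFactors = FALSE)
  structure(list(r = r, flagged = flagged, threshold = threshold,
                 passed = nrow(flagged) == 0L),
            class = "collinearity_report")
}

#' @export
print.collinearity_report <- function(x, ...) {
  if (x$passed) {
    cat(sprintf("collinearity screen passed: no |r| > %.2f\n", x$threshold))
  } else {
    cat(sprintf("collinearity screen FLAGGED %d pair(s) at |r| > %.2f:\n",
                nrow(x$flagged), x$threshold))
    print(x$flagged)
  }
  invisible(x)
}
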