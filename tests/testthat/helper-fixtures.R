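# Shared fixture builders: tiny detection histories, design matrices and an
# independent marginal-likelihood oracle.

make_history <- function(y, species = "cat", start = "2023-01-01") {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  sites <- paste0("S", seq_len(nrow(y)))
  design <- survey_design(sites, start,
                          deployment_days = 7L * ncol(y), occasion_days = 7)
  structure(list(sites = sites, y = y,
                 y_total = as.integer(rowSums(y)),
                 n = rep(ncol(y), nrow(y)),
                 species = species, design = design),
            class = "detection_history")
}

# plain named covariate matrix usable wherever a std_design is accepted
make_design_matrix <- function(n, covs, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(covs)), n, length(covs),
              dimnames = list(NULL, covs))
  X
}

# Independent oracle: the occupancy-model likelihood with the latent states
# integrated out analytically, site by site.
marginal_likelihood <- function(beta, alpha, y_total, n, X_psi, X_p) {
  psi <- plogis(drop(X_psi %*% beta))
  p <- plogis(drop(X_p %*% alpha))
  prod(psi * dbinom(y_total, n, p) + (1 - psi) * (y_total == 0))
}

make_records <- function(site_id, timestamp, species = "cat", count = 1L) {
  n <- length(site_id)
  data.frame(site_id = site_id, species = rep_len(species, n),
             timestamp = as.POSIXct(timestamp, tz = "UTC"),
             count = as.integer(rep_len(count, n)),
             stringsAsFactors = FALSE)
}

write_study_csvs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- study$records
  rec$timestamp <- format(rec$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  write.csv(rec, file.path(dir, "records.csv"), row.names = FALSE)
  write.csv(study$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  invisible(dir)
}
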