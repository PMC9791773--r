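# Independent oracles for the scoring rules and reliability statistics.
# These translate the verbal scoring rules literally, one scalar at a time,
# on purpose: they must stay independent of the vectorized implementation
# they check.

oracle_score_one <- function(density, row) {
  stopifnot(length(density) == 1)
  if (row$category == "adequacy") {
    if (density >= row$recommended_density) return(row$max_score)
    return(density / row$recommended_density * row$max_score)
  }
  if (row$category == "moderation") {
    if (density == 0) return(0)
    if (density > 2 * row$upper_density) return(0)
    if (density >= row$lower_density && density <= row$upper_density) {
      return(row$max_score)
    }
    bound <- if (density < row$lower_density) row$lower_density
             else row$upper_density
    return((1 - abs(1 - density / bound)) * row$max_score)
  }
  if (row$category == "limitation") {
    if (density >= row$limit_density) return(0)
    return((1 - density / row$limit_density) * row$max_score)
  }
  stop("unknown category")
}

# Raw alpha straight from the covariance matrix (not via column variances),
# standardized alpha from the correlation matrix trace identity.
oracle_alpha_raw <- function(m) {
  k <- ncol(m)
  v <- stats::cov(m)
  k / (k - 1) * (1 - sum(diag(v)) / sum(v))
}

oracle_alpha_std <- function(m) {
  k <- ncol(m)
  r <- stats::cor(m)
  rbar <- (sum(r) - k) / (k * (k - 1))
  k * rbar / (1 + (k - 1) * rbar)
}

spearman_brown <- function(k, loading) {
  k * loading^2 / (1 + (k - 1) * loading^2)
}

subscore_matrix_of <- function(scores) {
  ids <- component_ids(cpdi_standard())
  as.matrix(as.data.frame(scores)[ids])
}

run_cli <- function(args) {
  script <- system.file("cli", "cpdi.R", package = "cpdi")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(
    system2(rscript, c(script, args), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}

# A tiny deterministic cohort with every component present, used by several
# suites.
demo_cohort <- function(n = 60, seed = 7, day_sd = 0.25) {
  simulate_cohort(n, seed = seed,
                  config = cohort_config(day_sd = day_sd))
}
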