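#' Configuration for the synthetic cohort generator
#'
#' Describes the population the generator emulates: a survey-like cohort of
#' 2-5-year-olds with three consecutive 24-h recall days per child,
#' zero-inflated log-normal food-group densities, log-normal daily energy
#' within each age band's requirement range, and demographic gradients
#' (urban residence and household income shift log-densities additively).
#' The defaults mirror the published cohort's structure: age mix
#' 22.5/24.7/25.0/27.8% over ages 2-5, 54.1% boys, 28% urban, income bands
#' 41.2/27.5/21.0/5.7/4.6%, and a 69.3% dairy non-consumption rate.
#'
#' @param age_probs Named probabilities over completed ages `"2"`-`"5"`.
#' @param p_boy Probability of sex `"boy"`.
#' @param p_urban Probability of `residence == "urban"`.
#' @param income_probs Named probabilities over the five income bands.
#' @param components Tibble with one row per generated component:
#'   `component_id`, `median_density` (conditional on consumption, per 1000
#'   kcal), `sdlog` (log-scale spread), `zero_prob` (probability a child
#'   never consumes the component), `urban_shift` and `income_step_shift`
#'   (additive log-density shifts for urban residence and per income-band
#'   step above `low`).
#' @param energy_sdlog Log-scale spread of a child's mean daily energy
#'   around the midpoint of their age band's requirement range.
#' @param day_sd Day-to-day within-subject variation scale (log-normal sd on
#'   both daily energy and daily amounts). `0` gives noiseless records whose
#'   densified values reproduce the ground-truth densities exactly.
#' @param n_days Recall days per child.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(
    age_probs = c("2" = 0.225, "3" = 0.247, "4" = 0.250, "5" = 0.278),
    p_boy = 0.541,
    p_urban = 0.280,
    income_probs = c(low = 0.412, lower_middle = 0.275, middle = 0.210,
                     upper_middle = 0.057, high = 0.046),
    components = default_component_distributions(),
    energy_sdlog = 0.20,
    day_sd = 0.25,
    n_days = 3) {
  cfg <- list(age_probs = age_probs, p_boy = p_boy, p_urban = p_urban,
              income_probs = income_probs, components = components,
              energy_sdlog = energy_sdlog, day_sd = day_sd, n_days = n_days)
  ok_probs <- function(p) all(p >= 0 & p <= 1) && abs(sum(p) - 1) < 1e-8
  if (!ok_probs(age_probs) || !ok_probs(income_probs) ||
      p_boy < 0 || p_boy > 1 || p_urban < 0 || p_urban > 1) {
    stop("probabilities must lie in [0, 1] and sum to 1", call. = FALSE)
  }
  need <- c("component_id", "median_density", "sdlog", "zero_prob",
            "urban_shift", "income_step_shift")
  if (!all(need %in% names(components))) {
    stop("components table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(components$median_density <= 0) || any(components$sdlog <= 0) ||
      any(components$zero_prob < 0 | components$zero_prob > 1) ||
      energy_sdlog <= 0 || day_sd < 0 || n_days < 1) {
    stop("invalid generator config: scales must be > 0, zero_prob in [0,1], ",
         "n_days >= 1", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_component_distributions <- function() {
  tibble::tribble(
    ~component_id,      ~median_density, ~sdlog, ~zero_prob, ~urban_shift, ~income_step_shift,
    "vegetables",       100,             0.60,   0.05,       0.10,         0.03,
    "fruits",           30,              0.90,   0.40,       0.40,         0.10,
    "dairy",            60,              1.00,   0.693,      0.50,         0.12,
    "soybeans",         6,               0.90,   0.35,       0.10,         0.05,
    "aquatic",          5,               0.90,   0.45,       0.30,         0.08,
    "cereals",          160,             0.35,   0.01,       -0.10,        -0.03,
    "eggs",             15,              0.70,   0.30,       0.15,         0.05,
    "red_meat_poultry", 35,              0.70,   0.15,       0.10,         0.05,
    "vitamin_a",        180,             0.80,   0.02,       0.20,         0.08,
    "iron",             10,              0.40,   0.00,       0.05,         0.02,
    "snacks",           10,              0.80,   0.80,       0.40,         0.10
  )
}

#' Generate a synthetic recall cohort with known ground truth
#'
#' Draws `n_subjects` children from [cohort_config()]'s population model and
#' produces the same profile/record tables the scoring pipeline consumes.
#' Each child gets a true per-1000-kcal density per component (zero-inflated
#' log-normal, shifted by residence and income on the log scale), a mean
#' daily energy drawn within the age band's requirement range, and `n_days`
#' daily records whose amounts are `density * daily energy / 1000` times
#' log-normal day noise (mean 1).
#'
#' One pseudo-random stream is split hierarchically: per-subject seeds are
#' drawn first, so generating a larger cohort with the same seed leaves the
#' first subjects' data unchanged.
#'
#' @param n_subjects Number of children (>= 1).
#' @param seed Integer seed; output is bit-identical given (config, seed).
#' @param config A [cohort_config()].
#' @return A list: `profiles` (tibble: `subject_id`, `age_years`, `sex`,
#'   `residence`, `income_band`, `household_size`), `records` (tibble:
#'   `subject_id`, `day`, `energy_kcal`, one amount column per component),
#'   and `truth` (tibble of each child's true mean energy and densities; the
#'   config is attached as attribute `config`).
#' @examples
#' cohort <- simulate_cohort(20, seed = 42)
#' head(cohort$records)
#' @export
simulate_cohort <- function(n_subjects, seed, config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"), n_subjects >= 1)
  groups <- cpdi_standard()$age_groups
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)

  comp <- config$components
  income_levels <- names(config$income_probs)
  width <- max(5, nchar(as.character(n_subjects)))
  per_subject <- purrr::map(seq_len(n_subjects), function(i) {
    set.seed(subject_seeds[i])
    sid <- sprintf("S%0*d", width, i)
    age <- as.integer(sample(names(config$age_probs), 1,
                             prob = config$age_probs))
    sex <- if (stats::runif(1) < config$p_boy) "boy" else "girl"
    residence <- if (stats::runif(1) < config$p_urban) "urban" else "rural"
    income <- sample(income_levels, 1, prob = config$income_probs)
    income_step <- match(income, income_levels) - 1
    household <- 3L + stats::rpois(1, 1.2)

    grp <- groups[groups$label == assign_age_group(age), ]
    mean_energy <- stats::rlnorm(
      1, meanlog = log((grp$energy_low + grp$energy_high) / 2),
      sdlog = config$energy_sdlog)

    consumes <- stats::runif(nrow(comp)) >= comp$zero_prob
    meanlog <- log(comp$median_density) +
      (residence == "urban") * comp$urban_shift +
      income_step * comp$income_step_shift
    density <- ifelse(consumes,
                      stats::rlnorm(nrow(comp), meanlog, comp$sdlog), 0)

    day_noise <- function(n) {
      if (config$day_sd == 0) rep(1, n)
      else stats::rlnorm(n, -config$day_sd^2 / 2, config$day_sd)
    }
    energy_day <- mean_energy * day_noise(config$n_days)
    amounts <- outer(energy_day / 1000, density) *
      matrix(day_noise(config$n_days * nrow(comp)), nrow = config$n_days)
    colnames(amounts) <- comp$component_id

    list(
      profile = tibble::tibble(
        subject_id = sid, age_years = age, sex = sex, residence = residence,
        income_band = income, household_size = household),
      records = tibble::tibble(
        subject_id = sid, day = seq_len(config$n_days),
        energy_kcal = energy_day) |>
        dplyr::bind_cols(tibble::as_tibble(amounts)),
      truth = tibble::tibble(subject_id = sid, mean_energy = mean_energy) |>
        dplyr::bind_cols(tibble::as_tibble(as.list(
          stats::setNames(density, comp$component_id))))
    )
  })

  truth <- purrr::map_dfr(per_subject, "truth")
  attr(truth, "config") <- config
  list(
    profiles = purrr::map_dfr(per_subject, "profile"),
    records = purrr::map_dfr(per_subject, "records"),
    truth = truth
  )
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Build a fixture subject with exact target densities
#'
#' Deterministically constructs one child whose averaged, densified records
#' reproduce the requested per-1000-kcal densities exactly -- the natural
#' fixture for the published worked examples (e.g. a 5-year-old with dairy
#' density 200 g/1000 kcal scores 8 dairy points).
#'
#' @param age_years Completed age in years (2-5).
#' @param densities Named numeric vector, `component_id -> amount per 1000
#'   kcal`. Components not named are omitted from the records (scored as 0).
#' @param energy Daily energy in kcal; defaults to the midpoint of the age
#'   band's requirement range.
#' @param n_days Number of identical recall days to emit.
#' @param subject_id Identifier for the fixture child.
#' @return A list with `profile` and `records` tibbles ready for
#'   [score_subject()].
#' @examples
#' fix <- targeted_subject(5, c(dairy = 200))
#' score_subject(fix$profile, fix$records)$dairy  # 8
#' @export
targeted_subject <- function(age_years, densities, energy = NULL, n_days = 3,
                             subject_id = "target") {
  stopifnot(all(densities >= 0), is.null(energy) || energy > 0)
  grp <- assign_age_group(age_years)
  groups <- cpdi_standard()$age_groups
  if (is.null(energy)) {
    g <- groups[groups$label == grp, ]
    energy <- (g$energy_low + g$energy_high) / 2
  }
  records <- tibble::tibble(
    subject_id = subject_id, day = seq_len(n_days), energy_kcal = energy)
  for (id in names(densities)) {
    records[[id]] <- densities[[id]] * energy / 1000
  }
  profile <- tibble::tibble(
    subject_id = subject_id, age_years = age_years, sex = "girl",
    residence = "urban", income_band = "middle", household_size = 4L)
  list(profile = profile, records = records)
}

#' Simulate subscores from a one-common-factor model
#'
#' Generates `n` subjects x `k` components as `x_j = loading * f +
#' sqrt(1 - loading^2) * e_j` with independent standard-normal factor and
#' noise, so every pairwise correlation is `loading^2` and standardized
#' Cronbach's alpha converges to the Spearman-Brown value
#' `k * loading^2 / (1 + (k - 1) * loading^2)` -- the oracle for the
#' reliability-recovery tests.
#'
#' @param n Number of subjects (>= 2).
#' @param k Number of components (>= 2).
#' @param loading Common-factor loading in `[0, 1]`.
#' @param seed Integer seed.
#' @return An `n x k` numeric matrix with columns `component_1..k`.
#' @export
simulate_factor_subscores <- function(n, k, loading, seed) {
  stopifnot(n >= 2, k >= 2, loading >= 0, loading <= 1)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  f <- stats::rnorm(n)
  e <- matrix(stats::rnorm(n * k), n, k)
  m <- loading * f + sqrt(1 - loading^2) * e
  colnames(m) <- paste0("component_", seq_len(k))
  m
}
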