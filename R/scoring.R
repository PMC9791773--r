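#' Component scoring rules
#'
#' The CPDI scores each component on its energy-adjusted density (amount per
#' 1000 kcal) with one of three piecewise-linear rules:
#'
#' * **Adequacy** (`score_adequacy`): full marks at or above the recommended
#'   density, otherwise proportional --
#'   `(density / recommended) * max_score`.
#' * **Moderation** (`score_moderation`): full marks inside the recommended
#'   interval \[lower, upper\]; zero at density 0 and strictly above twice the
#'   upper bound; linear in between against the nearest bound --
#'   `(1 - |1 - density / bound|) * max_score` with `bound = lower` below the
#'   interval and `bound = upper` above it. The rule is continuous everywhere
#'   except the jump at density = 0.
#' * **Limitation** (`score_limitation`): full marks at zero intake, zero at
#'   or above the limit, otherwise `(1 - density / limit) * max_score`.
#'
#' All three are vectorized over `density` and clamp the result to
#' `[0, max_score]` to guard floating-point edges.
#'
#' @param density Numeric vector of densities (amount per 1000 kcal), >= 0.
#' @param recommended_density Density at which an adequacy component reaches
#'   its maximum score.
#' @param lower_density,upper_density Bounds of a moderation component's
#'   max-score interval.
#' @param zero_above_density Density strictly above which a moderation score
#'   is 0; must equal `2 * upper_density` (the published standard's rule).
#' @param limit_density Density at or above which a limitation score is 0;
#'   also the formula's denominator.
#' @param max_score Maximum points for the component.
#' @return Numeric vector of scores in `[0, max_score]`.
#' @examples
#' score_adequacy(200, recommended_density = 250, max_score = 10)   # 8
#' score_moderation(150, 71, 100, max_score = 10)                   # 5
#' score_limitation(45, 100, max_score = 5)                         # 2.75
#' @name component-scoring
NULL

#' @rdname component-scoring
#' @export
score_adequacy <- function(density, recommended_density, max_score = 10) {
  check_density(density)
  stopifnot(recommended_density > 0, max_score > 0)
  clamp(density / recommended_density * max_score, max_score)
}

#' @rdname component-scoring
#' @export
score_moderation <- function(density, lower_density, upper_density,
                             max_score = 10,
                             zero_above_density = 2 * upper_density) {
  check_density(density)
  stopifnot(lower_density > 0, lower_density <= upper_density, max_score > 0)
  if (abs(zero_above_density - 2 * upper_density) > 1e-9) {
    stop("zero_above_density must equal 2 * upper_density", call. = FALSE)
  }
  score <- numeric(length(density))
  inside <- density >= lower_density & density <= upper_density
  below <- density > 0 & density < lower_density
  above <- density > upper_density & density <= zero_above_density
  score[inside] <- max_score
  score[below] <- (1 - abs(1 - density[below] / lower_density)) * max_score
  score[above] <- (1 - abs(1 - density[above] / upper_density)) * max_score
  clamp(score, max_score)  # density == 0 or > zero_above stays 0
}

#' @rdname component-scoring
#' @export
score_limitation <- function(density, limit_density, max_score = 5) {
  check_density(density)
  stopifnot(limit_density > 0, max_score > 0)
  score <- ifelse(density >= limit_density, 0,
                  (1 - density / limit_density) * max_score)
  clamp(score, max_score)
}

check_density <- function(density) {
  if (any(!is.finite(density)) || any(density < 0)) {
    stop("densities must be finite and >= 0", call. = FALSE)
  }
}

clamp <- function(x, hi) pmin(pmax(x, 0), hi)

#' Score a density under a named component of a standard
#'
#' Looks up the component's category and age-group cutoffs in `standard` and
#' dispatches to the matching rule ([score_adequacy()], [score_moderation()]
#' or [score_limitation()]).
#'
#' @inheritParams component-scoring
#' @param component A component id of `standard` (e.g. `"dairy"`).
#' @param age_group An age-group label of `standard` (`"2-3"` or `"4-5"` for
#'   the default CPDI).
#' @param standard An `index_standard`; defaults to [cpdi_standard()].
#' @return Numeric vector of scores.
#' @examples
#' score_density(200, "dairy", "4-5")    # the 8-point worked example
#' @export
score_density <- function(density, component, age_group,
                          standard = cpdi_standard()) {
  comps <- standard$components
  row <- comps[comps$component_id == component &
                 comps$age_group == age_group, ]
  if (nrow(row) != 1) {
    stop("no component '", component, "' for age group '", age_group,
         "' in standard '", standard$name, "'", call. = FALSE)
  }
  switch(row$category,
    adequacy = score_adequacy(density, row$recommended_density,
                              row$max_score),
    moderation = score_moderation(density, row$lower_density,
                                  row$upper_density, row$max_score,
                                  row$zero_above_density),
    limitation = score_limitation(density, row$limit_density, row$max_score)
  )
}

#' Exclude subjects with implausible energy intakes
#'
#' Splits recall records into subjects kept for scoring and subjects excluded
#' because their mean daily energy intake is implausible: strictly below
#' `min_kcal` or strictly above `max_kcal` (defaults 400 and 4000 kcal/day;
#' means of exactly 400 or 4000 are kept).
#'
#' @param records A data frame of daily recall records with columns
#'   `subject_id` and `energy_kcal` (one row per subject-day).
#' @param min_kcal,max_kcal Plausibility bounds in kcal/day.
#' @return A list with `kept` (records of plausible subjects, unchanged) and
#'   `excluded` (tibble: `subject_id`, `mean_energy`, `reason` -- one of
#'   `"energy_below_minimum"`, `"energy_above_maximum"`).
#' @examples
#' rec <- tibble::tibble(subject_id = c("a", "a", "b"), day = c(1, 2, 1),
#'                       energy_kcal = c(300, 350, 1150))
#' filter_plausible_energy(rec)$excluded
#' @export
filter_plausible_energy <- function(records, min_kcal = 400,
                                    max_kcal = 4000) {
  stopifnot(min_kcal < max_kcal)
  check_records(records)
  means <- records |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(mean_energy = mean(.data$energy_kcal), .groups = "drop")
  excluded <- means |>
    dplyr::filter(.data$mean_energy < min_kcal |
                    .data$mean_energy > max_kcal) |>
    dplyr::mutate(reason = ifelse(.data$mean_energy < min_kcal,
                                  "energy_below_minimum",
                                  "energy_above_maximum"))
  list(
    kept = dplyr::filter(records,
                         !.data$subject_id %in% excluded$subject_id),
    excluded = excluded
  )
}

#' Average recall days and convert to per-1000-kcal densities
#'
#' Implements the index's averaging convention: per subject, intakes are
#' averaged over recall days first and the density is the ratio of means,
#' `density = mean daily amount / mean daily energy * 1000`. Every numeric
#' column other than `subject_id`, `day` and `energy_kcal` is densified.
#'
#' @param records A data frame of daily recall records (columns `subject_id`,
#'   `day`, `energy_kcal`, plus one column per component or nutrient, in
#'   amount-per-day units).
#' @return A tibble, one row per subject: `subject_id`, `mean_energy`
#'   (kcal/day), `n_days_used`, then one density column per amount column.
#' @examples
#' rec <- tibble::tibble(subject_id = "a", day = 1:3,
#'                       energy_kcal = c(1000, 1200, 1400),
#'                       dairy = c(150, 253, 250))
#' densify(rec)  # dairy density 181.39 g/1000 kcal
#' @export
densify <- function(records) {
  check_records(records)
  amount_cols <- amount_columns(records)
  out <- records |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      mean_energy = mean(.data$energy_kcal),
      n_days_used = dplyr::n(),
      dplyr::across(dplyr::all_of(amount_cols), mean),
      .groups = "drop"
    )
  if (any(out$mean_energy <= 0)) {
    stop("mean daily energy is 0 for subject(s): ",
         paste(utils::head(out$subject_id[out$mean_energy <= 0], 5),
               collapse = ", "),
         " -- densities are undefined", call. = FALSE)
  }
  out |>
    dplyr::mutate(dplyr::across(dplyr::all_of(amount_cols),
                                ~ .x / .data$mean_energy * 1000)) |>
    dplyr::arrange(.data$subject_id)
}

amount_columns <- function(records) {
  candidates <- setdiff(names(records), c("subject_id", "day", "energy_kcal"))
  candidates[vapply(records[candidates], is.numeric, logical(1))]
}

check_records <- function(records) {
  missing <- setdiff(c("subject_id", "energy_kcal"), names(records))
  if (length(missing)) {
    stop("records are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  amounts <- records[amount_columns(records)]
  bad <- vapply(amounts, function(x) any(!is.finite(x) | x < 0), logical(1))
  if (any(bad)) {
    stop("negative or non-finite amounts in column(s): ",
         paste(names(amounts)[bad], collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(records$energy_kcal) | records$energy_kcal < 0)) {
    stop("energy_kcal must be finite and >= 0", call. = FALSE)
  }
  invisible(records)
}

#' Score a cohort of children
#'
#' The package's main entry point: filters nothing (see
#' [filter_plausible_energy()] to pre-screen), averages each subject's recall
#' days, converts intakes to per-1000-kcal densities, and applies the
#' standard's component rules under the subject's age group. Per-subject
#' failures (age outside 2-5, zero mean energy) and records without a profile
#' are collected in a rejects table, not fatal. Components absent from the
#' records are scored as zero consumption and flagged.
#'
#' @param records Daily recall records: `subject_id`, `day`, `energy_kcal`,
#'   one column per component id (amount/day in the component's unit), plus
#'   optional extra nutrient columns (kept for adequacy-ratio analyses,
#'   not scored).
#' @param profiles Subject profiles: `subject_id`, `age_years`, and any
#'   demographic columns.
#' @param standard An `index_standard`; defaults to [cpdi_standard()].
#' @return A `cpdi_scores` tibble, one row per scored subject, sorted by
#'   `subject_id`: `subject_id`, `age_group`, one subscore column per
#'   component, `total`. Attributes:
#'   * `densities` -- per-subject density tibble (audit trail),
#'   * `nutrients` -- per-subject mean daily intakes of non-component
#'     columns,
#'   * `rejects` -- tibble of `subject_id`, `reason` for unscored subjects,
#'   * `missing_components` -- component ids absent from the records and
#'     scored as 0 consumption,
#'   * `standard_name`, `max_total`.
#'   Use [generics::tidy()] / [generics::glance()] / [ggplot2::autoplot()]
#'   on the result.
#' @examples
#' fix <- targeted_subject(5, c(dairy = 200))
#' score_cohort(fix$records, fix$profile)
#' @export
score_cohort <- function(records, profiles, standard = cpdi_standard()) {
  stopifnot(inherits(standard, "index_standard"))
  check_records(records)
  if (!all(c("subject_id", "age_years") %in% names(profiles))) {
    stop("profiles need columns 'subject_id' and 'age_years'", call. = FALSE)
  }

  rejects <- tibble::tibble(subject_id = character(), reason = character())
  orphan <- setdiff(unique(records$subject_id), profiles$subject_id)
  if (length(orphan)) {
    rejects <- dplyr::bind_rows(rejects, tibble::tibble(
      subject_id = as.character(orphan), reason = "no_profile"))
    records <- dplyr::filter(records, !.data$subject_id %in% orphan)
  }
  profiles <- dplyr::filter(profiles,
                            .data$subject_id %in% records$subject_id)
  age <- floor(profiles$age_years)
  bad_age <- !is.finite(age) | age < 2 | age > 5
  if (any(bad_age)) {
    rejects <- dplyr::bind_rows(rejects, tibble::tibble(
      subject_id = as.character(profiles$subject_id[bad_age]),
      reason = "age_outside_2_5"))
    records <- dplyr::filter(
      records, !.data$subject_id %in% profiles$subject_id[bad_age])
    profiles <- profiles[!bad_age, , drop = FALSE]
  }
  zero_energy <- records |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(me = mean(.data$energy_kcal), .groups = "drop") |>
    dplyr::filter(.data$me <= 0)
  if (nrow(zero_energy)) {
    rejects <- dplyr::bind_rows(rejects, tibble::tibble(
      subject_id = as.character(zero_energy$subject_id),
      reason = "zero_mean_energy"))
    records <- dplyr::filter(records,
                             !.data$subject_id %in% zero_energy$subject_id)
  }

  ids <- component_ids(standard)
  missing_components <- setdiff(ids, names(records))
  if (length(missing_components)) {
    warning("component(s) absent from records, scored as 0 consumption: ",
            paste(missing_components, collapse = ", "), call. = FALSE)
    for (id in missing_components) records[[id]] <- 0
  }

  if (nrow(records) == 0) {
    empty <- tibble::tibble(subject_id = character(),
                            age_group = character())
    for (id in ids) empty[[id]] <- numeric()
    empty$total <- numeric()
    return(new_cpdi_scores(empty,
                           densities = empty[c("subject_id", "age_group")],
                           nutrients = empty["subject_id"],
                           rejects = rejects,
                           missing_components = missing_components,
                           standard = standard))
  }

  dens <- densify(records)
  dens <- dplyr::left_join(
    dens,
    dplyr::mutate(profiles[c("subject_id", "age_years")],
                  age_group = assign_age_group(.data$age_years)),
    by = "subject_id")

  scores <- dens[c("subject_id", "age_group")]
  for (id in ids) {
    scores[[id]] <- score_by_group(dens[[id]], dens$age_group, id, standard)
  }
  scores$total <- rowSums(as.matrix(scores[ids]))
  scores <- dplyr::arrange(scores, .data$subject_id)

  nutrient_cols <- setdiff(amount_columns(records), ids)
  nutrients <- records |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(nutrient_cols), mean),
                     .groups = "drop") |>
    dplyr::arrange(.data$subject_id)

  new_cpdi_scores(
    scores,
    densities = dplyr::arrange(
      dens[c("subject_id", "age_group", "mean_energy", "n_days_used", ids)],
      .data$subject_id),
    nutrients = nutrients,
    rejects = rejects,
    missing_components = missing_components,
    standard = standard
  )
}

score_by_group <- function(density, age_group, component, standard) {
  out <- numeric(length(density))
  for (grp in unique(age_group)) {
    sel <- age_group == grp
    out[sel] <- score_density(density[sel], component, grp, standard)
  }
  out
}

new_cpdi_scores <- function(scores, densities, nutrients, rejects,
                            missing_components, standard) {
  structure(
    tibble::as_tibble(scores),
    class = c("cpdi_scores", class(tibble::tibble())),
    densities = densities,
    nutrients = nutrients,
    rejects = rejects,
    missing_components = missing_components,
    standard_name = standard$name,
    max_total = max_total_score(standard)
  )
}

#' Score a single child
#'
#' Convenience wrapper around [score_cohort()] for one subject; unlike the
#' cohort path, failures (age outside 2-5, zero energy) are errors.
#'
#' @param profile A one-row data frame with `subject_id` and `age_years`.
#' @param records That subject's daily recall records.
#' @inheritParams score_cohort
#' @return A one-row `cpdi_scores` tibble.
#' @export
score_subject <- function(profile, records, standard = cpdi_standard()) {
  stopifnot(nrow(profile) == 1)
  res <- score_cohort(records, profile, standard)
  rej <- rejects(res)
  if (nrow(rej)) {
    stop("subject could not be scored: ", rej$reason[1], call. = FALSE)
  }
  res
}

#' Rejected subjects of a scoring run
#' @param x A `cpdi_scores` object.
#' @return Tibble of `subject_id`, `reason`.
#' @export
rejects <- function(x) attr(x, "rejects")

#' Per-subject density audit trail of a scoring run
#' @param x A `cpdi_scores` object.
#' @return Tibble of per-1000-kcal densities used for scoring.
#' @export
densities <- function(x) attr(x, "densities")
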