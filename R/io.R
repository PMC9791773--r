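#' Read a cohort from profile and record CSV files
#'
#' The dialect is plain UTF-8 CSV with a header row. Profiles: `subject_id`,
#' `age_years`, plus optional demographics. Records: one row per
#' subject-day with `subject_id`, `day`, `energy_kcal`, then one column per
#' component id and any extra nutrient columns. Rows with negative or
#' non-finite amounts are rejected with line-numbered diagnostics rather
#' than failing the whole read.
#'
#' @param profiles_path,records_path Paths to the two CSV files.
#' @return A list: `profiles`, `records` (tibbles of the clean rows) and
#'   `rejected_rows` (tibble: `file`, `line`, `problem`). Line numbers count
#'   the header as line 1.
#' @export
read_cohort <- function(profiles_path, records_path) {
  profiles <- readr::read_csv(profiles_path, show_col_types = FALSE,
                              progress = FALSE)
  records <- readr::read_csv(records_path, show_col_types = FALSE,
                             progress = FALSE)
  need_p <- setdiff(c("subject_id", "age_years"), names(profiles))
  need_r <- setdiff(c("subject_id", "day", "energy_kcal"), names(records))
  if (length(need_p)) {
    stop(basename(profiles_path), ": missing mandatory column(s): ",
         paste(need_p, collapse = ", "), call. = FALSE)
  }
  if (length(need_r)) {
    stop(basename(records_path), ": missing mandatory column(s): ",
         paste(need_r, collapse = ", "), call. = FALSE)
  }
  profiles$subject_id <- as.character(profiles$subject_id)
  records$subject_id <- as.character(records$subject_id)
  num_cols <- c("energy_kcal", amount_columns(records))
  bad <- rep(FALSE, nrow(records))
  problem <- character(nrow(records))
  for (col in num_cols) {
    flag <- !is.finite(records[[col]]) | records[[col]] < 0
    problem[flag & !bad] <- paste0("invalid value in '", col, "'")
    bad <- bad | flag
  }
  rejected <- tibble::tibble(
    file = basename(records_path),
    line = which(bad) + 1L,
    problem = problem[bad])
  records <- records[!bad, , drop = FALSE]
  if (nrow(records) == 0) {
    warning("no usable recall records in ", basename(records_path),
            call. = FALSE)
  }
  list(profiles = profiles, records = records, rejected_rows = rejected)
}

#' Write scores (and companions) to CSV
#'
#' `write_scores()` writes a `cpdi_scores` table with a fixed column order
#' and fixed numeric formatting (scores rounded to 2 decimals) so outputs
#' diff cleanly; `write_rejects()` writes the rejects table;
#' `write_densities()` writes the per-subject density audit trail (densities
#' rounded to 1 decimal, full precision with `digits = NA`).
#'
#' @param scores A `cpdi_scores` object (or compatible data frame).
#' @param path Output CSV path.
#' @param digits Decimal places; `NA` keeps full precision.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, digits = 2) {
  df <- tibble::as_tibble(as.data.frame(scores))
  if (!is.na(digits)) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                          ~ round(.x, digits)))
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
write_rejects <- function(scores, path) {
  readr::write_csv(rejects(scores), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
write_densities <- function(scores, path, digits = 1) {
  df <- densities(scores)
  if (!is.na(digits)) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                          ~ round(.x, digits)))
  }
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Write a reliability report
#'
#' `write_report()` serializes a [reliability_report()] as a YAML mapping
#' (alphas, item-rest correlations, eigenvalues); `write_scree()` writes the
#' scree-plot data (one eigenvalue per rank) as CSV.
#'
#' @param report A `cpdi_reliability` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cpdi_reliability"))
  doc <- list(
    n_subjects = report$n_subjects,
    alpha_raw = report$alpha_raw,
    alpha_standardized = report$alpha_standardized,
    item_rest = purrr::pmap(report$item_rest, function(component_id,
                                                       item_rest_r,
                                                       undefined) {
      list(component_id = component_id,
           item_rest_r = if (undefined) NA else item_rest_r)
    }),
    pca = list(
      eigenvalues = report$pca$eigenvalues,
      n_eigen_gt_1 = report$pca$n_eigen_gt_1,
      cumulative_variance_top_k = report$pca$cumulative_variance_top_k
    )
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_report
#' @export
write_scree <- function(report, path) {
  stopifnot(inherits(report, "cpdi_reliability"))
  readr::write_csv(
    tibble::tibble(rank = seq_along(report$pca$eigenvalues),
                   eigenvalue = report$pca$eigenvalues),
    path, progress = FALSE)
  invisible(path)
}

#' Read a food composition table
#'
#' A food composition table (FCT) maps food items to a food-group component
#' and to nutrient contents per 100 g edible portion. The expected CSV
#' columns are `food_item`, `component_id` (empty for foods outside the
#' index's groups) and one `*_100g` column per nutrient, including
#' `energy_kcal_100g`. A small synthetic fixture ships at
#' `system.file("extdata", "fct_synthetic.csv", package = "cpdi")`; real
#' national tables are copyrighted and must be supplied by the user in this
#' schema.
#'
#' @param path CSV path.
#' @return A tibble, validated (amounts >= 0, unique food items).
#' @export
read_fct <- function(path) {
  fct <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("food_item", "component_id", "energy_kcal_100g")
  missing <- setdiff(need, names(fct))
  if (length(missing)) {
    stop("FCT is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  per100 <- grep("_100g$", names(fct), value = TRUE)
  for (col in per100) {
    if (any(!is.finite(fct[[col]]) | fct[[col]] < 0)) {
      stop("FCT column '", col, "' has negative or missing values",
           call. = FALSE)
    }
  }
  if (anyDuplicated(fct$food_item)) {
    stop("duplicate food_item entries in FCT", call. = FALSE)
  }
  fct
}

#' Convert food-item intakes to energy, components and nutrients
#'
#' Applies the standard-serving conversion: each nutrient contribution is
#' the per-100-g content times grams consumed / 100, summed over items, and
#' each component amount is the total grams of the items assigned to it.
#'
#' @param item_intakes A data frame with `food_item` and `grams` (consumed
#'   that day), or a named numeric vector `food_item -> grams`.
#' @param fct A food composition table from [read_fct()].
#' @param strict If `TRUE` (default), unknown food items are an error; if
#'   `FALSE` they are dropped and reported in the `rejected_items`
#'   attribute.
#' @return A one-row tibble: `energy_kcal`, one column per component with
#'   consumed grams, and one column per nutrient (the `*_100g` columns with
#'   the suffix stripped, in amount/day).
#' @examples
#' fct <- read_fct(system.file("extdata", "fct_synthetic.csv",
#'                             package = "cpdi"))
#' convert_foods_to_nutrients(c(whole_milk = 150), fct)  # 81 kcal
#' @export
convert_foods_to_nutrients <- function(item_intakes, fct, strict = TRUE) {
  if (!is.data.frame(item_intakes)) {
    item_intakes <- tibble::tibble(food_item = names(item_intakes),
                                   grams = as.numeric(item_intakes))
  }
  stopifnot(all(c("food_item", "grams") %in% names(item_intakes)),
            all(item_intakes$grams >= 0))
  unknown <- setdiff(item_intakes$food_item, fct$food_item)
  if (length(unknown)) {
    if (strict) {
      stop("food item(s) not in the composition table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    item_intakes <- dplyr::filter(item_intakes,
                                  !.data$food_item %in% unknown)
  }
  merged <- dplyr::inner_join(item_intakes, fct, by = "food_item")
  per100 <- grep("_100g$", names(fct), value = TRUE)
  out <- tibble::tibble(.rows = 1)
  for (col in per100) {
    out[[sub("_100g$", "", col)]] <- sum(merged[[col]] * merged$grams / 100)
  }
  by_component <- merged |>
    dplyr::filter(!is.na(.data$component_id)) |>
    dplyr::group_by(.data$component_id) |>
    dplyr::summarise(grams = sum(.data$grams), .groups = "drop")
  for (i in seq_len(nrow(by_component))) {
    out[[by_component$component_id[i]]] <- by_component$grams[i]
  }
  attr(out, "rejected_items") <- unknown
  out
}
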