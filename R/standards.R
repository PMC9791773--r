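#' The default CPDI scoring standard
#'
#' Returns the published scoring standard of the Chinese Preschooler Dietary
#' Index: 11 components (5 adequacy, 5 moderation, 1 limitation) scored on
#' per-1000-kcal densities, with separate cutoffs for the two age groups
#' (completed ages 2-3 and 4-5 years). Maximum subscores are 10 points for the
#' eight food-group components, 2.5 for vitamin A and iron, and 5 for
#' high-sugar/high-fat snacks, summing to a 0-90 total.
#'
#' The standard is shipped as a declarative YAML document
#' (`system.file("extdata", "cpdi_standard.yaml", package = "cpdi")`), so
#' variant indexes need no code changes: edit a copy and load it with
#' [read_standard()].
#'
#' @return An object of class `index_standard`: a list with `name`,
#'   `age_groups` (tibble: `label`, `energy_low`, `energy_high` in kcal/day;
#'   generator metadata only) and `components` (tibble, one row per component
#'   x age group, carrying `category`, `unit`, `max_score` and the
#'   category-specific density cutoffs).
#' @examples
#' std <- cpdi_standard()
#' sum(unique(std$components[c("component_id", "max_score")])$max_score)  # 90
#' @export
cpdi_standard <- function() {
  if (is.null(.cpdi_cache$default)) {
    path <- system.file("extdata", "cpdi_standard.yaml", package = "cpdi")
    .cpdi_cache$default <- read_standard(path)
  }
  .cpdi_cache$default
}

.cpdi_cache <- new.env(parent = emptyenv())

#' Read an index standard from a YAML document
#'
#' Parses and validates a scoring-standard document. The schema mirrors the
#' shipped default: top-level `name`, `age_groups` (list of `label` +
#' `energy_range`), and `components`, each with `component_id`,
#' `display_name`, `category` (one of `adequacy`, `moderation`,
#' `limitation`), `unit`, `max_score`, and per-age-group `cutoffs`
#' (adequacy: `recommended_density`; moderation: `lower_density`,
#' `upper_density`, `zero_above_density`; limitation: `limit_density`).
#'
#' @param path Path to a YAML standard document.
#' @return An `index_standard` object (see [cpdi_standard()]).
#' @seealso [write_standard()] for the inverse; round-trips are lossless.
#' @export
read_standard <- function(path) {
  doc <- yaml::read_yaml(path)
  standard_from_list(doc)
}

#' @rdname read_standard
#' @param doc A list following the standard schema (as parsed from YAML).
#' @export
standard_from_list <- function(doc) {
  for (field in c("name", "age_groups", "components")) {
    if (is.null(doc[[field]])) {
      stop("standard document is missing the '", field, "' entry",
           call. = FALSE)
    }
  }
  age_groups <- purrr::map_dfr(doc$age_groups, function(g) {
    if (is.null(g$label) || is.null(g$energy_range) ||
        length(g$energy_range) != 2) {
      stop("each age group needs a 'label' and a 2-element 'energy_range'",
           call. = FALSE)
    }
    tibble::tibble(
      label = as.character(g$label),
      energy_low = as.numeric(g$energy_range[[1]]),
      energy_high = as.numeric(g$energy_range[[2]])
    )
  })
  cutoff_fields <- c("recommended_density", "lower_density", "upper_density",
                     "zero_above_density", "limit_density")
  components <- purrr::map_dfr(doc$components, function(cmp) {
    for (field in c("component_id", "category", "unit", "max_score",
                    "cutoffs")) {
      if (is.null(cmp[[field]])) {
        stop("component '", cmp$component_id %||% "<unnamed>",
             "' is missing '", field, "'", call. = FALSE)
      }
    }
    purrr::map_dfr(age_groups$label, function(lab) {
      cuts <- cmp$cutoffs[[lab]]
      if (is.null(cuts)) {
        stop("component '", cmp$component_id, "' has no cutoffs for age ",
             "group '", lab, "'", call. = FALSE)
      }
      row <- tibble::tibble(
        component_id = cmp$component_id,
        display_name = cmp$display_name %||% cmp$component_id,
        category = cmp$category,
        unit = cmp$unit,
        max_score = as.numeric(cmp$max_score),
        age_group = lab
      )
      for (field in cutoff_fields) {
        row[[field]] <- if (is.null(cuts[[field]])) NA_real_
                        else as.numeric(cuts[[field]])
      }
      row
    })
  })
  validate_standard(new_index_standard(doc$name, age_groups, components))
}

new_index_standard <- function(name, age_groups, components) {
  structure(
    list(name = name, age_groups = age_groups, components = components),
    class = "index_standard"
  )
}

#' Validate an index standard
#'
#' Checks the structural invariants of a scoring standard: unique component
#' ids, positive maximum scores, and for every component x age group the
#' cutoff fields its category requires -- adequacy: `recommended_density > 0`
#' and no interval fields; moderation: `0 < lower <= upper` and
#' `zero_above_density = 2 * upper_density`; limitation: `limit_density > 0`.
#' Errors name the offending component and field.
#'
#' @param standard An `index_standard`.
#' @return The standard, invisibly usable, unchanged.
#' @export
validate_standard <- function(standard) {
  stopifnot(inherits(standard, "index_standard"))
  comps <- standard$components
  ids <- unique(comps$component_id)
  if (anyDuplicated(comps[c("component_id", "age_group")])) {
    stop("duplicate component_id / age_group rows in standard", call. = FALSE)
  }
  if (nrow(standard$age_groups) < 1) {
    stop("standard needs at least one age group", call. = FALSE)
  }
  bad_range <- standard$age_groups$energy_low >= standard$age_groups$energy_high
  if (any(bad_range)) {
    stop("age group '", standard$age_groups$label[bad_range][1],
         "': energy_range low must be < high", call. = FALSE)
  }
  for (i in seq_len(nrow(comps))) {
    row <- comps[i, ]
    id <- paste0(row$component_id, " [", row$age_group, "]")
    if (!row$category %in% c("adequacy", "moderation", "limitation")) {
      stop("component ", id, ": unknown category '", row$category, "'",
           call. = FALSE)
    }
    if (!is.finite(row$max_score) || row$max_score <= 0) {
      stop("component ", id, ": max_score must be > 0", call. = FALSE)
    }
    need <- switch(row$category,
      adequacy = "recommended_density",
      moderation = c("lower_density", "upper_density", "zero_above_density"),
      limitation = "limit_density"
    )
    for (field in need) {
      if (!is.finite(row[[field]])) {
        stop("component ", id, ": missing required field '", field, "'",
             call. = FALSE)
      }
    }
    forbid <- setdiff(c("recommended_density", "lower_density",
                        "upper_density", "zero_above_density",
                        "limit_density"), need)
    for (field in forbid) {
      if (is.finite(row[[field]])) {
        stop("component ", id, ": field '", field, "' is not allowed for ",
             row$category, " components", call. = FALSE)
      }
    }
    if (row$category == "adequacy" && row$recommended_density <= 0) {
      stop("component ", id, ": recommended_density must be > 0",
           call. = FALSE)
    }
    if (row$category == "moderation") {
      if (!(row$lower_density > 0 && row$lower_density <= row$upper_density)) {
        stop("component ", id, ": need 0 < lower_density <= upper_density",
             call. = FALSE)
      }
      if (abs(row$zero_above_density - 2 * row$upper_density) > 1e-9) {
        stop("component ", id, ": zero_above_density must equal ",
             "2 * upper_density", call. = FALSE)
      }
    }
    if (row$category == "limitation" && row$limit_density <= 0) {
      stop("component ", id, ": limit_density must be > 0", call. = FALSE)
    }
  }
  standard
}

#' Write an index standard to a YAML document
#'
#' Serializes a standard so that [read_standard()] recovers an equal object
#' (round-trip identity).
#'
#' @param standard An `index_standard`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_standard <- function(standard, path) {
  stopifnot(inherits(standard, "index_standard"))
  groups <- purrr::pmap(standard$age_groups, function(label, energy_low,
                                                      energy_high) {
    list(label = label, energy_range = c(energy_low, energy_high))
  })
  comps <- standard$components
  comp_docs <- purrr::map(unique(comps$component_id), function(id) {
    rows <- comps[comps$component_id == id, ]
    cutoffs <- list()
    for (j in seq_len(nrow(rows))) {
      row <- rows[j, ]
      fields <- c("recommended_density", "lower_density", "upper_density",
                  "zero_above_density", "limit_density")
      present <- fields[vapply(fields, function(f) is.finite(row[[f]]),
                               logical(1))]
      cutoffs[[row$age_group]] <- as.list(row[present])
    }
    list(
      component_id = id,
      display_name = rows$display_name[1],
      category = rows$category[1],
      unit = rows$unit[1],
      max_score = rows$max_score[1],
      cutoffs = cutoffs
    )
  })
  doc <- list(name = standard$name, age_groups = groups,
              components = comp_docs)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Map a child's age to a CPDI scoring age group
#'
#' The index defines separate cutoffs for completed ages 2-3 (daily energy
#' requirement 1000-1200 kcal) and 4-5 (1200-1400 kcal). Fractional ages are
#' floored to completed years before assignment; ages outside 2-5 are an
#' error because the index is undefined there.
#'
#' @param age_years Numeric vector of ages in years.
#' @return Character vector of age-group labels, `"2-3"` or `"4-5"`.
#' @examples
#' assign_age_group(c(2, 3.6, 5))
#' @export
assign_age_group <- function(age_years) {
  age <- floor(age_years)
  if (any(!is.finite(age)) || any(age < 2 | age > 5)) {
    bad <- age_years[!is.finite(age) | age < 2 | age > 5]
    stop("age outside the index domain [2, 5]: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  ifelse(age <= 3, "2-3", "4-5")
}

#' @export
print.index_standard <- function(x, ...) {
  totals <- unique(x$components[c("component_id", "max_score")])
  cat("<index_standard> ", x$name, "\n", sep = "")
  cat("  ", length(unique(x$components$component_id)), " components, ",
      "max total ", sum(totals$max_score), " points, ",
      nrow(x$age_groups), " age groups (",
      paste(x$age_groups$label, collapse = ", "), ")\n", sep = "")
  print(x$components, n = Inf)
  invisible(x)
}

#' Component ids of a standard, in scoring order
#' @param standard An `index_standard`.
#' @return Character vector of component ids.
#' @export
component_ids <- function(standard) {
  unique(standard$components$component_id)
}

#' Maximum attainable total score of a standard
#' @param standard An `index_standard`.
#' @return A number (90 for the default CPDI).
#' @export
max_total_score <- function(standard) {
  sum(unique(standard$components[c("component_id", "max_score")])$max_score)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
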