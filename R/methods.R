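#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a scored cohort
#'
#' One row per subject x component, with the density the subscore was
#' computed from, ready for dplyr/ggplot2 pipelines.
#'
#' @param x A `cpdi_scores` object.
#' @param ... Unused.
#' @return A tibble: `subject_id`, `age_group`, `component_id`, `density`,
#'   `score`.
#' @export
tidy.cpdi_scores <- function(x, ...) {
  comp_cols <- setdiff(names(x), c("subject_id", "age_group", "total"))
  long_scores <- tibble::as_tibble(as.data.frame(x)) |>
    tidyr::pivot_longer(dplyr::all_of(comp_cols),
                        names_to = "component_id", values_to = "score") |>
    dplyr::select("subject_id", "age_group", "component_id", "score")
  long_dens <- densities(x) |>
    tidyr::pivot_longer(dplyr::all_of(comp_cols),
                        names_to = "component_id", values_to = "density") |>
    dplyr::select("subject_id", "component_id", "density")
  dplyr::left_join(long_scores, long_dens,
                   by = c("subject_id", "component_id")) |>
    dplyr::relocate("density", .before = "score")
}

#' Summarize a scored cohort in one row
#'
#' @param x A `cpdi_scores` object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_rejected`, `mean_total`, `sd_total`,
#'   `p25`, `median_total`, `p75`, `max_total`.
#' @export
glance.cpdi_scores <- function(x, ...) {
  tibble::tibble(
    n = nrow(x),
    n_rejected = nrow(rejects(x)),
    mean_total = mean(x$total),
    sd_total = stats::sd(x$total),
    p25 = unname(stats::quantile(x$total, 0.25, type = 7)),
    median_total = stats::median(x$total),
    p75 = unname(stats::quantile(x$total, 0.75, type = 7)),
    max_total = attr(x, "max_total")
  )
}

#' Tidy a reliability report
#'
#' @param x A `cpdi_reliability` object.
#' @param ... Unused.
#' @return The item-rest correlation tibble (`component_id`, `item_rest_r`,
#'   `undefined`).
#' @export
tidy.cpdi_reliability <- function(x, ...) x$item_rest

#' Summarize a reliability report in one row
#'
#' @param x A `cpdi_reliability` object.
#' @param ... Unused.
#' @return A one-row tibble: `n_subjects`, `alpha_raw`,
#'   `alpha_standardized`, `n_eigen_gt_1`, `cumulative_variance_top_k`.
#' @export
glance.cpdi_reliability <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    alpha_raw = x$alpha_raw,
    alpha_standardized = x$alpha_standardized,
    n_eigen_gt_1 = x$pca$n_eigen_gt_1,
    cumulative_variance_top_k = x$pca$cumulative_variance_top_k
  )
}

#' Plot the total-score distribution of a scored cohort
#'
#' Histogram of totals with the cohort quartiles (the low/medium/high
#' category boundaries) marked.
#'
#' @param object A `cpdi_scores` object.
#' @param binwidth Histogram bin width in points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpdi_scores <- function(object, binwidth = 2.5, ...) {
  df <- tibble::as_tibble(as.data.frame(object))
  cuts <- stats::quantile(df$total, c(0.25, 0.75), type = 7)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$total)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = cuts, linetype = "dashed") +
    ggplot2::labs(x = "Total score (points)", y = "Children",
                  title = "Diet-quality score distribution",
                  subtitle = sprintf("quartile cuts at %.1f and %.1f",
                                     cuts[1], cuts[2])) +
    ggplot2::theme_minimal()
}

#' Scree plot of a reliability report
#'
#' Eigenvalues of the subscore correlation matrix by rank, with the
#' eigenvalue = 1 retention line (Kaiser's rule).
#'
#' @param object A `cpdi_reliability` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cpdi_reliability <- function(object, ...) {
  df <- tibble::tibble(rank = seq_along(object$pca$eigenvalues),
                       eigenvalue = object$pca$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$eigenvalue)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "Component rank", y = "Eigenvalue",
                  title = "Scree plot of index subscores") +
    ggplot2::theme_minimal()
}

#' @export
print.cpdi_scores <- function(x, ...) {
  cat("<cpdi_scores>  standard: ", attr(x, "standard_name"),
      " (max total ", attr(x, "max_total"), ")\n", sep = "")
  rej <- rejects(x)
  if (!is.null(rej) && nrow(rej)) {
    cat("  ", nrow(rej), " subject(s) rejected; see rejects(x)\n", sep = "")
  }
  mc <- attr(x, "missing_components")
  if (length(mc)) {
    cat("  components scored as zero consumption: ",
        paste(mc, collapse = ", "), "\n", sep = "")
  }
  NextMethod()
}
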