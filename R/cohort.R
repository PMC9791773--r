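#' Categorize diet quality by cohort percentiles
#'
#' Divides total scores into `low` (< 25th percentile), `medium` (>= 25th and
#' <= 75th percentile) and `high` (> 75th percentile) diet quality. The cut
#' points are the empirical quartiles of the supplied totals under the
#' linear-interpolation percentile convention ([stats::quantile()] type 7);
#' totals tied with a boundary fall in `medium`, matching the inclusive
#' definition.
#'
#' @param x A data frame with a `total` column (e.g. a `cpdi_scores` result)
#'   or a numeric vector of totals; at least 4 subjects.
#' @return A tibble with the input's `subject_id` (if any), `total`, and a
#'   `category` factor with levels `low < medium < high`. The cut points are
#'   attached as attributes `p25` and `p75`.
#' @examples
#' categorize_quality(c(10, 20, 30, 40, 50, 60, 70, 80))
#' @export
categorize_quality <- function(x) {
  if (is.data.frame(x)) {
    if (!"total" %in% names(x)) {
      stop("data frame input needs a 'total' column", call. = FALSE)
    }
    out <- tibble::as_tibble(x[intersect(c("subject_id", "total"), names(x))])
  } else {
    out <- tibble::tibble(total = as.numeric(x))
  }
  if (nrow(out) < 4) {
    stop("need at least 4 subjects to form quartile categories",
         call. = FALSE)
  }
  p25 <- unname(stats::quantile(out$total, 0.25, type = 7))
  p75 <- unname(stats::quantile(out$total, 0.75, type = 7))
  out$category <- factor(
    dplyr::case_when(
      out$total < p25 ~ "low",
      out$total > p75 ~ "high",
      TRUE ~ "medium"
    ),
    levels = c("low", "medium", "high"), ordered = TRUE)
  attr(out, "p25") <- p25
  attr(out, "p75") <- p75
  out
}

#' Nutrient adequacy ratio
#'
#' Ratio of actual to recommended daily nutrient intake, truncated at 1 so
#' that over-consumption does not inflate adequacy.
#'
#' @param actual Numeric vector of daily intakes (>= 0).
#' @param recommended Recommended daily amounts (> 0), recycled against
#'   `actual`.
#' @return `pmin(actual / recommended, 1)`.
#' @examples
#' nutrient_adequacy_ratio(c(0.3, 1, 2), 1)
#' @export
nutrient_adequacy_ratio <- function(actual, recommended) {
  if (any(!is.finite(recommended)) || any(recommended <= 0)) {
    stop("recommended amounts must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(actual)) || any(actual < 0)) {
    stop("actual intakes must be finite and >= 0", call. = FALSE)
  }
  pmin(actual / recommended, 1)
}

subscore_matrix <- function(x) {
  if (inherits(x, "cpdi_scores") || is.data.frame(x)) {
    cols <- setdiff(names(x), c("subject_id", "age_group", "total",
                                "category"))
    m <- as.matrix(as.data.frame(x)[cols])
  } else {
    m <- as.matrix(x)
  }
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) {
    colnames(m) <- paste0("component_", seq_len(ncol(m)))
  }
  m
}

#' Item-rest correlations of index components
#'
#' For each component, the Spearman rank correlation between its subscore and
#' the rest score (total minus that component) across subjects -- the
#' item-level validity screen of the index. Ties get average ranks. The full
#' pairwise Spearman correlation matrix of the components is attached as
#' attribute `pairwise`.
#'
#' @param x A `cpdi_scores` result, a subscore data frame, or a numeric
#'   matrix (rows = subjects, columns = components); >= 3 subjects and >= 2
#'   components.
#' @return A tibble with `component_id`, `item_rest_r`, and `undefined`
#'   (`TRUE` when a zero-variance column makes the correlation undefined;
#'   `item_rest_r` is then `NA`, never fabricated).
#' @export
item_rest_correlations <- function(x) {
  m <- subscore_matrix(x)
  if (nrow(m) < 3 || ncol(m) < 2) {
    stop("need >= 3 subjects and >= 2 components", call. = FALSE)
  }
  total <- rowSums(m)
  res <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    rest <- total - m[, j]
    undef <- stats::sd(m[, j]) == 0 || stats::sd(rest) == 0
    tibble::tibble(
      component_id = colnames(m)[j],
      item_rest_r = if (undef) NA_real_
                    else stats::cor(m[, j], rest, method = "spearman"),
      undefined = undef
    )
  })
  pairwise <- suppressWarnings(stats::cor(m, method = "spearman"))
  attr(res, "pairwise") <- pairwise
  res
}

#' Cronbach's coefficient alpha
#'
#' Internal-consistency reliability of the index's components. The raw
#' (covariance-based) form is `k/(k-1) * (1 - sum of item variances /
#' variance of the total)`; the standardized (correlation-based) form is
#' `k * rbar / (1 + (k-1) * rbar)` with `rbar` the mean pairwise Pearson
#' correlation. Both conventions are reported side by side by
#' [reliability_report()] since published "standard and nonstandard" alphas
#' rarely say which is which.
#'
#' @param x A `cpdi_scores` result, subscore data frame, or numeric matrix;
#'   >= 3 subjects and >= 2 components.
#' @param standardized Logical; return the correlation-based form?
#' @return A single number <= 1.
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(1.1, 2, 2.9, 4.2))
#' cronbach_alpha(m)
#' cronbach_alpha(m, standardized = TRUE)
#' @export
cronbach_alpha <- function(x, standardized = FALSE) {
  m <- subscore_matrix(x)
  if (nrow(m) < 3 || ncol(m) < 2) {
    stop("need >= 3 subjects and >= 2 components", call. = FALSE)
  }
  k <- ncol(m)
  if (standardized) {
    r <- stats::cor(m)
    if (any(is.na(r))) {
      stop("zero-variance component makes standardized alpha undefined",
           call. = FALSE)
    }
    rbar <- mean(r[lower.tri(r)])
    k * rbar / (1 + (k - 1) * rbar)
  } else {
    total_var <- stats::var(rowSums(m))
    if (total_var == 0) {
      stop("total score has zero variance; alpha undefined", call. = FALSE)
    }
    k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
  }
}

#' Principal-component dimensionality of the index
#'
#' Eigen-decomposition of the correlation matrix of component subscores
#' (correlation, not covariance, because components have unequal score
#' ranges). Reports the sorted eigenvalues, the number exceeding 1 (Kaiser's
#' rule) and the cumulative variance share those factors explain. Constant
#' columns are dropped with a warning before decomposition.
#'
#' @param x A `cpdi_scores` result, subscore data frame, or numeric matrix
#'   with more subjects than components.
#' @return A list: `eigenvalues` (decreasing), `n_eigen_gt_1`,
#'   `cumulative_variance_top_k` (share explained by the eigenvalue > 1
#'   factors), `n_components_retained`, `dropped` (constant columns).
#' @export
pca_dimensions <- function(x) {
  m <- subscore_matrix(x)
  constant <- apply(m, 2, stats::sd) == 0
  if (any(constant)) {
    warning("dropping constant component(s) before PCA: ",
            paste(colnames(m)[constant], collapse = ", "), call. = FALSE)
    m <- m[, !constant, drop = FALSE]
  }
  if (nrow(m) < ncol(m) + 1 || ncol(m) < 2) {
    stop("need more subjects than components (and >= 2 components)",
         call. = FALSE)
  }
  ev <- sort(eigen(stats::cor(m), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  ev <- pmax(ev, 0)  # clip numerically tiny negatives
  n_gt_1 <- sum(ev > 1)
  list(
    eigenvalues = ev,
    n_eigen_gt_1 = n_gt_1,
    cumulative_variance_top_k = if (n_gt_1 > 0)
      sum(ev[seq_len(n_gt_1)]) / length(ev) else 0,
    n_components_retained = length(ev),
    dropped = colnames(subscore_matrix(x))[constant]
  )
}

#' Correlate total scores with nutrient intakes
#'
#' Spearman rank correlation (with two-sided p-value) between per-subject
#' total scores and each nutrient column -- the construct-validity check that
#' higher index scores track higher energy and nutrient adequacy.
#'
#' @param scores A `cpdi_scores` result, or a data frame with `subject_id`
#'   and `total`.
#' @param nutrients A data frame with `subject_id` and one numeric column per
#'   nutrient (e.g. daily intakes or adequacy ratios). When `NULL` and
#'   `scores` is a `cpdi_scores` object, the mean daily intakes of the
#'   non-component record columns are used. Subjects must match `scores`
#'   one-to-one.
#' @return A tibble: `nutrient`, `rho`, `p_value`, `n`.
#' @export
correlate_with_nutrients <- function(scores, nutrients = NULL) {
  if (is.null(nutrients)) {
    nutrients <- attr(scores, "nutrients")
    if (is.null(nutrients)) {
      stop("supply 'nutrients' or a cpdi_scores object carrying them",
           call. = FALSE)
    }
  }
  if (!all(c("subject_id", "total") %in% names(scores))) {
    stop("scores need columns 'subject_id' and 'total'", call. = FALSE)
  }
  if (!"subject_id" %in% names(nutrients)) {
    stop("nutrients need a 'subject_id' column", call. = FALSE)
  }
  if (!setequal(scores$subject_id, nutrients$subject_id) ||
      nrow(scores) != nrow(nutrients)) {
    stop("scores and nutrients cover different subjects", call. = FALSE)
  }
  merged <- dplyr::inner_join(
    tibble::as_tibble(as.data.frame(scores)[c("subject_id", "total")]),
    tibble::as_tibble(nutrients), by = "subject_id")
  cols <- setdiff(names(merged), c("subject_id", "total"))
  cols <- cols[vapply(merged[cols], is.numeric, logical(1))]
  purrr::map_dfr(cols, function(nm) {
    ct <- suppressWarnings(
      stats::cor.test(merged$total, merged[[nm]], method = "spearman",
                      exact = FALSE))
    tibble::tibble(nutrient = nm, rho = unname(ct$estimate),
                   p_value = ct$p.value, n = nrow(merged))
  })
}

#' Reliability and dimensionality report for a scored cohort
#'
#' Bundles the index-validation statistics computed on the component
#' subscores: raw and standardized Cronbach's alpha, per-component item-rest
#' Spearman correlations (with the full pairwise correlation matrix), and
#' the principal-component eigenvalue screen.
#'
#' @inheritParams pca_dimensions
#' @return A `cpdi_reliability` object (list with `alpha_raw`,
#'   `alpha_standardized`, `item_rest`, `pairwise`, `pca`, `n_subjects`).
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()] (scree plot).
#' @examples
#' m <- simulate_factor_subscores(n = 200, k = 11, loading = 0.6, seed = 1)
#' reliability_report(m)
#' @export
reliability_report <- function(x) {
  m <- subscore_matrix(x)
  ir <- item_rest_correlations(m)
  structure(
    list(
      alpha_raw = cronbach_alpha(m, standardized = FALSE),
      alpha_standardized = cronbach_alpha(m, standardized = TRUE),
      item_rest = ir,
      pairwise = attr(ir, "pairwise"),
      pca = pca_dimensions(m),
      n_subjects = nrow(m)
    ),
    class = "cpdi_reliability"
  )
}

#' @export
print.cpdi_reliability <- function(x, ...) {
  cat("<cpdi_reliability>  n =", x$n_subjects, "subjects,",
      nrow(x$item_rest), "components\n")
  cat(sprintf("  Cronbach's alpha: raw %.3f, standardized %.3f\n",
              x$alpha_raw, x$alpha_standardized))
  cat(sprintf("  PCA: %d eigenvalue(s) > 1, explaining %.1f%% of variance\n",
              x$pca$n_eigen_gt_1, 100 * x$pca$cumulative_variance_top_k))
  cat("  Item-rest Spearman r:\n")
  print(x$item_rest, n = Inf)
  invisible(x)
}
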