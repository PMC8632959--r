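#' Round half up to a fixed number of decimals
#'
#' Clinical percentages are conventionally printed with exact half-up rounding
#' (base `round()` rounds half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Severity band of a rating-scale score
#'
#' SAS / SDS (index scores): below 50 none; 50-59 mild; 60-69 moderate; 70 and
#' above severe. HAMD: below 8 none; 8-20 mild; above 20 up to 35
#' mild-to-moderate; above 35 severe (the 20/34/35 band edges overlap in
#' common usage; bands here are the half-open intervals `[8, 20]`,
#' `(20, 35]`, `(35, Inf)`).
#'
#' @param instrument `"SAS"`, `"SDS"`, or `"HAMD"`.
#' @param score Numeric score(s), >= 0.
#' @return A character vector of categories.
#' @examples
#' classify_severity("SAS", 55)   # "mild"
#' classify_severity("HAMD", 36)  # "severe"
#' @export
classify_severity <- function(instrument, score) {
  instrument <- match.arg(instrument, c("SAS", "SDS", "HAMD"))
  if (any(score < 0)) abort("scores must be nonnegative.")
  if (instrument %in% c("SAS", "SDS")) {
    dplyr::case_when(
      score < 50 ~ "none",
      score < 60 ~ "mild",
      score < 70 ~ "moderate",
      TRUE ~ "severe"
    )
  } else {
    dplyr::case_when(
      score < 8 ~ "none",
      score <= 20 ~ "mild",
      score <= 35 ~ "mild_to_moderate",
      TRUE ~ "severe"
    )
  }
}

#' HAMD score reduction rate
#'
#' `100 * (baseline - post) / baseline`, in percent.
#'
#' @param baseline Pre-treatment HAMD score(s) (> 0).
#' @param post Post-treatment HAMD score(s).
#' @return Reduction rate(s) in percent.
#' @examples
#' hamd_reduction_rate(32, 6)  # 81.25
#' @export
hamd_reduction_rate <- function(baseline, post) {
  if (any(baseline <= 0)) abort("`baseline` must be positive.")
  100 * (baseline - post) / baseline
}

efficacy_levels <- c("cured", "markedly_effective", "effective", "ineffective")
compliance_levels <- c("complete", "basic", "non")

#' Efficacy category from a HAMD reduction rate
#'
#' Reduction above 75% is cured; (50, 75] markedly effective; (25, 50]
#' effective; at or below 25% ineffective (a rate of exactly 25% falls in the
#' ineffective band so the four bands partition the line).
#'
#' @param reduction_rate_percent Reduction rate(s) in percent.
#' @return A factor with levels cured / markedly_effective / effective /
#'   ineffective.
#' @examples
#' classify_efficacy(c(81.25, 60, 30, 14.3))
#' @export
classify_efficacy <- function(reduction_rate_percent) {
  out <- dplyr::case_when(
    reduction_rate_percent > 75 ~ "cured",
    reduction_rate_percent > 50 ~ "markedly_effective",
    reduction_rate_percent > 25 ~ "effective",
    TRUE ~ "ineffective"
  )
  factor(out, levels = efficacy_levels)
}

#' Per-group outcome table with derived totals and percentages
#'
#' Counts patients per category within each group and derives percentages
#' (half-up, 2 decimals) plus the composite rows: `total_effective`
#' (cured + markedly_effective + effective) for efficacy outcomes, or
#' `total_compliant` (complete + basic) for compliance outcomes.
#'
#' @param categories Per-patient category labels (efficacy or compliance).
#' @param groups Per-patient group labels.
#' @param type `"efficacy"` or `"compliance"`; inferred from the categories
#'   when `NULL`.
#' @return A tibble of class `clinical_outcomes` with columns `group`,
#'   `category`, `count`, `n_total`, `pct`; composite totals appear as extra
#'   `category` rows.
#' @examples
#' cats <- rep(c("cured", "markedly_effective", "effective", "ineffective"),
#'             c(12, 8, 5, 2))
#' aggregate_outcomes(cats, rep("intervention", 27))
#' @export
aggregate_outcomes <- function(categories, groups, type = NULL) {
  if (length(categories) != length(groups)) abort("length mismatch.")
  categories <- as.character(categories)
  if (is.null(type)) {
    type <- if (any(categories %in% efficacy_levels)) "efficacy" else "compliance"
  }
  type <- match.arg(type, c("efficacy", "compliance"))
  lev <- if (type == "efficacy") efficacy_levels else compliance_levels
  bad <- setdiff(categories, lev)
  if (length(bad)) {
    abort(paste0("unknown category(ies): ", paste(unique(bad), collapse = ", ")))
  }
  composite <- if (type == "efficacy") {
    list(name = "total_effective", members = lev[1:3])
  } else {
    list(name = "total_compliant", members = lev[1:2])
  }
  out <- purrr::map_dfr(sort(unique(groups)), function(g) {
    cats <- categories[groups == g]
    n <- length(cats)
    counts <- table(factor(cats, levels = lev))
    base <- tibble(group = g, category = lev, count = as.integer(counts))
    comp <- tibble(group = g, category = composite$name,
                   count = sum(counts[composite$members]))
    dplyr::mutate(dplyr::bind_rows(base, comp),
                  n_total = n,
                  pct = round_half_up(100 * .data$count / n, 2))
  })
  class(out) <- c("clinical_outcomes", class(out))
  out
}

#' Pearson chi-square test for a 2x2 count table
#'
#' Pearson chi-square without continuity correction by default (Yates
#' correction available via `correct = TRUE`); p-value from the chi-square
#' distribution with 1 degree of freedom.
#'
#' @param table_counts A 2x2 matrix of nonnegative integer counts with no zero
#'   marginal.
#' @param correct Apply the Yates continuity correction.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_2x2(matrix(c(25, 16, 2, 11), 2))
#' @export
chi_square_2x2 <- function(table_counts, correct = FALSE) {
  m <- as.matrix(table_counts)
  if (!all(dim(m) == c(2L, 2L))) abort("`table_counts` must be 2x2.")
  if (any(m < 0) || any(m != floor(m))) abort("counts must be nonnegative integers.")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("zero marginal: the test is undefined.")
  }
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = unname(ct$p.value))
}

#' Welch two-sample t-test
#'
#' Welch's unequal-variance t statistic with the two-sided p-value. When both
#' groups are constant with equal means the test statistic is taken as 0 with
#' p = 1.
#'
#' @param group_a_values,group_b_values Numeric vectors (each n >= 2).
#' @return A tibble with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(group_a_values, group_b_values) {
  if (length(group_a_values) < 2 || length(group_b_values) < 2) {
    abort("each group needs at least two observations.")
  }
  if (sd(group_a_values) == 0 && sd(group_b_values) == 0) {
    same <- mean(group_a_values) == mean(group_b_values)
    return(tibble(t = if (same) 0 else Inf,
                  df = length(group_a_values) + length(group_b_values) - 2,
                  p_value = if (same) 1 else 0,
                  mean_a = mean(group_a_values), mean_b = mean(group_b_values)))
  }
  tt <- t.test(group_a_values, group_b_values, var.equal = FALSE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value,
         mean_a = mean(group_a_values), mean_b = mean(group_b_values))
}

#' Group-comparison tests over a cohort table
#'
#' For every instrument and timepoint in a long cohort table (schema of
#' [simulate_cohort()]), runs the Welch t-test between the control and
#' intervention groups.
#'
#' @param cohort A tibble with columns `group`, `patient_id`, `instrument`,
#'   `timepoint`, `score`.
#' @return A tibble with one row per (instrument, timepoint): group means,
#'   `t`, `df`, `p_value`.
#' @export
cohort_tests <- function(cohort) {
  need <- c("group", "instrument", "timepoint", "score")
  if (!all(need %in% names(cohort))) {
    abort("`cohort` must have columns group, patient_id, instrument, timepoint, score.")
  }
  combos <- dplyr::distinct(cohort, .data$instrument, .data$timepoint)
  purrr::pmap_dfr(combos, function(instrument, timepoint) {
    sub <- cohort[cohort$instrument == instrument & cohort$timepoint == timepoint, ]
    res <- two_sample_t(sub$score[sub$group == "control"],
                        sub$score[sub$group == "intervention"])
    dplyr::bind_cols(tibble(instrument = instrument, timepoint = timepoint),
                     dplyr::rename(res, mean_control = "mean_a",
                                   mean_intervention = "mean_b"))
  })
}
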