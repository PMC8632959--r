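#' One-way ANOVA variance decomposition of a single feature
#'
#' Decomposes a feature's values by class into the total sum of squares about
#' the grand mean (`tv`), the between-group component (`bgv`) and the
#' within-group component (`wgv`), with mean squares `msg = bgv / (k - 1)`,
#' `msw = wgv / (N - k)` and `f_score = msg / msw`. Perfect within-group
#' homogeneity with distinct group means (`wgv = 0`, `bgv > 0`) yields
#' `f_score = Inf`, which ranks first.
#'
#' @param values Numeric feature values.
#' @param groups Group labels (>= 2 distinct groups, >= k + 1 observations).
#' @return A list of class `anova_decomposition` with fields `tv`, `bgv`,
#'   `wgv`, `msg`, `msw`, `f_score`, `k`, `n`.
#' @examples
#' anova_decompose(c(1, 2, 3, 4), c("A", "A", "B", "B"))$f_score  # 8
#' @export
anova_decompose <- function(values, groups) {
  if (length(values) != length(groups)) abort("`values` and `groups` lengths differ.")
  groups <- as.factor(as.character(groups))
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2) abort("need at least two groups.")
  if (n <= k) abort("need more observations than groups.")
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  tv <- sum((values - grand)^2)
  bgv <- sum(gn * (gm - grand)^2)
  wgv <- sum((values - gm[groups])^2)
  msg <- bgv / (k - 1)
  msw <- wgv / (n - k)
  f <- if (msw == 0) {
    if (bgv > 0) Inf else 0
  } else {
    msg / msw
  }
  structure(list(tv = tv, bgv = bgv, wgv = wgv, msg = msg, msw = msw,
                 f_score = f, k = k, n = n),
            class = "anova_decomposition")
}

#' @export
print.anova_decomposition <- function(x, ...) {
  cat(sprintf("<anova_decomposition> k = %d groups, N = %d\n", x$k, x$n))
  cat(sprintf("  tv = %.6g  bgv = %.6g  wgv = %.6g\n", x$tv, x$bgv, x$wgv))
  cat(sprintf("  msg = %.6g  msw = %.6g  F = %.6g\n", x$msg, x$msw, x$f_score))
  invisible(x)
}

#' @export
tidy.anova_decomposition <- function(x, ...) {
  tibble(tv = x$tv, bgv = x$bgv, wgv = x$wgv, msg = x$msg, msw = x$msw,
         f_score = x$f_score, k = x$k, n = x$n)
}

#' Mutual information of two discrete sequences
#'
#' Plug-in estimate from the empirical joint frequency table,
#' `I = sum p(x, y) log2( p(x, y) / (p(x) p(y)) )` with `0 log 0 = 0`.
#'
#' @param x,y Equal-length category sequences.
#' @return Mutual information in bits (>= 0 up to floating error).
#' @examples
#' z <- rep(c(0, 1), 50)
#' mutual_information_discrete(z, z)  # 1 bit
#' @export
mutual_information_discrete <- function(x, y) {
  if (!length(x)) abort("empty input.")
  if (length(x) != length(y)) abort("`x` and `y` lengths differ.")
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  terms <- joint * log2(joint / outer(px, py))
  sum(terms[joint > 0])
}

#' Mutual information of two continuous sequences (binned estimator)
#'
#' Approximates the density-based definition by discretizing both variables
#' into `mi_bins` equal-width bins over their observed ranges and applying the
#' discrete plug-in estimator to the bin indices. A constant variable occupies
#' a single bin and returns 0.
#'
#' @param x,y Equal-length numeric vectors.
#' @param mi_bins Number of equal-width bins per axis (>= 2).
#' @return Mutual information in bits.
#' @export
mutual_information_continuous <- function(x, y, mi_bins = 10) {
  if (!length(x)) abort("empty input.")
  if (length(x) != length(y)) abort("`x` and `y` lengths differ.")
  mi_bins <- check_count(mi_bins, "mi_bins", min = 2L)
  mutual_information_discrete(bin_equal_width(x, mi_bins),
                              bin_equal_width(y, mi_bins))
}

bin_equal_width <- function(x, bins) {
  if (max(x) == min(x)) return(rep(1L, length(x)))
  brk <- seq(min(x), max(x), length.out = bins + 1L)
  as.integer(cut(x, breaks = brk, include.lowest = TRUE))
}

# MI of a continuous feature against a (discrete) label
mi_feature_label <- function(x, label, mi_bins) {
  mutual_information_discrete(bin_equal_width(x, mi_bins), label)
}

#' Per-feature filter scores
#'
#' Computes the ANOVA F-score and the mutual information with the label (in
#' bits, binned estimator) for every feature column.
#'
#' @param data A data frame with feature columns and a class column.
#' @param label Name of the class column.
#' @param mi_bins Bins for the continuous MI estimator.
#' @return A tibble with columns `feature`, `f_score`, `mi_bits`.
#' @export
filter_scores <- function(data, label = "label", mi_bins = 10) {
  if (!label %in% names(data)) abort(sprintf("no `%s` column in `data`.", label))
  y <- as.factor(data[[label]])
  if (nlevels(y) < 2) abort("`data` must contain at least two classes.")
  feats <- setdiff(names(data), label)
  tibble(
    feature = feats,
    f_score = vapply(feats, function(f) anova_decompose(data[[f]], y)$f_score,
                     numeric(1)),
    mi_bits = vapply(feats, function(f) mi_feature_label(data[[f]], y, mi_bins),
                     numeric(1))
  )
}

#' Filter-stage feature selection: union of ANOVA and MI top-k sets
#'
#' Ranks features by ANOVA F-score and, separately, by mutual information with
#' the label, then selects the union of the two top-k sets as the new feature
#' space. Ties are broken by ascending feature index, so the selection is fully
#' reproducible.
#'
#' @param data A data frame with feature columns and a class column.
#' @param k_anova,k_mi Sizes of the two top-k sets; default
#'   `ceiling(n_features / 2)` each.
#' @param mi_bins Bins for the continuous MI estimator.
#' @param label Name of the class column.
#' @return An object of class `fawfs_filter`: list with `selected` (feature
#'   names, in column order), `mask` (named logical vector over all features),
#'   `scores` (the [filter_scores()] table with a `selected` flag), and the
#'   `k_anova` / `k_mi` used.
#' @examples
#' d <- simulate_classification(200, 10, 3, effect_size = 2, seed = 1)
#' filter_union(d, k_anova = 3, k_mi = 3)
#' @export
filter_union <- function(data, k_anova = NULL, k_mi = NULL, mi_bins = 10,
                         label = "label") {
  sc <- filter_scores(data, label = label, mi_bins = mi_bins)
  p <- nrow(sc)
  k_anova <- check_count(k_anova %||% ceiling(p / 2), "k_anova")
  k_mi <- check_count(k_mi %||% ceiling(p / 2), "k_mi")
  if (k_anova > p || k_mi > p) abort("`k_anova` and `k_mi` must not exceed n_features.")
  top_k <- function(score, k) {
    ord <- order(-score, seq_along(score))  # ties -> lower feature index first
    sort(ord[seq_len(k)])
  }
  sel_idx <- sort(union(top_k(sc$f_score, k_anova), top_k(sc$mi_bits, k_mi)))
  mask <- setNames(seq_len(p) %in% sel_idx, sc$feature)
  sc$selected <- mask
  structure(
    list(selected = sc$feature[sel_idx], mask = mask, scores = sc,
         k_anova = k_anova, k_mi = k_mi),
    class = "fawfs_filter"
  )
}

#' @export
print.fawfs_filter <- function(x, ...) {
  cat(sprintf("<fawfs_filter> %d / %d features selected (k_anova = %d, k_mi = %d)\n",
              length(x$selected), nrow(x$scores), x$k_anova, x$k_mi))
  cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.fawfs_filter <- function(x, ...) x$scores

#' @export
autoplot.fawfs_filter <- function(object, ...) {
  df <- tidyr::pivot_longer(object$scores, c("f_score", "mi_bits"),
                            names_to = "criterion", values_to = "score")
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$score,
                                   fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$criterion), scales = "free_y") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = "score")
}
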