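#' Classification accuracy
#'
#' Fraction of positions where the predicted label equals the true label.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return A fraction in `[0, 1]`.
#' @export
accuracy_score <- function(y_true, y_pred) {
  if (!length(y_true)) abort("empty input.")
  if (length(y_true) != length(y_pred)) abort("length mismatch.")
  mean(as.character(y_true) == as.character(y_pred))
}

#' Stratified fold assignment
#'
#' Assigns every sample to exactly one validation fold. Under stratification,
#' each class's indices are shuffled and dealt round-robin, so fold class
#' proportions track the full dataset's.
#'
#' @param y Class labels.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @param stratified Stratify by class (default `TRUE`).
#' @return An integer vector of fold ids in `1..n_folds`, one per sample.
#' @export
make_folds <- function(y, n_folds = 5, seed = 1L, stratified = TRUE) {
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  y <- as.factor(y)
  if (stratified && any(table(y) < n_folds)) {
    abort("stratification impossible: a class has fewer samples than folds.")
  }
  withr::with_seed(seed, {
    folds <- integer(length(y))
    if (stratified) {
      for (lv in levels(y)) {
        idx <- sample(which(y == lv))
        folds[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      folds <- sample(rep_len(seq_len(n_folds), length(y)))
    }
    folds
  })
}

#' Cross-validated evaluation of a feature subset
#'
#' The paper-style five-subset protocol: the data are split into `n_folds`
#' stratified folds; the classifier is trained on all but one fold and scored
#' on the held-out fold, rotating until every fold has served as the
#' verification set once.
#'
#' @param data A data frame with feature columns and a class column.
#' @param mask Logical/character selection of feature columns, or `NULL` for
#'   all features.
#' @param classifier One of `"lr"`, `"dt"`, `"knn"`, `"svm"`, `"rf"`.
#' @param n_folds Number of folds (default 5).
#' @param seed Seed controlling fold assignment and any classifier randomness.
#' @param stratified Stratify folds by class.
#' @param label Name of the class column.
#' @param params Per-classifier settings (see package defaults).
#' @return An object of class `fawfs_eval`: fields `classifier`, `features`,
#'   `fold_accuracy`, `mean_accuracy`, `n_samples`, `n_features_selected`.
#' @examples
#' d <- simulate_classification(120, 8, 3, effect_size = 1.5, seed = 2)
#' cross_validate(d, classifier = "knn", seed = 3)
#' @export
cross_validate <- function(data, mask = NULL, classifier = "lr", n_folds = 5,
                           seed = 1L, stratified = TRUE, label = "label",
                           params = list()) {
  classifier <- match.arg(classifier, classifier_names)
  if (!label %in% names(data)) abort(sprintf("no `%s` column in `data`.", label))
  y <- as.factor(data[[label]])
  feats <- resolve_mask(data, mask, label)
  if (!length(feats)) abort("`mask` selects no features.")
  x <- as.matrix(data[feats])
  folds <- make_folds(y, n_folds, seed = seed, stratified = stratified)
  stopifnot(sort(unique(folds)) == seq_len(n_folds))
  acc <- withr::with_seed(derive_seed(seed, 7L), {
    vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      pred <- fit_predict(classifier, x[tr, , drop = FALSE], y[tr],
                          x[!tr, , drop = FALSE], params)
      accuracy_score(y[!tr], pred)
    }, numeric(1))
  })
  structure(
    list(classifier = classifier, features = feats, fold_accuracy = acc,
         mean_accuracy = mean(acc), n_samples = nrow(data),
         n_features_selected = length(feats), n_folds = n_folds, seed = seed),
    class = "fawfs_eval"
  )
}

resolve_mask <- function(data, mask, label) {
  feats <- setdiff(names(data), label)
  if (is.null(mask)) return(feats)
  if (is.logical(mask)) {
    if (!is.null(names(mask))) return(intersect(names(mask)[mask], feats))
    if (length(mask) != length(feats)) abort("logical `mask` length mismatch.")
    return(feats[mask])
  }
  if (is.character(mask)) {
    missing <- setdiff(mask, feats)
    if (length(missing)) abort(paste0("unknown feature(s): ", paste(missing, collapse = ", ")))
    return(mask)
  }
  abort("`mask` must be NULL, a logical vector or feature names.")
}

#' @export
print.fawfs_eval <- function(x, ...) {
  cat(sprintf("<fawfs_eval> %s: mean CV accuracy %.4f over %d folds (%d features, n = %d)\n",
              x$classifier, x$mean_accuracy, x$n_folds,
              x$n_features_selected, x$n_samples))
  invisible(x)
}

#' @export
tidy.fawfs_eval <- function(x, ...) {
  tibble(classifier = x$classifier, fold = seq_along(x$fold_accuracy),
         accuracy = x$fold_accuracy)
}

#' @export
glance.fawfs_eval <- function(x, ...) {
  tibble(classifier = x$classifier, mean_accuracy = x$mean_accuracy,
         n_folds = x$n_folds, n_samples = x$n_samples,
         n_features_selected = x$n_features_selected)
}

#' Run the full FAW-FS pipeline on a labeled dataset
#'
#' Filter stage ([filter_union()]), wrapper stage ([run_ga()]) within the
#' filter union, then cross-validated evaluation of the selected subset with
#' each requested classifier. Returns a one-row-per-classifier tibble carrying
#' provenance metadata (config hash, seed, package version) as attributes; when
#' `out_dir` is given the per-feature scores, GA history, final mask and result
#' table are written there as CSV/JSON.
#'
#' @param data A data frame with feature columns and a class column (build one
#'   from EEG recordings with [feature_matrix()]).
#' @param label Name of the class column.
#' @param k_anova,k_mi Filter-stage subset sizes (defaults as in
#'   [filter_union()]).
#' @param cfg A [ga_config()] for the wrapper stage.
#' @param fitness_classifier Classifier whose cross-validated accuracy drives
#'   the GA fitness (`"knn"` by default, see [run_ga()]).
#' @param classifiers Classifier names to evaluate the final mask with.
#' @param n_folds Folds for the evaluation protocol.
#' @param seed Seed for the evaluation protocol (the GA uses `cfg$seed`).
#' @param out_dir Optional output directory for artifacts.
#' @return A tibble of class `fawfs_pipeline`: columns `classifier`,
#'   `mean_accuracy`, `fold_accuracy` (list), `n_selected`, `n_samples`;
#'   attributes `selected`, `filter`, `ga`, `config_hash`, `seed`.
#' @export
run_pipeline <- function(data, label = "label", k_anova = NULL, k_mi = NULL,
                         cfg = ga_config(), fitness_classifier = "knn",
                         classifiers = classifier_names, n_folds = 5,
                         seed = 1L, out_dir = NULL) {
  classifiers <- match.arg(classifiers, classifier_names, several.ok = TRUE)
  feats <- setdiff(names(data), label)
  if (all(vapply(data[feats], function(x) sd(as.numeric(x)) == 0, logical(1)))) {
    abort("pipeline error at filter stage: the feature matrix has only constant columns.")
  }
  flt <- filter_union(data, k_anova = k_anova, k_mi = k_mi, label = label)
  ga <- run_ga(data, union_mask = flt$mask, cfg = cfg,
               classifier = fitness_classifier, label = label)
  evals <- purrr::map(classifiers, function(cl) {
    cross_validate(data, mask = ga$selected, classifier = cl,
                   n_folds = n_folds, seed = seed, label = label)
  })
  out <- purrr::map_dfr(evals, function(e) {
    tibble(classifier = e$classifier, mean_accuracy = e$mean_accuracy,
           fold_accuracy = list(e$fold_accuracy),
           n_selected = e$n_features_selected, n_samples = e$n_samples)
  })
  hash <- rlang::hash(list(label, k_anova, k_mi, cfg, fitness_classifier,
                           classifiers, n_folds, seed))
  attr(out, "selected") <- ga$selected
  attr(out, "filter") <- flt
  attr(out, "ga") <- ga
  attr(out, "config_hash") <- hash
  attr(out, "seed") <- seed
  class(out) <- c("fawfs_pipeline", class(out))
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- sprintf("config_hash,%s\nseed,%s\nfawfs_version,%s\n",
                  attr(result, "config_hash"), attr(result, "seed"),
                  as.character(utils::packageVersion("fawfs")))
  writeLines(meta, file.path(out_dir, "provenance.csv"))
  readr::write_csv(tidy(attr(result, "filter")),
                   file.path(out_dir, "filter_scores.csv"))
  readr::write_csv(tidy(attr(result, "ga")),
                   file.path(out_dir, "ga_history.csv"))
  writeLines(paste0("[", paste(sprintf('"%s"', attr(result, "selected")),
                               collapse = ","), "]"),
             file.path(out_dir, "selected_features.json"))
  flat <- dplyr::select(tidyr::unnest(
    dplyr::mutate(as_tibble(result),
                  fold = purrr::map(.data$fold_accuracy, seq_along)),
    c("fold_accuracy", "fold")
  ), "classifier", "fold", accuracy = "fold_accuracy", "n_selected", "n_samples")
  readr::write_csv(flat, file.path(out_dir, "results.csv"))
  invisible(out_dir)
}

#' Compare selector stages on one dataset
#'
#' Evaluates mean cross-validated accuracy per classifier under three feature
#' sets: all features (`none`), the filter union (`filter_only`), and the full
#' FAW-FS selection (`faw_fs`).
#'
#' @inheritParams run_pipeline
#' @return A tibble with columns `selector`, `classifier`, `mean_accuracy`,
#'   `n_selected`.
#' @export
compare_selectors <- function(data, label = "label", k_anova = NULL,
                              k_mi = NULL, cfg = ga_config(),
                              fitness_classifier = "knn",
                              classifiers = classifier_names,
                              n_folds = 5, seed = 1L) {
  classifiers <- match.arg(classifiers, classifier_names, several.ok = TRUE)
  flt <- filter_union(data, k_anova = k_anova, k_mi = k_mi, label = label)
  ga <- run_ga(data, union_mask = flt$mask, cfg = cfg,
               classifier = fitness_classifier, label = label)
  masks <- list(none = NULL, filter_only = flt$selected, faw_fs = ga$selected)
  purrr::imap_dfr(masks, function(m, nm) {
    purrr::map_dfr(classifiers, function(cl) {
      e <- cross_validate(data, mask = m, classifier = cl, n_folds = n_folds,
                          seed = seed, label = label)
      tibble(selector = nm, classifier = cl, mean_accuracy = e$mean_accuracy,
             n_selected = e$n_features_selected)
    })
  })
}
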