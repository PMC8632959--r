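#' Wrapper-stage (GA + simulated annealing) configuration
#'
#' All hyperparameters of the genetic search: population size, generation and
#' local-search budgets, crossover/mutation probabilities, the
#' simulated-annealing temperature schedule and energy scale, elitism, the
#' fitness baseline, and the seed.
#'
#' @param population_size Individuals per generation.
#' @param n_generations Generation budget (0 = return the best of the random
#'   initial population).
#' @param local_search_iters Single-bit-flip proposals per individual per
#'   generation, judged by the annealing acceptance rule.
#' @param crossover_prob Probability that a mating pair undergoes single-point
#'   crossover.
#' @param mutation_prob Per-bit flip probability.
#' @param initial_temperature Starting temperature `T0` (> 0); the temperature
#'   at generation `g` is exactly `T0 * cooling_rate^g`.
#' @param cooling_rate Geometric cooling factor in (0, 1).
#' @param energy_scale Multiplier `E` of the energy difference in the
#'   acceptance probability `exp(-E * delta / T)`.
#' @param elitism Number of best individuals carried over unchanged (>= 1,
#'   `< population_size`).
#' @param fitness_baseline Baseline `D` subtracted from the cross-validated
#'   accuracy (fitness is the rectified excess); `NULL` uses the
#'   majority-class rate.
#' @param fitness_repeats Number of repeated stratified CV splits averaged
#'   into the fitness (>= 1). A single split lets the search overfit fold
#'   noise; averaging a few independent splits keeps the wrapper honest at a
#'   proportional evaluation cost.
#' @param patience Stop when the population best has not improved for this
#'   many generations.
#' @param seed Integer seed; the whole search is reproducible bit for bit.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 30, n_generations = 50,
                      local_search_iters = 10, crossover_prob = 0.8,
                      mutation_prob = 0.02, initial_temperature = 1,
                      cooling_rate = 0.95, energy_scale = 1, elitism = 1,
                      fitness_baseline = NULL, fitness_repeats = 3,
                      patience = 10, seed = 1L) {
  population_size <- check_count(population_size, "population_size", min = 2L)
  n_generations <- check_count(n_generations, "n_generations", min = 0L)
  local_search_iters <- check_count(local_search_iters, "local_search_iters", min = 0L)
  crossover_prob <- check_number(crossover_prob, "crossover_prob", 0, 1)
  mutation_prob <- check_number(mutation_prob, "mutation_prob", 0, 1)
  initial_temperature <- check_number(initial_temperature, "initial_temperature",
                                      min = 0, open_min = TRUE)
  cooling_rate <- check_number(cooling_rate, "cooling_rate", 0, 1,
                               open_min = TRUE, open_max = TRUE)
  energy_scale <- check_number(energy_scale, "energy_scale", min = 0, open_min = TRUE)
  elitism <- check_count(elitism, "elitism", min = 1L)
  if (elitism >= population_size) abort("`elitism` must be below `population_size`.")
  fitness_repeats <- check_count(fitness_repeats, "fitness_repeats", min = 1L)
  patience <- check_count(patience, "patience", min = 1L)
  if (!is.null(fitness_baseline)) {
    fitness_baseline <- check_number(fitness_baseline, "fitness_baseline")
  }
  structure(
    list(population_size = population_size, n_generations = n_generations,
         local_search_iters = local_search_iters,
         crossover_prob = crossover_prob, mutation_prob = mutation_prob,
         initial_temperature = initial_temperature,
         cooling_rate = cooling_rate, energy_scale = energy_scale,
         elitism = elitism, fitness_baseline = fitness_baseline,
         fitness_repeats = fitness_repeats,
         patience = patience, seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Rectified wrapper fitness of a feature mask
#'
#' `f(x)` is the mean cross-validated accuracy of the classifier on the masked
#' features; the fitness is the rectified excess over the baseline `D`:
#' `Fit = f(x) - D` when `f(x) > D`, else `0`. `D` defaults to the
#' majority-class rate, so a subset must beat the trivial classifier to score
#' at all.
#'
#' @inheritParams cross_validate
#' @param baseline Baseline `D`; `NULL` uses the majority-class rate.
#' @return A list with `fitness`, `cv_accuracy`, `baseline`.
#' @export
fitness_score <- function(data, mask, classifier = "lr", n_folds = 5,
                          seed = 1L, baseline = NULL, label = "label") {
  feats <- resolve_mask(data, mask, label)
  if (!length(feats)) abort("empty mask: the fitness of zero features is undefined.")
  y <- as.factor(data[[label]])
  d <- baseline %||% (max(table(y)) / length(y))
  f <- cross_validate(data, mask = feats, classifier = classifier,
                      n_folds = n_folds, seed = seed, label = label)$mean_accuracy
  list(fitness = if (f > d) f - d else 0, cv_accuracy = f, baseline = d)
}

#' Simulated-annealing acceptance rule
#'
#' Energies are minimized (`e = 1 - Fit`). A candidate whose energy does not
#' exceed the incumbent's is accepted with probability 1; a worse candidate is
#' accepted with probability `exp(-energy_scale * delta / temperature)`,
#' `delta = e_candidate - e_current`. One uniform draw is consumed per call, so
#' seeded runs are reproducible regardless of the decision path.
#'
#' @param e_current Incumbent energy.
#' @param e_candidate Proposed energy.
#' @param temperature Current temperature (> 0).
#' @param energy_scale Energy multiplier `E`.
#' @return A list with `accepted` (logical) and `prob`.
#' @examples
#' sa_accept(0.5, 0.6, temperature = 0.1)$prob  # exp(-1)
#' @export
sa_accept <- function(e_current, e_candidate, temperature, energy_scale = 1) {
  temperature <- check_number(temperature, "temperature", min = 0, open_min = TRUE)
  delta <- e_candidate - e_current
  prob <- if (delta <= 0) 1 else exp(-energy_scale * delta / temperature)
  list(accepted = runif(1) < prob || prob >= 1, prob = prob)
}

repair_mask <- function(mask) {
  if (!any(mask)) mask[sample.int(length(mask), 1L)] <- TRUE
  mask
}

#' Single-point crossover of two feature masks
#'
#' With probability `crossover_prob` the parents are cut at a uniform position
#' and their tails swapped; otherwise they are copied. A child left with no
#' active bit is repaired by activating one uniformly chosen bit.
#'
#' @param parent_a,parent_b Equal-length logical masks.
#' @param crossover_prob Probability of performing the crossover.
#' @return A list of two children masks.
#' @export
crossover_masks <- function(parent_a, parent_b, crossover_prob = 0.8) {
  if (length(parent_a) != length(parent_b)) abort("parent masks differ in length.")
  l <- length(parent_a)
  if (runif(1) < crossover_prob && l >= 2) {
    cut <- sample.int(l - 1L, 1L)
    child_a <- c(parent_a[seq_len(cut)], parent_b[(cut + 1L):l])
    child_b <- c(parent_b[seq_len(cut)], parent_a[(cut + 1L):l])
  } else {
    child_a <- parent_a
    child_b <- parent_b
  }
  list(repair_mask(child_a), repair_mask(child_b))
}

#' Per-bit mutation of a feature mask
#'
#' Each bit flips independently with probability `mutation_prob`; an
#' all-inactive result is repaired by activating one uniformly chosen bit.
#'
#' @param mask Logical mask.
#' @param mutation_prob Per-bit flip probability.
#' @return The mutated mask.
#' @export
mutate_mask <- function(mask, mutation_prob = 0.02) {
  flip <- runif(length(mask)) < mutation_prob
  repair_mask(xor(mask, flip))
}

#' Annealing-guided local search over a population of masks
#'
#' For each mask, `iters` single-bit-flip proposals are drawn; each proposal is
#' kept or rejected by [sa_accept()] at the given temperature on energies
#' `e = 1 - fitness`. At temperature near zero only non-worsening flips
#' survive, so each individual's fitness is non-decreasing.
#'
#' @param masks List of logical masks.
#' @param fitness_fn Function mask -> fitness (larger is better); cache
#'   repeated masks inside `fitness_fn` if evaluations are expensive.
#' @param iters Proposals per mask.
#' @param temperature Annealing temperature (> 0).
#' @param energy_scale Energy multiplier `E`.
#' @return The list of (possibly improved) masks.
#' @export
local_search <- function(masks, fitness_fn, iters, temperature,
                         energy_scale = 1) {
  if (iters == 0L) return(masks)
  lapply(masks, function(cur) {
    e_cur <- 1 - fitness_fn(cur)
    for (i in seq_len(iters)) {
      cand <- cur
      bit <- sample.int(length(cand), 1L)
      cand[bit] <- !cand[bit]
      cand <- repair_mask(cand)
      e_cand <- 1 - fitness_fn(cand)
      if (sa_accept(e_cur, e_cand, temperature, energy_scale)$accepted) {
        cur <- cand
        e_cur <- e_cand
      }
    }
    cur
  })
}

#' Genetic-algorithm wrapper search within the filter union
#'
#' Evolves feature masks restricted to the filter-stage union: tournament
#' selection (size 3), single-point crossover, per-bit mutation,
#' annealing-guided local search, elitism, and geometric cooling
#' (`T_g = T0 * cooling_rate^g`). Fitness is the rectified excess of the
#' classifier's cross-validated accuracy over the baseline (see
#' [fitness_score()]); a fitness cache keyed by the mask bits avoids
#' re-training on repeated masks. The search stops at the generation budget or
#' after `patience` generations without improvement, and is bit-for-bit
#' reproducible for a fixed `cfg$seed`.
#'
#' @param data A data frame with feature columns and a class column.
#' @param union_mask The filter union: named logical vector over features,
#'   feature names, or `NULL` for all features.
#' @param cfg A [ga_config()].
#' @param classifier Classifier whose CV accuracy drives the fitness. The
#'   default `"knn"` is deliberate: nearest-neighbour accuracy degrades
#'   steadily as irrelevant dimensions are added, so it gives the subset
#'   search a usable gradient where margin-based or linear fits saturate on
#'   easy problems.
#' @param n_folds Folds of the fitness protocol.
#' @param label Name of the class column.
#' @return An object of class `fawfs_ga`: `selected` (feature names),
#'   `best_mask` (named logical over the union), `best_fitness`,
#'   `best_cv_accuracy`, `baseline`, `history` (tibble: generation, best_fit,
#'   mean_fit, temperature), `n_evaluations`, `cfg`, `classifier`.
#' @examples
#' \donttest{
#' d <- simulate_classification(150, 10, 3, effect_size = 2, seed = 5)
#' ga <- run_ga(d, cfg = ga_config(population_size = 10, n_generations = 5,
#'                                 local_search_iters = 2, seed = 5))
#' ga$selected
#' }
#' @export
run_ga <- function(data, union_mask = NULL, cfg = ga_config(),
                   classifier = "knn", n_folds = 5, label = "label") {
  classifier <- match.arg(classifier, classifier_names)
  union_feats <- resolve_mask(data, union_mask, label)
  u <- length(union_feats)
  if (u < 1) abort("the filter union must contain at least one feature.")
  y <- as.factor(data[[label]])
  baseline <- cfg$fitness_baseline %||% (max(table(y)) / length(y))
  fold_seeds <- vapply(seq_len(cfg$fitness_repeats),
                       function(r) derive_seed(cfg$seed, 11L + r), integer(1))

  cache <- new.env(parent = emptyenv())
  n_evaluations <- 0L
  eval_mask <- function(mask) {
    key <- paste(as.integer(mask), collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    f <- mean(vapply(fold_seeds, function(s) {
      cross_validate(data, mask = union_feats[mask], classifier = classifier,
                     n_folds = n_folds, seed = s, label = label)$mean_accuracy
    }, numeric(1)))
    fit <- if (f > baseline) f - baseline else 0
    cache[[key]] <- fit
    n_evaluations <<- n_evaluations + 1L
    fit
  }

  withr::with_seed(cfg$seed, {
    pop <- replicate(cfg$population_size,
                     repair_mask(runif(u) < 0.5), simplify = FALSE)
    fit <- vapply(pop, eval_mask, numeric(1))
    best_i <- which.max(fit)
    best_mask <- pop[[best_i]]
    best_fitness <- fit[best_i]
    history <- tibble(generation = 0L, best_fit = max(fit),
                      mean_fit = mean(fit),
                      temperature = cfg$initial_temperature)
    stall <- 0L

    for (g in seq_len(cfg$n_generations)) {
      if (stall >= cfg$patience) break
      temp <- cfg$initial_temperature * cfg$cooling_rate^g

      sel <- vapply(seq_len(cfg$population_size), function(i) {
        cand <- sample.int(cfg$population_size, 3L, replace = TRUE)
        cand[which.max(fit[cand])]
      }, integer(1))
      newpop <- pop[sel]

      for (i in seq(1L, cfg$population_size - 1L, by = 2L)) {
        ch <- crossover_masks(newpop[[i]], newpop[[i + 1L]], cfg$crossover_prob)
        newpop[[i]] <- ch[[1]]
        newpop[[i + 1L]] <- ch[[2]]
      }
      newpop <- lapply(newpop, mutate_mask, cfg$mutation_prob)
      newpop <- local_search(newpop, eval_mask, cfg$local_search_iters,
                             temp, cfg$energy_scale)
      newfit <- vapply(newpop, eval_mask, numeric(1))

      elite <- order(-fit)[seq_len(cfg$elitism)]
      worst <- order(newfit)[seq_len(cfg$elitism)]
      newpop[worst] <- pop[elite]
      newfit[worst] <- fit[elite]

      pop <- newpop
      fit <- newfit
      gen_best <- which.max(fit)
      if (fit[gen_best] > best_fitness + 1e-12) {
        best_fitness <- fit[gen_best]
        best_mask <- pop[[gen_best]]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      history <- dplyr::bind_rows(history, tibble(
        generation = g, best_fit = max(fit), mean_fit = mean(fit),
        temperature = temp
      ))
    }

    structure(
      list(
        selected = union_feats[best_mask],
        best_mask = setNames(best_mask, union_feats),
        best_fitness = best_fitness,
        best_cv_accuracy = best_fitness + if (best_fitness > 0) baseline else NA_real_,
        baseline = baseline,
        history = history,
        n_evaluations = n_evaluations,
        union = union_feats,
        cfg = cfg,
        classifier = classifier
      ),
      class = "fawfs_ga"
    )
  })
}

#' @export
print.fawfs_ga <- function(x, ...) {
  cat(sprintf(
    "<fawfs_ga> %d/%d union features selected; best fitness %.4f (baseline D = %.4f, %s fitness)\n",
    length(x$selected), length(x$union), x$best_fitness, x$baseline, x$classifier
  ))
  cat(sprintf("  %d generations, %d unique masks evaluated\n",
              max(x$history$generation), x$n_evaluations))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.fawfs_ga <- function(x, ...) x$history

#' @export
glance.fawfs_ga <- function(x, ...) {
  tibble(best_fitness = x$best_fitness, baseline = x$baseline,
         n_selected = length(x$selected), n_union = length(x$union),
         n_generations = max(x$history$generation),
         n_evaluations = x$n_evaluations, classifier = x$classifier)
}

#' @describeIn run_ga Fitness and temperature trajectories over generations.
#' @param object A `fawfs_ga` object.
#' @param ... Unused.
#' @export
autoplot.fawfs_ga <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("best_fit", "mean_fit"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$fitness,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "fitness (rectified accuracy excess)")
}
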