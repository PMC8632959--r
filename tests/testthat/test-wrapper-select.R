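test_that("fitness is the rectified excess of CV accuracy over the baseline", {
  d <- small_planted()
  # baseline below any achievable accuracy: upper branch
  fs <- fitness_score(d, mask = NULL, classifier = "knn", seed = 2,
                      baseline = 0.5)
  expect_equal(fs$fitness, fs$cv_accuracy - 0.5)
  # baseline at the ceiling: lower branch clips to zero
  fs0 <- fitness_score(d, mask = NULL, classifier = "knn", seed = 2,
                       baseline = 1)
  expect_equal(fs0$fitness, 0)
  # boundary f(x) = D
  fsb <- fitness_score(d, mask = NULL, classifier = "knn", seed = 2,
                       baseline = fs$cv_accuracy)
  expect_equal(fsb$fitness, 0)
  # default baseline is the majority-class rate
  fd <- fitness_score(d, mask = NULL, classifier = "knn", seed = 2)
  expect_equal(fd$baseline, max(table(d$label)) / nrow(d))
  expect_error(fitness_score(d, mask = character(0)), "empty mask")
})

test_that("annealing acceptance follows the exponential law", {
  withr::with_seed(1, {
    expect_equal(sa_accept(0.6, 0.5, temperature = 0.1)$prob, 1)  # improvement
    expect_equal(sa_accept(0.5, 0.5, temperature = 0.1)$prob, 1)  # tie accepted
    expect_equal(sa_accept(0.5, 0.6, temperature = 0.1)$prob, exp(-1),
                 tolerance = 1e-12)
    expect_gte(sa_accept(0.1, 0.9, temperature = 1e9)$prob, 1 - 1e-6)
    expect_true(sa_accept(0.6, 0.5, temperature = 0.1)$accepted)
  })
  expect_error(sa_accept(0.5, 0.6, temperature = 0), "temperature")
})

test_that("single-point crossover recombines, copies, and repairs", {
  p1 <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  p2 <- !p1
  # crossover_prob = 0: exact copies
  res <- withr::with_seed(1, crossover_masks(p1, p2, crossover_prob = 0))
  expect_identical(res, list(p1, p2))
  # closure: identical parents reproduce themselves at any cut
  res2 <- withr::with_seed(2, crossover_masks(p1, p1, crossover_prob = 1))
  expect_identical(res2, list(p1, p1))
  # scan seeds until the cut lands after position 3: children are
  # 111111 and 000000, the empty child repaired to exactly one active bit
  found <- FALSE
  for (s in 1:200) {
    res3 <- withr::with_seed(s, crossover_masks(p1, p2, crossover_prob = 1))
    if (all(res3[[1]])) {
      expect_equal(sum(res3[[2]]), 1L)
      found <- TRUE
      break
    }
  }
  expect_true(found)
  expect_error(crossover_masks(p1, p2[-1]), "length")
})

test_that("mutation flips per-bit and repairs empty masks", {
  m <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  expect_identical(withr::with_seed(1, mutate_mask(m, 0)), m)
  expect_identical(withr::with_seed(1, mutate_mask(m, 1)), !m)
  all_on <- rep(TRUE, 5)
  flipped <- withr::with_seed(1, mutate_mask(all_on, 1))
  expect_equal(sum(flipped), 1L)  # 00000 repaired to one active bit
})

test_that("local search leaves state unchanged at zero iters and is greedy at T ~ 0", {
  target <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  fit_fn <- function(mask) mean(mask == target)  # cheap deterministic fitness
  masks <- withr::with_seed(3, replicate(6, fawfs:::repair_mask(runif(6) < 0.5),
                                         simplify = FALSE))
  expect_identical(local_search(masks, fit_fn, 0L, 1), masks)
  out <- withr::with_seed(4, local_search(masks, fit_fn, 20L, 1e-12))
  before <- vapply(masks, fit_fn, numeric(1))
  after <- vapply(out, fit_fn, numeric(1))
  expect_true(all(after >= before))  # greedy limit: never worsens
})

test_that("accepted-move statistics match the closed-form acceptance probability", {
  p_hat <- withr::with_seed(99, {
    mean(vapply(1:10000, function(i) {
      sa_accept(0.5, 0.6, temperature = 0.1, energy_scale = 1)$accepted
    }, logical(1)))
  })
  p_true <- exp(-1)
  se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("the GA is seeded-deterministic and closed over the union", {
  d <- small_planted()
  flt <- filter_union(d, k_anova = 4, k_mi = 4)
  ga1 <- run_ga(d, union_mask = flt$mask, cfg = tiny_ga_config())
  ga2 <- run_ga(d, union_mask = flt$mask, cfg = tiny_ga_config())
  expect_identical(ga1$history, ga2$history)
  expect_identical(ga1$selected, ga2$selected)
  expect_true(all(ga1$selected %in% flt$selected))
  expect_gte(length(ga1$selected), 1L)
})

test_that("elitism makes population best non-decreasing; temperature cools geometrically", {
  d <- small_planted(seed = 6)
  for (s in c(1, 2)) {
    ga <- run_ga(d, cfg = tiny_ga_config(seed = s))
    expect_true(all(diff(ga$history$best_fit) >= -1e-12))
    g <- ga$history$generation
    expect_equal(ga$history$temperature,
                 ga$cfg$initial_temperature * ga$cfg$cooling_rate^g)
  }
})

test_that("a zero-generation run returns the best of the initial population", {
  d <- small_planted(seed = 8)
  ga <- run_ga(d, cfg = tiny_ga_config(n_generations = 0, seed = 3))
  expect_equal(nrow(ga$history), 1L)
  expect_equal(ga$history$generation, 0L)
  expect_equal(ga$best_fitness, ga$history$best_fit)
  expect_error(run_ga(d, union_mask = character(0)), "at least one feature")
})

test_that("GA accessors expose history and summary in tidy form", {
  d <- small_planted(seed = 9)
  ga <- run_ga(d, cfg = tiny_ga_config(n_generations = 3, seed = 2))
  td <- tidy(ga)
  expect_named(td, c("generation", "best_fit", "mean_fit", "temperature"))
  gl <- glance(ga)
  expect_equal(gl$n_selected, length(ga$selected))
  expect_s3_class(autoplot(ga), "ggplot")
})
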