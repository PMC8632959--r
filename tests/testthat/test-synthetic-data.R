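test_that("classification generator honours shape, balance and ground truth", {
  d <- simulate_classification(569, 30, 5, effect_size = 1, class_balance = 0.5,
                               seed = 1)
  expect_s3_class(d, "fawfs_dataset")
  expect_equal(dim(d), c(569L, 31L))  # 30 features + label
  expect_setequal(levels(d$label), c("0", "1"))
  expect_length(attr(d, "informative"), 5L)
  expect_true(all(attr(d, "informative") %in% 1:30))
  # ground truth lives in metadata, not in the matrix
  expect_false("informative" %in% names(d))
  expect_error(simulate_classification(10, 3, 4, seed = 1), "n_informative")
})

test_that("planted features carry the requested mean shift; noise features do not", {
  d <- simulate_classification(400, 12, 4, effect_size = 2, seed = 11)
  inf <- attr(d, "informative")
  f_of <- function(j) anova_decompose(d[[j]], d$label)$f_score
  f_inf <- vapply(inf, f_of, numeric(1))
  f_noise <- vapply(setdiff(1:12, inf), f_of, numeric(1))
  expect_gt(mean(f_inf), mean(f_noise))
  expect_gt(min(f_inf), max(f_noise))  # effect 2 at n = 400 separates cleanly
})

test_that("null generator produces small ANOVA F throughout", {
  d <- simulate_classification(300, 8, 0, seed = 3)
  f <- vapply(1:8, function(j) anova_decompose(d[[j]], d$label)$f_score,
              numeric(1))
  expect_true(all(f < 10))
  expect_lt(mean(f), 3)
})

test_that("generators are pure functions of their seed", {
  expect_identical(simulate_classification(50, 5, 2, seed = 9),
                   simulate_classification(50, 5, 2, seed = 9))
  s1 <- simulate_eeg(duration = 2, fs = 250, n_blinks = 2, seed = 7)
  s2 <- simulate_eeg(duration = 2, fs = 250, n_blinks = 2, seed = 7)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$blinks, s2$blinks)
  expect_identical(simulate_cohort(seed = 4), simulate_cohort(seed = 4))
})

test_that("planted-signal recoverability: ANOVA ranks informative features on top", {
  for (seed in 1:5) {
    d <- simulate_classification(200, 15, 5, effect_size = 1.5, seed = seed)
    inf <- attr(d, "informative")
    f <- vapply(1:15, function(j) anova_decompose(d[[j]], d$label)$f_score,
                numeric(1))
    top5 <- order(-f)[1:5]
    expect_gte(length(intersect(top5, inf)), 4L)
  }
})

test_that("synthetic EEG plants tones, blinks and noise as requested", {
  sim <- simulate_eeg(n_channels = 1, duration = 2, fs = 1000,
                      sine_components = list(c(10, 1)), n_blinks = 0,
                      noise_sd = 0, seed = 1)
  expect_equal(ncol(sim$recording$data), 2000L)
  pg <- periodogram_tbl(sim$recording$data[1, ], 1000)
  expect_equal(pg$freq[which.max(pg$power)], 10)

  sim5 <- simulate_eeg(duration = 4, fs = 250, n_blinks = 5, seed = 2)
  expect_equal(nrow(sim5$blinks), 5L)
  # non-overlapping 300 ms pulses
  expect_true(all(diff(sort(sim5$blinks$onset_s)) >= 0.3))
  # contaminated = clean + artifact, artifact nonzero only around blinks
  expect_false(identical(sim5$recording$data, sim5$clean$data))

  expect_error(simulate_eeg(fs = 0), "fs")
  expect_error(simulate_eeg(duration = -1), "duration")
})

test_that("EEG spectral fidelity survives noise", {
  sim <- simulate_eeg(n_channels = 1, duration = 4, fs = 250,
                      sine_components = list(c(12, 2)), noise_sd = 0.5,
                      seed = 3)
  pg <- periodogram_tbl(sim$recording$data[1, ], 250)
  expect_lt(abs(pg$freq[which.max(pg$power)] - 12), 250 / 1000 + 1e-9)
})

test_that("cohort generator honours group sizes, ranges and the planted effect", {
  coh <- simulate_cohort(n_per_group = 27, seed = 1)
  counts <- dplyr::count(coh, group, timepoint, instrument)
  expect_true(all(counts$n == 27L))
  expect_true(all(coh$score[coh$instrument == "HAMD"] <= 68))
  expect_error(simulate_cohort(n_per_group = 1), "n_per_group")

  # planted effect recovered at large n
  big <- simulate_cohort(n_per_group = 200, instruments = "SDS",
                         intervention_effect = 10, seed = 2)
  post <- big[big$timepoint == "post", ]
  diff_hat <- mean(post$score[post$group == "control"]) -
    mean(post$score[post$group == "intervention"])
  expect_lt(abs(diff_hat - 10), 2)

  # null case: t statistic on post scores is centred on zero across seeds
  ts <- vapply(1:20, function(s) {
    c0 <- simulate_cohort(n_per_group = 30, instruments = "SDS",
                          intervention_effect = 0, seed = s)
    p <- c0[c0$timepoint == "post", ]
    two_sample_t(p$score[p$group == "control"],
                 p$score[p$group == "intervention"])$t
  }, numeric(1))
  expect_lt(abs(mean(ts)), 0.5)
})

test_that("CSV round trips preserve datasets and recordings", {
  d <- simulate_classification(30, 4, 1, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset_csv(d, f)
  d2 <- read_dataset_csv(f)
  expect_equal(as.matrix(d2[1:4]), as.matrix(d[1:4]), tolerance = 1e-12)
  expect_identical(as.character(d2$label), as.character(d$label))

  sim <- simulate_eeg(duration = 1, fs = 250, seed = 1)
  g <- withr::local_tempfile(fileext = ".csv")
  write_eeg_csv(sim$recording, g)
  r2 <- read_eeg_csv(g)
  expect_equal(r2$fs, 250, tolerance = 1e-9)
  expect_identical(r2$channel_labels, sim$recording$channel_labels)
  expect_equal(r2$data, sim$recording$data, tolerance = 1e-9)
})
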