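test_that("random templates are average-referenced, unit-norm, distinct and seeded", {
  tm <- make_templates(montage(), K = 4, seed = 1)
  expect_equal(dim(tm), c(4, 19))
  expect_equal(rowMeans(tm), rep(0, 4), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sqrt(rowSums(tm^2)), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-12)
  cc <- abs(tm %*% t(tm))
  expect_lte(max(cc[upper.tri(cc)]), 0.7)
  expect_identical(tm, make_templates(montage(), K = 4, seed = 1))
  expect_false(identical(tm, make_templates(montage(), K = 4, seed = 2)))
  expect_error(make_templates(montage(c("C3", "C4")), K = 2), "smaller than")
})

test_that("a two-channel montage admits only the antisymmetric map", {
  tm <- make_templates(montage(c("C3", "C4")), K = 1, seed = 0)
  expect_equal(abs(as.numeric(tm)), c(1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("fixed dwell with a two-state flip chain gives strict alternation", {
  tr <- ground_truth(make_templates(K = 2, seed = 3),
                     transition_probs = rbind(c(0, 1), c(1, 0)),
                     mean_dwell_ms = 100, dwell_law = "fixed")
  lab <- simulate_label_sequence(tr, duration_s = 4, fs = 200, seed = 5)
  r <- rle(lab)
  expect_true(all(r$lengths[-length(r$lengths)] == 20))
  expect_true(all(abs(diff(r$values)) == 1))
})

test_that("simulated dwell times and transition frequencies match the plan", {
  P <- rbind(c(0, 0.6, 0.4), c(0.2, 0, 0.8), c(0.5, 0.5, 0))
  tr <- ground_truth(make_templates(K = 3, seed = 9), transition_probs = P,
                     mean_dwell_ms = 80)
  lab <- simulate_label_sequence(tr, duration_s = 600, fs = 200, seed = 11)
  r <- rle(lab)
  # law-of-large-numbers check on the pooled mean dwell (in ms)
  expect_equal(mean(r$lengths) * 1000 / 200, 80, tolerance = 0.05)
  # Monte-Carlo check on the embedded transition frequencies
  from <- r$values[-length(r$values)]; to <- r$values[-1]
  expect_gt(length(from), 1000)
  emp <- prop.table(table(factor(from, 1:3), factor(to, 1:3)), 1)
  expect_lt(max(abs(emp - P)), 0.05)
  # long-run class coverage approaches the semi-Markov stationary law
  cov_emp <- tabulate(lab, 3) / length(lab)
  expect_lt(max(abs(cov_emp - stationary_distribution(tr))), 0.03)
})

test_that("synthesized EEG has the planted topography and is seed-reproducible", {
  tm <- make_templates(K = 4, seed = 21)
  sim <- synthesize_eeg(ground_truth(tm, snr = Inf), duration_s = 2, seed = 13)
  expect_equal(dim(sim$rec$data), c(400, 19))
  # noise-free: every sample correlates with its generating template at |r| = 1
  X <- sim$rec$data - rowMeans(sim$rec$data)
  r <- abs(rowSums(X * tm[sim$truth$label_sequence, ]) / sqrt(rowSums(X^2)))
  expect_equal(max(abs(rowMeans(sim$rec$data))), 0, tolerance = 1e-9)
  expect_equal(as.numeric(r), rep(1, 400), tolerance = 1e-9)
  again <- synthesize_eeg(ground_truth(tm, snr = Inf), duration_s = 2, seed = 13)
  expect_identical(sim$rec$data, again$rec$data)
  expect_identical(sim$truth$label_sequence, again$truth$label_sequence)
})

test_that("the default synthesis matches the clinical recording geometry", {
  sim <- synthesize_eeg(ground_truth(make_templates(K = 4, seed = 2)),
                        duration_s = 360, fs = 200, seed = 1)
  expect_equal(dim(sim$rec$data), c(72000, 19))
  expect_equal(sim$rec$fs, 200)
})

test_that("the signal-to-noise ratio is realized as a GFP ratio", {
  tm <- make_templates(K = 4, seed = 4)
  noisy <- synthesize_eeg(ground_truth(tm, snr = 5), duration_s = 30, seed = 6)
  clean <- synthesize_eeg(ground_truth(tm, snr = Inf), duration_s = 30, seed = 6)
  noise <- noisy$rec$data - clean$rec$data
  gfp_of <- function(m) mean(sqrt(rowSums((m - rowMeans(m))^2) / ncol(m)))
  expect_equal(gfp_of(clean$rec$data) / gfp_of(noise), 5, tolerance = 1e-6)
  expect_error(ground_truth(tm, snr = 0), "snr")
})

test_that("the bundled cohort table matches its printed source", {
  ch <- cohort_fixture()
  expect_equal(nrow(ch), 21)
  expect_equal(sum(ch$group == "RE"), 12)
  expect_equal(sum(ch$group == "N-RE"), 9)
  re1 <- ch[ch$patient_id == "RE1", ]
  expect_equal(re1$sex, "M")
  expect_equal(re1$age, 52)
  expect_equal(re1$etiology, "Trauma")
  expect_equal(re1$course_days, 84)
  expect_equal(c(re1$crsr_t0, re1$crsr_t1, re1$crsr_t2), c(11, 11, 12))
  # the grouping rule holds row by row: responsive iff the total improved
  expect_identical(classify_responders(ch), ch$group)
})
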