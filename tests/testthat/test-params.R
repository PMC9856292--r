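test_that("segments are maximal runs split at epoch boundaries", {
  s <- segments_of(toy_seg(c(1L, 1L, 2L, 2L, 2L), K = 2))
  expect_equal(s$class, c(1, 2))
  expect_equal(s$start, c(1, 3))
  expect_equal(s$length, c(2, 3))
  alt <- segments_of(toy_seg(c(1L, 2L, 1L, 2L), K = 2))
  expect_equal(alt$length, rep(1, 4))
  split <- segments_of(toy_seg(rep(1L, 4), K = 1, epoch_starts = c(1L, 3L)))
  expect_equal(split$length, c(2, 2))        # one class, two epochs, two runs
})

test_that("temporal parameters have their closed-form values on toy sequences", {
  seg <- toy_seg(c(rep(1L, 10), rep(2L, 20), rep(1L, 10)), fs = 200, K = 2)
  tp <- temporal_parameters(seg)
  expect_equal(tp$duration_ms, c(50, 100))
  expect_equal(tp$occurrence_per_s, c(10, 5))
  expect_equal(tp$coverage, c(0.5, 0.5))
  single <- temporal_parameters(toy_seg(rep(1L, 400), fs = 200, K = 2))
  expect_equal(single$coverage, c(1, 0))
  expect_equal(single$duration_ms, c(2000, 0))
  expect_equal(single$occurrence_per_s, c(0.5, 0))
})

test_that("coverage equals occurrence times duration on random sequences", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(50:400, 1)
    K <- sample(2:5, 1)
    eps <- sort(unique(c(1L, sample(2:n, sample(0:3, 1)))))
    tp <- temporal_parameters(toy_seg(sample(seq_len(K), n, replace = TRUE),
                                      fs = 250, K = K, epoch_starts = eps))
    expect_equal(tp$coverage,
                 tp$occurrence_per_s * tp$duration_ms / 1000,
                 tolerance = 1e-12)
    expect_equal(sum(tp$coverage), 1)
  }
})

test_that("transition counts and grand-total normalization are exact", {
  tm <- transition_syntax(toy_seg(c(1L, 2L, 1L, 2L), K = 2))
  expect_equal(tm$counts[1, 2], 2)
  expect_equal(tm$counts[2, 1], 1)
  expect_equal(tm$probs[1, 2], 2 / 3)
  expect_equal(tm$probs[2, 1], 1 / 3)
  tm2 <- transition_syntax(toy_seg(c(1L, 1L, 2L, 2L, 2L, 1L, 1L), K = 2))
  expect_equal(unname(tm2$probs[cbind(c(1, 2), c(2, 1))]), c(0.5, 0.5))
  # no transition is counted across an epoch boundary
  tm3 <- transition_syntax(toy_seg(c(1L, 1L, 2L, 2L), K = 2, epoch_starts = c(1L, 3L)))
  expect_equal(tm3$n_transitions, 0)
  expect_true(all(is.na(tm3$probs)))
})

test_that("empirical transition probabilities recover the generator's", {
  P <- rbind(c(0, 0.7, 0.3), c(0.4, 0, 0.6), c(0.25, 0.75, 0))
  tr <- ground_truth(make_templates(K = 3, seed = 6), transition_probs = P,
                     mean_dwell_ms = 80)
  lab <- simulate_label_sequence(tr, duration_s = 900, fs = 200, seed = 3)
  tm <- transition_syntax(toy_seg(lab, fs = 200, K = 3))
  expect_gt(tm$n_transitions, 1e4)
  # expected grand-normalized rate of i->j is nu_i * P_ij for the embedded chain
  e <- eigen(t(P)); nu <- abs(Re(e$vectors[, which.min(abs(e$values - 1))]))
  nu <- nu / sum(nu)
  expect_lt(max(abs(tm$probs - nu * P)), 0.02)
})

test_that("pair rates expose both directions and preserve normalization", {
  tm <- transition_syntax(toy_seg(c(1L, 3L, 1L, 3L, 2L), K = 3))
  pr <- symmetric_pair_rates(tm)
  expect_equal(nrow(pr), 6)
  expect_equal(pr$prob[pr$from == "A" & pr$to == "C"], 0.5)
  expect_equal(pr$prob[pr$from == "C" & pr$to == "A"], 0.25)
  expect_equal(sum(pr$prob), 1)
})

test_that("relabeling classes permutes parameters and transition axes together", {
  set.seed(9)
  lab <- sample(1:3, 500, replace = TRUE)
  perm <- c(3L, 1L, 2L)                      # new label of old class k
  seg1 <- toy_seg(lab, K = 3)
  seg2 <- toy_seg(perm[lab], K = 3)
  tp1 <- temporal_parameters(seg1); tp2 <- temporal_parameters(seg2)
  expect_equal(tp2$duration_ms[perm], tp1$duration_ms)
  expect_equal(tp2$coverage[perm], tp1$coverage)
  tm1 <- transition_syntax(seg1); tm2 <- transition_syntax(seg2)
  expect_equal(unname(tm2$probs[perm, perm]), unname(tm1$probs))
})
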