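test_that("GFP is the spatial population SD and is homogeneous", {
  mat <- rbind(c(4, 4, 4, 4), c(1, -1, 1, -1), c(2, -2, 2, -2))
  colnames(mat) <- c("C3", "C4", "O1", "O2")
  rec <- eeg_recording(mat, fs = 100, mont = montage(colnames(mat)))
  g <- global_field_power(rec)
  expect_equal(g$values, c(0, 1, 2))
  expect_equal(global_field_power(eeg_recording(5 * mat, 100, rec$montage))$values,
               5 * g$values)
  two <- eeg_recording(matrix(c(1, -1), 1, dimnames = list(NULL, c("C3", "C4"))),
                       fs = 100, mont = montage(c("C3", "C4")))
  expect_equal(global_field_power(two)$values, 1)
})

test_that("GFP peak detection finds local maxima and thins by separation", {
  expect_equal(detect_gfp_peaks(c(0, 1, 0, 1, 0), min_separation_ms = 0, fs = 200),
               c(2L, 4L))
  expect_identical(detect_gfp_peaks(1:10, fs = 200), integer(0))
  # a 10 Hz sinusoidal GFP over 1 s has exactly 10 maxima
  tt <- (0:199) / 200
  v <- 1.1 + sin(2 * pi * 10 * tt)
  expect_length(detect_gfp_peaks(v, fs = 200), 10)
  # thinning keeps the larger of two close peaks
  g <- c(0, 3, 0, 5, 0)
  expect_equal(detect_gfp_peaks(g, min_separation_ms = 100, fs = 200), 4L)
})

test_that("modified K-means recovers orthogonal prototypes exactly", {
  set.seed(8)
  # orthonormal zero-mean directions: orthogonalize against the constant map
  Q <- qr.Q(qr(cbind(rep(1, 19), matrix(rnorm(19 * 4), 19))))
  P <- t(Q[, 2:5])
  maps <- P[rep(1:4, each = 10), ] * runif(40, 0.5, 2)
  fit <- modified_kmeans(maps, K = 4, seed = 3)
  expect_equal(fit$gev, 1, tolerance = 1e-9)
  m <- order_classes(fit$model, P)
  expect_equal(abs(diag(m$maps %*% t(normalize_rows(P)))), rep(1, 4),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("modified K-means attains the exhaustive-search optimum on small instances", {
  # K = 2 on 6 maps over 3 channels, against all bipartitions
  set.seed(31)
  maps <- matrix(rnorm(18), 6)
  fit <- modified_kmeans(maps, K = 2, seed = 1)
  expect_equal(fit$gev, oracle_partition_gev(maps, 2), tolerance = 1e-9)
})

test_that("clustering and assignments ignore map polarity", {
  set.seed(12)
  maps <- matrix(rnorm(40 * 19), 40)
  fit <- modified_kmeans(maps, K = 3, seed = 5)
  flipped <- modified_kmeans(-maps, K = 3, seed = 5)
  expect_equal(flipped$gev, fit$gev, tolerance = 1e-12)
  expect_identical(flipped$assignments, fit$assignments)
})

test_that("class ordering matches the exhaustive matching oracle", {
  ref <- make_templates(K = 4, seed = 17)
  model <- microstate_model(ref)
  expect_equal(order_classes(model, ref)$maps, model$maps)      # identity
  swapped <- ref[c(2, 1, 4, 3), ]
  m2 <- order_classes(microstate_model(ref), swapped)
  expect_equal(unname(m2$maps), unname(ref[c(2, 1, 4, 3), ]))   # inverse recovered
  set.seed(23)
  fitted <- normalize_rows(matrix(rnorm(4 * 19), 4))
  m3 <- order_classes(microstate_model(fitted), ref)
  p <- oracle_best_matching(fitted, ref)
  expect_equal(unname(m3$maps), unname(fitted[p, ]))
})

test_that("group prototype aggregation recovers planted maps across subjects", {
  tm <- make_templates(K = 4, seed = 42)
  recs <- lapply(1:5, function(i) {
    average_reference(synthesize_eeg(ground_truth(tm, snr = 5),
                                     duration_s = 30, seed = 200 + i)$rec)
  })
  agg <- aggregate_group_prototypes(recs, K = 4, seed = 1, reference_maps = tm)
  expect_gte(mean(abs(diag(agg$model$maps %*% t(tm)))), 0.95)
  # pooling a single recording equals clustering its own peaks
  single <- aggregate_group_prototypes(recs[1], K = 4, seed = 1, reference_maps = tm)
  g <- global_field_power(recs[[1]])
  pk <- detect_gfp_peaks(g)
  own <- modified_kmeans(recs[[1]]$data[pk, ], K = 4, seed = 1)
  expect_equal(single$gev, own$gev, tolerance = 1e-9)
})

test_that("back-fitting is exact on noise-free data and hand-checkable on toys", {
  s <- toy_synth(duration_s = 5, snr = Inf)
  model <- order_classes(
    modified_kmeans(s$rec$data[detect_gfp_peaks(global_field_power(s$rec)), ],
                    K = 4, seed = 1)$model, s$templates)
  seg <- backfit(model, s$rec)
  expect_identical(seg$labels, s$truth$label_sequence)
  expect_equal(seg$fit, rep(1, length(seg$labels)), tolerance = 1e-9)
  # global sign flip changes nothing
  neg <- eeg_recording(-s$rec$data, fs = s$rec$fs, mont = s$rec$montage)
  expect_identical(backfit(model, neg)$labels, seg$labels)
  # two-channel toy: both prototypes collapse to the same zero-mean direction,
  # so the tie must resolve to the first class
  m2 <- montage(c("C3", "C4"))
  toy <- microstate_model(rbind(c(1, -1) / sqrt(2), c(0.6, -0.8)))
  rec2 <- eeg_recording(matrix(c(5, -5), 1, dimnames = list(NULL, c("C3", "C4"))),
                        fs = 200, mont = m2)
  expect_equal(backfit(toy, rec2)$labels, 1L)
  # zero-GFP first sample: class 1 with fit 0, then inherits
  rec0 <- eeg_recording(matrix(c(0, 0, 5, -5), 2, byrow = TRUE,
                               dimnames = list(NULL, c("C3", "C4"))),
                        fs = 200, mont = m2)
  seg0 <- backfit(toy, rec0)
  expect_equal(seg0$labels[1], 1L)
  expect_equal(seg0$fit[1], 0)
})

test_that("smoothing absorbs sub-threshold blips and nothing else", {
  seg <- toy_seg(c(rep(1L, 20), 2L, rep(1L, 20)), fs = 200, K = 2)
  sm <- smooth_segmentation(seg, 30)
  expect_identical(sm$labels, rep(1L, 41))
  expect_identical(smooth_segmentation(seg, 0)$labels, seg$labels)
  # postcondition: no internal segment shorter than the floor remains
  set.seed(4)
  noisy <- toy_seg(sample(1:3, 600, replace = TRUE), fs = 200, K = 3,
                   epoch_starts = c(1L, 301L))
  out <- smooth_segmentation(noisy, 30)
  runs <- segments_of(out)
  expect_true(all(runs$length[!runs$at_boundary] * 1000 / 200 >= 30))
})

test_that("GEV is 1 on perfect fits, 0 on orthogonal fits, and sums per class", {
  s <- toy_synth(duration_s = 5, snr = Inf)
  model <- microstate_model(s$templates)
  seg <- backfit(model, s$rec)
  gev <- global_explained_variance(model, s$rec, seg)
  expect_equal(gev$total, 1, tolerance = 1e-9)
  expect_equal(sum(gev$per_class), gev$total)
  # prototypes orthogonal to every sample explain nothing
  s2 <- toy_synth(K = 2, duration_s = 2, snr = Inf, templates_seed = 3)
  Q <- qr.Q(qr(cbind(rep(1, 19), t(s2$templates))), complete = TRUE)
  ortho <- normalize_rows(t(Q[, 4:5]))       # orthogonal to both maps and 1
  m0 <- microstate_model(ortho)
  seg0 <- backfit(m0, s2$rec)
  gev0 <- global_explained_variance(m0, s2$rec, seg0)
  expect_equal(gev0$total, 0, tolerance = 1e-9)
  zero <- eeg_recording(matrix(0, 10, 19, dimnames = list(NULL, channels_1020())),
                        fs = 200)
  expect_error(global_explained_variance(model, zero, backfit(model, zero)),
               "all-zero")
})

test_that("channel permutation permutes templates and leaves labels unchanged", {
  s <- toy_synth(duration_s = 10, snr = 5)
  pk <- detect_gfp_peaks(global_field_power(s$rec))
  fit <- modified_kmeans(s$rec$data[pk, ], K = 4, seed = 2)
  seg <- backfit(fit$model, s$rec)
  set.seed(77)
  perm <- sample(19)
  mont_p <- montage(s$rec$montage$channel_names[perm])
  rec_p <- eeg_recording(s$rec$data[, perm], fs = s$rec$fs, mont = mont_p)
  fit_p <- modified_kmeans(rec_p$data[pk, ], K = 4, seed = 2)
  expect_identical(fit_p$assignments, fit$assignments)
  expect_equal(fit_p$gev, fit$gev, tolerance = 1e-9)
  expect_equal(abs(unname(fit_p$model$maps)), abs(unname(fit$model$maps[, perm])),
               tolerance = 1e-9)
  seg_p <- backfit(fit_p$model, rec_p)
  expect_identical(seg_p$labels, seg$labels)
})
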