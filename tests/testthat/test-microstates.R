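test_that("GFP is the spatial SD: homogeneous, polarity-blind, zero for flat maps", {
  set.seed(2)
  topo <- rnorm(8)
  a <- sin(seq(0, 4 * pi, length.out = 500))
  rec <- eeg_recording(outer(topo, a), 250, sprintf("c%d", 1:8))
  g <- gfp(rec)
  expect_equal(g, abs(a) * sd(topo), tolerance = 1e-12)
  flat <- eeg_recording(matrix(3, 4, 100), 250, sprintf("c%d", 1:4))
  expect_equal(gfp(flat), rep(0, 100))
  rec_neg <- eeg_recording(-rec$data, 250, rec$labels)
  expect_equal(gfp(rec_neg), g)
  expect_error(gfp(eeg_recording(matrix(1, 1, 10), 250, "a")), "2 channels")
})

test_that("planted templates are recovered up to permutation and polarity", {
  cfg <- quick_ms_config(seed = 301)
  sub <- generate_subject_eeg(cfg, 1, 25)
  model <- fit_microstates(sub$recording, 4, seed = 11)
  expect_s3_class(model, "microstate_model")
  expect_equal(colSums(model$templates^2), rep(1, 4), tolerance = 1e-8)
  match_cor <- apply(abs(cor(model$templates, cfg$templates)), 2, max)
  expect_true(all(match_cor > 0.99))
  expect_gt(model$gev, 0.5)
})

test_that("microstate fitting is deterministic given the seed", {
  cfg <- quick_ms_config(seed = 302)
  rec <- generate_subject_eeg(cfg, 1, 25)$recording
  m1 <- fit_microstates(rec, 3, seed = 4)
  m2 <- fit_microstates(rec, 3, seed = 4)
  expect_identical(m1$templates, m2$templates)
})

test_that("fitting preconditions are enforced", {
  cfg <- quick_ms_config(seed = 303)
  rec <- generate_subject_eeg(cfg, 1, 25)$recording
  expect_error(fit_microstates(rec, 1), "k must be >= 2")
  short <- eeg_recording(rec$data[, 1:40], rec$rate, rec$labels)
  expect_error(fit_microstates(short, 4), "GFP peaks")
})

test_that("select_k needs a range of at least 3 candidates", {
  cfg <- quick_ms_config(seed = 304, duration = 20)
  rec <- generate_subject_eeg(cfg, 1, 25)$recording
  expect_error(select_k(rec, c(3, 4)), "at least 3")
})

test_that("backfit labels a template map with its own class, either polarity", {
  cfg <- quick_ms_config(seed = 305, duration = 30)
  rec <- generate_subject_eeg(cfg, 1, 25)$recording
  model <- fit_microstates(rec, 4, seed = 2)
  for (j in c(1, 3)) {
    for (pol in c(1, -1)) {
      probe <- eeg_recording(
        cbind(matrix(pol * 5 * model$templates[, j], ncol = 1)[, rep(1, 1100)]),
        rec$rate, rec$labels)
      lab <- backfit(probe, model, min_dur_s = 0)
      expect_true(all(lab$labels == j))
    }
  }
})

test_that("all-zero samples stay unassigned", {
  cfg <- quick_ms_config(seed = 306, duration = 30)
  rec <- generate_subject_eeg(cfg, 1, 25)$recording
  model <- fit_microstates(rec, 4, seed = 2)
  probe_data <- rec$data
  probe_data[, 11:20] <- 0
  lab <- backfit(eeg_recording(probe_data, rec$rate, rec$labels), model,
                 min_dur_s = 0)
  expect_true(all(is.na(lab$labels[11:20])))
})

test_that("backfit is polarity invariant and checks channel identity", {
  cfg <- quick_ms_config(seed = 307, duration = 30)
  rec <- generate_subject_eeg(cfg, 1, 25)$recording
  model <- fit_microstates(rec, 4, seed = 2)
  l1 <- backfit(rec, model)
  l2 <- backfit(eeg_recording(-rec$data, rec$rate, rec$labels), model)
  expect_identical(l1$labels, l2$labels)
  sub <- eeg_recording(rec$data[1:10, ], rec$rate, rec$labels[1:10])
  expect_error(backfit(sub, model), "match")
})

test_that("minimum-duration smoothing removes micro-segments", {
  labs <- c(rep(1L, 50), 2L, rep(1L, 49), rep(3L, 60))
  sm <- mspli:::merge_short_runs(labs, min_len = 5L)
  expect_false(any(sm == 2L))
  expect_true(all(sm %in% c(1L, 3L)))
  expect_equal(length(sm), length(labs))
})

test_that("labels agree with the simulated switching on clean data", {
  cfg <- quick_ms_config(seed = 308)
  sub <- generate_subject_eeg(cfg, 1, 25)
  model <- fit_microstates(sub$recording, 4, seed = 3)
  lab <- backfit(sub$recording, model)
  tab <- table(lab$labels, sub$truth$labels)
  agreement <- sum(apply(tab, 2, max)) / sum(tab)
  expect_gt(agreement, 0.9)
})
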