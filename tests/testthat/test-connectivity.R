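test_that("PLI matches its sign-count definition", {
  expect_equal(pli(rep(pi / 4, 1000)), 1.0)
  expect_equal(pli(rep(c(0.1, -0.1), 500)), 0.0)
  expect_equal(pli(c(rep(0.1, 3000), rep(-0.1, 1000))), 0.5)
  expect_equal(pli(c(0, 0, 0.2)), 1 / 3)  # sign(0) contributes 0
  expect_error(pli(numeric(0)), "empty")
})

test_that("PLI is invariant to common phase shifts; pair swap preserves it", {
  set.seed(4)
  p1 <- runif(2000, -pi, pi)
  p2 <- runif(2000, -pi, pi)
  expect_equal(pli(p1 - p2), pli((p1 + 1.3) - (p2 + 1.3)), tolerance = 1e-12)
  expect_equal(pli(p1 - p2), pli(p2 - p1), tolerance = 1e-12)
})

test_that("stitching cuts labelled samples into the expected epochs", {
  T <- 40000
  ph <- make_phase_tensor(matrix(runif(2 * T, -pi, pi), 2, T))
  labs <- rep(2L, T)
  labs[1:16000] <- 1L
  lv <- make_labels(labs, k = 3)
  ep <- extract_ms_epochs(ph, lv, epoch_len = 4000, n_epochs = 4)
  expect_equal(ep$coverage$n_epochs, c(4L, 4L, 0L))
  expect_equal(ep$coverage$n_labelled, c(16000L, 24000L, 0L))
  expect_equal(unlist(lapply(ep$epochs[[1]], length)), rep(4000L, 4))
  # class with 6000 samples yields a single full epoch
  labs2 <- rep(2L, T); labs2[1:6000] <- 1L
  ep2 <- extract_ms_epochs(ph, make_labels(labs2, 2), 4000, 4)
  expect_equal(ep2$coverage$n_epochs[1], 1L)
  expect_error(extract_ms_epochs(ph, lv, epoch_len = 0), "positive")
  expect_error(extract_ms_epochs(ph, make_labels(rep(1L, 10), 2)),
               "aligned")
})

test_that("a planted constant lag at full strength gives msPLI 1", {
  # trace sensor noise keeps every channel's phase defined; at lag pi/4 it
  # can never flip a sign, so the planted pair's PLI is still exactly 1
  cfg <- sim_config(n_subjects = 4, duration = 140, ms_amp = 0, bg_amp = 0,
                    noise_sd = 1e-3, carrier = "tone",
                    coupling_spec = data.frame(ch_i = "Fp1", ch_j = "P8",
                                               band = "alpha2", lag = pi / 4,
                                               strength = 1),
                    seed = 21)
  sub <- generate_subject_eeg(cfg, 1, 25)
  lv <- make_labels(sub$truth$labels, cfg$k)
  W <- ms_pli(sub$recording, lv, analysis_bands()$alpha2,
              epoch_len = 2000, n_epochs = 4)
  expect_equal(W["Fp1", "P8"], 1.0)
  expect_true(isSymmetric(unclass(W)))
  expect_true(all(diag(W) == 0))
  expect_true(all(W >= 0 & W <= 1))
})

test_that("single-class labels reproduce plain windowed PLI exactly", {
  set.seed(31)
  T <- 20000
  ph <- make_phase_tensor(matrix(runif(3 * T, -pi, pi), 3, T))
  lv <- make_labels(rep(1L, T), 1)
  ep <- extract_ms_epochs(ph, lv, epoch_len = 4000, n_epochs = 4)
  res <- pli_over_epochs(ph, ep)
  # oracle: plain PLI on the same stitched samples, per pair and epoch
  idx <- unlist(ep$epochs[[1]])
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    manual <- mean(vapply(ep$epochs[[1]], function(e)
      pli(ph$phase[pair[1], e] - ph$phase[pair[2], e]), numeric(1)))
    expect_lt(abs(res$mean[pair[1], pair[2]] - manual), 1e-12)
  }
})

test_that("independent uniform phases give near-zero msPLI", {
  set.seed(32)
  T <- 64000
  ph <- make_phase_tensor(matrix(runif(2 * T, -pi, pi), 2, T))
  lv <- make_labels(rep(1:4, each = T / 4), 4)
  ep <- extract_ms_epochs(ph, lv)
  res <- pli_over_epochs(ph, ep)
  expect_equal(res$n_matrices, 16)
  expect_lt(res$mean[1, 2], 0.05)
})

test_that("msPLI fails loudly when no class has a full epoch", {
  ph <- make_phase_tensor(matrix(runif(2 * 9000, -pi, pi), 2, 9000))
  lv <- make_labels(rep(1:4, length.out = 9000), 4)
  expect_error(pli_over_epochs(ph, extract_ms_epochs(ph, lv)),
               "no complete epochs")
})

test_that("partial coverage averages the available matrices", {
  set.seed(33)
  T <- 24000
  ph <- make_phase_tensor(matrix(runif(2 * T, -pi, pi), 2, T))
  lv <- make_labels(rep(c(1L, 2L), each = T / 2), 4)  # classes 3,4 absent
  ep <- extract_ms_epochs(ph, lv)
  res <- pli_over_epochs(ph, ep)
  expect_lte(res$n_matrices, 8)
  expect_true(all(res$mean >= 0 & res$mean <= 1))
})

test_that("ROI aggregation averages cross-region electrode pairs", {
  W <- tiny_graph(list(c(1, 3, .4), c(1, 4, .4), c(2, 3, .4), c(2, 4, .4)),
                  4, c("a1", "a2", "b1", "b2"))
  cm <- connectivity_matrix(W, rownames(W))
  map <- data.frame(channel = c("a1", "a2", "b1", "b2"),
                    roi = c("A", "A", "B", "B"))
  R <- roi_aggregate(cm, map)
  expect_equal(unname(R["A", "B"]), 0.4)
  W2 <- tiny_graph(list(c(1, 3, .2), c(1, 4, .6)), 4,
                   c("a1", "a2", "b1", "b2"))
  R2 <- roi_aggregate(connectivity_matrix(W2, rownames(W2)), map)
  expect_equal(unname(R2["A", "B"]), mean(c(.2, .6, 0, 0)))
  # unmapped channels are dropped with a message; empty ROI errors
  map3 <- data.frame(channel = c("a1", "b1"), roi = c("A", "B"))
  expect_message(roi_aggregate(cm, map3), "unmapped")
  map4 <- data.frame(channel = c("a1", "a2", "b1", "b2", "zz"),
                     roi = c("A", "A", "B", "B", "C"))
  expect_error(suppressMessages(roi_aggregate(cm, map4)), "ROI")
})

test_that("the packaged ROI map has 22 regions, 11 per hemisphere", {
  map <- default_roi_map()
  expect_equal(length(unique(map$roi)), 22)
  expect_equal(sum(grepl("_L$", unique(map$roi))), 11)
  expect_equal(sum(grepl("_R$", unique(map$roi))), 11)
  mon <- default_montage()
  expect_true(all(map$channel %in% mon$labels))
  midline <- setdiff(mon$labels, map$channel)
  expect_equal(length(midline), 10)
})

test_that("connectivity matrices validate and round-trip through CSV", {
  W <- triangle_half()
  cm <- connectivity_matrix(W, rownames(W))
  path <- tempfile(fileext = ".csv")
  write_connectivity_csv(cm, path)
  back <- read_connectivity_csv(path)
  expect_equal(unclass(back), unclass(cm), ignore_attr = TRUE)
  el <- edge_list(cm)
  expect_equal(nrow(el), 3)
  expect_true(all(el$value == 0.5))
  Wbad <- W; Wbad[1, 2] <- 0.7
  expect_error(connectivity_matrix(Wbad, rownames(W)), "symmetric")
  Wbad2 <- W; Wbad2[1, 2] <- Wbad2[2, 1] <- 1.5
  expect_error(connectivity_matrix(Wbad2, rownames(W)), "\\[0, 1\\]")
})
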