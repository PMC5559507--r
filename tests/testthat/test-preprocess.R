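test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  alpha1 <- analysis_bands()$alpha1
  rec <- sine_recording(9, duration = 60)
  out <- eeg_bandpass(rec, alpha1)
  mid <- 5000:10000
  expect_lt(abs(max(abs(out$data[1, mid])) - 1), 0.05)
  rec20 <- sine_recording(20, duration = 60)
  out20 <- eeg_bandpass(rec20, alpha1)
  expect_lt(max(abs(out20$data[1, mid])), 0.10)
})

test_that("band-pass removes DC offsets", {
  rec <- eeg_recording(matrix(5, 1, 5000), 250, "a")
  out <- eeg_bandpass(rec, analysis_bands()$theta)
  expect_lt(abs(mean(out$data[1, 1000:4000])), 1e-6)
})

test_that("bands above Nyquist are rejected", {
  rec <- sine_recording(9, duration = 10)
  expect_error(eeg_bandpass(rec, band_definition("hf", 100, 130)),
               "Nyquist")
  expect_error(band_definition("bad", 10, 8), "low < high")
})

test_that("Hilbert phase of a sinusoid advances at 2*pi*f", {
  f <- 11.5
  rec <- sine_recording(f, duration = 20)
  ph <- hilbert_phase(rec)
  ok <- which(ph$valid[1, ])
  dphi <- diff(ph$phase[1, ok[ok > 500 & ok < 4500]])
  slope <- mean(atan2(sin(dphi), cos(dphi))) * rec$rate
  expect_lt(abs(slope - 2 * pi * f) / (2 * pi * f), 0.01)
  expect_true(all(ph$phase[1, ok] > -pi & ph$phase[1, ok] <= pi))
})

test_that("a constant lag between two sinusoids is recovered", {
  rec <- sine_recording(9, duration = 20, phases = c(0, -pi / 3))
  ph <- hilbert_phase(rec)
  ok <- ph$valid[1, ] & ph$valid[2, ]
  d <- ph$phase[1, ok] - ph$phase[2, ok]
  d <- atan2(sin(d), cos(d))
  expect_lt(max(abs(d - pi / 3)), 0.01)
})

test_that("zero-amplitude channels are flagged invalid, not phase 0", {
  data <- rbind(cos(2 * pi * 9 * seq_len(5000) / 250),
                rep(0, 5000))
  rec <- eeg_recording(data, 250, c("a", "zero"))
  ph <- hilbert_phase(rec)
  expect_false(any(ph$valid[2, ]))
  expect_true(any(ph$valid[1, ]))
})

test_that("recordings shorter than one window are rejected", {
  rec <- eeg_recording(matrix(rnorm(2 * 500), 2, 500), 250, c("a", "b"))
  expect_error(hilbert_phase(rec), "shorter than one")
})

test_that("filtering then phase extraction commutes with channel order", {
  set.seed(1)
  rec <- eeg_recording(matrix(rnorm(3 * 5000), 3, 5000), 250,
                       c("a", "b", "c"))
  band <- analysis_bands()$alpha2
  ph <- hilbert_phase(eeg_bandpass(rec, band))
  perm <- c(3, 1, 2)
  rec_p <- eeg_recording(rec$data[perm, ], 250, rec$labels[perm])
  ph_p <- hilbert_phase(eeg_bandpass(rec_p, band))
  expect_equal(ph_p$phase, ph$phase[perm, ], tolerance = 1e-12)
})

test_that("a pure tone concentrates its relative power in its band", {
  rec <- sine_recording(6, duration = 30)
  bp <- relative_band_power(rec)
  expect_gt(bp["s01", "theta"], 0.95)
  expect_equal(sum(bp["s01", ]), 1, tolerance = 1e-9)
})

test_that("white-noise relative power scales with bandwidth", {
  bands <- list(a = band_definition("a", 5, 10),
                b = band_definition("b", 10, 15),
                c = band_definition("c", 15, 25))
  fracs <- sapply(1:8, function(s) {
    set.seed(s)
    rec <- eeg_recording(matrix(rnorm(60 * 250), 1, 60 * 250), 250, "n")
    unlist(relative_band_power(rec, bands, total_range = c(5, 25)))
  })
  m <- rowMeans(fracs)
  expect_equal(unname(m), c(0.25, 0.25, 0.5), tolerance = 0.05)
})

test_that("relative band power rejects degenerate inputs", {
  rec0 <- eeg_recording(matrix(0, 2, 5000), 250, c("a", "b"))
  expect_error(relative_band_power(rec0), "all-zero")
  rec <- sine_recording(6, duration = 10)
  expect_error(relative_band_power(rec, list()), "empty band set")
})

test_that("relative band power averages within ROIs when mapped", {
  rec <- sine_recording(6, duration = 20, phases = c(0, 1, 2, 3))
  map <- data.frame(channel = c("s01", "s02", "s03"),
                    roi = c("front", "front", "back"))
  bp <- relative_band_power(rec, roi_map = map)
  expect_setequal(rownames(bp), c("front", "back"))
})
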