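test_that("dpss tapers are orthonormal and spectrally concentrated", {
  tp <- dpss_tapers(512, nw = 2, k = 3)
  expect_equal(crossprod(tp), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # energy of the first taper within +/- nw/n cycles per sample
  spec <- abs(stats::fft(c(tp[, 1], rep(0, 512 * 7))))^2
  f <- (0:(length(spec) - 1)) / length(spec)
  fa <- pmin(f, 1 - f)
  conc <- sum(spec[fa <= 2 / 512]) / sum(spec)
  expect_gt(conc, 0.999)
})

test_that("a channel is perfectly real-coherent with itself", {
  set.seed(1)
  x <- matrix(rnorm(2 * 500), 2, 500)
  ic <- imaginary_coherency(x, fs = 250)
  expect_true(all(abs(ic$im[, 1, 1]) < 1e-12))
  expect_true(all(abs(ic$im[, 2, 2]) < 1e-12))
})

test_that("zero-lag scaled copies have zero imaginary coherency (volume-conduction null)", {
  set.seed(2)
  x <- band_limited_noise(1000, 500, 4, 7)
  m <- rbind(x, -3.7 * x)
  ic <- imaginary_coherency(m, 500)
  ba <- band_average(ic, "theta")
  expect_lt(ba[1, 2], 1e-10)
})

test_that("quarter-period lagged sinusoids reach |Im C| ~ 1 at their bin", {
  t <- (0:999) / 500
  m <- rbind(sin(2 * pi * 5.5 * t), sin(2 * pi * 5.5 * t - pi / 2))
  ic <- imaginary_coherency(m, 500)
  bin <- which.min(abs(ic$freq - 5.5))
  expect_gt(abs(ic$im[bin, 1, 2]), 0.99)
})

test_that("single-taper single-segment coherency is degenerate, multitaper is not", {
  set.seed(3)
  x <- matrix(rnorm(2 * 1000), 2, 1000)  # independent channels
  cs1 <- asrtnet:::cross_spectra_segment(x, 500, bins = 2:200, nw = 1,
                                         k = 1)
  C1 <- asrtnet:::normalize_coherency(cs1$S)
  expect_equal(max(abs(Mod(C1[, 1, 2]) - 1)), 0, tolerance = 1e-9)
  ic3 <- imaginary_coherency(x, 500, nw = 2, n_tapers = 3)
  offdiag <- ic3$im[2:200, 1, 2]
  expect_lt(max(abs(offdiag)), 1)
  expect_lt(abs(mean(offdiag)), 0.1)
})

test_that("band definitions use half-open alpha edges and closed theta/beta", {
  b <- eeg_bands()
  expect_equal(b$name, c("theta", "low_alpha", "high_alpha", "beta"))
  freq <- seq(0, 40, by = 0.5)
  expect_equal(freq[asrtnet:::band_bin_index(freq, "theta")],
               seq(4, 7, by = 0.5))
  la <- freq[asrtnet:::band_bin_index(freq, "low_alpha")]
  expect_false(10 %in% la)
  expect_true(10 %in% freq[asrtnet:::band_bin_index(freq, "high_alpha")])
  expect_false(13 %in% freq[asrtnet:::band_bin_index(freq, "high_alpha")])
  expect_true(all(c(13, 30) %in%
                    freq[asrtnet:::band_bin_index(freq, "beta")]))
})

test_that("theta band spans 7 bins at 0.5 Hz resolution", {
  set.seed(4)
  x <- matrix(rnorm(3 * 1000), 3, 1000)  # 2000 ms at 500 Hz
  ic <- imaginary_coherency(x, 500)
  ba <- band_average(ic, "theta")
  expect_equal(attr(ba, "n_bins"), 7L)
})

test_that("single-bin bands are the identity on that bin", {
  set.seed(5)
  x <- matrix(rnorm(3 * 1000), 3, 1000)
  ic <- imaginary_coherency(x, 500)
  bin <- which.min(abs(ic$freq - 5))
  ba <- band_average(ic, c(5, 5))
  expect_equal(unclass(ba), abs(ic$im[bin, , ]), ignore_attr = TRUE)
})

test_that("empty bands are rejected", {
  set.seed(6)
  x <- matrix(rnorm(2 * 100), 2, 100)  # 5 Hz resolution at fs 500
  ic <- imaginary_coherency(x, 500)
  expect_error(band_average(ic, c(6, 7)), "no frequency bins")
})

test_that("zero-variance channels are zeroed with a warning", {
  set.seed(7)
  x <- rbind(rnorm(500), 0, rnorm(500))
  expect_warning(ic <- imaginary_coherency(x, 250), "zero-variance")
  expect_true(all(ic$im[, 2, ] == 0))
})

test_that("resting segmentation counts and bounds", {
  net <- generate_planted_network("erdos_renyi", 6, 0.5, lag_ms = 20,
                                  seed = 8)
  rec <- synthesize_coupled_recording(net, n_segments = 6,
                                      segment_ms = 2000, seed = 9)
  ep <- segment_resting(rec)
  expect_equal(dim(ep$data), c(6L, 6L, 1000L))
  # 3.9 s -> one 2000-ms segment, remainder dropped
  rec$samples <- rec$samples[, 1:1950]
  ep2 <- segment_resting(rec)
  expect_equal(dim(ep2$data)[1], 1L)
  rec$samples <- rec$samples[, 1:250]
  expect_error(segment_resting(rec), "shorter")
})

test_that("task segmentation bins by probability and half, keeping correct trials only", {
  d <- asrt_design(n_blocks = 2)
  s <- generate_asrt_sequence(d, seed = 10)
  r <- simulate_responses(s, subject_params(lapse_rate = 0), seed = 11)
  net <- generate_planted_network("erdos_renyi", 6, 0.5, lag_ms = 20,
                                  seed = 12)
  rec <- synthesize_task_recording(net, r, seed = 13)
  labs <- categorize_triplets(r)
  eps <- suppressWarnings(segment_task(rec, r, half_size_blocks = 1L))
  expect_named(eps, c("high_h1", "high_h2", "low_h1", "low_h2"))
  n_expected <- sum(r$block == 1 & r$trial_class == "random" &
                      !is.na(labs$probability) &
                      labs$probability == "high" & r$correct %in% 1)
  expect_equal(dim(eps$high_h1$data)[1], n_expected)
  expect_equal(dim(eps$high_h1$data)[3], 750L)  # -500..1000 ms at 500 Hz
})

test_that("empty task bins are flagged", {
  d <- asrt_design(n_blocks = 2)
  s <- generate_asrt_sequence(d, seed = 14)
  r <- simulate_responses(s, subject_params(lapse_rate = 0), seed = 15)
  r$correct[r$block == 2] <- 0L  # no correct trials in the second half
  net <- generate_planted_network("erdos_renyi", 6, 0.5, lag_ms = 20,
                                  seed = 16)
  rec <- synthesize_task_recording(net, r, seed = 17)
  w <- testthat::capture_warnings(
    eps <- segment_task(rec, r, half_size_blocks = 1L)
  )
  expect_true(any(grepl("no epochs", w)))
  expect_true(isTRUE(attr(eps$high_h2, "empty")))
})
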