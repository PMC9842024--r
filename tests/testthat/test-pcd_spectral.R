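test_that("uniform segmentation yields PRF-spaced windows of duty-cycle length", {
  meta <- fast_meta(spots = 1, seconds_per_spot = 1)
  n <- as.integer(meta$sampling_rate)        # 1 s of samples
  train <- segment_pulses(numeric(n), meta)
  expect_equal(ncol(train$pulses), 10)       # 10 Hz PRF for 1 s
  expect_equal(nrow(train$pulses), 125000)   # 10 ms at 12.5 MHz
  expect_equal(nrow(train$pulses), pulse_window_length(meta))
})

test_that("trigger-locked segmentation recovers pulses and flags bad triggers", {
  meta <- fast_meta(spots = 1, seconds_per_spot = 0.4)
  len <- pulse_window_length(meta)
  pulses <- 4
  x <- rep(seq_len(pulses), each = len) / 10
  triggers <- (seq_len(pulses) - 1) * len / meta$sampling_rate
  train <- segment_pulses(x, meta, triggers)
  expect_equal(ncol(train$pulses), pulses)
  expect_equal(unname(train$pulses[1, ]), seq_len(pulses) / 10)

  expect_error(segment_pulses(x, meta, trigger_times = 10), "beyond")
  expect_warning(
    tr2 <- segment_pulses(x[1:(2 * len + 10)], meta, triggers[1:3]),
    "dropped")
  expect_equal(ncol(tr2$pulses), 2)
  expect_error(segment_pulses(numeric(0), meta), "empty")
})

test_that("pulse count per spot equals sonication seconds times PRF", {
  meta <- fast_meta(spots = 3, seconds_per_spot = 6)
  expect_equal(pulses_per_spot(meta), 60)
  n_pulses <- meta$spots * pulses_per_spot(meta)
  sim <- simulate_session_intensities(silent_params(), meta,
                                      seed = 5)
  expect_equal(nrow(sim), 180)
  expect_equal(as.integer(table(sim$spot)), rep(60L, 3))
})

test_that("spectrum matches the brute-force DFT and obeys Parseval exactly", {
  set.seed(42)
  for (n in c(64, 257, 512)) {
    x <- rnorm(n)
    sp <- compute_spectrum(x)
    expect_equal(sp$n_ft, n)
    expect_lt(max(Mod(sp$S_f - brute_dft(x))) / max(Mod(sp$S_f)), 1e-10)
    expect_equal(sum(Mod(sp$S_f)^2) / n, sum(x^2), tolerance = 1e-12)
  }
  expect_error(compute_spectrum(c(1, NaN)), "NaN")
  expect_error(compute_spectrum(numeric(0)), "empty")
})

test_that("an on-bin cosine concentrates all energy at its two mirror bins", {
  n <- 1000
  m <- 40
  x <- bin_tone(m, n, n)   # fs = n so bin k sits at frequency k
  S <- compute_spectrum(x)$S_f
  expect_equal(Mod(S[m + 1]), n / 2, tolerance = 1e-9)
  expect_equal(Mod(S[n - m + 1]), n / 2, tolerance = 1e-9)
  expect_lt(max(Mod(S[-c(m + 1, n - m + 1)])), 1e-7)
})

test_that("band bins match the printed intervals and are pairwise disjoint", {
  cfg <- spectral_config()
  n <- 312500; fs <- 31.25e6
  bins <- band_bins(cfg, n, fs)
  freq <- function(k) k * fs / n
  expect_equal(range(freq(bins$HH)), c(3.97e6, 5.03e6))
  hh_f <- freq(bins$HH)
  expect_true(all((hh_f >= 3.97e6 & hh_f <= 4.03e6) |
                  (hh_f >= 4.97e6 & hh_f <= 5.03e6)))
  uh_f <- freq(bins$UH)
  expect_true(all((uh_f >= 3.47e6 & uh_f <= 3.53e6) |
                  (uh_f >= 4.47e6 & uh_f <= 4.53e6)))
  bb_f <- freq(bins$BB)
  expect_true(all((bb_f >= 3.03e6 & bb_f <= 3.97e6) |
                  (bb_f >= 4.03e6 & bb_f <= 4.97e6)))
  # ultraharmonic windows are carved out of the broadband band
  expect_false(any(bb_f >= 3.47e6 & bb_f <= 3.53e6))
  expect_length(intersect(bins$HH, bins$UH), 0)
  expect_length(intersect(bins$HH, bins$BB), 0)
  expect_length(intersect(bins$UH, bins$BB), 0)
  # guard must stay below f0/2 and bands below Nyquist
  expect_error(spectral_config(guard = 6e5), "guard")
  expect_error(band_bins(cfg, 1000, 9e6), "Nyquist")
})

test_that("Parseval band intensity isolates on-bin tones to their band", {
  cfg <- spectral_config()
  n <- 125000; fs <- 12.5e6
  bins <- band_bins(cfg, n, fs)
  tones <- c(HH = 4e6, UH = 3.5e6, BB = 3.75e6)
  for (b in names(tones)) {
    x <- bin_tone(tones[[b]], fs, n)
    sp <- compute_spectrum(x, fs)
    I <- vapply(bins, function(bb) parseval_intensity(sp, bb), 0)
    expect_equal(unname(I[b]), n / 4, tolerance = 1e-9)
    expect_true(all(I[setdiff(names(I), b)] <= I[b] * 1e-6))
  }
  # zero pulse gives zero intensity in every band
  spz <- compute_spectrum(numeric(n) + 0, fs)
  expect_equal(vapply(bins, function(bb) parseval_intensity(spz, bb), 0),
               c(HH = 0, UH = 0, BB = 0))
})

test_that("scaling a pulse by c scales every band intensity by c^2", {
  cfg <- spectral_config()
  n <- 125000; fs <- 12.5e6
  set.seed(7)
  x <- bin_tone(4e6, fs, n, 0.3) + bin_tone(3.5e6, fs, n, 0.1) + rnorm(n, 0, 0.05)
  bins <- band_bins(cfg, n, fs)
  I1 <- vapply(bins, function(b) parseval_intensity(compute_spectrum(x, fs), b), 0)
  for (c_scale in c(0.5, 3)) {
    I2 <- vapply(bins, function(b) {
      parseval_intensity(compute_spectrum(c_scale * x, fs), b)
    }, 0)
    expect_equal(I2, c_scale^2 * I1, tolerance = 1e-10)
  }
})

test_that("magnitude histograms conserve pulse counts and clamp outliers", {
  ints <- tibble::tibble(pulse = 1:60, spot = 1L,
                         I_HH = rep(2, 60), I_UH = 1, I_BB = 1)
  h <- pulse_magnitude_histogram(ints, "HH")
  expect_equal(sum(h$counts), 60)
  expect_equal(sum(h$counts > 0), 1)

  ints$I_HH <- c(1e-3, rep(1, 58), 1e9)
  edges <- 10^seq(-1, 1, length.out = 25)
  h2 <- pulse_magnitude_histogram(ints, "HH", edges = edges)
  expect_equal(sum(h2$counts), 60)
  expect_equal(h2$counts[1], 1)                 # below-range value clamped low
  expect_equal(h2$counts[length(h2$counts)], 1) # above-range value clamped high
  expect_error(pulse_magnitude_histogram(ints, "HH", edges = c(1, 1, 2)),
               "increasing")
  expect_error(pulse_magnitude_histogram(ints[0, ], "HH"), "finite")
})

test_that("session aggregation reduces spots correctly", {
  ints <- tibble::tibble(pulse = 1:4, spot = c(1L, 1L, 2L, 2L),
                         I_HH = c(2, 2, 6, 6), I_UH = 1, I_BB = 0.5)
  agg <- aggregate_session(ints)
  hh_spot <- agg$spot_summary[agg$spot_summary$band == "HH", ]
  expect_equal(hh_spot$mean, c(2, 6))
  hh_sess <- agg$session_summary[agg$session_summary$band == "HH", ]
  expect_equal(hh_sess$mean, 4)       # pooled mean strictly between spot means
  expect_equal(hh_sess$max, 6)
  expect_equal(agg$histograms$HH$total, 4)

  one <- aggregate_session(ints[1, ])
  s1 <- one$session_summary
  expect_equal(s1$mean, s1$median)
  expect_equal(s1$mean, s1$max)
})
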