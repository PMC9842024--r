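test_that("simulated sessions are bit-identical under the same seed", {
  meta <- fast_meta(spots = 1, seconds_per_spot = 0.3)
  params <- emission_params()
  s1 <- simulate_session(params, meta, seed = 77)
  s2 <- simulate_session(params, meta, seed = 77)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$trigger_times, s2$trigger_times)
  s3 <- simulate_session(params, meta, seed = 78)
  expect_false(identical(s1$samples, s3$samples))
  # generators restore the caller's RNG stream
  set.seed(1); before <- runif(5)
  set.seed(1); invisible(runif(2))
  invisible(simulate_session(params, meta, seed = 9))
  expect_identical(runif(3), before[3:5])
})

test_that("a pure 4th-harmonic emission is recovered as HH intensity N/4", {
  meta <- fast_meta(spots = 1, seconds_per_spot = 0.3)
  params <- silent_params()
  params$harmonics[4] <- 1
  sim <- simulate_session(params, meta, seed = 3)
  train <- segment_pulses(sim$samples, meta, sim$trigger_times)
  ints <- band_intensities(train)
  n <- nrow(train$pulses)
  expect_equal(ints$I_HH, rep(n / 4, 3), tolerance = 0.02)
  expect_true(all(ints$I_UH < 1e-6 * ints$I_HH))
  expect_true(all(ints$I_BB < 1e-6 * ints$I_HH))
})

test_that("ultraharmonic amplitude is recovered from I_UH to within 2%", {
  meta <- fast_meta(spots = 1, seconds_per_spot = 0.2)
  a <- 0.37
  params <- silent_params()
  params$ultraharmonics[3] <- a       # 3.5 x f0
  ints <- simulate_session_intensities(params, meta, seed = 12)
  n <- pulse_window_length(meta)
  est <- sqrt(4 * ints$I_UH / n)
  expect_equal(est, rep(a, nrow(ints)), tolerance = 0.02)
})

test_that("intensity scales with the square of the planted amplitude", {
  meta <- fast_meta(spots = 1, seconds_per_spot = 1)
  make <- function(u) {
    p <- silent_params(jitter_sdlog = 0.1)
    p$ultraharmonics[3] <- u
    mean(simulate_session_intensities(p, meta, seed = 40)$I_UH)
  }
  ratio <- make(1.0) / make(0.5)
  expect_equal(ratio, 4, tolerance = 0.05)
})

test_that("raising broadband noise raises mean I_BB but not tonal bands", {
  meta <- fast_meta(spots = 1, seconds_per_spot = 2)
  mean_bands <- function(sigma) {
    p <- emission_params(sigma_bb = sigma, jitter_sdlog = 0)
    ints <- simulate_session_intensities(p, meta, seed = 55)
    colMeans(ints[, c("I_HH", "I_UH", "I_BB")])
  }
  lo <- mean_bands(0.005); hi <- mean_bands(0.01)
  expect_gt(hi[["I_BB"]], lo[["I_BB"]])
  expect_equal(hi[["I_HH"]], lo[["I_HH"]], tolerance = 0.02)
})

test_that("simulated recordings survive the on-disk round trip", {
  meta <- fast_meta(spots = 1, seconds_per_spot = 0.2)
  sim <- simulate_session(emission_params(), meta, seed = 19)
  path <- withr::local_tempfile(fileext = ".raw")
  write_pcd_recording(sim$samples, meta, path, trigger_times = sim$trigger_times)
  rec <- read_pcd_recording(path, paste0(path, ".json"))
  expect_identical(rec$samples, sim$samples)   # already on the int16 grid
  train <- segment_pulses(rec$samples, rec$meta, rec$trigger_times)
  expect_equal(ncol(train$pulses), 2)
})

test_that("planted DEG generation is deterministic and respects its spec", {
  spec <- planted_deg_spec(up_a = 10, down_a = 2, up_b = 8, down_b = 1,
                           shared_up = 4, shared_down = 1, n_null = 200)
  g1 <- generate_deg_tables(spec, seed = 5)
  g2 <- generate_deg_tables(spec, seed = 5)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$xo4plus), 200 + length(g1$truth$union))
  expect_true(all(g1$xo4plus$adjPVal >= g1$xo4plus$PVal))
  # planted signs match their direction lists
  a <- g1$xo4plus
  expect_true(all(a$logFC[a$gene %in% g1$truth$up_a] > 0))
  expect_true(all(a$logFC[a$gene %in% g1$truth$down_a] < 0))

  expect_error(planted_deg_spec(shared_up = 300), "shared")
  expect_error(planted_deg_spec(n_null = -1), "non-negative")
})

test_that("a global-null table yields (almost) no discoveries after BH", {
  fp_raw <- 0; fp_bh <- 0; n_null <- 400
  for (seed in 1:50) {
    spec <- planted_deg_spec(up_a = 0, down_a = 0, up_b = 0, down_b = 0,
                             shared_up = 0, shared_down = 0, n_null = n_null)
    g <- generate_deg_tables(spec, seed = seed)
    fp_raw <- fp_raw + sum(g$xo4plus$PVal <= 0.05)
    fp_bh <- fp_bh + nrow(filter_significant(g$xo4plus, 0.05))
  }
  expect_lte(fp_raw / 50, 0.05 * n_null)
  expect_lte(fp_bh / 50, 0.5)
})

test_that("fluorescence phantom generation is deterministic", {
  p1 <- generate_fluorescence_pairs(seed = 2)
  p2 <- generate_fluorescence_pairs(seed = 2)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 8)   # 4 animals x 2 sections
  expect_error(generate_fluorescence_pairs(ratio = -1), "positive")
})
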