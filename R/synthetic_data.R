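# Seedable generators that emulate the statistical structure of each
# pipeline input: cavitation pulse trains with controlled harmonic,
# ultraharmonic and broadband content; DEG tables with planted
# up/down/shared partition structure; and paired hemisphere
# fluorescence with a known fold-change.

# Run `code` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Microbubble emission parameters for the pulse-train simulator
#'
#' Describes the synthetic acoustic emission of one sonication:
#' harmonics of the transmit frequency `f0` (volumetric bubble
#' oscillation), ultraharmonics at half-integer multiples (nonlinear
#' stable cavitation) and band-limited Gaussian broadband noise
#' (inertial cavitation).  Amplitudes are dimensionless; the recording
#' writer rescales to the 16-bit range and records the scale.
#'
#' Defaults sketch a stable-cavitation-dominated emission: a strong
#' fundamental with geometrically decaying harmonics, weak
#' ultraharmonics at 1.5x-5.5x `f0`, and a low broadband floor.
#'
#' @param harmonics Named or positional numeric vector of harmonic
#'   amplitudes `a_k` for integer orders 1..6.
#' @param ultraharmonics Amplitudes `u_m` for half-integer orders
#'   1.5, 2.5, 3.5, 4.5, 5.5.
#' @param sigma_bb Standard deviation of the white Gaussian noise that is
#'   band-limited to `bb_band` before being added (default 0.005).
#' @param bb_band Two-element band (Hz) the broadband noise is limited
#'   to, via a brick-wall FFT filter (default 2-6 MHz).
#' @param jitter_sdlog Log-scale SD of the lognormal per-pulse amplitude
#'   jitter applied to the whole pulse (default 0.1; 0 disables).
#' @return An object of class `emission_params`.
#' @export
emission_params <- function(harmonics = c(0.5, 0.25, 0.12, 0.06, 0.03, 0.015),
                            ultraharmonics = c(0.01, 0.008, 0.006, 0.004, 0.002),
                            sigma_bb = 0.005,
                            bb_band = c(2e6, 6e6),
                            jitter_sdlog = 0.1) {
  if (length(harmonics) > 6L || length(ultraharmonics) > 5L) {
    stop("at most 6 harmonic and 5 ultraharmonic amplitudes", call. = FALSE)
  }
  harmonics <- c(harmonics, numeric(6L - length(harmonics)))
  ultraharmonics <- c(ultraharmonics, numeric(5L - length(ultraharmonics)))
  if (any(harmonics < 0) || any(ultraharmonics < 0) || sigma_bb < 0) {
    stop("amplitudes and sigma_bb must be non-negative", call. = FALSE)
  }
  if (jitter_sdlog < 0) stop("jitter_sdlog must be non-negative", call. = FALSE)
  structure(list(harmonics = harmonics,
                 harmonic_orders = 1:6,
                 ultraharmonics = ultraharmonics,
                 ultraharmonic_orders = seq(1.5, 5.5, by = 1),
                 sigma_bb = sigma_bb, bb_band = bb_band,
                 jitter_sdlog = jitter_sdlog),
            class = "emission_params")
}

# One pulse window: tonal components with per-pulse uniform phases,
# plus brick-wall band-limited Gaussian noise, all scaled by a single
# lognormal jitter factor.  RNG draws happen in a fixed order so the
# full-recording and streaming paths are bit-identical.
simulate_pulse <- function(params, meta, n) {
  fs <- meta$sampling_rate
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  orders <- c(params$harmonic_orders, params$ultraharmonic_orders)
  amps <- c(params$harmonics, params$ultraharmonics)
  phases <- stats::runif(length(amps), 0, 2 * pi)
  for (i in seq_along(amps)) {
    if (amps[i] > 0) {
      x <- x + amps[i] * cos(2 * pi * orders[i] * meta$f0 * t + phases[i])
    }
  }
  if (params$sigma_bb > 0) {
    noise <- stats::rnorm(n, 0, params$sigma_bb)
    x <- x + bandlimit(noise, fs, params$bb_band)
  }
  jit <- if (params$jitter_sdlog > 0) stats::rlnorm(1, 0, params$jitter_sdlog) else 1
  x * jit
}

# Brick-wall FFT band-pass: zero every bin outside [lo, hi] (two-sided).
bandlimit <- function(x, fs, band) {
  n <- length(x)
  sp <- stats::fft(x)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * fs / n
  sp[freq < band[1] | freq > band[2]] <- 0i
  Re(stats::fft(sp, inverse = TRUE)) / n
}

#' Simulate a PCD recording for a sonication session
#'
#' Generates `spots * seconds_per_spot * prf` pulse windows (60 pulses
#' per spot at the defaults) and concatenates them back to back, with
#' trigger times marking each window start — mirroring a digitizer that
#' acquires in synchronization with the pulse excitation and is silent
#' between bursts.  If the waveform would clip the 16-bit range it is
#' rescaled to just inside `[-1, 1)` and the factor recorded.
#'
#' Deterministic given `seed`.
#'
#' @param params An [emission_params()].
#' @param meta A [recording_meta()] (its `spots` field sets the session
#'   length).
#' @param seed Integer seed.
#' @param quantize Quantize to the 16-bit sample grid (default `TRUE`),
#'   exercising the same representation the reader consumes.
#' @return List with `samples` (numeric vector in `[-1, 1)`),
#'   `trigger_times` (seconds), `meta`, and `scale` (applied rescale
#'   factor, 1 when no rescue was needed).
#' @export
simulate_session <- function(params, meta, seed = 1L, quantize = TRUE) {
  len <- pulse_window_length(meta)
  n_pulses <- meta$spots * pulses_per_spot(meta)
  with_seed(seed, {
    samples <- numeric(len * n_pulses)
    for (p in seq_len(n_pulses)) {
      samples[((p - 1) * len + 1):(p * len)] <- simulate_pulse(params, meta, len)
    }
    m <- max(abs(samples))
    scale <- if (m >= 1) (1 - 1 / 32768) / m else 1
    samples <- samples * scale
    if (quantize) {
      samples <- pmin(round(samples * 32768), 32767) / 32768
    }
    if (max(samples) >= 1 || min(samples) < -1) {
      stop("internal error: clipping after rescale", call. = FALSE)
    }
    list(samples = samples,
         trigger_times = (seq_len(n_pulses) - 1) * len / meta$sampling_rate,
         meta = meta, scale = scale)
  })
}

#' Simulate and analyze a session spot by spot
#'
#' Streaming companion to [simulate_session()]: generates each pulse,
#' computes its band intensities, and discards the waveform, so long
#' sessions never hold a full recording in memory.  The unscaled,
#' unquantized waveform is analyzed (draws are made in the same order as
#' [simulate_session()], so tonal content matches to quantization and
#' rescale factors).
#'
#' @inheritParams simulate_session
#' @param config A [spectral_config()].
#' @return A [band_intensities()]-style tibble (`pulse`, `spot`,
#'   `I_HH`, `I_UH`, `I_BB`).
#' @export
simulate_session_intensities <- function(params, meta, config = spectral_config(),
                                         seed = 1L) {
  len <- pulse_window_length(meta)
  bins <- band_bins(config, len, meta$sampling_rate)
  n_pulses <- meta$spots * pulses_per_spot(meta)
  pps <- pulses_per_spot(meta)
  with_seed(seed, {
    out <- matrix(0, n_pulses, 3L)
    for (p in seq_len(n_pulses)) {
      sp <- compute_spectrum(simulate_pulse(params, meta, len),
                             meta$sampling_rate)
      out[p, ] <- c(parseval_intensity(sp, bins$HH),
                    parseval_intensity(sp, bins$UH),
                    parseval_intensity(sp, bins$BB))
    }
    tibble::tibble(pulse = seq_len(n_pulses),
                   spot = as.integer((seq_len(n_pulses) - 1L) %/% pps + 1L),
                   I_HH = out[, 1], I_UH = out[, 2], I_BB = out[, 3])
  })
}

#' Planted structure for synthetic DEG tables
#'
#' Counts of truly regulated genes per contrast and the overlap between
#' contrasts, plus the effect-size model.  Defaults reproduce the
#' partition structure of a two-contrast microglia experiment: 248
#' up / 30 down in contrast A, 225 up / 17 down in contrast B, 120
#' shared up and 3 shared down (123 shared in total, union 397), on top
#' of 12,000 null genes.
#'
#' True DEGs receive raw p-values far below any practical threshold;
#' null genes receive p-values uniform on `(null_p_min, 1)`.  Keeping
#' `null_p_min` at the intended significance level guarantees that
#' Benjamini-Hochberg filtering at that level recovers the planted
#' partition exactly (a null's adjusted p can never drop below its raw
#' p); set `null_p_min = 0` for a fully uniform null.
#'
#' @param up_a,down_a Truly up-/down-regulated gene counts in contrast A.
#' @param up_b,down_b The same for contrast B.
#' @param shared_up,shared_down Genes regulated in both contrasts, same
#'   direction (must not exceed the per-contrast direction counts).
#' @param n_null Unregulated genes (default 12,000).
#' @param effect_meanlog,effect_sdlog Lognormal parameters of `|logFC|`
#'   for true DEGs (default meanlog 1, sdlog 0.35: median 2.7).
#' @param null_lfc_sd SD of the null genes' logFC noise (default 0.15).
#' @param null_p_min Lower bound of the null p-value distribution
#'   (default 0.05).
#' @return An object of class `planted_deg_spec`.
#' @export
planted_deg_spec <- function(up_a = 248L, down_a = 30L,
                             up_b = 225L, down_b = 17L,
                             shared_up = 120L, shared_down = 3L,
                             n_null = 12000L,
                             effect_meanlog = 1, effect_sdlog = 0.35,
                             null_lfc_sd = 0.15, null_p_min = 0.05) {
  counts <- c(up_a = up_a, down_a = down_a, up_b = up_b, down_b = down_b,
              shared_up = shared_up, shared_down = shared_down,
              n_null = n_null)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (shared_up > min(up_a, up_b) || shared_down > min(down_a, down_b)) {
    stop("shared counts cannot exceed the per-contrast direction counts",
         call. = FALSE)
  }
  if (null_p_min < 0 || null_p_min >= 1) {
    stop("null_p_min must lie in [0, 1)", call. = FALSE)
  }
  structure(list(up_a = up_a, down_a = down_a, up_b = up_b, down_b = down_b,
                 shared_up = shared_up, shared_down = shared_down,
                 n_null = n_null, effect_meanlog = effect_meanlog,
                 effect_sdlog = effect_sdlog, null_lfc_sd = null_lfc_sd,
                 null_p_min = null_p_min),
            class = "planted_deg_spec")
}

#' Generate a pair of DEG tables with planted partition structure
#'
#' Builds per-contrast DEG tables over a common gene universe.  True
#' DEGs of each contrast get `|logFC|` drawn from the spec's lognormal
#' effect distribution with the planted sign and a raw p-value in
#' `(1e-12, 1e-9)`; all other genes get small zero-centred logFC noise
#' and a null p-value.  `adjPVal` is the Benjamini-Hochberg adjustment
#' within each table.  Row order is shuffled.  Deterministic given
#' `seed`.
#'
#' @param spec A [planted_deg_spec()].
#' @param seed Integer seed.
#' @return List with `xo4plus` and `xo4neg` (DEG tibbles in
#'   [read_deg_table()] format, contrast A and B respectively) and
#'   `truth` (membership character vectors: `up_a`, `down_a`, `up_b`,
#'   `down_b`, `shared`, `union`).
#' @export
generate_deg_tables <- function(spec = planted_deg_spec(), seed = 1L) {
  spots <- list(
    shared_up = spec$shared_up,
    shared_down = spec$shared_down,
    only_up_a = spec$up_a - spec$shared_up,
    only_down_a = spec$down_a - spec$shared_down,
    only_up_b = spec$up_b - spec$shared_up,
    only_down_b = spec$down_b - spec$shared_down,
    null = spec$n_null
  )
  n_total <- sum(unlist(spots))
  genes <- sprintf("gene%05d", seq_len(n_total))
  role <- rep(names(spots), unlist(spots))
  up_a_genes <- genes[role %in% c("shared_up", "only_up_a")]
  down_a_genes <- genes[role %in% c("shared_down", "only_down_a")]
  up_b_genes <- genes[role %in% c("shared_up", "only_up_b")]
  down_b_genes <- genes[role %in% c("shared_down", "only_down_b")]

  with_seed(seed, {
    avg_exp <- stats::rnorm(n_total, mean = 2, sd = 2)
    make_table <- function(up_genes, down_genes) {
      is_up <- genes %in% up_genes
      is_down <- genes %in% down_genes
      true_de <- is_up | is_down
      lfc <- stats::rnorm(n_total, 0, spec$null_lfc_sd)
      n_de <- sum(true_de)
      effect <- stats::rlnorm(n_de, spec$effect_meanlog, spec$effect_sdlog)
      lfc[true_de] <- effect * ifelse(is_up[true_de], 1, -1)
      p <- stats::runif(n_total, spec$null_p_min, 1)
      p[true_de] <- stats::runif(n_de, 1e-12, 1e-9)
      tstat <- sign(lfc) * stats::qt(p / 2, df = 30, lower.tail = FALSE)
      tbl <- tibble::tibble(
        gene = genes, logFC = lfc, AvgExp = avg_exp, t = tstat,
        PVal = p, adjPVal = bh_adjust(p),
        B = -log10(pmax(p, 1e-300)) - 4
      )
      tbl[sample.int(n_total), , drop = FALSE]
    }
    tbl_a <- make_table(up_a_genes, down_a_genes)
    tbl_b <- make_table(up_b_genes, down_b_genes)
    list(
      xo4plus = tbl_a, xo4neg = tbl_b,
      truth = list(
        up_a = up_a_genes, down_a = down_a_genes,
        up_b = up_b_genes, down_b = down_b_genes,
        shared = genes[role %in% c("shared_up", "shared_down")],
        union = genes[role != "null"]
      )
    )
  })
}

#' Generate paired hemisphere fluorescence intensities
#'
#' Simulates a dye-extravasation readout: per animal and section, a
#' control-hemisphere mean intensity and a treated-hemisphere intensity
#' at a planted fold-change `ratio`, with additive Gaussian noise
#' proportional to each signal.  Deterministic given `seed`.
#'
#' @param ratio Planted treated/control fold-change (> 0).
#' @param noise_frac Noise SD as a fraction of each hemisphere's true
#'   signal (default 0.01; 0 gives exact ratios).
#' @param n_animals Number of animals (default 4).
#' @param sections Sections per animal (default 2).
#' @param control_mean Mean control-hemisphere intensity, arbitrary
#'   units (default 100).
#' @param control_cv Between-animal coefficient of variation of the
#'   control intensity (default 0.1).
#' @param background Common background level added to both hemispheres
#'   (default 0).
#' @param genotypes Optional character vector (length `n_animals`)
#'   labelling each animal's group.
#' @param seed Integer seed.
#' @return A tibble with columns `animal`, optionally `genotype`,
#'   `section`, `treated`, `control`, `background`.
#' @export
generate_fluorescence_pairs <- function(ratio = 2.5, noise_frac = 0.01,
                                        n_animals = 4L, sections = 2L,
                                        control_mean = 100, control_cv = 0.1,
                                        background = 0, genotypes = NULL,
                                        seed = 1L) {
  if (ratio <= 0) stop("`ratio` must be positive", call. = FALSE)
  if (!is.null(genotypes) && length(genotypes) != n_animals) {
    stop("`genotypes` must have one label per animal", call. = FALSE)
  }
  with_seed(seed, {
    rows <- lapply(seq_len(n_animals), function(a) {
      ctrl_level <- control_mean * max(stats::rnorm(1, 1, control_cv), 0.1)
      ctrl_true <- background + ctrl_level
      trt_true <- background + ratio * ctrl_level
      tibble::tibble(
        animal = sprintf("m%02d", a),
        section = seq_len(sections),
        treated = pmax(trt_true + stats::rnorm(sections, 0, noise_frac * trt_true), 0),
        control = pmax(ctrl_true + stats::rnorm(sections, 0, noise_frac * ctrl_true), 0),
        background = background
      )
    })
    out <- dplyr::bind_rows(rows)
    if (!is.null(genotypes)) {
      out <- tibble::add_column(out,
                                genotype = rep(genotypes, each = sections),
                                .after = "animal")
    }
    out
  })
}
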