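# Spectral decomposition of PCD pulse trains: trigger-locked
# segmentation, rectangular-window DFT, harmonic/ultraharmonic/broadband
# band assignment, Parseval band intensities, magnitude histograms and
# session aggregation.

#' Band definitions for PCD spectral decomposition
#'
#' Defines the analysis bands around a transmit center frequency `f0`:
#'
#' * higher harmonics (HH): `k * f0 +/- guard` for integer orders
#'   (default 4 and 5),
#' * ultraharmonics (UH): `m * f0 +/- guard` for half-integer orders
#'   (default 3.5 and 4.5),
#' * broadband (BB): the between-harmonic ranges
#'   `[3 f0 + guard, 4 f0 - guard]` and `[4 f0 + guard, 5 f0 - guard]`,
#'   with the ultraharmonic windows they contain carved out so that the
#'   three bands are pairwise disjoint.
#'
#' All interval endpoints are closed.  Elevated HH content indicates
#' volumetric (stable) bubble oscillation, UH content nonlinear stable
#' cavitation, and BB content inertial cavitation.
#'
#' @param f0 Transmit center frequency in Hz (default 1 MHz).
#' @param guard Half-width of each harmonic/ultraharmonic window in Hz
#'   (default 30 kHz); also the margin kept between the broadband band
#'   and the neighbouring harmonics.
#' @param harmonic_orders Integer harmonic orders for HH (default `c(4, 5)`).
#' @param ultraharmonic_orders Half-integer orders for UH
#'   (default `c(3.5, 4.5)`).
#' @param broadband_ranges Two-column matrix of BB base intervals in
#'   units of `f0`; default `rbind(c(3, 4), c(4, 5))` meaning
#'   `[3 f0 + guard, 4 f0 - guard]` and `[4 f0 + guard, 5 f0 - guard]`.
#' @return An object of class `spectral_config`.
#' @examples
#' cfg <- spectral_config()
#' band_intervals(cfg)
#' @export
spectral_config <- function(f0 = 1e6, guard = 30e3,
                            harmonic_orders = c(4, 5),
                            ultraharmonic_orders = c(3.5, 4.5),
                            broadband_ranges = rbind(c(3, 4), c(4, 5))) {
  if (!is.numeric(f0) || f0 <= 0) stop("`f0` must be positive", call. = FALSE)
  if (!is.numeric(guard) || guard <= 0) {
    stop("`guard` must be positive", call. = FALSE)
  }
  if (guard >= f0 / 2) {
    stop("`guard` must be below f0/2 or the analysis windows collide",
         call. = FALSE)
  }
  structure(list(f0 = f0, guard = guard,
                 harmonic_orders = sort(harmonic_orders),
                 ultraharmonic_orders = sort(ultraharmonic_orders),
                 broadband_ranges = broadband_ranges),
            class = "spectral_config")
}

#' @export
print.spectral_config <- function(x, ...) {
  cat("<spectral_config> f0 =", format(x$f0, big.mark = ","),
      "Hz, guard =", format(x$guard, big.mark = ","), "Hz\n")
  print(band_intervals(x))
  invisible(x)
}

# Subtract closed intervals `cut` from closed intervals `base`; the
# removed stretches take their endpoints with them (the overlap is
# resolved at bin level by assignment priority, see band_bins).
subtract_intervals <- function(base, cut) {
  out <- base
  for (i in seq_len(nrow(cut))) {
    nxt <- matrix(numeric(), 0L, 2L)
    for (j in seq_len(nrow(out))) {
      lo <- out[j, 1]; hi <- out[j, 2]
      clo <- cut[i, 1]; chi <- cut[i, 2]
      if (chi < lo || clo > hi) {
        nxt <- rbind(nxt, c(lo, hi))
      } else {
        if (clo > lo) nxt <- rbind(nxt, c(lo, clo))
        if (chi < hi) nxt <- rbind(nxt, c(chi, hi))
      }
    }
    out <- nxt
  }
  out
}

#' Frequency intervals of each analysis band
#'
#' @param config A [spectral_config()].
#' @return A tibble with columns `band` (`"HH"`, `"UH"`, `"BB"`), `lo`
#'   and `hi` (Hz, closed endpoints).  BB rows are the printed
#'   between-harmonic ranges with the ultraharmonic windows removed.
#' @export
band_intervals <- function(config) {
  f0 <- config$f0; g <- config$guard
  hh <- cbind(config$harmonic_orders * f0 - g,
              config$harmonic_orders * f0 + g)
  uh <- cbind(config$ultraharmonic_orders * f0 - g,
              config$ultraharmonic_orders * f0 + g)
  bb_base <- cbind(config$broadband_ranges[, 1] * f0 + g,
                   config$broadband_ranges[, 2] * f0 - g)
  bb <- subtract_intervals(bb_base, rbind(uh, hh))
  tibble::tibble(
    band = rep(c("HH", "UH", "BB"), c(nrow(hh), nrow(uh), nrow(bb))),
    lo = c(hh[, 1], uh[, 1], bb[, 1]),
    hi = c(hh[, 2], uh[, 2], bb[, 2])
  )
}

#' Segment a recording into a trigger-locked pulse train
#'
#' Cuts fixed-length pulse windows out of a continuous PCD trace, either
#' at supplied trigger times (seconds) or, in uniform mode, at the pulse
#' repetition grid `k / PRF`.  The window length is
#' `round(duty_cycle / prf * sampling_rate)` samples (10 ms, i.e. 312,500
#' samples, at the defaults).  A trailing window that would overrun the
#' recording is dropped with a warning.
#'
#' @param samples Numeric vector, the full recording.
#' @param meta A [recording_meta()].
#' @param trigger_times Optional pulse trigger times in seconds; when
#'   `NULL`, uniform segmentation at the PRF grid is used.
#' @return An object of class `pulse_train`: list with `pulses` (a
#'   `window_length x n_pulses` matrix), `spot` (integer spot index per
#'   pulse, from `pulses_per_spot(meta)`), and `meta`.
#' @export
segment_pulses <- function(samples, meta, trigger_times = NULL) {
  if (!length(samples)) stop("empty sample sequence", call. = FALSE)
  fs <- meta$sampling_rate
  len <- pulse_window_length(meta)
  n <- length(samples)
  if (is.null(trigger_times)) {
    starts <- as.integer(round(seq(0, by = fs / meta$prf,
                                   length.out = ceiling(n / (fs / meta$prf))))) + 1L
    starts <- starts[starts <= n]
  } else {
    starts <- as.integer(round(trigger_times * fs)) + 1L
    if (any(starts > n)) {
      stop("trigger time beyond recording end", call. = FALSE)
    }
  }
  keep <- starts + len - 1L <= n
  if (!any(keep)) stop("recording shorter than one pulse window", call. = FALSE)
  if (any(!keep)) {
    warning(sum(!keep), " pulse window(s) overrun the recording and were dropped")
  }
  starts <- starts[keep]
  idx <- outer(seq_len(len) - 1L, starts, `+`)
  pulses <- matrix(samples[idx], nrow = len)
  pps <- pulses_per_spot(meta)
  structure(list(
    pulses = pulses,
    spot = as.integer((seq_along(starts) - 1L) %/% pps + 1L),
    meta = meta
  ), class = "pulse_train")
}

#' @export
print.pulse_train <- function(x, ...) {
  cat("<pulse_train>", ncol(x$pulses), "pulses x", nrow(x$pulses),
      "samples,", max(x$spot), "spot(s)\n")
  invisible(x)
}

#' Discrete Fourier spectrum of one pulse
#'
#' Plain rectangular-window DFT (no taper), so Parseval's theorem holds
#' exactly: `sum(|S_f|^2) / N_FT == sum(x_t^2)`.
#'
#' @param x Numeric vector, one pulse window (finite values).
#' @param fs Sampling rate in Hz (used only to annotate the bin width).
#' @return An object of class `pcd_spectrum`: list with complex `S_f`,
#'   `n_ft` (number of bins, equal to `length(x)`) and `bin_width`
#'   (`fs / n_ft`, or `NA` when `fs` is missing).
#' @export
compute_spectrum <- function(x, fs = NA_real_) {
  if (!length(x)) stop("empty pulse window", call. = FALSE)
  if (any(!is.finite(x))) stop("pulse contains NaN or Inf", call. = FALSE)
  n <- length(x)
  structure(list(S_f = stats::fft(x), n_ft = n, bin_width = fs / n),
            class = "pcd_spectrum")
}

#' Positive-frequency bin indices of each band
#'
#' Maps band intervals to DFT bin indices for a pulse of `n_ft` samples
#' at sampling rate `fs`.  Bin `k` (frequency `k * fs / n_ft`) is
#' assigned to a band when its frequency lies inside one of that band's
#' closed intervals; assignment priority HH, then UH, then BB makes the
#' three sets pairwise disjoint even for configurations whose printed
#' intervals touch.  The DC bin and (for even `n_ft`) the Nyquist bin are
#' never assigned.
#'
#' @param config A [spectral_config()].
#' @param n_ft Number of DFT bins (pulse sample count).
#' @param fs Sampling rate in Hz.
#' @return Named list of integer vectors `HH`, `UH`, `BB`; values are
#'   bin indices `k` in `1 .. floor(n_ft / 2)` (frequency `k * fs / n_ft`).
#' @export
band_bins <- function(config, n_ft, fs) {
  iv <- band_intervals(config)
  if (max(iv$hi) > fs / 2) {
    stop("band extends past Nyquist (", format(fs / 2), " Hz)", call. = FALSE)
  }
  k_max <- floor(n_ft / 2)
  k <- seq_len(k_max)
  if (n_ft %% 2L == 0L) k <- k[-length(k)]   # exclude Nyquist bin by rule
  freq <- k * fs / n_ft
  in_band <- function(b) {
    rows <- iv[iv$band == b, , drop = FALSE]
    hit <- rep(FALSE, length(k))
    for (j in seq_len(nrow(rows))) {
      hit <- hit | (freq >= rows$lo[j] & freq <= rows$hi[j])
    }
    hit
  }
  hh <- in_band("HH")
  uh <- in_band("UH") & !hh
  bb <- in_band("BB") & !hh & !uh
  list(HH = k[hh], UH = k[uh], BB = k[bb])
}

#' Parseval band intensity
#'
#' The per-pulse intensity of a spectral component is the Parseval sum
#' `I = sum_{f in band} |S_f|^2 / N_FT` over positive-frequency bins
#' only, matching band definitions stated on the positive half-axis.
#' (A tone of amplitude `a` on a bin center therefore contributes
#' `N_FT * a^2 / 4`.)
#'
#' @param spectrum A [compute_spectrum()] result.
#' @param bins Integer vector of positive-frequency bin indices
#'   (`1 .. floor(n_ft/2)`), e.g. one element of [band_bins()].
#' @return Non-negative scalar intensity.
#' @export
parseval_intensity <- function(spectrum, bins) {
  if (length(bins) &&
      (min(bins) < 1L || max(bins) > floor(spectrum$n_ft / 2))) {
    stop("bins must be positive-frequency indices", call. = FALSE)
  }
  sum(Mod(spectrum$S_f[bins + 1L])^2) / spectrum$n_ft
}

#' Per-pulse band intensities of a pulse train
#'
#' Computes the HH/UH/BB Parseval intensities of every pulse.
#'
#' @param train A [segment_pulses()] result.
#' @param config A [spectral_config()]; its bands must lie below Nyquist
#'   for the train's sampling rate.
#' @return A tibble with columns `pulse`, `spot`, `I_HH`, `I_UH`, `I_BB`.
#' @export
band_intensities <- function(train, config = spectral_config()) {
  n_ft <- nrow(train$pulses)
  fs <- train$meta$sampling_rate
  bins <- band_bins(config, n_ft, fs)
  n_p <- ncol(train$pulses)
  out <- matrix(0, n_p, 3L, dimnames = list(NULL, c("I_HH", "I_UH", "I_BB")))
  for (i in seq_len(n_p)) {
    sp <- compute_spectrum(train$pulses[, i], fs)
    out[i, ] <- c(parseval_intensity(sp, bins$HH),
                  parseval_intensity(sp, bins$UH),
                  parseval_intensity(sp, bins$BB))
  }
  tibble::tibble(pulse = seq_len(n_p), spot = train$spot,
                 I_HH = out[, 1], I_UH = out[, 2], I_BB = out[, 3])
}

#' Pulse-magnitude histogram for one band
#'
#' Counts the number of ultrasound pulses whose band intensity falls in
#' each magnitude bin, the per-band "pulses of a particular magnitude"
#' summary used to compare cavitation activity between sessions.  Default
#' edges are log10-spaced across the observed positive intensity range;
#' values below the first or above the last edge accumulate in the end
#' bins, so counts always conserve the pulse number.
#'
#' @param intensities A [band_intensities()] tibble (or any data frame
#'   with an `I_<band>` column).
#' @param band One of `"HH"`, `"UH"`, `"BB"`.
#' @param edges Strictly increasing numeric vector of bin edges
#'   (`n_bins + 1` values); default log10-spaced over the observed range.
#' @param n_bins Number of bins when `edges` is `NULL` (default 24).
#' @return An object of class `magnitude_histogram`: list with `band`,
#'   `edges`, `counts` and `total`.
#' @export
pulse_magnitude_histogram <- function(intensities, band = c("HH", "UH", "BB"),
                                      edges = NULL, n_bins = 24L) {
  band <- match.arg(band)
  values <- intensities[[paste0("I_", band)]]
  if (is.null(values)) stop("no I_", band, " column in `intensities`", call. = FALSE)
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite intensities to histogram", call. = FALSE)
  if (is.null(edges)) {
    pos <- values[values > 0]
    if (!length(pos)) {
      edges <- c(0, seq_len(n_bins))  # degenerate all-zero input
    } else {
      lo <- min(pos); hi <- max(pos)
      if (lo == hi) hi <- lo * 10
      edges <- 10^seq(log10(lo), log10(hi), length.out = n_bins + 1L)
    }
  }
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing", call. = FALSE)
  # [e_i, e_{i+1}) bins with clamped ends
  bin <- findInterval(values, edges, left.open = FALSE)
  bin <- pmin(pmax(bin, 1L), length(edges) - 1L)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  structure(list(band = band, edges = edges, counts = counts,
                 total = length(values)),
            class = "magnitude_histogram")
}

#' @export
print.magnitude_histogram <- function(x, ...) {
  cat("<magnitude_histogram>", x$band, "band,", x$total, "pulses in",
      length(x$counts), "bins\n")
  invisible(x)
}

#' Aggregate per-pulse intensities over spots and session
#'
#' @param intensities A [band_intensities()] tibble.
#' @param n_bins Bins for the pooled per-band magnitude histograms.
#' @return List with `spot_summary` (mean/median/max per spot and band),
#'   `session_summary` (the same pooled over the whole session) and
#'   `histograms` (named list of [pulse_magnitude_histogram()] results).
#' @export
aggregate_session <- function(intensities, n_bins = 24L) {
  if (!nrow(intensities)) stop("no pulses to aggregate", call. = FALSE)
  long <- tidyr_pivot(intensities)
  spot_summary <- dplyr::summarise(
    dplyr::group_by(long, .data$spot, .data$band),
    mean = mean(.data$I), median = stats::median(.data$I), max = max(.data$I),
    n_pulses = dplyr::n(), .groups = "drop"
  )
  session_summary <- dplyr::summarise(
    dplyr::group_by(long, .data$band),
    mean = mean(.data$I), median = stats::median(.data$I), max = max(.data$I),
    n_pulses = dplyr::n(), .groups = "drop"
  )
  hists <- lapply(c(HH = "HH", UH = "UH", BB = "BB"), function(b) {
    pulse_magnitude_histogram(intensities, b, n_bins = n_bins)
  })
  list(spot_summary = spot_summary, session_summary = session_summary,
       histograms = hists)
}

# base-only long reshape of the three I_ columns
tidyr_pivot <- function(intensities) {
  bands <- c("HH", "UH", "BB")
  tibble::tibble(
    pulse = rep(intensities$pulse, length(bands)),
    spot = rep(intensities$spot, length(bands)),
    band = rep(bands, each = nrow(intensities)),
    I = c(intensities$I_HH, intensities$I_UH, intensities$I_BB)
  )
}
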