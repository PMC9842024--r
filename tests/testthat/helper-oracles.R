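# Independent oracles and small fixtures shared across tests.

# Brute-force DFT straight from the definition (O(n^2)); the reference
# against which the FFT-based spectrum is checked.
brute_dft <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk) {
    sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n))
  }, complex(1))
}

# Direct step-up BH oracle: q_(k) = min_{j >= k} p_(j) * n / j, mapped
# back to input order.
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- pmin(rev(cummin(rev(ps * n / seq_len(n)))), 1)
  out <- numeric(n)
  out[ord] <- q
  out
}

# Exhaustive hypergeometric upper tail: enumerate every possible draw of
# `d` genes from a universe of size `n_u` whose first `n_set` elements
# form the gene set, and count draws overlapping the set by >= de.
enum_hyper_tail <- function(n_u, n_set, d, de) {
  draws <- utils::combn(n_u, d)
  overlaps <- colSums(draws <= n_set)
  mean(overlaps >= de)
}

# Reduced-rate acquisition metadata for fast spectral tests: 10 ms
# windows of 125,000 samples instead of 312,500.
fast_meta <- function(...) {
  recording_meta(sampling_rate = 12.5e6, ...)
}

silent_params <- function(jitter_sdlog = 0) {
  emission_params(harmonics = numeric(6), ultraharmonics = numeric(5),
                  sigma_bb = 0, jitter_sdlog = jitter_sdlog)
}

extdata <- function(file) {
  system.file("extdata", file, package = "sonoquant", mustWork = TRUE)
}

# A cosine sampled exactly on a DFT bin.
bin_tone <- function(freq, fs, n, amplitude = 1, phase = 0) {
  amplitude * cos(2 * pi * freq * (0:(n - 1)) / fs + phase)
}

# Minimal valid DEG tibble for algebra tests.
deg_tbl <- function(gene, logFC, adjPVal = rep(0.01, length(gene)),
                    PVal = adjPVal / 2) {
  tibble::tibble(gene = gene, logFC = logFC,
                 AvgExp = 0, t = sign(logFC), PVal = PVal,
                 adjPVal = adjPVal, B = 0)
}
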