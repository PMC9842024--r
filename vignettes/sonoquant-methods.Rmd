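---
title: "Methods: cavitation band intensities, DEG set algebra and hemisphere fold-change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cavitation band intensities, DEG set algebra and hemisphere fold-change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoquant)
```

# Scope

`sonoquant` implements the off-line analysis chain of a scanning-ultrasound
(SUS^+MB^) blood–brain-barrier (BBB) opening experiment in which transcranial
ultrasound is delivered with intravenously injected microbubbles:

1. **Cavitation monitoring** — decomposition of passive cavitation detector
   (PCD) recordings into higher-harmonic (HH), ultraharmonic (UH) and
   broadband (BB) components, with a per-pulse Parseval intensity and
   pulse-magnitude counting.
2. **Transcriptome post-processing** — set algebra over per-contrast
   differential-expression (DEG) tables: FDR filtering, direction splitting,
   two-contrast Venn partitioning and top-N ranking.
3. **Over-representation** — hypergeometric tail tests of gene sets among the
   significant genes.
4. **BBB quantification** — fluorescence fold-change between the sonicated
   and control hemispheres of dye-extravasation sections.

Upstream steps (read alignment, the limma/edgeR model fit that produces the
per-gene statistics, normalization, image registration) are out of scope; the
package consumes their outputs.

# PCD spectral model

## Acquisition geometry

The transmit sequence is a 1 MHz center frequency (`f0`) burst train at a
10 Hz pulse repetition frequency (PRF) with a 10% duty cycle — 10 ms bursts —
and 6 s of sonication per spot, so each spot contributes
`6 s × 10 Hz = 60` pulses. The PCD trace is digitized at 16-bit resolution
and 31.25 MHz in synchronization with the pulse excitation, giving
`0.1 / 10 × 31.25e6 = 312,500` samples per pulse window. These values are the
defaults of `recording_meta()`; the constructor enforces positivity, a duty
cycle in (0, 1], and Nyquist coverage of the 5th-harmonic band
(`fs > 2 (5 f0 + guard)`).

Pulse windows are cut at the digitizer trigger times when present
(`segment_pulses(..., trigger_times =)`); without triggers, uniform
segmentation at the PRF grid is used. Trigger-locked windows take precedence
because acquisition is synchronized to the excitation.

## Band definitions

With a guard half-width `g` (default 30 kHz, chosen to separate the narrow
tonal peaks from the inter-harmonic floor), the bands around `f0 = 1 MHz`
are, with closed endpoints:

* HH: `[4f0 − g, 4f0 + g] ∪ [5f0 − g, 5f0 + g]`
* UH: `[3.5f0 − g, 3.5f0 + g] ∪ [4.5f0 − g, 4.5f0 + g]`
* BB: `[3f0 + g, 4f0 − g] ∪ [4f0 + g, 5f0 − g]`, **minus** the UH windows.

The carve-out is deliberate: the literal between-harmonic broadband ranges
contain the 3.5`f0` and 4.5`f0` ultraharmonic windows, and a bin assigned to
two bands would make band intensities non-additive and double-count tonal
energy as "broadband". `band_bins()` therefore assigns each DFT bin to at
most one band with priority HH → UH → BB. The effective broadband width at
defaults is `2(f0 − 2g) − 2(2g) = 1.76 MHz` (1.88 MHz before the
ultraharmonic notches). The DC bin and the Nyquist bin are excluded from all
bands by rule; at default settings they never intersect the printed
intervals anyway.

## Intensity statistic

Each pulse is transformed with a plain rectangular-window DFT
(`compute_spectrum()`); no taper is applied, so Parseval's theorem is exact:
`Σ_f |S_f|² / N_FT = Σ_t x_t²`. Spectral leakage from off-bin tones is
handled by the ±30 kHz guard rather than by windowing. The band intensity is
the Parseval sum over the band's **positive-frequency** bins,

```
I_band = Σ_{f ∈ band} |S_f|² / N_FT ,
```

matching band definitions stated on the positive half-axis. One-sided
accounting halves tone energy relative to a two-sided sum: an on-bin cosine
of amplitude `a` yields `I = N_FT a² / 4`, which is why the simulator
recovery tests compare `I_HH` against `N/4` and estimate amplitudes as
`sqrt(4 I / N)`.

```{r bands}
cfg <- spectral_config()
band_intervals(cfg)
```

## Pulse-magnitude counting and aggregation

`pulse_magnitude_histogram()` counts pulses per intensity bin. Published
cavitation-dose figures do not state their binning or per-animal
normalization, so edges are parameters: the default is 24 log10-spaced bins
spanning the observed positive range, with values outside the range clamped
into the end bins so counts always conserve the pulse number. Whether
intensities were originally computed per pulse or per sonication spot is
equally unstated; the package computes **per pulse** and aggregates to spots
and sessions with `aggregate_session()` (mean, median, max per band).

# Synthetic pulse trains

`emission_params()` + `simulate_session()` generate surrogate microbubble
emissions: harmonics `a_k cos(2π k f0 t + φ_k)` for k = 1..6,
ultraharmonics at half-integer orders 1.5–5.5, and white Gaussian noise
brick-wall band-limited to 2–6 MHz, all scaled by a per-pulse lognormal
jitter. Phases are independent Uniform(0, 2π) per pulse. Defaults sketch a
stable-cavitation-dominated emission (fundamental 0.5 with geometrically
decaying harmonics, ultraharmonics ≤ 0.01, broadband σ 0.005, jitter
σ_log 0.1); the study supplies no emission model, so these are round numbers
chosen for realism, not fitted values. The generator rescales if the
waveform would clip 16-bit range, records the scale, and quantizes to the
int16 grid by default so the reader path is exercised.

What the simulator does **not** capture: physical bubble dynamics
(Rayleigh–Plesset-type responses), structured inertial-cavitation spectra
(the BB component is flat within its band), skull attenuation, and
inter-pulse quiet intervals (the synthetic recording concatenates
acquisition windows back to back, with explicit trigger times). Passing
recovery tests therefore demonstrates the correctness of the analysis
algebra — band assignment, Parseval accounting, amplitude recovery — not
fidelity to in vivo emission spectra.

`simulate_session_intensities()` is a streaming companion that analyzes each
pulse as it is generated (same RNG draw order, so tonal content matches the
materialized recording) and never holds a full session in memory; a 20-spot
session is 1,200 pulses ≈ 375M samples at the full rate.

# DEG set algebra

Significance is `adjPVal ≤ α` with α = 0.05 on the Benjamini–Hochberg (BH)
adjusted p-value. The closed threshold follows the convention "FDR ≤ 0.05";
a `strict` flag provides the `<` variant since figure captions sometimes
state "adjusted p < 0.05". Deposited adjusted p-values are trusted by
default (recomputing BH over a different gene universe would change the
counts); `readjust = TRUE` recomputes them from the raw p column via
`bh_adjust()`, a validated wrapper over `stats::p.adjust(method = "BH")`
that the test suite cross-checks against a direct step-up oracle.

`split_direction()` classifies by the sign of `logFC` (positive =
up-regulated by treatment); a *significant* gene with `logFC = 0` is an
error rather than silently binned. `venn_partition()` computes shared and
contrast-specific sets separately for up- and down-regulated genes. A gene
significant in both contrasts with opposite signs — possible in principle,
unaddressed in the conventions this follows — is counted as specific within
each direction set but shared at the symbol level, which preserves the
partition identities `|specific_A| + |shared| = |sig_A|` and
`|union| = |sig_A| + |sig_B| − |shared|`.

`rank_top_n()` orders by descending `|logFC|`; ties (absent in practice at
full precision) break by ascending `adjPVal`, then gene symbol, to keep the
ranking deterministic.

```{r deg}
g <- generate_deg_tables(planted_deg_spec(), seed = 1)
vp <- venn_partition(filter_significant(g$xo4plus, 0.05),
                     filter_significant(g$xo4neg, 0.05))
partition_counts(vp)
```

## Planted DEG tables

`planted_deg_spec()` defaults plant the partition structure of a
two-contrast microglia experiment — 248 up / 30 down in the
amyloid-internalizing (XO4^+^) contrast, 225 up / 17 down in the XO4^−^
contrast, 120 shared up and 3 shared down — over 12,000 null genes. The
shared-direction split is implied by the published totals: 353 up-regulated
and 44 down-regulated genes across the 397-gene union give
`248 + 225 − 353 = 120` shared up and `30 + 17 − 44 = 3` shared down.

True DEGs draw `|logFC|` from lognormal(meanlog 1, sdlog 0.35) (median 2.7,
comparable to significant microglial responses) with raw p in
(10⁻¹², 10⁻⁹); nulls get logFC ~ N(0, 0.15²) and p uniform on
(`null_p_min`, 1). The floor (default 0.05) is a deliberate departure from a
fully uniform null: with 12,000 uniform nulls, BH at 0.05 admits a handful
of false positives in most draws, so exact recovery of planted counts — the
property the generator exists to guarantee — would fail. Because an adjusted
p-value can never drop below its raw p, a floor at the significance level
makes recovery exact for any seed; `null_p_min = 0` restores the uniform
null for FDR-behaviour studies. One published count ("199 genes specific"
for the second contrast) is arithmetically inconsistent with its own totals
(242 significant − 123 shared = 119); the package reports the computed 119
and leaves the discrepancy to the reader.

# Over-representation

`enrich()` reports, per gene set: `N` (set members in the universe), `DE`
(set members among the significant genes) and `p.DE`, the hypergeometric
upper tail `P(X ≥ DE)` for `|de_genes|` draws without replacement from the
universe — the standard "at least this much overlap" convention. No
multiple-testing correction is applied, mirroring conventional enrichment
tables that print raw `p.DE`. The recommended universe is the tested
(expression-filtered) gene list rather than the whole genome; an enrichment
against all annotated genes systematically inflates significance. No
abundance/length bias correction is attempted. The tail probability is
computed with `stats::phyper`; tests verify it against exhaustive
enumeration of all draws for universes up to 12 genes.

# Hemisphere fold-change

`fold_change()` is `(treated − background) / (control − background)`.
Background handling is not described in the conventions this follows; the
package subtracts a user-supplied level (image mode uses the median of an
off-tissue mask region, default 0) because infrared scanner sections carry a
non-zero baseline that biases raw ratios toward 1. The statistic is
invariant under common intensity rescaling, and a non-positive corrected
control is a hard error, not an `Inf`. `animal_summary()` averages the two
(or more) sections per mouse; the genotype comparison itself is left to the
user — no hypothesis test is bundled because the appropriate test depends on
the design.

# Numerical and testing choices

* Exact Parseval identity is asserted at 1e−9 relative tolerance on
  full-length (312,500-sample) pulses; double-precision FFTs achieve ~1e−15.
* Tone-classification dominance (≥ 10⁶:1 between bands) is tested with
  on-bin tones, where rectangular-window leakage is zero to rounding.
* Most spectral unit tests run at a 12.5 MHz sampling rate (125,000-sample
  windows) — every band identity is rate-independent above Nyquist coverage —
  while the acceptance-scale tests use the full 31.25 MHz geometry with 100
  random pulses, 200-pulse noise-monotonicity sessions and a 1,200-pulse
  20-spot session.
* All generators are pure functions of (parameters, seed), restore the
  caller's RNG state, and are exercised for bit-identical reproducibility.
* Degenerate inputs fail loudly: empty recordings, triggers beyond the
  recording, NaN pulses, p-values outside [0, 1], adjusted p below raw p,
  zero-logFC significant genes, DE genes absent from the universe,
  non-positive corrected control intensities.

# Known limitations

* Intensities are relative (dimensionless digitizer units); no hydrophone
  calibration to absolute pressure is attempted.
* The broadband statistic measures in-band energy; it does not separate
  inertial-cavitation noise from other wideband interference.
* GO/KEGG-style enrichment results depend on the annotation snapshot used
  for the gene-set collection; the package ships no annotation and makes no
  attempt to reproduce published enrichment rows.
* The Venn algebra trusts deposited adjusted p-values; reproducing published
  significant-gene counts requires the original deposited tables, not the
  printed top-50 excerpts.
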