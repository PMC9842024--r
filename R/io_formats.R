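# Readers and writers for every external representation the pipeline
# touches: raw PCD recordings (int16 + JSON sidecar, or PCM WAV), DEG
# tables, and GMT gene-set collections.

#' Acquisition metadata for a PCD recording
#'
#' Bundles and validates the acquisition parameters of a passive
#' cavitation detector (PCD) session: digitizer sampling rate, bit depth,
#' ultrasound pulse repetition frequency (PRF), duty cycle, sonication
#' time per spot, number of spots and transmit center frequency `f0`.
#'
#' The sampling rate must satisfy Nyquist for the highest analysis band:
#' `sampling_rate > 2 * (5 * f0 + guard)` so that the 5th-harmonic window
#' is representable.
#'
#' @param sampling_rate Digitizer sampling rate in Hz (default 31.25 MHz).
#' @param bit_depth Digitizer bit depth (default 16).
#' @param prf Pulse repetition frequency in Hz (default 10).
#' @param duty_cycle On-fraction of each pulse period, in (0, 1]
#'   (default 0.1, i.e. 10 ms bursts at 10 Hz).
#' @param seconds_per_spot Sonication time per spot in seconds (default 6).
#' @param spots Number of sonication spots in the session.
#' @param f0 Transmit center frequency in Hz (default 1 MHz).
#' @param guard Half-width of the harmonic analysis windows in Hz, used
#'   only for the Nyquist check (default 30 kHz).
#' @return An object of class `recording_meta` (a validated list).
#' @examples
#' meta <- recording_meta(spots = 20)
#' meta$prf
#' @export
recording_meta <- function(sampling_rate = 31.25e6, bit_depth = 16L,
                           prf = 10, duty_cycle = 0.1,
                           seconds_per_spot = 6, spots = 1L,
                           f0 = 1e6, guard = 30e3) {
  num1 <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("`", name, "` must be a single finite number", call. = FALSE)
    }
    as.numeric(x)
  }
  meta <- list(
    sampling_rate = num1(sampling_rate, "sampling_rate"),
    bit_depth = as.integer(num1(bit_depth, "bit_depth")),
    prf = num1(prf, "prf"),
    duty_cycle = num1(duty_cycle, "duty_cycle"),
    seconds_per_spot = num1(seconds_per_spot, "seconds_per_spot"),
    spots = as.integer(num1(spots, "spots")),
    f0 = num1(f0, "f0")
  )
  for (field in c("sampling_rate", "bit_depth", "prf", "seconds_per_spot",
                  "spots", "f0")) {
    if (meta[[field]] <= 0) {
      stop("recording metadata invalid: `", field, "` must be positive",
           call. = FALSE)
    }
  }
  if (meta$duty_cycle <= 0 || meta$duty_cycle > 1) {
    stop("recording metadata invalid: `duty_cycle` must lie in (0, 1]",
         call. = FALSE)
  }
  if (meta$sampling_rate <= 2 * (5 * meta$f0 + guard)) {
    stop("recording metadata invalid: `sampling_rate` must exceed ",
         "2 * (5 * f0 + guard) so the 5th-harmonic band is below Nyquist",
         call. = FALSE)
  }
  structure(meta, class = "recording_meta")
}

#' @export
print.recording_meta <- function(x, ...) {
  cat("<recording_meta>\n")
  cat(sprintf("  fs = %.6g Hz, %d-bit, f0 = %.6g Hz\n",
              x$sampling_rate, x$bit_depth, x$f0))
  cat(sprintf("  PRF = %g Hz, duty = %g, %g s/spot x %d spots\n",
              x$prf, x$duty_cycle, x$seconds_per_spot, x$spots))
  invisible(x)
}

#' Pulses per spot and pulse window length implied by metadata
#'
#' @param meta A [recording_meta()].
#' @return `pulses_per_spot()`: pulses emitted per sonication spot
#'   (`seconds_per_spot * prf`).  `pulse_window_length()`: samples per
#'   pulse window (`round(duty_cycle / prf * sampling_rate)`).
#' @export
pulses_per_spot <- function(meta) {
  as.integer(round(meta$seconds_per_spot * meta$prf))
}

#' @rdname pulses_per_spot
#' @export
pulse_window_length <- function(meta) {
  as.integer(round(meta$duty_cycle / meta$prf * meta$sampling_rate))
}

meta_to_list <- function(meta) unclass(meta)

meta_from_list <- function(x) {
  recording_meta(
    sampling_rate = x$sampling_rate, bit_depth = x$bit_depth %||% 16L,
    prf = x$prf, duty_cycle = x$duty_cycle,
    seconds_per_spot = x$seconds_per_spot, spots = x$spots %||% 1L,
    f0 = x$f0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a raw PCD recording
#'
#' Reads a passive-cavitation-detector voltage trace stored either as
#' headerless signed 16-bit little-endian samples with a JSON sidecar, or
#' as a mono 16-bit PCM WAV file.  Samples are rescaled to dimensionless
#' units in `[-1, 1)` by dividing by 32768, so the most negative int16
#' value maps exactly to -1.
#'
#' The sidecar is a JSON object with the [recording_meta()] fields
#' (`sampling_rate`, `prf`, `duty_cycle`, `seconds_per_spot`, `spots`,
#' `f0`, optional `bit_depth`), plus optional `n_samples` (checked
#' against the file) and optional `trigger_times` in seconds.
#'
#' @param path Path to the sample file (`.raw`/`.bin` int16, or `.wav`).
#' @param meta_path Path to the JSON sidecar.  Required for raw files;
#'   for WAV files it supplies everything except the sampling rate, which
#'   must agree with the WAV header.
#' @return A list with `samples` (numeric vector in `[-1, 1)`),
#'   `meta` (a `recording_meta`) and `trigger_times` (seconds, or `NULL`).
#' @export
read_pcd_recording <- function(path, meta_path) {
  if (!file.exists(path)) stop("recording file not found: ", path, call. = FALSE)
  if (missing(meta_path) || !file.exists(meta_path)) {
    stop("metadata sidecar not found", call. = FALSE)
  }
  side <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  meta <- meta_from_list(side)

  is_wav <- grepl("\\.wav$", path, ignore.case = TRUE) ||
    identical(readBin(path, "raw", n = 4L), charToRaw("RIFF"))
  if (is_wav) {
    wav <- read_wav_pcm16(path)
    if (abs(wav$sample_rate - meta$sampling_rate) > 0.5) {
      stop("WAV sample rate (", wav$sample_rate,
           ") disagrees with sidecar sampling_rate", call. = FALSE)
    }
    raw_int <- wav$samples
  } else {
    n_bytes <- file.info(path)$size
    if (n_bytes %% 2L != 0L) {
      stop("truncated recording: file size is not a whole number of ",
           "16-bit samples", call. = FALSE)
    }
    raw_int <- readBin(path, "integer", n = n_bytes / 2L, size = 2L,
                       signed = TRUE, endian = "little")
  }
  if (!is.null(side$n_samples) && length(raw_int) != side$n_samples) {
    stop("truncated recording: expected ", side$n_samples,
         " samples, found ", length(raw_int), call. = FALSE)
  }
  trig <- side$trigger_times
  if (!is.null(trig)) {
    trig <- as.numeric(trig)
    if (any(!is.finite(trig)) || any(trig < 0)) {
      stop("invalid trigger_times in sidecar", call. = FALSE)
    }
  }
  list(samples = raw_int / 32768, meta = meta, trigger_times = trig)
}

#' Write a raw PCD recording with JSON sidecar
#'
#' Quantizes samples in `[-1, 1)` to signed 16-bit integers
#' (`round(x * 32768)`, clamped to 32767) and writes them little-endian,
#' with a JSON sidecar holding the metadata, sample count and optional
#' trigger times.
#'
#' @param samples Numeric vector in `[-1, 1)`.
#' @param meta A [recording_meta()].
#' @param path Output path for the sample file.
#' @param meta_path Output path for the sidecar (default: `path` with
#'   `.json` appended).
#' @param trigger_times Optional pulse trigger times in seconds.
#' @return Invisibly, `path`.
#' @export
write_pcd_recording <- function(samples, meta, path,
                                meta_path = paste0(path, ".json"),
                                trigger_times = NULL) {
  if (any(!is.finite(samples))) stop("samples must be finite", call. = FALSE)
  if (max(abs(samples)) > 1) {
    stop("samples exceed [-1, 1): rescale before writing", call. = FALSE)
  }
  q <- pmin(as.integer(round(samples * 32768)), 32767L)
  writeBin(q, path, size = 2L, endian = "little")
  side <- meta_to_list(meta)
  side$n_samples <- length(q)
  if (!is.null(trigger_times)) side$trigger_times <- trigger_times
  jsonlite::write_json(side, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Minimal mono PCM16 WAV reader; vendor formats are out of scope and no
# audio package ships with the analysis stack, so the RIFF walk is done
# by hand.
read_wav_pcm16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file", call. = FALSE)
  readBin(con, "integer", 1L, size = 4L, endian = "little") # chunk size
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file", call. = FALSE)
  }
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop("WAV: no data chunk", call. = FALSE)
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      n_channels <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      sample_rate <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      readBin(con, "integer", 1L, size = 4L, endian = "little") # byte rate
      readBin(con, "integer", 1L, size = 2L, endian = "little") # block align
      bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      if (sz > 16L) seek(con, sz - 16L, origin = "current")
      if (audio_format != 1L || n_channels != 1L || bits != 16L) {
        stop("only mono 16-bit PCM WAV is supported", call. = FALSE)
      }
    } else if (identical(id, "data")) {
      if (is.null(sample_rate)) stop("WAV: data before fmt chunk", call. = FALSE)
      samples <- readBin(con, "integer", sz / 2L, size = 2L,
                         signed = TRUE, endian = "little")
      if (length(samples) < sz / 2L) stop("truncated WAV data chunk", call. = FALSE)
      return(list(samples = samples, sample_rate = sample_rate))
    } else {
      seek(con, sz, origin = "current")
    }
  }
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param samples Numeric vector in `[-1, 1)`.
#' @param sample_rate Sampling rate in Hz (written as an integer field).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_wav_pcm16 <- function(samples, sample_rate, path) {
  if (max(abs(samples)) > 1) stop("samples exceed [-1, 1)", call. = FALSE)
  q <- pmin(as.integer(round(samples * 32768)), 32767L)
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(q)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  sr <- as.integer(round(sample_rate))
  # fmt: PCM, mono, rate, byte rate, block align, bits
  writeBin(c(1L, 1L), con, size = 2L, endian = "little")
  writeBin(c(sr, sr * 2L), con, size = 4L, endian = "little")
  writeBin(c(2L, 16L), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4L, endian = "little")
  writeBin(q, con, size = 2L, endian = "little")
  invisible(path)
}

deg_canonical_cols <- c(gene = "gene", genesymbol = "gene",
                        logfc = "logFC", avgexp = "AvgExp", aveexpr = "AvgExp",
                        t = "t", pval = "PVal", pvalue = "PVal",
                        adjpval = "adjPVal", adjp = "adjPVal",
                        b = "B")

# Published tables use U+2010/U+2212/U+2013 where ASCII '-' is meant,
# both as sign and inside exponents ("2.22E-10" printed with a hyphen
# glyph); normalize before numeric parsing.
normalize_minus <- function(x) {
  gsub("[\u2010\u2011\u2012\u2013\u2212]", "-", x)
}

parse_deg_numeric <- function(x, col, offenders_are_rows = TRUE) {
  out <- suppressWarnings(as.numeric(normalize_minus(trimws(x))))
  bad <- which(is.na(out) & !(trimws(x) %in% c("NA", "")))
  if (length(bad)) {
    stop("non-numeric value in column `", col, "` at row ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

#' Read a differential-expression table
#'
#' Reads a tab- or comma-separated DEG table whose header contains the
#' seven per-gene statistics (matched case- and whitespace-insensitively):
#' gene symbol, `logFC` (log2 fold change, treated vs sham), `AvgExp`
#' (average log2 expression), moderated `t`, raw `PVal`, BH-adjusted
#' `adjPVal` and the `B` log-odds of differential expression.  Unicode
#' hyphen/minus glyphs (as printed in publication tables) are accepted in
#' numeric fields.  Gene symbols are whitespace-stripped and kept
#' case-sensitive.
#'
#' @param path Path to the table.
#' @return A [tibble::tibble()] with columns `gene`, `logFC`, `AvgExp`,
#'   `t`, `PVal`, `adjPVal`, `B`, one row per input row, order preserved.
#' @export
read_deg_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty DEG table: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  split_row <- function(l) trimws(strsplit(l, sep, fixed = TRUE)[[1]])
  header <- split_row(lines[[1]])
  key <- gsub("[^a-z]", "", tolower(header))
  canon <- unname(deg_canonical_cols[key])
  missing_cols <- setdiff(unique(unname(deg_canonical_cols)),
                          canon[!is.na(canon)])
  if (length(missing_cols)) {
    stop("DEG table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rows <- lines[-1]
  cells <- lapply(rows, split_row)
  n_col <- length(header)
  bad_len <- which(vapply(cells, length, 1L) != n_col)
  if (length(bad_len)) {
    stop("malformed DEG row (wrong field count) at row ",
         paste(bad_len, collapse = ", "), call. = FALSE)
  }
  mat <- if (length(cells)) do.call(rbind, cells) else
    matrix(character(), 0L, n_col)
  col_of <- function(name) mat[, which(canon == name)[1]]
  out <- tibble::tibble(
    gene = if (nrow(mat)) trimws(col_of("gene")) else character(),
    logFC = parse_deg_numeric(col_of("logFC"), "logFC"),
    AvgExp = parse_deg_numeric(col_of("AvgExp"), "AvgExp"),
    t = parse_deg_numeric(col_of("t"), "t"),
    PVal = parse_deg_numeric(col_of("PVal"), "PVal"),
    adjPVal = parse_deg_numeric(col_of("adjPVal"), "adjPVal"),
    B = parse_deg_numeric(col_of("B"), "B")
  )
  validate_deg_table(out)
  out
}

validate_deg_table <- function(tbl) {
  for (col in c("PVal", "adjPVal")) {
    bad <- which(tbl[[col]] < 0 | tbl[[col]] > 1)
    if (length(bad)) {
      stop("`", col, "` outside [0, 1] at row ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  bad <- which(tbl$adjPVal < tbl$PVal)
  if (length(bad)) {
    stop("`adjPVal` undershoots `PVal` at row ",
         paste(bad, collapse = ", "),
         ": BH-adjusted p-values can never be below the raw p",
         call. = FALSE)
  }
  invisible(tbl)
}

#' Write a differential-expression table
#'
#' Writes the seven canonical columns as TSV at full double precision, so
#' a write/read round trip reproduces every statistic exactly.
#'
#' @param tbl A DEG table as returned by [read_deg_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_deg_table <- function(tbl, path) {
  cols <- c("gene", "logFC", "AvgExp", "t", "PVal", "adjPVal", "B")
  stopifnot(all(cols %in% names(tbl)))
  num <- vapply(cols[-1], function(cl) sprintf("%.17g", tbl[[cl]]),
                character(nrow(tbl)))
  if (nrow(tbl) == 1L) num <- matrix(num, nrow = 1L)
  lines <- c(paste(cols, collapse = "\t"),
             if (nrow(tbl)) paste(tbl$gene, apply(num, 1L, paste, collapse = "\t"),
                                  sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' `id <tab> description <tab> member...`.  Members are de-duplicated
#' within each set; duplicated set ids are an error.
#'
#' @param path Path to the `.gmt` file.
#' @return A tibble with columns `set_id`, `description` and a
#'   list-column `members` (character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) {
    stop("GMT line ", paste(bad, collapse = ", "),
         " has fewer than 3 fields", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicated GMT set id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  members <- lapply(fields, function(f) {
    m <- unique(trimws(f[-(1:2)]))
    m <- m[nzchar(m)]
    if (!length(m)) stop("GMT set `", f[[1]], "` has no members", call. = FALSE)
    m
  })
  tibble::tibble(
    set_id = ids,
    description = vapply(fields, `[[`, "", 2L),
    members = members
  )
}

#' Write a GMT gene-set collection
#'
#' @param collection A tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  lines <- mapply(function(id, desc, mem) {
    paste(c(id, desc, mem), collapse = "\t")
  }, collection$set_id, collection$description, collection$members)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
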