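# Hemisphere fluorescence fold-change for dye-extravasation BBB-opening
# assays: per-section ratios, per-animal means and group tables.

#' Fluorescence fold-change between hemispheres
#'
#' Ratio of background-corrected mean fluorescence in the sonicated
#' hemisphere to the untreated control hemisphere:
#' `(treated - background) / (control - background)`.  All inputs are in
#' the same arbitrary fluorescence units; the ratio is unit-free and
#' invariant under a common positive rescaling.
#'
#' @param treated,control Mean intensity of the sonicated and control
#'   hemispheres (non-negative, vectorized).
#' @param background Background level subtracted from both (default 0);
#'   typically the median intensity of an off-tissue region.
#' @return Numeric vector of fold-changes.
#' @export
fold_change <- function(treated, control, background = 0) {
  if (any(treated < 0) || any(control < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  denom <- control - background
  if (any(denom <= 0)) {
    stop("control minus background must be positive for a computable ratio",
         call. = FALSE)
  }
  (treated - background) / denom
}

#' Per-section fold-changes for a hemisphere-pair table
#'
#' @param pairs A data frame with columns `animal`, `section`, `treated`,
#'   `control` and optionally `background` (default 0) and grouping
#'   columns such as `genotype`.
#' @return `pairs` with a `fold` column appended.
#' @export
fold_change_table <- function(pairs) {
  bg <- if ("background" %in% names(pairs)) pairs$background else 0
  pairs$fold <- fold_change(pairs$treated, pairs$control, bg)
  pairs
}

#' Per-animal fold-change summary
#'
#' Averages section-level fold-changes within each animal (typically two
#' sections per mouse) and lists animals with any grouping column (e.g.
#' genotype) carried through, ready for a group comparison.  No
#' hypothesis test is bundled.
#'
#' @param pairs A hemisphere-pair table ([fold_change_table()] input);
#'   the `fold` column is computed if absent.
#' @param group Optional name of a grouping column to carry (e.g.
#'   `"genotype"`).
#' @return A tibble with one row per animal: `animal`, the group column
#'   if requested, `n_sections` and `fold` (mean over sections).
#' @export
animal_summary <- function(pairs, group = NULL) {
  if (!nrow(pairs)) stop("no sections to summarise", call. = FALSE)
  if (!"fold" %in% names(pairs)) pairs <- fold_change_table(pairs)
  keys <- c("animal", group)
  grouped <- dplyr::group_by(pairs, dplyr::across(dplyr::all_of(keys)))
  dplyr::summarise(grouped, n_sections = dplyr::n(),
                   fold = mean(.data$fold), .groups = "drop")
}

#' Hemisphere mean intensities from a section image
#'
#' Image-mode entry point: reduces a 2-D intensity image and two
#' hemisphere masks to mean intensities (plus an optional off-tissue
#' background region, summarised by its median), after which the
#' analysis proceeds identically to the summary-table mode.
#'
#' @param image Numeric matrix of pixel intensities, or a path to a
#'   grayscale TIFF (read with the `tiff` package).
#' @param mask_treated,mask_control Logical/0-1 matrices (or TIFF paths)
#'   selecting the sonicated and control hemispheres.
#' @param mask_background Optional mask of an off-tissue region; its
#'   median intensity becomes the background estimate (0 when absent).
#' @return A one-row tibble with `treated`, `control`, `background` and
#'   `fold`.
#' @export
hemisphere_means <- function(image, mask_treated, mask_control,
                             mask_background = NULL) {
  image <- as_image_matrix(image)
  m_t <- as_image_matrix(mask_treated) > 0
  m_c <- as_image_matrix(mask_control) > 0
  if (!any(m_t) || !any(m_c)) stop("empty hemisphere mask", call. = FALSE)
  bg <- 0
  if (!is.null(mask_background)) {
    m_b <- as_image_matrix(mask_background) > 0
    if (any(m_b)) bg <- stats::median(image[m_b])
  }
  treated <- mean(image[m_t])
  control <- mean(image[m_c])
  tibble::tibble(treated = treated, control = control, background = bg,
                 fold = fold_change(treated, control, bg))
}

as_image_matrix <- function(x) {
  if (is.character(x)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF images requires the `tiff` package", call. = FALSE)
    }
    x <- tiff::readTIFF(x)
    if (length(dim(x)) == 3L) x <- x[, , 1]
  }
  if (!is.matrix(x)) stop("image must be a matrix or a TIFF path", call. = FALSE)
  x
}
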