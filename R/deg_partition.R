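# Set algebra over per-contrast differential-expression tables:
# FDR filtering, direction splitting, two-contrast Venn partitioning and
# top-N ranking by absolute log fold change.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values (a validated
#' front end to [stats::p.adjust()] with `method = "BH"`).  Adjusted
#' values are monotonically enforced, never below the raw p, and
#' rank-preserving.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Filter a DEG table to the significant genes
#'
#' Keeps genes whose adjusted p-value passes the FDR threshold
#' (`adjPVal <= alpha` by default; set `strict = TRUE` for a strict
#' `<` comparison).  Row order is preserved.
#'
#' @param records A DEG table ([read_deg_table()] format).
#' @param alpha FDR threshold (default 0.05).
#' @param strict Use `adjPVal < alpha` instead of `<=`.
#' @param readjust Recompute `adjPVal` from the raw `PVal` column with
#'   [bh_adjust()] before filtering (default `FALSE`: the table's own
#'   adjusted values are trusted).
#' @return The significant subset, same columns.
#' @export
filter_significant <- function(records, alpha = 0.05, strict = FALSE,
                               readjust = FALSE) {
  if (readjust) records$adjPVal <- bh_adjust(records$PVal)
  keep <- if (strict) records$adjPVal < alpha else records$adjPVal <= alpha
  records[keep, , drop = FALSE]
}

#' Split significant genes by direction of regulation
#'
#' Positive `logFC` means the gene is up-regulated by the treatment
#' (treated/sham log2 ratio).  A significant gene with `logFC == 0` is
#' unclassifiable and raises an error.
#'
#' @param significant A table of significant genes with a `logFC` column.
#' @return List with elements `up` and `down` (disjoint subsets whose
#'   union is the input).
#' @export
split_direction <- function(significant) {
  zero <- which(significant$logFC == 0)
  if (length(zero)) {
    stop("significant gene(s) with logFC = 0 cannot be assigned a ",
         "direction: ", paste(significant$gene[zero], collapse = ", "),
         call. = FALSE)
  }
  list(up = significant[significant$logFC > 0, , drop = FALSE],
       down = significant[significant$logFC < 0, , drop = FALSE])
}

#' Venn partition of two significance contrasts
#'
#' Partitions the significant genes of two contrasts (e.g. amyloid-
#' internalizing XO4+ vs non-internalizing XO4- microglia, each
#' treated-vs-sham) into shared and contrast-specific subsets, computed
#' separately for up- and down-regulated genes.  A gene significant in
#' both contrasts but with opposite signs is counted as specific within
#' each direction set (it still counts as shared at the symbol level).
#'
#' @param sig_a,sig_b Significant DEG tables for the two contrasts
#'   (unique gene symbols within each, `logFC` non-zero).
#' @param labels Character vector of length 2 naming the contrasts.
#' @param alpha The significance threshold the inputs were filtered at
#'   (recorded, not applied).
#' @return Object of class `contrast_partition`: list with per-direction
#'   membership (`up_shared`, `up_specific_a`, ..., `down_specific_b`),
#'   symbol-level sets (`shared`, `specific_a`, `specific_b`, `union`)
#'   and a `counts` tibble.  Identities
#'   `|specific_a| + |shared| = |sig_a|` and
#'   `|union| = |sig_a| + |sig_b| - |shared|` hold by construction.
#' @export
venn_partition <- function(sig_a, sig_b,
                           labels = c("XO4plus", "XO4neg"),
                           alpha = 0.05) {
  for (s in list(sig_a, sig_b)) {
    dup <- s$gene[duplicated(s$gene)]
    if (length(dup)) {
      stop("duplicated gene symbol(s) within a contrast: ",
           paste(unique(dup), collapse = ", "), call. = FALSE)
    }
  }
  dir_a <- split_direction(sig_a)
  dir_b <- split_direction(sig_b)
  up_a <- dir_a$up$gene; down_a <- dir_a$down$gene
  up_b <- dir_b$up$gene; down_b <- dir_b$down$gene
  res <- list(
    labels = labels, alpha = alpha,
    up_shared = intersect(up_a, up_b),
    up_specific_a = setdiff(up_a, up_b),
    up_specific_b = setdiff(up_b, up_a),
    down_shared = intersect(down_a, down_b),
    down_specific_a = setdiff(down_a, down_b),
    down_specific_b = setdiff(down_b, down_a),
    shared = intersect(sig_a$gene, sig_b$gene),
    specific_a = setdiff(sig_a$gene, sig_b$gene),
    specific_b = setdiff(sig_b$gene, sig_a$gene),
    union = union(sig_a$gene, sig_b$gene)
  )
  res$counts <- tibble::tibble(
    quantity = c(paste0("sig_", c("a", "b")),
                 "up_a", "down_a", "up_b", "down_b",
                 "shared", "shared_up", "shared_down",
                 "specific_a", "specific_b",
                 "union", "up_total", "down_total"),
    n = c(nrow(sig_a), nrow(sig_b),
          length(up_a), length(down_a), length(up_b), length(down_b),
          length(res$shared), length(res$up_shared), length(res$down_shared),
          length(res$specific_a), length(res$specific_b),
          length(res$union),
          length(union(up_a, up_b)), length(union(down_a, down_b)))
  )
  structure(res, class = "contrast_partition")
}

#' @export
print.contrast_partition <- function(x, ...) {
  cat("<contrast_partition>", x$labels[1], "vs", x$labels[2],
      "(alpha =", x$alpha, ")\n")
  print(x$counts, n = Inf)
  invisible(x)
}

#' Counts of a contrast partition as a named vector
#'
#' @param partition A [venn_partition()] result.
#' @return Named integer vector of the partition counts.
#' @export
partition_counts <- function(partition) {
  stats::setNames(as.integer(partition$counts$n), partition$counts$quantity)
}

#' Top-N genes by absolute log fold change
#'
#' Orders a table by descending `|logFC|`, breaking ties by ascending
#' `adjPVal` and then lexicographic gene symbol, and returns the first
#' `min(n, nrow)` rows — the construction behind "top 50 DEG" tables.
#'
#' @param records A DEG table.
#' @param n Number of genes to keep (default 50).
#' @return The ordered head of the table.
#' @export
rank_top_n <- function(records, n = 50L) {
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  ord <- order(-abs(records$logFC), records$adjPVal, records$gene)
  records[ord[seq_len(min(n, nrow(records)))], , drop = FALSE]
}
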