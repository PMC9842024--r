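# Hypergeometric over-representation of gene sets among significant
# genes, reporting the (set, N, DE, p.DE) columns of a standard
# enrichment table.

#' Gene-set over-representation analysis
#'
#' For each gene set, tests whether the significant ("DE") genes overlap
#' it more than expected when drawing `|de_genes|` genes uniformly
#' without replacement from the universe.  Reported per set:
#'
#' * `N` — set members present in the universe,
#' * `DE` — set members among the significant genes,
#' * `p.DE` — the hypergeometric upper tail `P(X >= DE)` with `N` white
#'   balls, `|universe| - N` black balls and `|de_genes|` draws.
#'
#' Sets with `N = 0` are omitted.  No multiple-testing correction is
#' applied: `p.DE` is the raw tail probability, as conventionally
#' printed in over-representation tables.  The recommended universe is
#' the full tested gene list (post expression-filtering), not the whole
#' genome.
#'
#' @param de_genes Character vector of significant gene symbols
#'   (must be a subset of `universe`).
#' @param universe Character vector of all tested gene symbols.
#' @param collection Gene-set collection as returned by [read_gmt()]
#'   (tibble with `set_id`, `description`, list-column `members`).
#' @return A tibble with columns `set_id`, `description`, `N`, `DE`,
#'   `p.DE`, sorted by ascending `p.DE` (ties by `set_id`).
#' @examples
#' sets <- tibble::tibble(set_id = "S1", description = "toy",
#'                        members = list(c("g1", "g2", "g3", "g8")))
#' # overlap 3 of a 4-gene set with 5 DE genes in a 10-gene universe:
#' enrich(paste0("g", 1:5), paste0("g", 1:10), sets)  # p.DE = 66/252
#' @export
enrich <- function(de_genes, universe, collection) {
  universe <- unique(trimws(universe))
  de_genes <- unique(trimws(de_genes))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  missing_de <- setdiff(de_genes, universe)
  if (length(missing_de)) {
    stop("DE gene(s) absent from the universe: ",
         paste(missing_de, collapse = ", "), call. = FALSE)
  }
  n_u <- length(universe)
  n_d <- length(de_genes)
  rows <- lapply(seq_len(nrow(collection)), function(i) {
    in_univ <- intersect(collection$members[[i]], universe)
    N <- length(in_univ)
    if (N == 0L) return(NULL)
    DE <- length(intersect(in_univ, de_genes))
    p <- stats::phyper(DE - 1L, N, n_u - N, n_d, lower.tail = FALSE)
    tibble::tibble(set_id = collection$set_id[i],
                   description = collection$description[i],
                   N = N, DE = DE, p.DE = p)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(set_id = character(), description = character(),
                          N = integer(), DE = integer(), p.DE = numeric()))
  }
  out[order(out$p.DE, out$set_id), , drop = FALSE]
}
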