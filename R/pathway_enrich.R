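# Hypergeometric enrichment of driver genes in flat gene-set collections
# (GO/KEGG-style), with BH FDR control across tested sets.

#' Hypergeometric driver-pathway enrichment
#'
#' Tests each gene set for over-representation of driver genes against a
#' background universe with the upper-tail hypergeometric test
#' `p = sum_{i >= k} C(K, i) C(N-K, n-i) / C(N, n)`, where `N` is the
#' background size, `K` the set size within the background, `n` the number
#' of driver genes in the background and `k` their overlap with the set.
#' p-values are BH-corrected across all tested sets.
#'
#' Sets are intersected with the background before testing; sets with
#' fewer than `min_size` or more than `max_size` members in the background
#' are excluded (conventional enrichment hygiene), as are sets with zero
#' background members. Symbols are harmonized case-insensitively.
#'
#' @param driver_genes Character vector of driver gene symbols (non-empty;
#'   must be contained in the background after harmonization).
#' @param collection A [gene_set_collection()].
#' @param background Character vector: the gene universe (e.g. all genes
#'   in the annotated MAF).
#' @param fdr_threshold Significance threshold on q, default 0.05.
#' @param min_size,max_size Set-size bounds after background intersection,
#'   defaults 3 and 5000.
#' @return Data frame sorted by (q, p): `set_id`, `set_name`, `k`, `K`,
#'   `n`, `N`, `p_value`, `q_value`, `significant`, `overlap`
#'   (semicolon-joined gene symbols).
#' @export
hypergeom_enrich <- function(driver_genes, collection, background,
                             fdr_threshold = 0.05, min_size = 3,
                             max_size = 5000) {
  stopifnot(inherits(collection, "gene_set_collection"))
  bg <- unique(sym_key(background))
  if (length(bg) == 0) stop("empty background universe")
  drv_in <- unique(sym_key(driver_genes))
  if (length(drv_in) == 0) stop("empty driver gene set")
  outside <- setdiff(drv_in, bg)
  if (length(outside) > 0) {
    stop(length(outside), " driver gene(s) are not in the background",
         " universe: ", paste(utils::head(outside, 5), collapse = ", "))
  }
  N <- length(bg)
  n <- length(drv_in)
  display <- stats::setNames(as.character(driver_genes),
                             sym_key(driver_genes))
  rows <- lapply(names(collection$sets), function(id) {
    members <- intersect(unique(sym_key(collection$sets[[id]])), bg)
    K <- length(members)
    if (K < min_size || K > max_size) return(NULL)
    overlap <- intersect(members, drv_in)
    k <- length(overlap)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, set_name = unname(collection$set_names[[id]]),
               k = k, K = K, n = n, N = N, p_value = p,
               overlap = paste(display[overlap], collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    res <- data.frame(set_id = character(), set_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      overlap = character(), stringsAsFactors = FALSE)
    return(res)
  }
  res <- do.call(rbind, rows)
  res$q_value <- bh_correct(res$p_value)
  res$significant <- res$q_value <= fdr_threshold
  res <- res[order(res$q_value, res$p_value, res$set_id), ]
  rownames(res) <- NULL
  res[, c("set_id", "set_name", "k", "K", "n", "N", "p_value", "q_value",
          "significant", "overlap")]
}
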