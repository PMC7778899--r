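# Pairwise mutual-exclusivity / co-occurrence among top driver genes via
# Fisher's exact test on per-sample mutation status.

#' Per-sample binary mutation status
#'
#' @param maf MAF data frame.
#' @param genes Gene symbols of interest.
#' @param include_silent Count silent mutations as "mutated"? Default
#'   FALSE (driver analyses focus on nonsilent changes).
#' @return Logical matrix samples x genes.
#' @export
mutation_status_matrix <- function(maf, genes, include_silent = FALSE) {
  samples <- unique(maf$Tumor_Sample_Barcode)
  keep <- if (include_silent) rep(TRUE, nrow(maf)) else
    maf$Variant_Classification != "Silent"
  keys <- sym_key(genes)
  status <- matrix(FALSE, length(samples), length(genes),
                   dimnames = list(samples, genes))
  mg <- sym_key(maf$Hugo_Symbol)
  for (j in seq_along(genes)) {
    hit <- keep & mg == keys[j]
    status[unique(maf$Tumor_Sample_Barcode[hit]), j] <- TRUE
  }
  status
}

#' Pairwise exclusivity / co-occurrence among top driver genes
#'
#' For every unordered pair among the first `top_k` genes of the ranked
#' driver list, builds the 2x2 table of per-sample mutation status and
#' applies the two-sided Fisher exact test (point-probability rule: the
#' p-value sums hypergeometric probabilities of tables no more likely
#' than the observed one). Direction is taken from the sample odds ratio
#' `(n11 n00) / (n10 n01)`: co-occurrence when it exceeds 1, mutual
#' exclusivity otherwise; a pair with an all-zero gene margin is reported
#' with p = 1 and direction "ns". Pairs are labeled at the raw-p
#' thresholds 0.05 and 0.01; a BH-corrected column is emitted as well.
#'
#' @param maf MAF data frame.
#' @param genes Ranked driver gene list (best first).
#' @param top_k How many of the top genes to analyze, default 50 (>= 2).
#' @param include_silent Passed to [mutation_status_matrix()].
#' @return Data frame, one row per unordered pair: `gene_a`, `gene_b`,
#'   `n11`, `n10`, `n01`, `n00`, `odds_ratio`, `p_value`, `q_value`,
#'   `direction`, `label`.
#' @export
pairwise_interactions <- function(maf, genes, top_k = 50,
                                  include_silent = FALSE) {
  stopifnot(top_k >= 2)
  genes <- utils::head(genes, top_k)
  if (length(genes) < 2) stop("need at least two genes for pair analysis")
  status <- mutation_status_matrix(maf, genes, include_silent)
  pairs <- utils::combn(seq_along(genes), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    a <- status[, i]; b <- status[, j]
    n11 <- sum(a & b); n10 <- sum(a & !b)
    n01 <- sum(!a & b); n00 <- sum(!a & !b)
    or <- (n11 * n00) / (n10 * n01)
    if (sum(a) == 0 || sum(b) == 0) {
      p <- 1
      direction <- "ns"
      or <- NA_real_
    } else {
      # fisher.test can overshoot 1 by a few ulps when summing tail terms
      p <- min(stats::fisher.test(matrix(c(n11, n01, n10, n00), 2))$p.value, 1)
      direction <- if (is.nan(or)) "ns" else
        if (or > 1) "co-occurrence" else "mutual exclusivity"
    }
    data.frame(gene_a = genes[i], gene_b = genes[j],
               n11 = n11, n10 = n10, n01 = n01, n00 = n00,
               odds_ratio = or, p_value = p, direction = direction,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- bh_correct(res$p_value)
  res$label <- ifelse(res$p_value < 0.01, "p<0.01",
                      ifelse(res$p_value < 0.05, "p<0.05", "ns"))
  rownames(res) <- NULL
  res[, c("gene_a", "gene_b", "n11", "n10", "n01", "n00", "odds_ratio",
          "p_value", "q_value", "direction", "label")]
}
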