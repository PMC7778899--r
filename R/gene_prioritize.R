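# Gene-level prioritization: Fisher-combined significance from two
# per-gene p-value streams, BH correction, the weighted Borda consensus
# score over driver catalogs, five-tier classification, and the final
# driver-gene call.

#' Combine two p-values with Fisher's method
#'
#' X = -2(ln p1 + ln p2) is referred to the upper tail of a chi-square
#' distribution with 4 degrees of freedom, which for two p-values has the
#' closed form `exp(-X/2) * (1 + X/2)`.
#'
#' @param p1,p2 Numeric vectors of p-values in `(0, 1]` (recycled).
#' @return Combined p-values in `(0, 1]`.
#' @export
fisher_combine <- function(p1, p2) {
  if (any(p1 <= 0 | p1 > 1, na.rm = TRUE) ||
      any(p2 <= 0 | p2 > 1, na.rm = TRUE)) {
    stop("fisher_combine: p-values must lie in (0, 1]; floor zeros first")
  }
  x <- -2 * (log(p1) + log(p2))
  stats::pchisq(x, df = 4, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up correction
#'
#' Returns q-values in input order: `q_(i) = min_{j>=i} p_(j) * m / j`,
#' capped at 1.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_correct <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Combine per-gene p-values from two significance methods
#'
#' Merges the (gene, p) tables of a MutSigCV-like and a MutPanning-like
#' method over the union of their genes (symbols matched
#' case-insensitively), floors p-values at `p_floor` before taking logs,
#' combines them with [fisher_combine()], and BH-corrects the combined
#' p-values. A gene covered by only one method keeps that method's p-value
#' as its combined p (the absent one is treated as 1) and is flagged.
#'
#' @param mutsig Data frame with columns `gene`, `p` (or a named numeric
#'   vector).
#' @param mutpanning Same shape as `mutsig`.
#' @param p_floor Lower floor applied before logs, default 1e-300.
#' @return Data frame: `gene`, `p_mutsig`, `p_mutpanning`, `p_combined`,
#'   `q_value`, `single_method`.
#' @export
combine_gene_pvalues <- function(mutsig, mutpanning, p_floor = 1e-300) {
  p1 <- as_gene_pvec(mutsig, "mutsig")
  p2 <- as_gene_pvec(mutpanning, "mutpanning")
  keys <- union(names(p1), names(p2))
  display <- c(attr(p1, "display"), attr(p2, "display"))
  display <- display[!duplicated(names(display))]
  v1 <- unname(p1[keys])
  v2 <- unname(p2[keys])
  single <- is.na(v1) | is.na(v2)
  f1 <- pmax(ifelse(is.na(v1), 1, v1), p_floor)
  f2 <- pmax(ifelse(is.na(v2), 1, v2), p_floor)
  p_comb <- fisher_combine(f1, f2)
  # a gene seen by one method keeps that p-value untouched
  p_comb[single] <- pmax(ifelse(is.na(v1[single]), v2[single], v1[single]),
                         p_floor)
  data.frame(gene = unname(display[keys]),
             p_mutsig = v1, p_mutpanning = v2,
             p_combined = p_comb,
             q_value = bh_correct(p_comb),
             single_method = single,
             stringsAsFactors = FALSE)
}

as_gene_pvec <- function(x, what) {
  if (is.data.frame(x)) {
    if (!all(c("gene", "p") %in% names(x))) {
      stop("'", what, "' table needs columns gene and p")
    }
    v <- stats::setNames(as.numeric(x$p), sym_key(x$gene))
    disp <- stats::setNames(as.character(x$gene), sym_key(x$gene))
  } else {
    v <- stats::setNames(as.numeric(x), sym_key(names(x)))
    disp <- stats::setNames(names(x), sym_key(names(x)))
  }
  if (anyDuplicated(names(v))) stop("'", what, "' has duplicate gene symbols")
  if (any(v <= 0 | v > 1, na.rm = TRUE)) {
    stop("'", what, "' p-values must lie in (0, 1]")
  }
  attr(v, "display") <- disp
  v
}

#' Select AI-DriverGenes at an FDR threshold
#'
#' Genes whose BH-corrected combined p-value is at or below
#' `fdr_threshold` (boundary inclusive). The resulting set is installed in
#' the driver catalog as the Group1 set named `AI-DriverGene` before
#' consensus scoring.
#'
#' @param stats Data frame from [combine_gene_pvalues()] (needs `gene`,
#'   `q_value`).
#' @param fdr_threshold Default 0.05.
#' @return Character vector of gene symbols.
#' @export
ai_driver_genes <- function(stats, fdr_threshold = 0.05) {
  stopifnot(is.data.frame(stats), all(c("gene", "q_value") %in% names(stats)))
  stats$gene[!is.na(stats$q_value) & stats$q_value <= fdr_threshold]
}

#' Weighted Borda consensus score over driver catalogs
#'
#' Each gene scores the sum of the weights of the driver sets that contain
#' it: 10 per Group1 set, 1 per Group2 set. Genes in no set score 0.
#' Membership is matched case-insensitively.
#'
#' @param genes Character vector of gene symbols.
#' @param catalog A [driver_catalog()].
#' @return Integer vector of consensus scores, named by `genes`.
#' @export
consensus_score <- function(genes, catalog) {
  stopifnot(inherits(catalog, "driver_catalog"))
  keys <- sym_key(genes)
  score <- integer(length(genes))
  for (nm in names(catalog$sets)) {
    score <- score + catalog$weight[[nm]] *
      (keys %in% sym_key(catalog$sets[[nm]]))
  }
  stats::setNames(as.integer(score), genes)
}

#' Five-tier pathogenicity level from a consensus score
#'
#' Level 0 (non-pathogenic, score = 0), Level 1 (possible pathogenic,
#' score = 1), Level 2 (likely pathogenic, 1 < score <= 10), Level 3
#' (probable pathogenic, 10 < score < 20), Level 4 (pathogenic,
#' score >= 20). Level-4 genes are the driver-gene candidates.
#'
#' @param score Non-negative numeric vector of consensus scores.
#' @return Integer vector of levels 0-4.
#' @export
tier_classify <- function(score) {
  if (any(score < 0, na.rm = TRUE)) stop("tier_classify: negative score")
  level <- integer(length(score))
  level[score == 0] <- 0L
  level[score == 1] <- 1L
  level[score > 1 & score <= 10] <- 2L
  level[score > 10 & score < 20] <- 3L
  level[score >= 20] <- 4L
  level
}

#' Tier-classify all genes of a cohort
#'
#' Convenience wrapper producing the per-gene tier table.
#'
#' @param genes Character vector of gene symbols.
#' @param catalog A [driver_catalog()].
#' @return Data frame: `gene`, `consensus_score`, `level`.
#' @export
tier_table <- function(genes, catalog) {
  score <- consensus_score(genes, catalog)
  data.frame(gene = genes, consensus_score = unname(score),
             level = tier_classify(unname(score)), stringsAsFactors = FALSE)
}

#' Final driver-gene call
#'
#' A gene is a final driver if it is pathogenic (Level 4, consensus score
#' >= 20) and harbors at least one driver or extreme mutation.
#'
#' @param tiers Data frame with `gene` and `level` (see [tier_table()]).
#' @param mutation_calls Data frame from [call_driver_mutations()] with
#'   `gene`, `is_driver`, `is_extreme`.
#' @return Character vector of driver gene symbols (display case from
#'   `tiers`).
#' @export
finalize_driver_genes <- function(tiers, mutation_calls) {
  stopifnot(all(c("gene", "level") %in% names(tiers)),
            all(c("gene", "is_driver", "is_extreme") %in% names(mutation_calls)))
  evid <- mutation_calls$is_driver | mutation_calls$is_extreme
  evid_genes <- sym_key(unique(mutation_calls$gene[evid]))
  keep <- tiers$level == 4 & sym_key(tiers$gene) %in% evid_genes
  tiers$gene[keep]
}

#' Per-gene binomial recurrence p-values (stand-in significance method)
#'
#' A deliberately simple frequency test so synthetic pipelines can run end
#' to end without an external significance tool: per gene, the observed
#' nonsilent mutation count is referred to the upper tail of a
#' Binomial(length x n_samples, rate) null, where rate is the cohort-wide
#' per-bp nonsilent mutation rate. This ignores every covariate a real
#' background-mutation-rate model conditions on (expression, replication
#' timing, nucleotide context) and is NOT a replacement for one; it is a
#' plumbing stand-in with roughly calibrated nulls.
#'
#' With `midp = TRUE` the mid-p correction (half the point probability is
#' subtracted) is applied, which gives markedly better null uniformity for
#' the discrete binomial tail; the classic tail (`midp = FALSE`, default)
#' returns exactly 1 for genes with zero mutations.
#'
#' @param maf MAF data frame.
#' @param gene_lengths Named numeric vector: gene symbol -> coding length
#'   in bp (positive).
#' @param midp Apply the mid-p correction? Default FALSE.
#' @return Data frame `gene`, `n_nonsilent`, `p`, restricted to genes with
#'   known lengths (genes missing from the length table are skipped with a
#'   warning).
#' @export
frequency_pvalue_standin <- function(maf, gene_lengths, midp = FALSE) {
  stopifnot(is.data.frame(maf), !is.null(names(gene_lengths)))
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  len <- stats::setNames(as.numeric(gene_lengths), sym_key(names(gene_lengths)))
  nonsilent <- !(maf$Variant_Classification %in%
                   c("Silent", "3'UTR", "5'UTR", "3'Flank", "5'Flank",
                     "Intron", "RNA", "IGR", "Targeted_Region"))
  mut_genes <- sym_key(maf$Hugo_Symbol)
  unknown <- setdiff(unique(mut_genes[nonsilent]), names(len))
  if (length(unknown) > 0) {
    warning(length(unknown), " mutated gene(s) absent from the length table",
            " were skipped")
  }
  n_samples <- length(unique(maf$Tumor_Sample_Barcode))
  counts <- table(factor(mut_genes[nonsilent], levels = names(len)))
  k <- as.integer(counts)
  size <- round(len * n_samples)
  rate <- sum(k) / sum(size)
  p <- stats::pbinom(k - 1, size = size, prob = rate, lower.tail = FALSE)
  if (midp) {
    p <- p - 0.5 * stats::dbinom(k, size = size, prob = rate)
  }
  data.frame(gene = names(gene_lengths), n_nonsilent = k,
             p = pmin(pmax(unname(p), .Machine$double.xmin), 1),
             stringsAsFactors = FALSE)
}

#' Annotate driver genes with drug-gene interactions
#'
#' Left-joins the gene list onto a drug-gene interaction table; a gene is
#' actionable if it has any entry. When a MAF is supplied, samples
#' carrying nonsilent mutations in at least `min_targetable` actionable
#' genes are flagged as combination-therapy candidates.
#'
#' @param genes Character vector of (driver) gene symbols.
#' @param drug_table Data frame from [read_drug_table()].
#' @param maf Optional MAF data frame for per-sample combination flags.
#' @param min_targetable Actionable-gene count that flags a sample,
#'   default 2.
#' @return List with `annotations` (gene, actionable, drugs) and, when a
#'   MAF is given, `samples` (sample_id, n_targetable,
#'   combination_candidate).
#' @export
annotate_druggability <- function(genes, drug_table, maf = NULL,
                                  min_targetable = 2) {
  stopifnot(is.data.frame(drug_table),
            all(c("gene", "drug") %in% names(drug_table)))
  tab_key <- sym_key(drug_table$gene)
  ann <- data.frame(gene = genes, stringsAsFactors = FALSE)
  ann$drugs <- vapply(sym_key(genes), function(k) {
    paste(unique(drug_table$drug[tab_key == k]), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  ann$actionable <- ann$drugs != ""
  out <- list(annotations = ann)
  if (!is.null(maf)) {
    actionable <- sym_key(genes)[ann$actionable]
    nonsilent <- maf$Variant_Classification != "Silent"
    hit <- nonsilent & sym_key(maf$Hugo_Symbol) %in% actionable
    samples <- unique(maf$Tumor_Sample_Barcode)
    n_targ <- vapply(samples, function(s) {
      length(unique(sym_key(maf$Hugo_Symbol)[hit & maf$Tumor_Sample_Barcode == s]))
    }, integer(1), USE.NAMES = FALSE)
    out$samples <- data.frame(sample_id = samples, n_targetable = n_targ,
                              combination_candidate = n_targ >= min_targetable,
                              stringsAsFactors = FALSE)
  }
  out
}
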