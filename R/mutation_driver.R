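# Mutation-level classification: extreme (loss-of-function / damaging
# missense) and driver (recurrent high-score missense) calls, ReVe
# percentile transform, Ti/Tv classification, hypermutator filtering.

#' Classify mutations as extreme
#'
#' Extreme mutations are loss-of-function changes (stop-gain, stop-loss,
#' splice site, frameshift indels) or missense mutations whose ReVe
#' pathogenicity score is at least `reve_threshold` (boundary inclusive).
#' Missense records with no ReVe score are not extreme. The raw ReVe score
#' is used, not its percentile.
#'
#' @param classification Character vector of MAF `Variant_Classification`
#'   terms, or a MAF data frame (in which case `reve_score` is taken from
#'   its `reve_score` column).
#' @param reve_score Numeric vector of ReVe scores in `[0, 1]` (NA allowed).
#' @param reve_threshold Missense damage threshold, default 0.5.
#' @return Logical vector.
#' @export
classify_extreme <- function(classification, reve_score = NULL,
                             reve_threshold = 0.5) {
  if (is.data.frame(classification)) {
    maf <- classification
    classification <- maf$Variant_Classification
    if (is.null(reve_score)) reve_score <- maf$reve_score
  }
  if (is.null(reve_score)) reve_score <- rep(NA_real_, length(classification))
  stopifnot(length(reve_score) == length(classification))
  lof <- classification %in% LOF_CLASSES
  missense_damaging <- classification == "Missense_Mutation" &
    !is.na(reve_score) & reve_score >= reve_threshold
  lof | missense_damaging
}

#' Transform scores to rank percentiles
#'
#' Percentile of each score is its average rank divided by the number of
#' scores, so ties share a percentile, the maximum maps to 1.0, and the
#' transform is order-preserving. Used to present ReVe pathogenicity scores
#' as relative ranks (0 most benign, 1 most deleterious).
#'
#' @param scores Numeric vector of finite scores (length >= 1).
#' @return Numeric vector of percentiles in `(0, 1]`.
#' @export
reve_percentile <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) == 0) stop("reve_percentile needs at least one score")
  if (any(!is.finite(scores))) stop("reve_percentile: scores must be finite")
  rank(scores, ties.method = "average") / length(scores)
}

#' Call driver mutations from a cohort
#'
#' Groups the cohort by exact genomic change (chromosome, position,
#' reference allele, alternate allele) and flags as driver mutations the
#' missense changes whose maximum AI-Driver score reaches
#' `score_threshold` and that occur in at least `min_recurrence` distinct
#' patients (tumor sample barcodes). Each distinct change is also flagged
#' extreme if any of its records is extreme, and annotated with the ReVe
#' percentile of its maximum ReVe score within the cohort of scored
#' missense changes.
#'
#' @param maf MAF data frame from [read_maf()].
#' @param score_threshold Minimum AI-Driver score, default 0.95.
#' @param min_recurrence Minimum number of distinct patients, default 2.
#' @param reve_threshold Passed to [classify_extreme()].
#' @return Data frame with one row per distinct mutation: `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `variant_classification`, `n_patients`,
#'   `max_ai_driver`, `max_reve`, `reve_percentile`, `is_driver`,
#'   `is_extreme`.
#' @export
call_driver_mutations <- function(maf, score_threshold = 0.95,
                                  min_recurrence = 2, reve_threshold = 0.5) {
  stopifnot(is.data.frame(maf), nrow(maf) > 0)
  key <- paste(maf$Chromosome, maf$Start_Position, maf$Reference_Allele,
               maf$Tumor_Seq_Allele2, sep = "\r")
  extreme_rec <- classify_extreme(maf$Variant_Classification, maf$reve_score,
                                  reve_threshold)
  first <- !duplicated(key)
  calls <- data.frame(
    chrom = maf$Chromosome[first],
    pos = maf$Start_Position[first],
    ref = maf$Reference_Allele[first],
    alt = maf$Tumor_Seq_Allele2[first],
    gene = maf$Hugo_Symbol[first],
    variant_classification = maf$Variant_Classification[first],
    stringsAsFactors = FALSE
  )
  ukey <- key[first]
  idx <- split(seq_len(nrow(maf)), factor(key, levels = ukey))
  calls$n_patients <- vapply(idx, function(i) {
    length(unique(maf$Tumor_Sample_Barcode[i]))
  }, integer(1))
  max_or_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  calls$max_ai_driver <- vapply(idx, function(i) max_or_na(maf$ai_driver_score[i]),
                                numeric(1))
  calls$max_reve <- vapply(idx, function(i) max_or_na(maf$reve_score[i]),
                           numeric(1))
  calls$is_extreme <- vapply(idx, function(i) any(extreme_rec[i]), logical(1))
  calls$is_driver <- calls$variant_classification == "Missense_Mutation" &
    !is.na(calls$max_ai_driver) & calls$max_ai_driver >= score_threshold &
    calls$n_patients >= min_recurrence
  calls$reve_percentile <- NA_real_
  scored <- which(!is.na(calls$max_reve))
  if (length(scored) > 0) {
    calls$reve_percentile[scored] <- reve_percentile(calls$max_reve[scored])
  }
  rownames(calls) <- NULL
  calls
}

#' Classify SNPs into the six pyrimidine-collapsed conversion classes
#'
#' Purine-reference changes are complemented onto the pyrimidine strand
#' (G>A becomes C>T), yielding the six classes C>A, C>G, C>T, T>A, T>C,
#' T>G. C>T and T>C are transitions; the rest are transversions.
#'
#' @param ref Reference allele (single base) or a MAF data frame of SNPs.
#' @param alt Alternate allele (single base).
#' @return Data frame with columns `conversion` and `titv`
#'   ("transition"/"transversion").
#' @export
classify_titv <- function(ref, alt = NULL) {
  if (is.data.frame(ref)) {
    maf <- ref
    if (!is.null(maf$Variant_Type) && any(maf$Variant_Type != "SNP")) {
      stop("classify_titv: all records must be SNPs")
    }
    alt <- maf$Tumor_Seq_Allele2
    ref <- maf$Reference_Allele
  }
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  stopifnot(length(ref) == length(alt))
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  if (!all(ok)) stop("classify_titv: non-SNP allele pair at position ",
                     which(!ok)[1])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  conversion <- paste0(ref, ">", alt)
  data.frame(conversion = conversion,
             titv = ifelse(conversion %in% c("C>T", "T>C"),
                           "transition", "transversion"),
             stringsAsFactors = FALSE)
}

#' Remove hypermutated samples from a cohort
#'
#' Drops every sample whose total mutation count strictly exceeds
#' `max_mutations_per_sample`; frequency-based driver tests are sensitive
#' to the high background rates of hypermutators.
#'
#' @param maf MAF data frame.
#' @param max_mutations_per_sample Cap on mutations per sample (>= 1),
#'   default 1000.
#' @return List with `retained` (MAF subset) and `removed_samples`
#'   (character vector of barcodes).
#' @export
filter_hypermutated <- function(maf, max_mutations_per_sample = 1000) {
  stopifnot(is.data.frame(maf), max_mutations_per_sample >= 1)
  counts <- table(maf$Tumor_Sample_Barcode)
  removed <- names(counts)[counts > max_mutations_per_sample]
  list(retained = maf[!maf$Tumor_Sample_Barcode %in% removed, , drop = FALSE],
       removed_samples = removed)
}
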