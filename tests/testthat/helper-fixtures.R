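# In-code fixtures and independent oracles shared across test files.

# Build a MAF-shaped data frame from per-row arguments; fills the
# normalized score columns the way read_maf would.
toy_maf <- function(gene, sample, chrom = "chr1", pos = 100,
                    ref = "C", alt = "T",
                    classification = "Missense_Mutation",
                    type = "SNP", ai = NA_real_, reve = NA_real_) {
  n <- max(lengths(list(gene, sample, pos, classification)))
  df <- data.frame(
    Hugo_Symbol = rep_len(gene, n),
    Chromosome = rep_len(chrom, n),
    Start_Position = rep_len(pos, n),
    End_Position = rep_len(pos, n),
    Reference_Allele = rep_len(ref, n),
    Tumor_Seq_Allele2 = rep_len(alt, n),
    Variant_Classification = rep_len(classification, n),
    Variant_Type = rep_len(type, n),
    Tumor_Sample_Barcode = rep_len(sample, n),
    AI_Driver_score = rep_len(ai, n),
    ReVe_score = rep_len(reve, n),
    stringsAsFactors = FALSE
  )
  df$ai_driver_score <- df$AI_Driver_score
  df$reve_score <- df$ReVe_score
  df
}

write_toy_maf <- function(maf, path, comments = character()) {
  con <- file(path, "w")
  if (length(comments) > 0) writeLines(comments, con)
  close(con)
  out <- maf[, setdiff(names(maf), c("ai_driver_score", "reve_score"))]
  suppressWarnings(utils::write.table(out, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  path
}

# Literal step-up BH, independent of stats::p.adjust.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  if (n > 1) for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  res <- numeric(n)
  res[o] <- pmin(q, 1)
  res
}

# Upper-tail hypergeometric p by exhaustive enumeration over overlap
# outcomes, using only choose().
hyper_oracle <- function(k, K, n, N) {
  i <- max(0, n - (N - K)):min(K, n)
  probs <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  sum(probs[i >= k])
}

# Two-sided Fisher exact p (point-probability rule) by enumeration over
# all tables with the observed margins.
fisher2x2_oracle <- function(n11, n10, n01, n00) {
  r <- n11 + n10
  c <- n11 + n01
  N <- n11 + n10 + n01 + n00
  a <- max(0, r + c - N):min(r, c)
  probs <- choose(c, a) * choose(N - c, r - a) / choose(N, r)
  p_obs <- probs[a == n11]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One deterministic small cohort reused by several files.
standard_sim <- function(seed = 101) {
  simulate_cohort(sim_config(seed = seed))
}
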