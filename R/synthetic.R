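# Synthetic cohorts with planted driver signal: background passenger
# mutations drawn per gene at a rate proportional to coding length, plus
# recurrent identical high-score missense changes concentrated in
# designated driver genes. Every artifact round-trips through the package
# readers, so the full pipeline is testable without external downloads.

#' Simulation configuration
#'
#' Defaults describe a mid-sized tumor cohort: 200 samples over a
#' 500-gene panel, a background rate of 2 mutations per megabase per
#' sample (TCGA-like for non-hypermutated tumors), 30% of background
#' mutations silent, and 20 planted driver genes each carrying one
#' recurrent missense hotspot shared by 6 patients plus occasional extra
#' high-score missense changes. Passenger missense AI-Driver scores are
#' drawn from Beta(1.2, 8) (concentrated near 0); driver-mutation scores
#' from Beta(30, 1) (concentrated near 1, mostly above the 0.95 call
#' threshold). ReVe scores follow Beta(1.5, 3.5) for passengers and
#' Beta(8, 2) for driver-gene hotspots.
#'
#' @param n_samples Number of tumor samples.
#' @param n_genes Number of genes in the panel.
#' @param gene_length_range Coding length range in bp (uniform draw).
#' @param background_rate Background mutation rate per bp per sample
#'   (silent + nonsilent).
#' @param fraction_silent Bernoulli probability that a background mutation
#'   is silent.
#' @param n_drivers Number of planted driver genes.
#' @param recurrence_target Patients sharing each planted hotspot
#'   (must not exceed `n_samples`).
#' @param driver_mut_rate Per-sample rate of extra (non-hotspot) driver
#'   missense mutations per planted gene.
#' @param ai_driver_shape,ai_passenger_shape Beta shape pairs `c(a, b)`
#'   for AI-Driver scores of driver and passenger missense mutations.
#' @param reve_driver_shape,reve_passenger_shape Beta shape pairs for
#'   ReVe scores.
#' @param seed Integer RNG seed; identical seed + config gives identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 200,
                       n_genes = 500,
                       gene_length_range = c(500, 5000),
                       background_rate = 2e-6,
                       fraction_silent = 0.3,
                       n_drivers = 20,
                       recurrence_target = 6,
                       driver_mut_rate = 0.01,
                       ai_driver_shape = c(30, 1),
                       ai_passenger_shape = c(1.2, 8),
                       reve_driver_shape = c(8, 2),
                       reve_passenger_shape = c(1.5, 3.5),
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes),
              gene_length_range = gene_length_range,
              background_rate = background_rate,
              fraction_silent = fraction_silent,
              n_drivers = as.integer(n_drivers),
              recurrence_target = as.integer(recurrence_target),
              driver_mut_rate = driver_mut_rate,
              ai_driver_shape = ai_driver_shape,
              ai_passenger_shape = ai_passenger_shape,
              reve_driver_shape = reve_driver_shape,
              reve_passenger_shape = reve_passenger_shape,
              seed = as.integer(seed))
  stopifnot(cfg$n_samples >= 1, cfg$n_genes >= 1,
            cfg$background_rate >= 0, cfg$driver_mut_rate >= 0,
            cfg$fraction_silent >= 0, cfg$fraction_silent <= 1,
            cfg$n_drivers >= 0, cfg$n_drivers <= cfg$n_genes,
            length(cfg$gene_length_range) == 2,
            cfg$gene_length_range[1] >= 1,
            diff(cfg$gene_length_range) >= 0)
  if (cfg$recurrence_target > cfg$n_samples) {
    stop("recurrence_target (", cfg$recurrence_target,
         ") exceeds n_samples (", cfg$n_samples, ")")
  }
  class(cfg) <- c("sim_config", "list")
  cfg
}

BG_NONSILENT_CLASSES <- c("Missense_Mutation", "Nonsense_Mutation",
                          "Splice_Site", "Frame_Shift_Del",
                          "Frame_Shift_Ins", "Nonstop_Mutation")
BG_NONSILENT_PROBS <- c(0.80, 0.08, 0.04, 0.04, 0.03, 0.01)

#' Simulate a somatic mutation cohort with planted drivers
#'
#' Passenger mutations are drawn per gene as Poisson with mean
#' `background_rate * length * n_samples` and assigned to uniformly
#' random samples and positions; planted driver genes additionally get a
#' recurrent missense hotspot (identical chrom/pos/ref/alt) shared by
#' `recurrence_target` random samples plus extra high-score missense
#' changes. All genes occupy disjoint coordinate blocks on the single
#' synthetic contig `chrS`; no reference genome is used.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `cohort.maf`
#'   (with a `#version` comment line), `truth_genes.tsv`,
#'   `truth_mutations.tsv` and `gene_lengths.tsv`.
#' @return List with `maf` (MAF-shaped data frame including normalized
#'   `ai_driver_score`/`reve_score` columns), `truth_genes`,
#'   `truth_mutations`, `gene_lengths` (named vector), `config`, and any
#'   written `paths`.
#' @export
simulate_cohort <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  lens <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                 config$n_genes, replace = TRUE)
  block_start <- cumsum(c(1, utils::head(lens, -1) + 100))
  samples <- sprintf("SAMPLE%04d", seq_len(config$n_samples))
  driver_idx <- if (config$n_drivers > 0) {
    sort(sample(config$n_genes, config$n_drivers))
  } else integer(0)

  rbeta2 <- function(n, shape) stats::rbeta(n, shape[1], shape[2])
  draw_alleles <- function(n) {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                  USE.NAMES = FALSE)
    list(ref = ref, alt = alt)
  }

  # background passengers
  n_bg <- stats::rpois(config$n_genes,
                       config$background_rate * lens * config$n_samples)
  gidx <- rep(seq_len(config$n_genes), n_bg)
  m <- length(gidx)
  silent <- stats::runif(m) < config$fraction_silent
  vc <- character(m)
  vc[silent] <- "Silent"
  vc[!silent] <- sample(BG_NONSILENT_CLASSES, sum(!silent), replace = TRUE,
                        prob = BG_NONSILENT_PROBS)
  pos <- block_start[gidx] + floor(stats::runif(m) * lens[gidx])
  al <- draw_alleles(m)
  vt <- rep("SNP", m)
  fs_del <- vc == "Frame_Shift_Del"
  fs_ins <- vc == "Frame_Shift_Ins"
  vt[fs_del] <- "DEL"; vt[fs_ins] <- "INS"
  al$alt[fs_del] <- "-"
  al$ref[fs_ins] <- "-"
  ai <- rep(NA_real_, m)
  reve <- rep(NA_real_, m)
  mis <- vc == "Missense_Mutation"
  ai[mis] <- rbeta2(sum(mis), config$ai_passenger_shape)
  reve[mis] <- rbeta2(sum(mis), config$reve_passenger_shape)
  bg <- data.frame(
    Hugo_Symbol = genes[gidx], Chromosome = "chrS", Start_Position = pos,
    End_Position = pos, Reference_Allele = al$ref,
    Tumor_Seq_Allele2 = al$alt, Variant_Classification = vc,
    Variant_Type = vt,
    Tumor_Sample_Barcode = samples[sample.int(config$n_samples, m,
                                              replace = TRUE)],
    AI_Driver_score = ai, ReVe_score = reve, stringsAsFactors = FALSE)

  # planted recurrent hotspots + extra driver missense
  planted <- NULL
  truth_mut <- NULL
  if (length(driver_idx) > 0) {
    hot <- lapply(driver_idx, function(g) {
      p <- block_start[g] + floor(stats::runif(1) * lens[g])
      a <- draw_alleles(1)
      carriers <- sample(samples, config$recurrence_target)
      k <- length(carriers)
      extra <- stats::rpois(1, config$driver_mut_rate * config$n_samples)
      epos <- block_start[g] + floor(stats::runif(extra) * lens[g])
      eal <- draw_alleles(extra)
      rows <- data.frame(
        Hugo_Symbol = genes[g], Chromosome = "chrS",
        Start_Position = c(rep(p, k), epos),
        End_Position = c(rep(p, k), epos),
        Reference_Allele = c(rep(a$ref, k), eal$ref),
        Tumor_Seq_Allele2 = c(rep(a$alt, k), eal$alt),
        Variant_Classification = "Missense_Mutation", Variant_Type = "SNP",
        Tumor_Sample_Barcode = c(carriers,
                                 samples[sample.int(config$n_samples, extra,
                                                    replace = TRUE)]),
        AI_Driver_score = rbeta2(k + extra, config$ai_driver_shape),
        ReVe_score = rbeta2(k + extra, config$reve_driver_shape),
        stringsAsFactors = FALSE)
      list(rows = rows,
           truth = data.frame(gene = genes[g], chrom = "chrS", pos = p,
                              ref = a$ref, alt = a$alt,
                              n_carriers = k, stringsAsFactors = FALSE))
    })
    planted <- do.call(rbind, lapply(hot, `[[`, "rows"))
    truth_mut <- do.call(rbind, lapply(hot, `[[`, "truth"))
  }

  maf <- rbind(bg, planted)
  maf <- maf[order(maf$Start_Position, maf$Tumor_Sample_Barcode), ]
  rownames(maf) <- NULL
  maf$ai_driver_score <- maf$AI_Driver_score
  maf$reve_score <- maf$ReVe_score
  truth_genes <- data.frame(gene = genes[driver_idx], stringsAsFactors = FALSE)
  if (is.null(truth_mut)) {
    truth_mut <- data.frame(gene = character(), chrom = character(),
                            pos = numeric(), ref = character(),
                            alt = character(), n_carriers = integer(),
                            stringsAsFactors = FALSE)
  }
  out <- list(maf = maf, truth_genes = truth_genes,
              truth_mutations = truth_mut,
              gene_lengths = stats::setNames(as.numeric(lens), genes),
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    maf_path <- file.path(out_dir, "cohort.maf")
    con <- file(maf_path, "w")
    writeLines("#version synthetic-cohort 1.0", con)
    close(con)
    file_maf <- maf[, setdiff(names(maf), c("ai_driver_score", "reve_score"))]
    suppressWarnings(utils::write.table(file_maf, maf_path, sep = "\t",
                                        quote = FALSE, row.names = FALSE,
                                        append = TRUE))
    write_results(truth_genes, file.path(out_dir, "truth_genes.tsv"))
    write_results(truth_mut, file.path(out_dir, "truth_mutations.tsv"))
    write_results(data.frame(gene = genes, length = as.numeric(lens)),
                  file.path(out_dir, "gene_lengths.tsv"))
    out$paths <- c(maf = maf_path,
                   truth_genes = file.path(out_dir, "truth_genes.tsv"),
                   truth_mutations = file.path(out_dir, "truth_mutations.tsv"),
                   gene_lengths = file.path(out_dir, "gene_lengths.tsv"))
  }
  out
}

GROUP2_SET_NAMES <- c("IntOGen", "CTAT", "C3", "ConsensusDriver", "DriverDB",
                      "SBCDDB", "CancerMine", "NCG", "TSGene", "ONGene",
                      "CGI", "CompositeDriver", "Extra13", "Extra14",
                      "Extra15", "Extra16")

#' Simulate a driver-set catalog with partial coverage of planted drivers
#'
#' Builds `n_sets` synthetic catalogs: each contains every planted driver
#' independently with probability `coverage` plus random decoy genes.
#' The first `group1_count` sets take the gold-standard names (CGC,
#' OncoKB, AI-DriverGene, MutPanning) and Group1 weight; gold-standard
#' sets receive fewer decoys than supplementary ones, mirroring their
#' higher curation stringency.
#'
#' @param universe Character vector of all gene symbols.
#' @param planted Character vector of planted driver genes.
#' @param n_sets Total sets, default 16.
#' @param group1_count Gold-standard sets, default 4.
#' @param coverage Probability a planted driver appears in each set.
#' @param n_decoys_group1,n_decoys_group2 Decoy genes per set.
#' @param seed Optional RNG seed.
#' @param out_dir Optional directory; writes one gene-list file per set.
#' @return List with `catalog` (a [driver_catalog()]), `group1_names`,
#'   and `paths` when files were written.
#' @export
simulate_driver_catalog <- function(universe, planted, n_sets = 16,
                                    group1_count = 4, coverage = 0.9,
                                    n_decoys_group1 = 5,
                                    n_decoys_group2 = 20,
                                    seed = NULL, out_dir = NULL) {
  stopifnot(coverage >= 0, coverage <= 1, group1_count <= n_sets,
            all(planted %in% universe))
  if (!is.null(seed)) set.seed(seed)
  g1_names <- c("CGC", "OncoKB", "AI-DriverGene", "MutPanning")
  set_names <- c(utils::head(g1_names, group1_count),
                 utils::head(GROUP2_SET_NAMES, n_sets - group1_count))
  decoy_pool <- setdiff(universe, planted)
  sets <- lapply(seq_along(set_names), function(i) {
    keep <- planted[stats::runif(length(planted)) < coverage]
    n_dec <- if (i <= group1_count) n_decoys_group1 else n_decoys_group2
    decoys <- sample(decoy_pool, min(n_dec, length(decoy_pool)))
    unique(c(keep, decoys))
  })
  names(sets) <- set_names
  catalog <- driver_catalog(sets,
                            group1_names = utils::head(set_names, group1_count))
  out <- list(catalog = catalog,
              group1_names = utils::head(set_names, group1_count))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(set_names, function(nm) {
      p <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9_-]", "_", nm), ".txt"))
      writeLines(sets[[nm]], p)
      p
    }, character(1))
    out$paths <- paths
  }
  out
}

#' Simulate a GMT gene-set collection with one enriched pathway
#'
#' Generates random gene sets plus one designated "true pathway" that
#' heavily overlaps the planted driver genes, so enrichment recovery can
#' be tested against a known answer.
#'
#' @param universe Character vector of all gene symbols.
#' @param planted Planted driver genes (the true pathway contains each
#'   with probability `driver_coverage`).
#' @param n_sets Number of random background sets, default 49 (plus the
#'   true pathway).
#' @param size_range Random set sizes, default c(10, 60).
#' @param driver_coverage Fraction of planted drivers in the true
#'   pathway, default 1.0.
#' @param seed Optional RNG seed.
#' @param path Optional GMT output path.
#' @return List with `collection` (a [gene_set_collection()]),
#'   `true_set_id` (`"TRUE_PATHWAY"`, NULL when no drivers were planted),
#'   and `path` when written.
#' @export
simulate_gene_sets <- function(universe, planted, n_sets = 49,
                               size_range = c(10, 60),
                               driver_coverage = 1.0, seed = NULL,
                               path = NULL) {
  stopifnot(size_range[1] >= 1, size_range[2] <= length(universe))
  if (!is.null(seed)) set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) {
    size <- sample(seq(size_range[1], size_range[2]), 1)
    sample(universe, size)
  })
  names(sets) <- sprintf("RANDOM%03d", seq_len(n_sets))
  true_id <- NULL
  if (length(planted) > 0) {
    members <- planted[stats::runif(length(planted)) < driver_coverage]
    filler <- sample(setdiff(universe, planted),
                     max(0, size_range[1] - length(members)))
    sets <- c(stats::setNames(list(unique(c(members, filler))),
                              "TRUE_PATHWAY"), sets)
    true_id <- "TRUE_PATHWAY"
  }
  descs <- stats::setNames(
    ifelse(names(sets) == "TRUE_PATHWAY", "planted driver pathway",
           "random background set"), names(sets))
  collection <- gene_set_collection(sets, descs, source_tag = "synthetic")
  out <- list(collection = collection, true_set_id = true_id)
  if (!is.null(path)) {
    write_gmt(collection, path)
    out$path <- path
  }
  out
}

#' Simulate a drug-gene interaction table
#'
#' Assigns fictive inhibitors to a fraction of the given genes; used to
#' exercise the druggability join.
#'
#' @param genes Gene symbols eligible for drug annotation.
#' @param fraction_targetable Fraction of genes receiving at least one
#'   drug, default 0.5.
#' @param seed Optional RNG seed.
#' @param path Optional TSV output path.
#' @return Data frame with columns gene, drug, interaction_type, source.
#' @export
simulate_drug_table <- function(genes, fraction_targetable = 0.5,
                                seed = NULL, path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  target <- genes[stats::runif(length(genes)) < fraction_targetable]
  tab <- data.frame(gene = target,
                    drug = paste0(tolower(target), "inib"),
                    interaction_type = "inhibitor",
                    source = "synthetic", stringsAsFactors = FALSE)
  if (!is.null(path)) write_results(tab, path)
  tab
}
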