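# End-to-end orchestration: hypermutator filter -> mutation calls ->
# combined gene significance -> AI-DriverGene injection -> consensus
# tiers -> final drivers -> driverness scores -> pathway enrichment ->
# pairwise interactions -> drug annotation.

#' Pipeline configuration
#'
#' Inputs may be file paths (read with the package readers) or in-memory
#' objects of the matching shape. `mutsig` / `mutpanning` are (gene, p)
#' tables; when both are NULL and `gene_lengths` is supplied, the
#' binomial stand-in ([frequency_pvalue_standin()]) provides the single
#' significance stream. `gmt` and `drug_table` are optional; their stages
#' are skipped (with a manifest note) when absent.
#'
#' @param maf MAF path or data frame.
#' @param mutsig,mutpanning Per-gene p-value tables (path or data frame
#'   with columns gene, p), or NULL.
#' @param gene_lengths Named vector or (gene, length) table/path; enables
#'   the stand-in significance stream and defines gene coding lengths.
#' @param driver_sets A [driver_catalog()], or a named vector of gene-list
#'   file paths.
#' @param group1_names Group1 set names when `driver_sets` is paths.
#' @param gmt Gene-set collection, GMT path, or NULL.
#' @param drug_table Drug-gene table, path, or NULL.
#' @param background Gene universe for enrichment; NULL uses all genes in
#'   the filtered MAF.
#' @param cohort Cohort label recorded in the manifest.
#' @param score_threshold AI-Driver driver-mutation threshold (0.95).
#' @param min_recurrence Minimum patients per driver mutation (2).
#' @param reve_threshold Extreme-mutation ReVe threshold (0.5).
#' @param fdr_threshold FDR cut for AI-DriverGenes and enrichment (0.05).
#' @param top_k Genes entering the pairwise interaction analysis (50).
#' @param max_per_sample Hypermutator cap (1000 mutations/sample).
#' @param standin_midp Use the mid-p stand-in correction? Default FALSE.
#' @param out_dir Optional output directory for TSVs and the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(maf, mutsig = NULL, mutpanning = NULL,
                            gene_lengths = NULL, driver_sets,
                            group1_names = c("CGC", "OncoKB",
                                             "AI-DriverGene", "MutPanning"),
                            gmt = NULL, drug_table = NULL, background = NULL,
                            cohort = "cohort",
                            score_threshold = 0.95, min_recurrence = 2,
                            reve_threshold = 0.5, fdr_threshold = 0.05,
                            top_k = 50, max_per_sample = 1000,
                            standin_midp = FALSE, out_dir = NULL) {
  stopifnot(score_threshold >= 0, score_threshold <= 1,
            min_recurrence >= 1, reve_threshold >= 0, reve_threshold <= 1,
            fdr_threshold > 0, fdr_threshold <= 1, top_k >= 2,
            max_per_sample >= 1)
  structure(list(maf = maf, mutsig = mutsig, mutpanning = mutpanning,
                 gene_lengths = gene_lengths, driver_sets = driver_sets,
                 group1_names = group1_names, gmt = gmt,
                 drug_table = drug_table, background = background,
                 cohort = cohort, score_threshold = score_threshold,
                 min_recurrence = min_recurrence,
                 reve_threshold = reve_threshold,
                 fdr_threshold = fdr_threshold, top_k = top_k,
                 max_per_sample = max_per_sample,
                 standin_midp = standin_midp, out_dir = out_dir),
            class = c("pipeline_config", "list"))
}

load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

#' Run the driver-prioritization pipeline
#'
#' Executes the fixed stage order: hypermutator filter, driver/extreme
#' mutation calls, combined gene significance with BH correction,
#' AI-DriverGene injection into the catalog, consensus scores and tiers,
#' final driver-gene call, Gaussian driverness scores for the gene and
#' pathway entity classes, pathway enrichment, pairwise interactions
#' among the top ranked drivers, and drug annotation. Any stage error
#' aborts the run naming the stage; partial outputs are removed.
#' Identical config and inputs give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List with `mutations`, `genes`, `driver_genes`, `enrichment`,
#'   `interactions`, `drug` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  notes <- character()
  counts <- list()
  written <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (length(written) > 0) unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  maf <- stage("read_maf", {
    m <- load_input(config$maf, read_maf)
    stopifnot(is.data.frame(m), nrow(m) > 0)
    if (is.null(m$ai_driver_score)) m$ai_driver_score <- NA_real_
    if (is.null(m$reve_score)) m$reve_score <- NA_real_
    m
  })
  counts$mutations_in <- nrow(maf)

  flt <- stage("hypermutator_filter",
               filter_hypermutated(maf, config$max_per_sample))
  maf <- flt$retained
  counts$hypermutated_samples_removed <- length(flt$removed_samples)
  counts$mutations_retained <- nrow(maf)

  calls <- stage("mutation_calls",
                 call_driver_mutations(maf, config$score_threshold,
                                       config$min_recurrence,
                                       config$reve_threshold))
  counts$distinct_mutations <- nrow(calls)
  counts$driver_mutations <- sum(calls$is_driver)
  counts$extreme_mutations <- sum(calls$is_extreme)

  gene_lengths <- config$gene_lengths
  if (!is.null(gene_lengths)) {
    gene_lengths <- load_input(gene_lengths, function(p) {
      tab <- utils::read.delim(p, stringsAsFactors = FALSE)
      stats::setNames(as.numeric(tab$length), tab$gene)
    })
    if (is.data.frame(gene_lengths)) {
      gene_lengths <- stats::setNames(as.numeric(gene_lengths$length),
                                      gene_lengths$gene)
    }
  }

  gstats <- stage("gene_significance", {
    mutsig <- load_input(config$mutsig, function(p)
      utils::read.delim(p, stringsAsFactors = FALSE))
    mutpanning <- load_input(config$mutpanning, function(p)
      utils::read.delim(p, stringsAsFactors = FALSE))
    if (is.null(mutsig) && is.null(mutpanning)) {
      if (is.null(gene_lengths)) {
        stop("no significance input: supply mutsig/mutpanning tables or",
             " gene_lengths for the stand-in")
      }
      notes <<- c(notes, paste("gene significance from the binomial",
                               "stand-in only (no external p-value tables)"))
      standin <- frequency_pvalue_standin(maf, gene_lengths,
                                          midp = config$standin_midp)
      combine_gene_pvalues(data.frame(gene = standin$gene, p = standin$p),
                           data.frame(gene = character(), p = numeric()))
    } else {
      if (is.null(mutsig)) mutsig <- data.frame(gene = character(),
                                                p = numeric())
      if (is.null(mutpanning)) mutpanning <- data.frame(gene = character(),
                                                        p = numeric())
      combine_gene_pvalues(mutsig, mutpanning)
    }
  })
  counts$genes_tested <- nrow(gstats)

  catalog <- stage("driver_catalog", {
    cat_in <- config$driver_sets
    if (inherits(cat_in, "driver_catalog")) cat_in
    else read_driver_sets(cat_in, config$group1_names)
  })

  aidg <- stage("ai_driver_genes",
                ai_driver_genes(gstats, config$fdr_threshold))
  counts$ai_driver_genes <- length(aidg)
  catalog <- catalog_set(catalog, "AI-DriverGene", aidg, group1 = TRUE)

  genes_universe <- stage("tier_classification", {
    uni <- unique(c(maf$Hugo_Symbol, gstats$gene))
    uni[!duplicated(sym_key(uni))]
  })
  tiers <- tier_table(genes_universe, catalog)
  counts$genes_per_level <- as.list(table(factor(tiers$level, levels = 0:4)))

  drivers <- stage("finalize_drivers", finalize_driver_genes(tiers, calls))
  counts$driver_genes <- length(drivers)

  # assemble the per-gene table
  gene_tab <- stage("gene_table", {
    tab <- merge(tiers, gstats, by = "gene", all.x = TRUE, sort = FALSE)
    per_gene <- function(flag) {
      agg <- tapply(flag, sym_key(calls$gene), sum)
      out <- as.integer(agg[sym_key(tab$gene)])
      ifelse(is.na(out), 0L, out)
    }
    tab$n_driver_mutations <- per_gene(calls$is_driver)
    tab$n_extreme_mutations <- per_gene(calls$is_extreme)
    tab$is_driver_gene <- tab$gene %in% drivers
    tab
  })

  gene_tab <- stage("driverness_scores", {
    tested <- !is.na(gene_tab$q_value)
    gene_tab$driverness <- NA_real_
    if (sum(tested) >= 2) {
      ds <- driverness_score(stats::setNames(gene_tab$q_value[tested],
                                             gene_tab$gene[tested]))
      gene_tab$driverness[tested] <- ds$score
    } else {
      notes <<- c(notes, "fewer than 2 tested genes; gene driverness skipped")
    }
    gene_tab
  })
  notes <- c(notes, paste("mutation-level driverness not computed: no",
                          "mutation FDR stream is produced in this scope"))

  ranked <- gene_tab[gene_tab$is_driver_gene, ]
  ranked <- ranked[order(-ranked$consensus_score,
                         ifelse(is.na(ranked$q_value), 1, ranked$q_value),
                         ranked$gene), ]

  enrichment <- NULL
  collection <- load_input(config$gmt, read_gmt)
  if (is.null(collection)) {
    notes <- c(notes, "enrichment skipped: no gene-set collection supplied")
  } else if (length(drivers) == 0) {
    notes <- c(notes, "enrichment skipped: no driver genes")
  } else {
    enrichment <- stage("pathway_enrichment", {
      bg <- config$background
      if (is.null(bg)) bg <- unique(maf$Hugo_Symbol)
      res <- hypergeom_enrich(drivers, collection, bg, config$fdr_threshold)
      if (nrow(res) >= 2) {
        ds <- driverness_score(stats::setNames(pmax(res$q_value, 1e-300),
                                               res$set_id))
        res$driverness <- ds$score
      }
      res
    })
    counts$pathways_tested <- nrow(enrichment)
    counts$pathways_significant <- sum(enrichment$significant)
  }

  interactions <- NULL
  if (nrow(ranked) >= 2) {
    interactions <- stage("pairwise_interactions",
                          pairwise_interactions(maf, ranked$gene,
                                                config$top_k))
    counts$interaction_pairs <- nrow(interactions)
  } else {
    notes <- c(notes, "interaction analysis skipped: fewer than 2 drivers")
  }

  drug <- NULL
  drug_tab <- load_input(config$drug_table, read_drug_table)
  if (is.null(drug_tab)) {
    notes <- c(notes, "drug annotation skipped: no drug table supplied")
  } else if (length(drivers) > 0) {
    drug <- stage("drug_annotation",
                  annotate_druggability(drivers, drug_tab, maf = maf))
    counts$actionable_driver_genes <- sum(drug$annotations$actionable)
    counts$combination_candidate_samples <-
      sum(drug$samples$combination_candidate)
  }

  manifest <- list(
    package = "driverscape",
    version = as.character(utils::packageVersion("driverscape")),
    cohort = config$cohort,
    thresholds = config[c("score_threshold", "min_recurrence",
                          "reve_threshold", "fdr_threshold", "top_k",
                          "max_per_sample")],
    counts = counts,
    notes = notes
  )

  result <- list(mutations = calls, genes = gene_tab,
                 driver_genes = drivers, enrichment = enrichment,
                 interactions = interactions, drug = drug,
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    stage("write_outputs", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      wr <- function(obj, name) {
        if (is.null(obj)) return()
        p <- file.path(config$out_dir, name)
        write_results(obj, p)
        written <<- c(written, p)
      }
      wr(calls, "mutations.tsv")
      wr(gene_tab, "genes.tsv")
      wr(enrichment, "enrichment.tsv")
      wr(interactions, "interactions.tsv")
      if (!is.null(drug)) {
        wr(drug$annotations, "drug_annotations.tsv")
        wr(drug$samples, "drug_samples.tsv")
      }
      mp <- file.path(config$out_dir, "manifest.json")
      jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      written <<- c(written, mp)
    })
  }
  result
}
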