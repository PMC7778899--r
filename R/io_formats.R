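# Readers/writers for the external formats the pipeline consumes:
# MAF cohorts, driver-set gene lists, GMT gene-set collections, drug-gene
# tables, and TSV result output.

MAF_REQUIRED_COLS <- c(
  "Hugo_Symbol", "Tumor_Sample_Barcode", "Chromosome", "Start_Position",
  "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Classification"
)

#' MAF variant classification vocabulary
#'
#' Controlled terms accepted in the `Variant_Classification` column, the
#' MC3-style dialect. Loss-of-function classes (used for extreme-mutation
#' calling) are stop-gain (`Nonsense_Mutation`), stop-loss
#' (`Nonstop_Mutation`), splice site, and frameshift indels.
#'
#' @format Character vector of MAF classification terms.
#' @export
MAF_CLASSIFICATIONS <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation", "Splice_Site",
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Silent", "Translation_Start_Site", "3'UTR", "5'UTR", "3'Flank", "5'Flank",
  "Intron", "RNA", "IGR", "Targeted_Region"
)

#' Loss-of-function variant classes
#'
#' @format Character vector: the MAF classes treated as loss-of-function.
#' @export
LOF_CLASSES <- c(
  "Nonsense_Mutation", "Nonstop_Mutation", "Splice_Site",
  "Frame_Shift_Del", "Frame_Shift_Ins"
)

#' Read a MAF-format somatic mutation table
#'
#' Parses a tab-separated Mutation Annotation Format file (1-based inclusive
#' coordinates, `#` comment lines skipped) into a data frame of per-variant
#' records. Optional per-mutation pathogenicity score columns are mapped onto
#' the normalized names `ai_driver_score` and `reve_score`; when a score
#' column is absent from the file, the corresponding column is all-`NA`.
#'
#' Only `Tumor_Seq_Allele2` is used as the alternate allele.
#'
#' @param path Path to a MAF file.
#' @param score_columns Named character vector locating the extra score
#'   columns; names must be `ai_driver` and `reve`. Defaults to
#'   `c(ai_driver = "AI_Driver_score", reve = "ReVe_score")`.
#' @return A data frame with the original MAF columns plus numeric
#'   `ai_driver_score` and `reve_score` columns.
#' @export
read_maf <- function(path,
                     score_columns = c(ai_driver = "AI_Driver_score",
                                       reve = "ReVe_score")) {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  # read everything as character: type.convert would turn allele "T" into
  # logical TRUE; numeric columns are converted explicitly below
  maf <- utils::read.delim(path, comment.char = "#", sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(MAF_REQUIRED_COLS, names(maf))
  if (length(missing_cols) > 0) {
    stop("MAF is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pos <- suppressWarnings(as.numeric(maf$Start_Position))
  bad <- which(is.na(pos) & !is.na(maf$Start_Position) &
                 maf$Start_Position != "")
  if (length(bad) > 0) {
    stop("Unparseable Start_Position in MAF data row ", bad[1],
         " (value '", maf$Start_Position[bad[1]], "')")
  }
  maf$Start_Position <- pos
  if (any(!is.na(pos) & pos < 1)) {
    stop("Start_Position must be >= 1 (MAF is 1-based)")
  }
  maf$ai_driver_score <- extract_score(maf, score_columns[["ai_driver"]])
  maf$reve_score <- extract_score(maf, score_columns[["reve"]])
  validate_maf(maf)
  maf
}

extract_score <- function(maf, column) {
  if (is.null(column) || !column %in% names(maf)) {
    return(rep(NA_real_, nrow(maf)))
  }
  x <- suppressWarnings(as.numeric(maf[[column]]))
  if (any(!is.na(x) & (x < 0 | x > 1))) {
    stop("Score column '", column, "' has values outside [0, 1]")
  }
  x
}

validate_maf <- function(maf) {
  is_snp <- !is.null(maf$Variant_Type) && any(maf$Variant_Type == "SNP")
  if (is_snp) {
    snp <- maf$Variant_Type == "SNP"
    bad <- snp & (nchar(maf$Reference_Allele) != 1 |
                    nchar(maf$Tumor_Seq_Allele2) != 1)
    if (any(bad, na.rm = TRUE)) {
      warning(sum(bad, na.rm = TRUE),
              " SNP row(s) have multi-base alleles")
    }
  }
  invisible(maf)
}

#' Read driver-set gene lists into a weighted catalog
#'
#' Each file holds one gene symbol per line. Sets named in `group1_names`
#' form the gold-standard Group1 (weight 10); all others are Group2
#' (weight 1). The default Group1 is the four gold-standard catalogs
#' CGC, OncoKB, AI-DriverGene and MutPanning.
#'
#' @param paths Named character vector: set name -> file path.
#' @param group1_names Set names to assign to Group1.
#' @return A `driver_catalog` object.
#' @export
read_driver_sets <- function(paths,
                             group1_names = c("CGC", "OncoKB",
                                              "AI-DriverGene", "MutPanning")) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    stop("'paths' must be a named vector of set name -> file path")
  }
  sets <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("Driver-set file not found: ", p)
    genes <- trimws(readLines(p, warn = FALSE))
    genes <- genes[genes != ""]
    if (length(genes) == 0) {
      warning("Driver-set file is empty: ", p)
    }
    unique(genes)
  })
  names(sets) <- names(paths)
  driver_catalog(sets, group1_names = intersect(group1_names, names(sets)))
}

#' Construct a driver-set catalog
#'
#' A catalog is a collection of named gene sets partitioned into Group1
#' (gold standard, weight 10) and Group2 (supplementary, weight 1), the
#' weighting used by the Borda consensus score.
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param group1_names Which set names belong to Group1.
#' @return An object of class `driver_catalog` with elements `sets`,
#'   `group` and `weight`.
#' @export
driver_catalog <- function(sets, group1_names = character()) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) stop("Duplicate set names in catalog")
  extra <- setdiff(group1_names, names(sets))
  if (length(extra) > 0) {
    stop("group1_names not present in catalog: ", paste(extra, collapse = ", "))
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  group <- ifelse(names(sets) %in% group1_names, "Group1", "Group2")
  weight <- ifelse(group == "Group1", 10, 1)
  names(group) <- names(weight) <- names(sets)
  structure(list(sets = sets, group = group, weight = weight),
            class = "driver_catalog")
}

#' @export
print.driver_catalog <- function(x, ...) {
  cat("driver_catalog:", length(x$sets), "sets (",
      sum(x$group == "Group1"), "Group1 /",
      sum(x$group == "Group2"), "Group2 )\n")
  for (nm in names(x$sets)) {
    cat(sprintf("  %-20s %-6s weight %2d  %d genes\n", nm, x$group[[nm]],
                x$weight[[nm]], length(x$sets[[nm]])))
  }
  invisible(x)
}

#' Replace or inject a set in a driver catalog
#'
#' Used by the pipeline to install the computed AI-DriverGene set into the
#' catalog (as Group1) before consensus scoring.
#'
#' @param catalog A `driver_catalog`.
#' @param name Set name to replace or add.
#' @param genes Character vector of member gene symbols.
#' @param group1 Whether the set belongs to Group1.
#' @return The updated catalog.
#' @export
catalog_set <- function(catalog, name, genes, group1 = TRUE) {
  stopifnot(inherits(catalog, "driver_catalog"))
  catalog$sets[[name]] <- unique(as.character(genes))
  catalog$group[[name]] <- if (group1) "Group1" else "Group2"
  catalog$weight[[name]] <- if (group1) 10 else 1
  catalog
}

#' Read a GMT gene-set collection
#'
#' One set per line: `set_id TAB description TAB member1 TAB member2 ...`.
#'
#' @param path Path to a GMT file.
#' @param source_tag Label for the collection's provenance (e.g. "GO",
#'   "KEGG", "custom").
#' @return A `gene_set_collection`: list with `sets` (named list of member
#'   vectors), `set_names` (descriptions) and `source_tag`.
#' @export
read_gmt <- function(path, source_tag = "custom") {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[lines != ""]
  if (length(lines) == 0) {
    return(gene_set_collection(list(), character(), source_tag))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("GMT line ", which(nf < 3)[1], " has fewer than 3 tab-separated fields")
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("GMT has duplicate set id '", ids[anyDuplicated(ids)], "'")
  }
  descs <- vapply(fields, `[[`, character(1), 2)
  members <- lapply(fields, function(f) unique(f[-(1:2)][f[-(1:2)] != ""]))
  names(members) <- ids
  names(descs) <- ids
  gene_set_collection(members, descs, source_tag)
}

#' Construct a gene-set collection
#'
#' @param sets Named list (set_id -> member gene symbols), each non-empty.
#' @param set_names Optional named character vector of descriptions.
#' @param source_tag Provenance label.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, set_names = NULL, source_tag = "custom") {
  stopifnot(is.list(sets))
  if (length(sets) > 0) {
    stopifnot(!is.null(names(sets)))
    if (anyDuplicated(names(sets))) stop("Duplicate set ids")
    if (any(lengths(sets) == 0)) stop("Every gene set must have >= 1 member")
  }
  if (is.null(set_names)) {
    set_names <- stats::setNames(names(sets), names(sets))
  }
  structure(list(sets = sets, set_names = set_names, source_tag = source_tag),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection [", x$source_tag, "]: ", length(x$sets),
      " sets, sizes ", if (length(x$sets)) paste(range(lengths(x$sets)),
                                                 collapse = "-") else "NA",
      "\n", sep = "")
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output file path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$set_names[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read a drug-gene interaction table
#'
#' Tab-separated with a header; required columns `gene` and `drug`, optional
#' `interaction_type` and `source` (missing optional columns are filled
#' with NA).
#'
#' @param path Path to the TSV.
#' @return Data frame with columns gene, drug, interaction_type, source.
#' @export
read_drug_table <- function(path) {
  if (!file.exists(path)) stop("Drug table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  names(tab) <- tolower(names(tab))
  for (col in c("gene", "drug")) {
    if (!col %in% names(tab)) stop("Drug table missing column '", col, "'")
  }
  if (any(is.na(tab$gene) | tab$gene == "")) {
    stop("Drug table has empty gene symbols")
  }
  for (col in c("interaction_type", "source")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_character_
  }
  tab[, c("gene", "drug", "interaction_type", "source")]
}

#' Write a result table as TSV
#'
#' Tab-separated UTF-8 with a header row; numeric columns keep full double
#' precision so a write/read round trip reproduces values.
#'
#' @param records A data frame.
#' @param path Output path.
#' @export
write_results <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- vapply(out[[col]], function(v) {
        if (is.na(v)) NA_character_ else format(v, digits = 15, trim = TRUE,
                                                scientific = NA)
      }, character(1))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
}

# Case-insensitive symbol matching: driver-set files and MAFs mix cases in
# the wild. Keys are uppercased for matching; display case is preserved
# by callers.
sym_key <- function(x) toupper(trimws(as.character(x)))
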