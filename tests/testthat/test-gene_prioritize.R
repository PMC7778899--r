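test_that("fisher_combine matches the df=4 closed form on a grid", {
  expect_equal(fisher_combine(1, 1), 1.0)
  expect_equal(fisher_combine(0.01, 0.01), 1.021034e-3, tolerance = 1e-6)
  expect_equal(fisher_combine(0.05, 1), 0.1997866, tolerance = 1e-6)
  grid <- expand.grid(p1 = seq(0.01, 1, length.out = 10),
                      p2 = seq(0.005, 1, length.out = 10))
  x <- -2 * (log(grid$p1) + log(grid$p2))
  closed <- exp(-x / 2) * (1 + x / 2)
  expect_true(max(abs(fisher_combine(grid$p1, grid$p2) - closed)) < 1e-12)
  expect_error(fisher_combine(0, 0.5), "floor")
})

test_that("fisher_combine is symmetric and monotone in each argument", {
  set.seed(3)
  a <- runif(50, 1e-6, 1)
  b <- runif(50, 1e-6, 1)
  expect_equal(fisher_combine(a, b), fisher_combine(b, a))
  ps <- sort(runif(20, 1e-4, 1))
  for (fixed in c(0.01, 0.3, 1)) {
    expect_false(is.unsorted(fisher_combine(ps, fixed)))
  }
})

test_that("bh_correct equals the literal step-up oracle", {
  expect_equal(bh_correct(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_correct(1.0), 1.0)
  set.seed(11)
  for (rep in 1:200) {
    p <- runif(sample(1:50, 1))
    q <- bh_correct(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
  }
})

test_that("combine_gene_pvalues merges case-insensitively and flags single-method genes", {
  ms <- data.frame(gene = c("TP53", "kras", "EGFR"), p = c(0.01, 0.2, 0.5))
  mp <- data.frame(gene = c("tp53", "KRAS"), p = c(0.02, 0.9))
  got <- combine_gene_pvalues(ms, mp)
  expect_equal(nrow(got), 3)
  tp53 <- got[got$gene == "TP53", ]
  expect_equal(tp53$p_combined, fisher_combine(0.01, 0.02))
  expect_false(tp53$single_method)
  egfr <- got[got$gene == "EGFR", ]
  expect_true(egfr$single_method)
  expect_equal(egfr$p_combined, 0.5)  # lone p-value kept as combined p
  expect_equal(got$q_value, bh_oracle(got$p_combined))
})

test_that("ai_driver_genes uses an inclusive FDR boundary", {
  stats <- data.frame(gene = c("A", "B", "C"),
                      q_value = c(0.01, 0.05, 0.06))
  expect_setequal(ai_driver_genes(stats), c("A", "B"))
  expect_length(ai_driver_genes(data.frame(gene = "A", q_value = 1)), 0)
  expect_setequal(ai_driver_genes(stats, fdr_threshold = 1.0),
                  c("A", "B", "C"))
})

test_that("consensus_score sums 10 per Group1 and 1 per Group2 membership", {
  sets <- c(list(CGC = "TP53", OncoKB = "TP53", `AI-DriverGene` = "TP53",
                 MutPanning = "TP53"),
            stats::setNames(replicate(12, "TP53", simplify = FALSE),
                            paste0("SUPP", 1:12)))
  cat16 <- driver_catalog(sets, group1_names = c("CGC", "OncoKB",
                                                 "AI-DriverGene", "MutPanning"))
  expect_equal(unname(consensus_score("TP53", cat16)), 52L)
  expect_equal(unname(consensus_score("BRAF", cat16)), 0L)

  two <- driver_catalog(list(CGC = c("TP53", "KRAS"), OncoKB = "TP53"),
                        group1_names = c("CGC", "OncoKB"))
  expect_equal(unname(consensus_score(c("TP53", "KRAS"), two)), c(20L, 10L))
})

test_that("consensus_score equals the naive membership sum on random catalogs", {
  set.seed(21)
  universe <- sprintf("G%03d", 1:60)
  for (rep in 1:20) {
    n_sets <- sample(3:16, 1)
    sets <- lapply(seq_len(n_sets), function(i)
      sample(universe, sample(1:25, 1)))
    names(sets) <- paste0("SET", seq_len(n_sets))
    g1 <- sample(names(sets), sample(0:min(4, n_sets), 1))
    cat_r <- driver_catalog(sets, group1_names = g1)
    genes <- sample(universe, 15)
    naive <- vapply(genes, function(g) {
      sum(vapply(names(sets), function(nm)
        ifelse(g %in% sets[[nm]], ifelse(nm %in% g1, 10, 1), 0), numeric(1)))
    }, numeric(1))
    expect_equal(unname(consensus_score(genes, cat_r)), as.integer(naive))
  }
})

test_that("tier_classify maps the documented score intervals to levels", {
  expect_equal(tier_classify(c(0, 1, 10, 11, 15, 19, 20, 52)),
               c(0L, 1L, 2L, 3L, 3L, 3L, 4L, 4L))
  expect_equal(tier_classify(2), 2L)
  expect_error(tier_classify(-1), "negative")
  # every reachable score {0..52} lands in exactly one level, all levels hit
  lv <- tier_classify(0:52)
  expect_setequal(unique(lv), 0:4)
  expect_true(all(diff(lv) >= 0))
})

test_that("adding a gene to any driver set never lowers its level", {
  set.seed(33)
  universe <- sprintf("G%03d", 1:30)
  sets <- lapply(1:8, function(i) sample(universe, 10))
  names(sets) <- paste0("SET", 1:8)
  cat_r <- driver_catalog(sets, group1_names = c("SET1", "SET2"))
  gene <- "G001"
  before <- tier_classify(consensus_score(gene, cat_r))
  for (nm in names(sets)) {
    grown <- catalog_set(cat_r, nm, c(cat_r$sets[[nm]], gene),
                         group1 = cat_r$group[[nm]] == "Group1")
    after <- tier_classify(consensus_score(gene, grown))
    expect_gte(after, before)
  }
})

test_that("finalize_driver_genes requires Level 4 plus driver/extreme evidence", {
  tiers <- data.frame(gene = c("A", "B", "C"), level = c(4L, 4L, 3L))
  calls <- data.frame(gene = c("A", "B", "C", "C"),
                      is_driver = c(TRUE, FALSE, TRUE, TRUE),
                      is_extreme = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(finalize_driver_genes(tiers, calls), "A")

  calls$is_extreme[2] <- TRUE  # extreme evidence also qualifies
  expect_setequal(finalize_driver_genes(tiers, calls), c("A", "B"))
})

test_that("binomial stand-in gives p=1 at zero counts and small p for hot genes", {
  lens <- stats::setNames(rep(1000, 100), sprintf("G%03d", 1:100))
  # 50 of 100 mutations concentrated in one of 100 equal-length genes
  maf <- toy_maf(gene = c(rep("G001", 50),
                          sprintf("G%03d", sample(2:100, 50, replace = TRUE))),
                 sample = sprintf("S%02d", 1:100), pos = 1:100)
  got <- frequency_pvalue_standin(maf, lens)
  expect_lt(got$p[got$gene == "G001"], 1e-10)
  cold <- setdiff(got$gene, unique(maf$Hugo_Symbol))
  expect_true(all(got$p[got$gene %in% cold] == 1.0))
  expect_true(all(got$n_nonsilent[got$gene %in% cold] == 0))
})

test_that("stand-in skips genes missing from the length table with a warning", {
  lens <- c(G001 = 1000)
  maf <- toy_maf(gene = c("G001", "MYSTERY"), sample = c("S1", "S2"),
                 pos = c(1, 2))
  expect_warning(got <- frequency_pvalue_standin(maf, lens), "skipped")
  expect_equal(got$gene, "G001")
})

test_that("druggability annotation joins drugs and flags combination candidates", {
  drug <- data.frame(gene = c("KRAS", "KRAS", "BRAF"),
                     drug = c("drugX", "drugY", "drugZ"),
                     interaction_type = "inhibitor", source = "syn")
  ann <- annotate_druggability(c("KRAS", "TP53"), drug)$annotations
  expect_equal(ann$actionable, c(TRUE, FALSE))
  expect_equal(ann$drugs[1], "drugX;drugY")

  empty <- annotate_druggability(c("KRAS"), drug[0, ])$annotations
  expect_false(any(empty$actionable))

  maf <- toy_maf(gene = c("KRAS", "BRAF", "KRAS", "TP53"),
                 sample = c("S1", "S1", "S2", "S2"), pos = 1:4)
  got <- annotate_druggability(c("KRAS", "BRAF", "TP53"), drug, maf = maf)
  s <- got$samples
  expect_true(s$combination_candidate[s$sample_id == "S1"])
  expect_false(s$combination_candidate[s$sample_id == "S2"])
})
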