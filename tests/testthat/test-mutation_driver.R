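test_that("classify_extreme covers LoF classes and the inclusive ReVe boundary", {
  expect_true(classify_extreme("Nonsense_Mutation", NA_real_))
  expect_true(all(classify_extreme(
    c("Nonstop_Mutation", "Splice_Site", "Frame_Shift_Del", "Frame_Shift_Ins"),
    rep(NA_real_, 4))))
  expect_true(classify_extreme("Missense_Mutation", 0.50))
  expect_false(classify_extreme("Missense_Mutation", 0.49))
  expect_false(classify_extreme("Silent", 0.99))
  expect_false(classify_extreme("Missense_Mutation", NA_real_))
  # extreme status ignores AI-Driver scores entirely
  maf <- toy_maf(gene = "A", sample = c("S1", "S2"),
                 classification = c("Missense_Mutation", "Silent"),
                 reve = c(0.7, 0.7), ai = c(0.99, 0.99))
  expect_equal(classify_extreme(maf), c(TRUE, FALSE))
})

test_that("call_driver_mutations applies the recurrence and score rule", {
  # same missense change in 2 samples, scores 0.96/0.97 -> driver
  maf <- toy_maf(gene = "A", sample = c("S1", "S2"), pos = 10,
                 ai = c(0.96, 0.97))
  calls <- call_driver_mutations(maf)
  expect_equal(nrow(calls), 1)
  expect_true(calls$is_driver)
  expect_equal(calls$n_patients, 2L)
  expect_equal(calls$max_ai_driver, 0.97)

  # one patient at 0.99 -> not recurrent
  one <- call_driver_mutations(toy_maf(gene = "A", sample = "S1", ai = 0.99))
  expect_false(one$is_driver)

  # three patients below threshold -> not driver
  low <- call_driver_mutations(toy_maf(gene = "A",
                                       sample = c("S1", "S2", "S3"),
                                       ai = 0.90))
  expect_equal(low$n_patients, 3L)
  expect_false(low$is_driver)

  # non-missense recurrent high score is never a driver mutation
  lof <- call_driver_mutations(toy_maf(gene = "A", sample = c("S1", "S2"),
                                       classification = "Nonsense_Mutation",
                                       ai = 0.99))
  expect_false(lof$is_driver)
  expect_true(lof$is_extreme)
})

test_that("driver calls are invariant to row order and repeated sample rows", {
  maf <- rbind(
    toy_maf(gene = "A", sample = c("S1", "S2"), pos = 10, ai = c(0.96, 0.97)),
    toy_maf(gene = "B", sample = c("S1", "S3", "S4"), pos = 50,
            ai = c(0.2, 0.99, 0.97))
  )
  base <- call_driver_mutations(maf)
  perm <- call_driver_mutations(maf[rev(seq_len(nrow(maf))), ])
  ord <- function(x) x[order(x$pos), ]
  expect_equal(ord(perm), ord(base), ignore_attr = TRUE)

  # duplicating an already-counted (sample, mutation) pair changes nothing
  dup <- call_driver_mutations(rbind(maf, maf[1, ]))
  expect_equal(ord(dup)$n_patients, ord(base)$n_patients)
  expect_equal(ord(dup)$is_driver, ord(base)$is_driver)
})

test_that("lowering the score threshold or recurrence never shrinks the driver set", {
  set.seed(42)
  for (rep in 1:5) {
    maf <- toy_maf(gene = sample(LETTERS[1:6], 40, replace = TRUE),
                   sample = sample(paste0("S", 1:12), 40, replace = TRUE),
                   pos = sample(1:8, 40, replace = TRUE) * 10,
                   ai = runif(40))
    strict <- call_driver_mutations(maf, score_threshold = 0.8,
                                    min_recurrence = 3)
    key <- function(calls) paste(calls$pos, calls$is_driver)
    for (st in c(0.6, 0.4)) {
      for (mr in c(3, 2, 1)) {
        loose <- call_driver_mutations(maf, score_threshold = st,
                                       min_recurrence = mr)
        strict_set <- strict$pos[strict$is_driver]
        loose_set <- loose$pos[loose$is_driver]
        expect_true(all(strict_set %in% loose_set))
      }
    }
  }
})

test_that("reve_percentile is average-rank/n, order preserving, max at 1", {
  expect_equal(reve_percentile(c(0.1, 0.5, 0.9)), c(1 / 3, 2 / 3, 1))
  expect_equal(reve_percentile(0.7), 1)
  # ties share the average-rank percentile
  expect_equal(reve_percentile(c(0.4, 0.4)), c(0.75, 0.75))
  expect_error(reve_percentile(numeric(0)), "at least one")
  set.seed(7)
  x <- runif(50)
  p <- reve_percentile(x)
  expect_equal(order(p), order(x))
  expect_equal(max(p), 1)
  expect_true(all(p > 0 & p <= 1))
})

test_that("classify_titv collapses to six pyrimidine classes", {
  got <- classify_titv(c("C", "G", "C", "A", "G"),
                       c("T", "A", "A", "C", "T"))
  expect_equal(got$conversion, c("C>T", "C>T", "C>A", "T>G", "C>A"))
  expect_equal(got$titv, c("transition", "transition", "transversion",
                           "transversion", "transversion"))
  # all 12 ordered substitutions collapse onto exactly six classes
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  all12 <- classify_titv(pairs$ref, pairs$alt)
  expect_setequal(unique(all12$conversion),
                  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  expect_equal(sum(all12$titv == "transition"), 4)
  expect_error(classify_titv("C", "C"))
  expect_error(classify_titv("-", "T"))
})

test_that("hypermutator filter removes strictly-over-threshold samples", {
  maf <- toy_maf(gene = "A",
                 sample = rep(c("S1", "S2", "S3"), times = c(10, 10, 5000)),
                 pos = seq_len(5020))
  got <- filter_hypermutated(maf, 1000)
  expect_equal(got$removed_samples, "S3")
  expect_equal(nrow(got$retained), 20)

  none <- filter_hypermutated(maf, 10000)
  expect_length(none$removed_samples, 0)
  expect_equal(nrow(none$retained), nrow(maf))

  # boundary: counts equal to the threshold are retained
  eq <- toy_maf(gene = "A", sample = rep(c("S1", "S2", "S3"), each = 3),
                pos = 1:9)
  expect_length(filter_hypermutated(eq, 3)$removed_samples, 0)
})
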