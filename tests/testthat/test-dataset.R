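test_that("deduplication treats pairs as unordered within a label class", {
  ds <- pair_dataset(c("CCO", "CCC", "CCO"), c("CCC", "CCO", "CCCC"),
                     c(0L, 0L, 0L), "gen_neg")
  out <- deduplicate_pairs(ds)
  expect_equal(nrow(out), 2L)  # (CCO,CCC) == (CCC,CCO); (CCO,CCCC) distinct
  expect_equal(out$api_smiles[1], canonicalize_smiles("CCO"))

  many <- pair_dataset(rep("CCO", 10), rep("CCC", 10), rep(0L, 10), "gen_neg")
  expect_equal(nrow(deduplicate_pairs(many)), 1L)
})

test_that("pair_dataset validates labels, sources and self-pairs", {
  expect_error(pair_dataset("CCO", "CCO", 0L), "different molecules")
  expect_error(pair_dataset("CCO", "CCC", 2L), "0 or 1")
  expect_error(pair_dataset("CCO", "CCC", 0L, "csd_pos"), "inconsistent")
  expect_equal(unname(class_counts(small_dataset())), c(80L, 80L))
})

test_that("negative pair generation is exact, deterministic and bounded", {
  pool <- c("CC", "CCC", "CCCC", "CCCCC", "CCCCCC")
  all_pairs <- generate_negative_pairs(pool, 10L, seed = 5)
  expect_equal(nrow(all_pairs), 10L)  # C(5,2) = 10, every pair exactly once
  expect_equal(anyDuplicated(cocrystalgcn:::pair_key(all_pairs$api_smiles,
                                                     all_pairs$cf_smiles)), 0L)
  expect_true(all(all_pairs$label == 0L))
  expect_true(all(all_pairs$source == "gen_neg"))

  again <- generate_negative_pairs(pool, 10L, seed = 5)
  expect_identical(as.data.frame(all_pairs), as.data.frame(again))

  # exhaustion: all 3 pairs of a 3-pool forbidden
  p3 <- c("CC", "CCC", "CCCC")
  forb <- generate_negative_pairs(p3, 3L, seed = 1)
  expect_error(generate_negative_pairs(p3, 1L, forbidden = forb), "0 distinct")
})

test_that("compound frequencies count both members of each pair", {
  ds <- pair_dataset(c("CC", "CC"), c("CCC", "CCCC"), c(0L, 0L), "gen_neg")
  freq <- compound_frequency(ds)
  expect_equal(freq[[canonicalize_smiles("CC")]], 2L)
  expect_equal(sum(freq), 2L * nrow(ds))
  expect_length(compound_frequency(ds[0, ]), 0L)
})

test_that("maxmin selection matches hand cases and the brute-force oracle", {
  d <- abs(outer(c(0, 1, 10), c(0, 1, 10), "-"))
  expect_equal(sort(maxmin_select(1:3, 2L, d)), c(1L, 3L))
  expect_equal(maxmin_select(1:3, 1L, d), 1L)
  expect_equal(sort(maxmin_select(1:3, 3L, d)), 1:3)
  expect_error(maxmin_select(1:3, 4L, d), "must be in")

  # random instances up to 8 items
  for (rep in 1:25) {
    n <- cocrystalgcn:::with_seed(rep, sample(2:8, 1))
    pts <- cocrystalgcn:::with_seed(rep + 100L, runif(n))
    dm <- abs(outer(pts, pts, "-"))
    k <- cocrystalgcn:::with_seed(rep + 200L, sample(n, 1))
    expect_equal(maxmin_select(seq_len(n), k, dm), oracle_maxmin(dm, k))
  }
})

test_that("rebalancing follows the frequency-difference MaxMin procedure", {
  # toy: compound q in 3 gen_neg pairs and 1 csd_pos pair; removing 2 leaves
  # exactly 1 surviving q-pair chosen by MaxMin
  q <- "CCCCC"
  others <- c("CC", "CCC", "CCCC")
  gen_neg <- pair_dataset(rep(q, 3), others, rep(0L, 3), "gen_neg")
  csd_pos <- pair_dataset(q, "CCCCCC", 1L, "csd_pos")
  exp_neg <- pair_dataset("CCCCCCC", "CCCCCCCC", 0L, "exp_neg")

  out <- rebalance_negatives(gen_neg, csd_pos, exp_neg, remove_total = 2L)
  expect_equal(nrow(out), 3L - 2L + 1L)
  canon_q <- canonicalize_smiles(q)
  expect_equal(sum(out$api_smiles == canon_q | out$cf_smiles == canon_q), 1L)
  # all exp_neg retained
  expect_true(all(exp_neg$api_smiles %in% out$api_smiles))

  # remove_total = 0 leaves gen_neg untouched
  out0 <- rebalance_negatives(gen_neg, csd_pos, exp_neg, remove_total = 0L)
  expect_equal(nrow(out0), nrow(gen_neg) + nrow(exp_neg))

  # infeasible removal errors (only 3 gen_neg pairs exist)
  expect_error(rebalance_negatives(gen_neg, csd_pos, exp_neg, remove_total = 4L),
               "exceeds|removable")
})

test_that("rebalancing conserves counts and caps surviving frequencies", {
  # engineered skew: a positive set and a skewed generated-negative set
  spec <- synthetic_spec(n_molecules = 30L, n_pos = 60L, n_neg = 60L,
                         frequency_skew = 1.2, seed = 77L)
  ds <- generate_dataset(spec)
  pos <- ds[ds$label == 1L, ]; pos$source <- "csd_pos"
  neg <- ds[ds$label == 0L, ]; neg$source <- "gen_neg"
  pos <- cocrystalgcn:::as_pair_dataset(pos)
  neg <- cocrystalgcn:::as_pair_dataset(neg)
  exp_neg <- pair_dataset(c("ClCCCl", "BrCCBr"), c("ClCCCCl", "BrCCCBr"),
                          c(0L, 0L), "exp_neg")

  remove_total <- 10L
  out <- rebalance_negatives(neg, pos, exp_neg, remove_total, seed = 4L)
  expect_equal(nrow(out), nrow(neg) - remove_total + nrow(exp_neg))
  ekeys <- cocrystalgcn:::pair_key(exp_neg$api_smiles, exp_neg$cf_smiles)
  okeys <- cocrystalgcn:::pair_key(out$api_smiles, out$cf_smiles)
  expect_true(all(ekeys %in% okeys))

  # fully processed compounds end at or below their positive frequency
  fg <- compound_frequency(neg)
  fp <- compound_frequency(pos)
  fsurv <- compound_frequency(cocrystalgcn:::as_pair_dataset(
    out[out$source == "gen_neg", ]))
  diffs <- fg - ifelse(is.na(fp[names(fg)]), 0L, fp[names(fg)])
  ord <- names(fg)[order(-diffs, names(fg))]
  removed <- 0L
  for (cmp in ord) {
    if (removed >= remove_total) break
    M <- fg[[cmp]]
    N <- if (is.na(fp[cmp])) 0L else fp[[cmp]]
    if (M <= N) next
    surv <- if (is.na(fsurv[cmp])) 0L else fsurv[[cmp]]
    if (removed + (M - N) <= remove_total) {
      expect_lte(surv, N)
    }
    removed <- removed + min(M - N, remove_total - removed)
  }
})

test_that("stratified splits have exact sizes and partition the data", {
  ds <- small_dataset()[1:100, ]
  class(ds) <- c("pair_dataset", "data.frame")
  # make it balanced 50/50 for the arithmetic check
  ds <- rbind(small_dataset()[small_dataset()$label == 1L, ][1:50, ],
              small_dataset()[small_dataset()$label == 0L, ][1:50, ])
  ds <- cocrystalgcn:::as_pair_dataset(ds)
  sp <- split_dataset(ds, c(0.8, 0.1, 0.1), seed = 9L)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 80L, val = 10L, test = 10L))
  expect_equal(sum(sp$val$label), 5L)
  expect_equal(sum(sp$test$label), 5L)

  # partition: union equals input multiset
  key <- function(d) sort(paste(d$api_smiles, d$cf_smiles, d$label))
  expect_equal(sort(c(key(sp$train), key(sp$val), key(sp$test))), key(ds))

  sp2 <- split_dataset(ds, c(0.8, 0.1, 0.1), seed = 9L)
  expect_identical(lapply(sp, as.data.frame), lapply(sp2, as.data.frame))

  expect_error(split_dataset(ds[1:5, ], c(0.8, 0.1, 0.1), seed = 1L), "empty")
})

test_that("k-fold resplits are independent but reproducible", {
  ds <- small_dataset()
  folds <- kfold_splits(ds, k = 3L, seed = 21L)
  expect_length(folds, 3L)
  for (f in folds) {
    expect_equal(nrow(f$train) + nrow(f$val) + nrow(f$test), nrow(ds))
  }
  # different folds give different partitions
  expect_false(identical(as.data.frame(folds[[1]]$train),
                         as.data.frame(folds[[2]]$train)))
  folds2 <- kfold_splits(ds, k = 3L, seed = 21L)
  expect_identical(as.data.frame(folds[[2]]$val), as.data.frame(folds2[[2]]$val))
})

test_that("pair tables round-trip through CSV", {
  ds <- small_dataset()[1:10, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_pair_table(ds, path)
  back <- read_pair_table(path)
  expect_equal(as.data.frame(back),
               as.data.frame(cocrystalgcn:::as_pair_dataset(ds)))
})
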