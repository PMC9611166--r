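test_that("node embedding follows the two-layer ReLU form", {
  zero <- list(W1 = matrix(0, 2, 2), b1 = c(0, 0),
               W2 = matrix(0, 2, 2), b2 = c(0, 0))
  expect_equal(node_embed(rbind(c(1, 2)), zero), matrix(0, 1, 2))

  ident <- list(W1 = diag(2), b1 = c(0, 0), W2 = diag(2), b2 = c(0, 0))
  x <- rbind(c(0.5, 2), c(1, 0))
  expect_equal(node_embed(x, ident), x)

  # hand computation with clipping: inner ReLU [[1, 0]], all-ones W2
  p <- list(W1 = diag(2), b1 = c(0, 0), W2 = matrix(1, 2, 2), b2 = c(0, 0))
  expect_equal(node_embed(rbind(c(1, -1)), p), rbind(c(1, 1)))

  expect_error(node_embed(matrix(1, 1, 3), ident), "mismatch")
})

test_that("graph convolution steps aggregate neighbors with residuals", {
  h <- rbind(1, 2)
  path <- rbind(c(0, 1), c(1, 0))
  expect_equal(gc_step(h, matrix(0, 2, 2), matrix(1)), h)
  expect_equal(gc_step(h, path, matrix(1)), rbind(3, 3))
  expect_equal(gc_step(rbind(1, -2), path, matrix(1)), rbind(1, -1))
  expect_error(gc_step(h, matrix(0, 3, 3), matrix(1)), "mismatch")
})

test_that("global pooling is a masked row sum, invariant to permutation", {
  h <- rbind(c(1, 2), c(3, 4))
  expect_equal(global_pool(h), c(4, 6))
  expect_equal(global_pool(h[2:1, ]), c(4, 6))
  expect_equal(global_pool(h[1, , drop = FALSE]), c(1, 2))
  expect_equal(global_pool(h, pooling = "mean"), c(2, 3))
  expect_equal(global_pool(h, mask = c(1, 0)), c(1, 2))
  expect_error(global_pool(h, mask = c(0, 0)), "mask")
})

test_that("the prediction head is a sigmoid over two FC layers", {
  zero <- list(W_FC1 = matrix(0, 2, 3), b_FC1 = numeric(3),
               W_FC2 = matrix(0, 3, 1), b_FC2 = 0)
  expect_equal(predict_head(c(1, 2), zero), 0.5)
  big <- zero; big$b_FC2 <- 50
  expect_gt(predict_head(c(1, 2), big), 1 - 1e-6)
  expect_error(predict_head(c(1, 2, 3), zero), "mismatch")
})

test_that("binary cross-entropy matches its closed forms", {
  expect_lt(bce_loss(1, 1 - 1e-12), 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(c(1, 0), c(0.9, 0.2)),
               -(log(0.9) + log(0.8)) / 2, tolerance = 1e-9)
  expect_error(bce_loss(numeric(0), numeric(0)), "empty")
  expect_error(bce_loss(c(1, 0), 0.5), "length")
})

test_that("the batched forward pass matches the entry-by-entry oracle", {
  ctl <- gcn_control()
  params <- rand_params(ctl, seed = 5L)
  picks <- cocrystalgcn:::with_seed(9L, t(replicate(12, sample(length(small_mols), 2L))))
  for (i in seq_len(nrow(picks))) {
    pg <- pair_graph(small_mols[picks[i, 1]], small_mols[picks[i, 2]])
    b <- cocrystalgcn:::build_batch(list(pg), ctl)
    fw <- cocrystalgcn:::forward_batch(params, b, ctl)
    expected <- oracle_forward(params, pg, ctl)
    expect_lt(abs(fw$prob - expected$prob), 1e-6)
    expect_lt(abs(fw$logit - expected$logit), 1e-6)
  }
})

test_that("mean pooling and adjacency normalization variants stay consistent", {
  pg <- pair_graph("CCO", "c1ccncc1")
  for (ctl in list(gcn_control(pooling = "mean"),
                   gcn_control(normalize_adjacency = TRUE))) {
    params <- rand_params(ctl, seed = 8L)
    b <- cocrystalgcn:::build_batch(list(pg), ctl)
    fw <- cocrystalgcn:::forward_batch(params, b, ctl)
    expected <- oracle_forward(params, cocrystalgcn:::with_seed(1L, {
      q <- pg
      if (ctl$normalize_adjacency) {
        q$a_c <- cocrystalgcn:::sym_normalize(q$a_c)
        q$a_nc <- cocrystalgcn:::sym_normalize(q$a_nc)
      }
      q
    }), ctl)
    expect_lt(abs(fw$prob - expected$prob), 1e-6)
  }
})

test_that("predictions are invariant to atom relabeling and argument swap", {
  ctl <- gcn_control()
  params <- rand_params(ctl, seed = 6L)
  fit <- fake_fit(params, ctl)
  pgs <- random_test_pairs(15, seed = 40L)
  for (pg in pgs) {
    p_ab <- predict(fit, list(pg))
    # swap argument order
    p_ba <- predict(fit, list(pair_graph(pg$coformer, pg$api)))
    expect_lt(abs(p_ab - p_ba), 1e-6)
    # relabel atoms within each molecule: permute rows/cols consistently
    na <- pg$api$atom_count; nc <- pg$coformer$atom_count
    perm <- c(cocrystalgcn:::with_seed(1L, sample(na)),
              na + cocrystalgcn:::with_seed(2L, sample(nc)))
    q <- pg
    q$x_in <- pg$x_in[perm, , drop = FALSE]
    q$a_c <- pg$a_c[perm, perm]
    q$a_nc <- pg$a_nc[perm, perm]
    q$ac_idx <- which(q$a_c == 1, arr.ind = TRUE)
    q$nc_idx <- which(q$a_nc == 1, arr.ind = TRUE)
    p_perm <- predict(fit, list(q))
    expect_lt(abs(p_ab - p_perm), 1e-6)
  }
})

test_that("block-diagonal batching equals unbatched per-pair forwards", {
  ctl <- gcn_control()
  params <- rand_params(ctl, seed = 12L)
  pgs <- random_test_pairs(20, seed = 55L)
  b <- cocrystalgcn:::build_batch(pgs, ctl)
  batched <- cocrystalgcn:::forward_batch(params, b, ctl)$prob
  single <- vapply(pgs, function(pg) {
    cocrystalgcn:::forward_batch(params, cocrystalgcn:::build_batch(list(pg), ctl),
                                 ctl)$prob
  }, numeric(1))
  expect_lt(max(abs(batched - single)), 1e-5)
})

test_that("ablation flags skip exactly one convolution block", {
  params <- rand_params(gcn_control(), seed = 3L)
  pg <- pair_graph("CCO", "c1cnccn1")
  ctl_nc <- gcn_control(use_covalent = FALSE)   # noncovalent-only variant
  ctl_c <- gcn_control(use_noncovalent = FALSE) # covalent-only variant
  for (ctl in list(ctl_nc, ctl_c)) {
    b <- cocrystalgcn:::build_batch(list(pg), ctl)
    fw <- cocrystalgcn:::forward_batch(params, b, ctl)
    expected <- oracle_forward(params, pg, ctl)
    expect_lt(abs(fw$prob - expected$prob), 1e-6)
  }
  # the two variants genuinely differ from the full model on this pair
  full <- cocrystalgcn:::forward_batch(
    params, cocrystalgcn:::build_batch(list(pg), gcn_control()), gcn_control())
  nc_only <- cocrystalgcn:::forward_batch(params,
    cocrystalgcn:::build_batch(list(pg), ctl_nc), ctl_nc)
  expect_false(isTRUE(all.equal(full$logit, nc_only$logit)))
  expect_error(gcn_control(use_covalent = FALSE, use_noncovalent = FALSE),
               "at least one")
})

test_that("training is deterministic, seeded and loss-reducing", {
  ds <- small_dataset()
  sp <- split_dataset(ds, seed = 33L)
  ctl <- gcn_control(epochs = 8L, batch_size = 32L)
  fit1 <- cocrystal_gcn(sp$train, sp$val, control = ctl, seed = 99L)
  fit2 <- cocrystal_gcn(sp$train, sp$val, control = ctl, seed = 99L)
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$history, fit2$history)

  # loss decreases on the planted-rule data
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])

  # zero learning rate leaves parameters at initialization
  ctl0 <- gcn_control(epochs = 2L, learning_rate = 0)
  fit0 <- cocrystal_gcn(sp$train, sp$val, control = ctl0, seed = 7L)
  init <- cocrystalgcn:::init_params(atom_feature_dim(), ctl0,
                                     cocrystalgcn:::derive_seed(7L, 1L))
  expect_equal(fit0$final_params, init, ignore_attr = TRUE)

  # single-class training set is rejected
  pos_only <- cocrystalgcn:::as_pair_dataset(sp$train[sp$train$label == 1L, ])
  expect_error(cocrystal_gcn(pos_only, control = ctl, seed = 1L), "both classes")
})

test_that("fitted models expose the standard modelling methods", {
  ds <- small_dataset()
  sp <- split_dataset(ds, seed = 42L)
  ctl <- gcn_control(epochs = 4L, batch_size = 32L)
  fit <- cocrystal_gcn(sp$train, sp$val, control = ctl, seed = 15L)

  expect_s3_class(fit, "cocrystal_gcn")
  expect_output(print(fit), "CocrystalGCN")
  expect_output(print(summary(fit)), "trainable parameters")
  expect_named(coef(fit), c("W1", "b1", "W2", "b2", "W_C", "W_NC",
                            "W_FC1", "b_FC1", "W_FC2", "b_FC2"))
  p <- predict(fit, sp$test)
  expect_length(p, nrow(sp$test))
  expect_true(all(p > 0 & p < 1))
  z <- predict(fit, sp$test, type = "logit")
  expect_equal(1 / (1 + exp(-z)), p, tolerance = 1e-12)
  cl <- predict(fit, sp$test, type = "class")
  expect_true(all(cl %in% 0:1))
  r <- residuals(fit)
  expect_equal(r, fit$data$label - fit$fitted)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(nrow(sp$train), 2L))

  # checkpoint round trip preserves predictions exactly
  path <- withr::local_tempfile(fileext = ".json")
  save_gcn(fit, path)
  back <- load_gcn(path)
  expect_equal(predict(back, sp$test), p, tolerance = 1e-12)
})

test_that("cross-validation reports per-fold and mean metrics", {
  ds <- small_dataset()
  ctl <- gcn_control(epochs = 3L, batch_size = 32L)
  cv <- cross_validate(ds, k = 2L, control = ctl, seed = 8L)
  expect_equal(nrow(cv$folds), 2L)
  expect_equal(unname(cv$mean["test_acc"]), mean(cv$folds$test_acc))
  expect_true(all(c("val_auc", "test_auc", "val_precision", "test_recall")
                  %in% names(cv$folds)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cv_report(cv, path)
  rep <- read.csv(path)
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$fold[3], "mean")
})
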