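# Small-scale model behavior tests; full learning checks live in
# test-acceptance.R.

tiny_config <- function(...) {
  args <- list(hidden_dim = 16, n_heads = 2, dropout = 0, batch_size = 32,
               max_epochs = 3, learning_rate = 3e-3, seed = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

tiny_dataset <- function(n = 120, seed = 3) {
  emb <- test_embedding()
  pt <- test_pseudo()
  gen_labeled_dataset(synthetic_config(seed = seed, n_peptides = n,
                                       n_alleles = length(pt)),
                      emb, pt)$data
}

test_that("forward is deterministic, in (0,1), and batch-consistent", {
  emb <- test_embedding()
  pt <- test_pseudo()
  model <- init_model(phla_feature_width(emb), tiny_config())
  g <- build_phla_graph("SIINFEKLM", "HLA-A*02:01", pt, emb)
  p1 <- forward(model, g)
  p2 <- forward(model, g)
  expect_identical(p1, p2)
  expect_gt(p1, 0); expect_lt(p1, 1)
  # batch of one equals forward; batch equals loop over singles
  pairs <- data.frame(peptide = c("SIINFEKLM", "ACDEFGHK"),
                      allele = c("HLA-A*02:01", "HLA-B*07:02"))
  bat <- predict_batch(pairs, model, emb, pt)
  expect_equal(bat$score[1], p1, tolerance = 1e-12)
  singles <- vapply(seq_len(2), function(i)
    forward(model, build_phla_graph(pairs$peptide[i], pairs$allele[i],
                                    pt, emb)), numeric(1))
  expect_equal(bat$score, singles, tolerance = 1e-6)
})

test_that("forward is invariant under node relabeling", {
  emb <- test_embedding()
  pt <- test_pseudo()
  model <- init_model(phla_feature_width(emb), tiny_config())
  g <- build_phla_graph("KVAELVHFL", "HLA-A*02:01", pt, emb)
  p0 <- forward(model, g)
  set.seed(11)
  for (r in 1:3) {
    perm <- sample(nrow(g$node_features))
    inv <- order(perm)
    gp <- g
    gp$node_features <- g$node_features[perm, , drop = FALSE]
    gp$node_types <- g$node_types[perm]
    gp$edges <- cbind(from = inv[g$edges[, 1]], to = inv[g$edges[, 2]])
    expect_equal(forward(model, gp), p0, tolerance = 1e-5)
  }
})

test_that("forward validates feature width and graph structure", {
  emb <- test_embedding()
  pt <- test_pseudo()
  model <- init_model(10, tiny_config())
  g <- build_phla_graph("SIINFEKLM", "HLA-A*02:01", pt, emb)
  expect_error(forward(model, g), "width")
  g2 <- g
  g2$edges <- g2$edges[-1, , drop = FALSE]
  model2 <- init_model(phla_feature_width(emb), tiny_config())
  expect_error(forward(model2, g2), "complete")
})

test_that("model gradients match finite differences", {
  emb <- test_embedding()
  pt <- test_pseudo()
  cfg <- model_config(hidden_dim = 8, n_heads = 2, dropout = 0, seed = 3)
  model <- init_model(phla_feature_width(emb), cfg)
  g1 <- build_phla_graph("SIINFEKLM", "HLA-A*02:01", pt, emb)
  g2 <- build_phla_graph("ACDEFGHK", "HLA-B*07:02", pt, emb)
  X <- list(g1$node_features, g2$node_features)
  vi <- as.integer(vapply(X, nrow, integer(1)))
  y <- c(1, 0)
  core <- immunograph:::gnn_batch_cpp
  res <- core(X, vi, y, model$params, cfg$n_layers, cfg$n_heads, 0, 0,
              TRUE, TRUE)
  lossf <- function(p) core(X, vi, y, p, cfg$n_layers, cfg$n_heads, 0, 0,
                            FALSE, FALSE)$loss
  base <- lossf(model$params)
  set.seed(5)
  for (nm in sample(names(model$params), 8)) {
    i <- sample(length(model$params[[nm]]), 1)
    pp <- model$params
    pp[[nm]][i] <- pp[[nm]][i] + 1e-6
    num <- (lossf(pp) - base) / 1e-6
    expect_equal(res$grads[[nm]][i], num, tolerance = 1e-3)
  }
})

test_that("training reduces loss and is seed-reproducible", {
  emb <- test_embedding()
  pt <- test_pseudo()
  ds <- tiny_dataset(160)
  cfg <- tiny_config(max_epochs = 5)
  fit1 <- train(ds, cfg, emb, pt)
  ep <- fit1$report$epochs
  expect_lt(ep$train_loss[nrow(ep)], ep$train_loss[1])
  expect_true(all(is.finite(ep$train_loss)))
  fit2 <- train(ds, cfg, emb, pt)
  expect_equal(fit1$report$epochs$train_loss,
               fit2$report$epochs$train_loss, tolerance = 1e-6)
  expect_identical(fit1$model$params, fit2$model$params)
})

test_that("training requires both classes", {
  ds <- tiny_dataset(60)
  ds$label <- 1
  expect_error(train(ds, tiny_config(), test_embedding(), test_pseudo()),
               "single class")
})

test_that("stratified split honors per-class floor rounding and seeding", {
  ds <- data.frame(peptide = sprintf("P%03d", 1:200),
                   allele = "HLA-A*02:01",
                   label = rep(c(1, 0), each = 100))
  sp <- stratified_split(ds, 0.7, seed = 1)
  expect_equal(sum(sp$train$label == 1), 70)
  expect_equal(sum(sp$train$label == 0), 70)
  expect_equal(nrow(sp$validation), 60)
  expect_equal(sort(c(rownames(sp$train), rownames(sp$validation))),
               sort(rownames(ds)))
  # 7 positives + 3 negatives: floor -> 4 + 2 in train
  ds2 <- data.frame(peptide = sprintf("Q%02d", 1:10), allele = "x",
                    label = c(rep(1, 7), rep(0, 3)))
  sp2 <- stratified_split(ds2, 0.7, seed = 2)
  expect_equal(sum(sp2$train$label == 1), 4)
  expect_equal(sum(sp2$train$label == 0), 2)
  # seeding contract
  spa <- stratified_split(ds, 0.7, seed = 5)
  spb <- stratified_split(ds, 0.7, seed = 5)
  spc <- stratified_split(ds, 0.7, seed = 6)
  expect_identical(spa$train, spb$train)
  expect_false(identical(spa$train, spc$train))
  expect_equal(table(spc$train$label), table(spa$train$label))
  expect_error(stratified_split(data.frame(label = c(1, 0, 0)), 0.7, 1),
               "at least 2")
})

test_that("grid search is exhaustive and returns the single-point grid", {
  emb <- test_embedding()
  pt <- test_pseudo()
  ds <- tiny_dataset(80)
  base <- tiny_config(max_epochs = 2)
  gs1 <- grid_search(ds, list(hidden_dim = 8), emb, pt, seed = 1,
                     base_config = base)
  expect_equal(gs1$best_config$hidden_dim, 8L)
  expect_equal(nrow(gs1$results), 1)
  gs <- grid_search(ds, list(hidden_dim = c(8, 16), dropout = c(0, 0.1)),
                    emb, pt, seed = 1, base_config = base)
  expect_equal(nrow(gs$results), 4)  # fits = product of grid sizes
  expect_error(grid_search(ds, list(), emb, pt), "non-empty")
})

test_that("cross-validation folds are stratified, exhaustive and serializable", {
  emb <- test_embedding()
  pt <- test_pseudo()
  ds <- tiny_dataset(100, seed = 9)
  k <- 5
  cv <- cross_validate(ds, k = k, tiny_config(max_epochs = 2), emb, pt,
                       seed = 4)
  expect_equal(nrow(cv$folds), k)
  expect_equal(sum(cv$folds$n_test), nrow(ds))
  for (f in seq_len(k)) {
    in_f <- cv$fold_assignment == f
    # stratification: fold class counts within 1 of n_class / k
    for (cl in 0:1) {
      n_cl <- sum(ds$label == cl)
      expect_lte(abs(sum(ds$label[in_f] == cl) - n_cl / k), 1)
    }
  }
  cv2 <- cross_validate(ds, k = k, tiny_config(max_epochs = 2), emb, pt,
                        seed = 4)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_equal(cv$oof_scores, cv2$oof_scores, tolerance = 1e-12)
  expect_error(cross_validate(ds[1:8, ], k = 5, tiny_config(), emb, pt),
               "at least k")
})

test_that("predict_batch preserves order and supports row-level skip", {
  emb <- test_embedding()
  pt <- test_pseudo()
  model <- init_model(phla_feature_width(emb), tiny_config())
  pairs <- data.frame(
    peptide = c("SIINFEKLM", "ACDEFGHK", "KVAELVHFL"),
    allele = c("HLA-A*02:01", "HLA-A*99:99", "HLA-B*07:02"))
  expect_error(predict_batch(pairs, model, emb, pt), "row 2")
  out <- predict_batch(pairs, model, emb, pt, on_error = "skip")
  expect_equal(nrow(out), 3)
  expect_true(is.na(out$score[2]) && !is.na(out$error[2]))
  expect_equal(sum(!is.na(out$score)), 2)
  expect_equal(out$peptide, pairs$peptide)
  empty <- predict_batch(pairs[0, ], model, emb, pt)
  expect_equal(nrow(empty), 0)
})

test_that("configuration is validated", {
  expect_error(model_config(hidden_dim = 30, n_heads = 4))  # not divisible
  expect_error(model_config(dropout = 1))
  expect_error(model_config(n_layers = 0))
  expect_equal(model_config()$n_layers, 3L)
})
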