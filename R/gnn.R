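# The pHLA immunogenicity classifier: multi-head attention message passing
# over the fully connected peptide-HLA graph in a pre-norm arrangement
# (GraphNorm on each layer's input, attention + root weight, dropout,
# identity residual skip), a final GraphNorm, virtual-node readout and a
# one-hidden-layer perceptron with sigmoid output, trained with binary
# cross-entropy and Adam (linear warmup, global-norm gradient clipping).
# The numerical core (forward + exact backprop) lives in
# src/gnn_core.cpp; this file owns configuration, parameter
# initialization, the optimizer loop, splitting, grid search and k-fold
# cross-validation.

#' Model configuration
#'
#' @param n_layers Number of message-passing layers (default 3).
#' @param hidden_dim Width of node states; must be divisible by `n_heads`.
#' @param n_heads Number of attention heads.
#' @param dropout Dropout probability in `[0, 1)` applied to node states
#'   after each layer and to the perceptron hidden layer during training.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without validation-AUC improvement
#'   before stopping (only used when a validation set is supplied).
#' @param seed Seed fixing initialization, shuffling and dropout.
#' @return A `model_config` list.
#' @export
model_config <- function(n_layers = 3, hidden_dim = 64, n_heads = 4,
                         dropout = 0.1, learning_rate = 1e-3,
                         batch_size = 128, max_epochs = 50,
                         early_stop_patience = 10, seed = 1) {
  stopifnot(n_layers >= 1, hidden_dim >= n_heads,
            hidden_dim %% n_heads == 0,
            dropout >= 0, dropout < 1,
            learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            early_stop_patience >= 1)
  structure(list(n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 n_heads = as.integer(n_heads),
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed)),
            class = "model_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize an untrained model
#'
#' Parameter draws are Glorot-uniform and fully determined by
#' `config$seed`; GraphNorm scale/shift start at (1, 0) and the mean-scale
#' at 1.
#'
#' @param input_dim Node-feature width (see [phla_feature_width()]).
#' @param config A [model_config()].
#' @return An `immuno_gnn` model object.
#' @export
init_model <- function(input_dim, config = model_config()) {
  stopifnot(inherits(config, "model_config"), input_dim >= 1)
  d <- config$hidden_dim
  h2 <- max(2L, d %/% 2L)
  params <- with_local_seed(config$seed, {
    p <- list()
    din <- input_dim
    for (l in seq_len(config$n_layers)) {
      pre <- paste0("L", l, ".")
      p[[paste0(pre, "Wq")]] <- glorot(din, d)
      p[[paste0(pre, "Wk")]] <- glorot(din, d)
      p[[paste0(pre, "Wv")]] <- glorot(din, d)
      p[[paste0(pre, "Wr")]] <- glorot(din, d)
      p[[paste0(pre, "b")]] <- numeric(d)
      # GraphNorm acts on the layer *input* (pre-norm), hence width din
      p[[paste0(pre, "gamma")]] <- rep(1, din)
      p[[paste0(pre, "beta")]] <- numeric(din)
      p[[paste0(pre, "alpha")]] <- rep(1, din)
      din <- d
    }
    p[["GN.gamma"]] <- rep(1, d)  # final pre-readout GraphNorm
    p[["GN.beta"]] <- numeric(d)
    p[["GN.alpha"]] <- rep(1, d)
    p[["mlp.W1"]] <- glorot(d, h2)
    p[["mlp.b1"]] <- numeric(h2)
    p[["mlp.W2"]] <- glorot(h2, 1L)
    p[["mlp.b2"]] <- 0
    p
  })
  structure(list(params = params, config = config,
                 input_dim = as.integer(input_dim), trained = FALSE),
            class = "immuno_gnn")
}

#' @export
print.immuno_gnn <- function(x, ...) {
  cat("pHLA attention classifier:", x$config$n_layers,
      "attention layers, hidden",
      x$config$hidden_dim, "x", x$config$n_heads, "heads, input width",
      x$input_dim, if (x$trained) "(trained)" else "(untrained)", "\n")
  invisible(x)
}

#' Total number of trainable parameters
#' @param model An `immuno_gnn`.
#' @return Integer count.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

check_phla_graph <- function(graph) {
  stopifnot(inherits(graph, "phla_graph"))
  n <- nrow(graph$node_features)
  if (nrow(graph$edges) != n * (n - 1) || any(graph$edges[, 1] == graph$edges[, 2]))
    stop("forward: graph is not a complete digraph without self-loops")
  vi <- which(graph$node_types == "virtual")
  if (length(vi) != 1) stop("forward: graph must have exactly one virtual node")
  vi
}

#' Score one peptide-HLA graph
#'
#' Runs the attention message-passing layers (GraphNorm on each layer's
#' input, multi-head attention over all ordered node pairs, residual
#' stream), the final normalization and the perceptron head in evaluation
#' mode (dropout off); deterministic for a fixed model and graph.  Because
#' the graph is complete and the readout uses the virtual node, the score
#' is invariant under any relabeling of the nodes that tracks the virtual
#' node.
#'
#' @param model An `immuno_gnn`.
#' @param graph A `phla_graph`.
#' @return A probability strictly in (0, 1).
#' @export
forward <- function(model, graph) {
  stopifnot(inherits(model, "immuno_gnn"))
  vi <- check_phla_graph(graph)
  if (ncol(graph$node_features) != model$input_dim)
    stop("forward: node feature width ", ncol(graph$node_features),
         " does not match model input width ", model$input_dim)
  res <- gnn_batch_cpp(list(graph$node_features), as.integer(vi), numeric(0),
                       model$params, model$config$n_layers,
                       model$config$n_heads, 0, 0, FALSE, FALSE)
  res$probs[1]
}

# Internal batched forward on prebuilt matrices (eval mode).
predict_graph_matrices <- function(model, Xlist, vidx) {
  if (length(Xlist) == 0) return(numeric(0))
  gnn_batch_cpp(Xlist, as.integer(vidx), numeric(0), model$params,
                model$config$n_layers, model$config$n_heads,
                0, 0, FALSE, FALSE)$probs
}

build_graph_matrices <- function(peptides, alleles, emb, pseudo_table) {
  lapply(seq_along(peptides), function(i) {
    g <- build_phla_graph(peptides[i], alleles[i], pseudo_table, emb)
    g$node_features
  })
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  if (is.finite(clip)) {  # global-norm gradient clipping
    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (gnorm > clip) grads <- lapply(grads, function(g) g * clip / gnorm)
  }
  st$t <- st$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

check_dataset <- function(dataset) {
  dataset <- as.data.frame(dataset)
  stopifnot(all(c("peptide", "allele", "label") %in% names(dataset)))
  if (nrow(dataset) == 0) stop("dataset is empty")
  if (!all(dataset$label %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(dataset$label)) < 2)
    stop("dataset contains a single class; both labels are required")
  dataset
}

#' Train the classifier
#'
#' Minimizes binary cross-entropy with Adam on minibatches.  All
#' randomness (initialization, shuffling, dropout) derives from
#' `config$seed`, so identical calls reproduce identical models.  When a
#' validation set is supplied, training early-stops on validation AUC and
#' the best-epoch parameters are restored; pass `early_stop = FALSE` for a
#' faithful fixed-epoch run.
#'
#' @param dataset Data frame with columns `peptide`, `allele`, `label`
#'   (0/1), e.g. a curated dataset or [gen_labeled_dataset()] output.
#' @param config A [model_config()].
#' @param emb An `aa_feature_table`.
#' @param pseudo_table A `pseudo_sequence_table`.
#' @param validation Optional data frame with the same columns.
#' @param early_stop Use validation-AUC early stopping (default TRUE when
#'   `validation` is given).
#' @param verbose Print per-epoch progress.
#' @return List with `model` (trained `immuno_gnn`) and `report`
#'   (`train_report`: per-epoch losses/AUCs, best epoch).
#' @export
train <- function(dataset, config = model_config(), emb, pseudo_table,
                  validation = NULL, early_stop = !is.null(validation),
                  verbose = FALSE) {
  dataset <- check_dataset(dataset)
  model <- init_model(phla_feature_width(emb), config)
  X <- build_graph_matrices(dataset$peptide, dataset$allele, emb, pseudo_table)
  vidx <- vapply(X, nrow, integer(1))  # virtual node is last
  y <- as.numeric(dataset$label)
  Xval <- NULL
  if (!is.null(validation)) {
    validation <- as.data.frame(validation)
    Xval <- build_graph_matrices(validation$peptide, validation$allele,
                                 emb, pseudo_table)
    vval <- vapply(Xval, nrow, integer(1))
    yval <- as.numeric(validation$label)
  }

  params <- model$params
  st <- adam_state(params)
  n <- length(X)
  epochs <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0), val_auc = numeric(0))
  best <- list(auc = -Inf, params = params, epoch = 0L)
  wait <- 0L

  warmup_steps <- 50  # linear learning-rate warmup, standard for attention
  step <- 0L
  with_local_seed(config$seed + 1L, {
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        drop_seed <- sample.int(.Machine$integer.max, 1)
        res <- gnn_batch_cpp(X[idx], as.integer(vidx[idx]), y[idx], params,
                             config$n_layers, config$n_heads, config$dropout,
                             drop_seed, TRUE, TRUE)
        step <- step + 1L
        lr <- config$learning_rate * min(1, step / warmup_steps)
        upd <- adam_step(params, res$grads, st, lr)
        params <- upd$params
        st <- upd$state
        losses <- c(losses, res$loss * length(idx))
      }
      train_loss <- sum(losses) / n
      val_loss <- NA_real_
      val_auc <- NA_real_
      if (!is.null(Xval)) {
        tmp_model <- model
        tmp_model$params <- params
        pv <- predict_graph_matrices(tmp_model, Xval, vval)
        pvc <- pmin(pmax(pv, 1e-12), 1 - 1e-12)
        val_loss <- -mean(yval * log(pvc) + (1 - yval) * log(1 - pvc))
        val_auc <- roc_auc(pv, yval)
        if (val_auc > best$auc + 1e-9) {
          best <- list(auc = val_auc, params = params, epoch = ep)
          wait <- 0L
        } else wait <- wait + 1L
      }
      epochs[nrow(epochs) + 1L, ] <- list(ep, train_loss, val_loss, val_auc)
      if (verbose)
        message(sprintf("epoch %d: train loss %.4f val auc %s", ep,
                        train_loss,
                        ifelse(is.na(val_auc), "-", sprintf("%.4f", val_auc))))
      if (early_stop && !is.null(Xval) && wait >= config$early_stop_patience)
        break
    }
  })
  if (early_stop && !is.null(Xval) && best$epoch > 0L) params <- best$params
  model$params <- params
  model$trained <- TRUE
  report <- structure(list(epochs = epochs,
                           best_epoch = if (!is.null(Xval)) best$epoch else
                             nrow(epochs),
                           best_val_auc = if (!is.null(Xval)) best$auc else
                             NA_real_),
                      class = "train_report")
  list(model = model, report = report)
}

#' @export
print.train_report <- function(x, ...) {
  cat("Training report:", nrow(x$epochs), "epochs, final train loss",
      sprintf("%.4f", x$epochs$train_loss[nrow(x$epochs)]))
  if (!is.na(x$best_val_auc))
    cat(", best val AUC", sprintf("%.4f", x$best_val_auc),
        "at epoch", x$best_epoch)
  cat("\n")
  invisible(x)
}

#' Stratified train/validation split
#'
#' Per class, `floor(n * train_fraction)` instances go to the training set
#' and the remainder to validation, so a 70/30 split of 100+100 gives
#' 70+70 training instances.
#'
#' @param dataset Data frame with a `label` column.
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param seed Seed for the per-class shuffles.
#' @return List with `train` and `validation` data frames (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(dataset, train_fraction = 0.7, seed = 1) {
  dataset <- as.data.frame(dataset)
  stopifnot("label" %in% names(dataset), train_fraction > 0, train_fraction < 1)
  counts <- table(dataset$label)
  if (any(counts < 2))
    stop("stratified_split: every class needs at least 2 members")
  train_idx <- with_local_seed(seed, {
    unlist(lapply(unique(dataset$label), function(cl) {
      idx <- which(dataset$label == cl)
      sample(idx, floor(length(idx) * train_fraction))
    }), use.names = FALSE)
  })
  list(train = dataset[sort(train_idx), , drop = FALSE],
       validation = dataset[setdiff(seq_len(nrow(dataset)), train_idx), ,
                            drop = FALSE])
}

#' Grid search over hyperparameters
#'
#' Trains every combination on a stratified 70% split and selects the
#' configuration with the highest validation AUC; ties break toward fewer
#' parameters, then grid order.
#'
#' @param dataset Labeled data frame (`peptide`, `allele`, `label`).
#' @param grid Named list mapping [model_config()] fields to value vectors.
#' @param emb,pseudo_table Featurization inputs as in [train()].
#' @param seed Seed for the split and the base config.
#' @param base_config Defaults for fields absent from `grid`.
#' @return List with `best_config` and `results` (one row per
#'   combination: parameters, validation AUC, parameter count).
#' @export
grid_search <- function(dataset, grid, emb, pseudo_table, seed = 1,
                        base_config = model_config(seed = seed)) {
  if (!is.list(grid) || length(grid) == 0 ||
      any(!nzchar(names(grid))) || any(lengths(grid) == 0))
    stop("grid_search: grid must be a non-empty named list of value vectors")
  combos <- expand.grid(grid, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  sp <- stratified_split(dataset, 0.7, seed)
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg_args <- as.list(base_config)
    cfg_args[names(combos)] <- as.list(combos[i, , drop = FALSE])
    cfg <- do.call(model_config, cfg_args)
    fit <- train(sp$train, cfg, emb, pseudo_table,
                 validation = sp$validation, early_stop = FALSE)
    preds <- predict_batch(sp$validation[, c("peptide", "allele")],
                           fit$model, emb, pseudo_table)
    rows[[i]] <- data.frame(combos[i, , drop = FALSE],
                            val_auc = roc_auc(preds$score,
                                              sp$validation$label),
                            n_params = n_params(fit$model))
  }
  results <- do.call(rbind, rows)
  results$fit_index <- seq_len(nrow(results))
  ord <- order(-results$val_auc, results$n_params, results$fit_index)
  best_row <- combos[ord[1], , drop = FALSE]
  cfg_args <- as.list(base_config)
  cfg_args[names(best_row)] <- as.list(best_row)
  list(best_config = do.call(model_config, cfg_args), results = results)
}

#' Stratified k-fold cross-validation
#'
#' Assigns stratified folds (deterministically from `seed` and dataset
#' order), trains on each complement for a fixed number of epochs and
#' reports out-of-fold AUC, sensitivity and F1.
#'
#' @inheritParams train
#' @param k Number of folds (default 10); every class must have at least
#'   `k` members.
#' @param seed Seed for fold assignment.
#' @return A `cv_report`: list with `folds` (per-fold metric data frame),
#'   `mean`/`sd` summaries, `fold_assignment` (integer vector, serializable
#'   and reusable), and `oof_scores` (out-of-fold predicted probabilities).
#' @export
cross_validate <- function(dataset, k = 10, config = model_config(), emb,
                           pseudo_table, seed = 1) {
  dataset <- check_dataset(dataset)
  counts <- table(dataset$label)
  if (any(counts < k))
    stop("cross_validate: every class needs at least k = ", k, " members")
  fold <- integer(nrow(dataset))
  with_local_seed(seed, {
    for (cl in unique(dataset$label)) {
      idx <- which(dataset$label == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  oof <- numeric(nrow(dataset))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- dataset[fold != f, , drop = FALSE]
    te <- dataset[fold == f, , drop = FALSE]
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- train(tr, cfg, emb, pseudo_table, early_stop = FALSE)
    preds <- predict_batch(te[, c("peptide", "allele")], fit$model, emb,
                           pseudo_table)
    oof[fold == f] <- preds$score
    rows[[f]] <- data.frame(fold = f,
                            n_test = nrow(te),
                            auc = roc_auc(preds$score, te$label),
                            sensitivity = sensitivity(preds$score, te$label),
                            f1 = f1(preds$score, te$label))
  }
  folds <- do.call(rbind, rows)
  structure(list(folds = folds,
                 mean = colMeans(folds[, c("auc", "sensitivity", "f1")]),
                 sd = vapply(folds[, c("auc", "sensitivity", "f1")], sd,
                             numeric(1)),
                 fold_assignment = fold,
                 oof_scores = oof,
                 labels = dataset$label,
                 k = k),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV: AUC %.4f +/- %.4f, sensitivity %.4f, F1 %.4f\n",
              x$k, x$mean["auc"], x$sd["auc"], x$mean["sensitivity"],
              x$mean["f1"]))
  invisible(x)
}

#' Score a batch of peptide-allele pairs
#'
#' Order-preserving; with `on_error = "skip"` a bad row (unknown allele,
#' invalid peptide length or character) is reported in the `error` column
#' while the rest of the batch is scored.
#'
#' @param pairs Data frame with columns `peptide` and `allele`.
#' @param model A trained (or, deliberately, untrained) `immuno_gnn`.
#' @param emb,pseudo_table Featurization inputs as in [train()].
#' @param on_error `"stop"` (default) or `"skip"`.
#' @return Data frame with columns `peptide`, `allele`, `score`, `error`
#'   (`NA` for clean rows).
#' @export
predict_batch <- function(pairs, model, emb, pseudo_table,
                          on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0)
    return(data.frame(peptide = character(0), allele = character(0),
                      score = numeric(0), error = character(0)))
  stopifnot(all(c("peptide", "allele") %in% names(pairs)))
  graphs <- vector("list", nrow(pairs))
  errs <- rep(NA_character_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g <- tryCatch(build_phla_graph(pairs$peptide[i], pairs$allele[i],
                                   pseudo_table, emb),
                  error = function(e) e)
    if (inherits(g, "error")) {
      if (on_error == "stop") stop("predict_batch row ", i, ": ",
                                   conditionMessage(g))
      errs[i] <- conditionMessage(g)
    } else graphs[[i]] <- g$node_features
  }
  ok <- which(is.na(errs))
  scores <- rep(NA_real_, nrow(pairs))
  if (length(ok))
    scores[ok] <- predict_graph_matrices(
      model, graphs[ok], vapply(graphs[ok], nrow, integer(1)))
  data.frame(peptide = pairs$peptide, allele = pairs$allele,
             score = scores, error = errs, stringsAsFactors = FALSE)
}
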