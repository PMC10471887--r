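#' Training configuration
#'
#' Defaults follow the reference protocol: stochastic gradient descent with
#' learning rate 0.001, momentum 0.9, weight decay 1e-6, batch size 16,
#' 200 epochs and five-fold cross-validation, with the incomplete final
#' batch kept. Model selection keeps the weights of the epoch with the
#' highest training accuracy (earliest epoch on ties).
#'
#' @param learning_rate,momentum,weight_decay SGD hyperparameters.
#' @param batch_size minibatch size.
#' @param epochs number of passes over the training fold.
#' @param n_folds number of cross-validation folds.
#' @param seed integer seed controlling fold assignment, weight
#'   initialization and epoch shuffling.
#' @param grouping `"scene"` (default) splits scenes freely; `"patient"`
#'   keeps all scenes of a patient in one fold (leakage-safe mode).
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, momentum = 0.9,
                         weight_decay = 1e-6, batch_size = 16, epochs = 200,
                         n_folds = 5, seed = 1L,
                         grouping = c("scene", "patient")) {
  if (learning_rate < 0 || momentum < 0 || weight_decay < 0) {
    stop_config("rates must be non-negative")
  }
  if (batch_size < 1) stop_config("batch_size must be >= 1")
  if (n_folds < 2) stop_config("n_folds must be >= 2")
  if (epochs < 1) stop_config("epochs must be >= 1")
  grouping <- match.arg(grouping)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), n_folds = as.integer(n_folds),
                 seed = as.integer(seed), grouping = grouping),
            class = "train_config")
}

#' Stratified cross-validation folds
#'
#' Partitions the manifest's scenes into `n_folds` test folds, stratified by
#' label: each class is shuffled (seeded) and dealt round-robin, so per-fold
#' class counts differ from perfect proportionality by at most one scene.
#' With `grouping = "patient"` whole patients are dealt instead, balancing
#' scene counts greedily within each class.
#'
#' @param manifest a `dataset_manifest`.
#' @param cfg a [train_config()] (uses `n_folds`, `seed`, `grouping`).
#' @return a `fold_split`: list of `n_folds` elements, each with `train` and
#'   `test` scene-id vectors.
#' @export
make_folds <- function(manifest, cfg = train_config()) {
  s <- manifest$samples
  if (nrow(s) == 0) stop_data("manifest is empty")
  k <- cfg$n_folds
  for (lab in unique(s$label)) {
    n_lab <- if (cfg$grouping == "patient") {
      length(unique(s$patient_id[s$label == lab]))
    } else {
      sum(s$label == lab)
    }
    if (n_lab < k) {
      stop_data("class '%s' has only %d %s but %d folds were requested",
                lab, n_lab,
                if (cfg$grouping == "patient") "patients" else "scenes", k,
                subclass = "fusenet_class_too_small")
    }
  }
  assign_fold <- integer(nrow(s))
  with_seed(derive_seed(cfg$seed, "folds"), {
    for (lab in unique(s$label)) {
      idx <- which(s$label == lab)
      if (cfg$grouping == "scene") {
        idx <- idx[sample.int(length(idx))]
        assign_fold[idx] <- rep_len(seq_len(k), length(idx))
      } else {
        pats <- unique(s$patient_id[idx])
        pats <- pats[sample.int(length(pats))]
        sizes <- vapply(pats, function(p) sum(s$patient_id == p), 0L)
        load <- numeric(k)
        for (j in order(sizes, decreasing = TRUE)) {
          f <- which.min(load)
          assign_fold[idx[s$patient_id[idx] == pats[j]]] <- f
          load[f] <- load[f] + sizes[j]
        }
      }
    }
  })
  folds <- lapply(seq_len(k), function(f) {
    list(train = s$scene_id[assign_fold != f],
         test = s$scene_id[assign_fold == f])
  })
  structure(folds, class = "fold_split")
}

# Load, preprocess and stack a set of scenes; returns the (C,H,W,N) tensor
# and integer labels (1 = benign, 2 = malignant).
prepare_tensor <- function(manifest, scene_ids, pre_cfg) {
  imgs <- lapply(scene_ids, function(id) {
    preprocess(load_scene(manifest, id)$pixels, pre_cfg)
  })
  lab <- manifest$samples$label[match(scene_ids, manifest$samples$scene_id)]
  list(x = as_batch(imgs), y = ifelse(lab == "malignant", 2L, 1L),
       label = lab)
}

sgd_step <- function(params, grads, velocity, lr, momentum, weight_decay) {
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      if (is.null(g)) next
      g <- g + weight_decay * params[[nm]][[pn]]
      v <- velocity[[nm]][[pn]]
      v <- if (is.null(v)) g else momentum * v + g
      velocity[[nm]][[pn]] <- v
      params[[nm]][[pn]] <- params[[nm]][[pn]] - lr * v
    }
  }
  list(params = params, velocity = velocity)
}

#' Train a model by minibatch SGD
#'
#' Cross-entropy loss over the class logits; SGD with momentum and weight
#' decay; seeded shuffling each epoch; the incomplete final batch is kept.
#' Per-epoch training accuracy is the fraction of correct argmax predictions
#' accumulated over the epoch's minibatches. The returned model carries the
#' weights of the epoch with the highest training accuracy (earliest on
#' ties), mirroring best-training-accuracy checkpoint selection.
#'
#' @param model a `dcfcnn_model` from [init_model()].
#' @param x training tensor (C, H, W, N) from [as_batch()].
#' @param y integer class labels in 1..num_classes.
#' @param cfg a [train_config()].
#' @return list with `model` (selected weights), `final_model`, `history`
#'   (data.frame epoch/loss/accuracy) and `best_epoch`.
#' @export
train_model <- function(model, x, y, cfg = train_config()) {
  n <- dim(x)[4]
  if (n == 0) stop_data("empty training set")
  if (length(y) != n) stop_data("labels do not match the batch")
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  velocity <- list()
  best <- list(acc = -Inf, epoch = NA_integer_, params = NULL, state = NULL)
  for (epoch in seq_len(cfg$epochs)) {
    perm <- with_seed(derive_seed(cfg$seed, paste0("epoch", epoch)),
                      sample.int(n))
    starts <- seq(1, n, by = cfg$batch_size)
    tot_loss <- 0; tot_correct <- 0
    for (s0 in starts) {
      idx <- perm[s0:min(s0 + cfg$batch_size - 1, n)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[idx]
      fwd <- nn_forward(model, xb, train = TRUE)
      model$state <- fwd$state
      ls <- softmax_xent(fwd$out, yb)
      if (!is.finite(ls$loss)) {
        stop_numeric("non-finite loss at epoch %d, batch starting %d",
                     epoch, s0)
      }
      pred <- max.col(t(ls$probs), ties.method = "first")
      tot_correct <- tot_correct + sum(pred == yb)
      tot_loss <- tot_loss + ls$loss * length(idx)
      grads <- nn_backward(model, fwd, ls$dlogits)
      upd <- sgd_step(model$params, grads, velocity, cfg$learning_rate,
                      cfg$momentum, cfg$weight_decay)
      model$params <- upd$params
      velocity <- upd$velocity
    }
    acc <- tot_correct / n
    history <- rbind(history, data.frame(epoch = epoch, loss = tot_loss / n,
                                         accuracy = acc))
    if (acc > best$acc) {
      best <- list(acc = acc, epoch = epoch, params = model$params,
                   state = model$state)
    }
  }
  selected <- model
  selected$params <- best$params
  selected$state <- best$state
  list(model = selected, final_model = model, history = history,
       best_epoch = best$epoch)
}

#' Train on one cross-validation fold
#'
#' Computes per-channel statistics on the training split, preprocesses both
#' splits with them, initializes a fresh network (seed derived from the fold)
#' and trains it; test predictions come from the selected checkpoint in
#' evaluation mode.
#'
#' @param manifest a `dataset_manifest`.
#' @param fold one element of a [make_folds()] split.
#' @param arch an [arch_config()].
#' @param pre a [preprocess_config()]; its channel statistics are replaced by
#'   statistics of the fold's training split.
#' @param cfg a [train_config()].
#' @param fold_id integer used to derive the fold's seeds.
#' @return list with `result` (as [train_model()]), `predictions`
#'   (data.frame: scene_id, truth, pred, score) and the channel stats used.
#' @export
train_fold <- function(manifest, fold, arch, pre, cfg, fold_id = 1L) {
  if (length(fold$train) == 0) stop_data("empty training fold")
  train_imgs <- lapply(fold$train, function(id) load_scene(manifest, id)$pixels)
  st <- channel_stats(train_imgs)
  pre_fold <- preprocess_config(short_edge = pre$short_edge,
                                crop_size = pre$crop_size,
                                channel_mean = st$mean, channel_std = st$std)
  tr_imgs <- lapply(train_imgs, preprocess, cfg = pre_fold)
  xtr <- as_batch(tr_imgs)
  lab <- manifest$samples$label[match(fold$train, manifest$samples$scene_id)]
  ytr <- ifelse(lab == "malignant", 2L, 1L)
  model <- init_model(build_dcfcnn(arch),
                      seed = derive_seed(cfg$seed, paste0("init", fold_id)))
  res <- train_model(model, xtr, ytr, cfg)
  preds <- NULL
  if (length(fold$test) > 0) {
    te <- prepare_tensor(manifest, fold$test, pre_fold)
    probs <- predict_proba(res$model, te$x)
    preds <- data.frame(scene_id = fold$test,
                        truth = te$label,
                        pred = ifelse(probs[2, ] >= probs[1, ],
                                      "malignant", "benign"),
                        score = probs[2, ],
                        stringsAsFactors = FALSE)
  }
  list(result = res, predictions = preds, channel_stats = st)
}

#' Full cross-validated training and evaluation
#'
#' Runs [make_folds()], trains one model per fold and evaluates it on the
#' held-out fold, then aggregates the metric reports.
#'
#' @inheritParams train_fold
#' @return list with `folds`, per-fold `reports`, `aggregate` and the
#'   per-fold prediction tables.
#' @export
run_cv <- function(manifest, arch = arch_config(),
                   pre = preprocess_config(), cfg = train_config()) {
  folds <- make_folds(manifest, cfg)
  fold_out <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    fold_out[[i]] <- train_fold(manifest, folds[[i]], arch, pre, cfg,
                                fold_id = i)
  }
  reports <- lapply(fold_out, function(f) compute_metrics(f$predictions))
  agg <- aggregate_metrics(reports)
  list(folds = folds,
       histories = lapply(fold_out, function(f) f$result$history),
       predictions = lapply(fold_out, function(f) f$predictions),
       reports = reports, aggregate = agg)
}
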