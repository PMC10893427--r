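#' Training configuration
#'
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size samples per task per optimization step (default 128).
#' @param patience early-stopping patience in epochs (default 10).
#' @param max_epochs maximum number of epochs (default 500).
#' @param seed integer seed for batching and balancing.
#' @param balance `"oversample"` (per-epoch resampling of each task's
#'   minority class with replacement up to the majority size, reshuffled
#'   every epoch; the default), `"undersample"` (majority class subsampled
#'   down to the minority size) or `"none"`.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 0.001, batch_size = 128L, patience = 10L,
                         max_epochs = 500L, seed = 1L,
                         balance = c("oversample", "undersample", "none")) {
  balance <- match.arg(balance)
  if (lr <= 0 || batch_size < 1L || patience < 1L || max_epochs < 1L)
    stop("lr, batch_size, patience and max_epochs must be positive")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), balance = balance),
            class = "train_config")
}

#' Per-task binary cross-entropy losses and their sum
#'
#' The validator and link-predictor heads each receive their own mean binary
#' cross-entropy; the shared embedding block is trained on the unweighted sum
#' of both. An empty batch for a task contributes a zero loss.
#'
#' @param v_probs,v_labels validator probabilities and 0/1 labels.
#' @param l_probs,l_labels link-predictor probabilities and 0/1 labels.
#' @return list with `loss_V`, `loss_L`, `loss_E` (= `loss_V + loss_L`).
#' @export
multitask_loss <- function(v_probs, v_labels, l_probs, l_labels) {
  lv <- bce_loss(v_probs, v_labels)
  ll <- bce_loss(l_probs, l_labels)
  list(loss_V = lv, loss_L = ll, loss_E = lv + ll)
}

#' Balanced index sample for one task
#'
#' Equalizes the two classes either by resampling the minority with
#' replacement up to the majority size (`"oversample"`) or by subsampling
#' the majority down to the minority size (`"undersample"`), then shuffles.
#' Uses the global RNG, so successive epochs draw different subsets.
#'
#' @param labels 0/1 vector.
#' @param mode `"oversample"`, `"undersample"` or `"none"`.
#' @param task task name used in error messages.
#' @return integer indices into `labels`.
#' @export
balance_indices <- function(labels, mode = "oversample", task = "task") {
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  if (!length(pos)) stop(task, ": class 1 absent, cannot balance")
  if (!length(neg)) stop(task, ": class 0 absent, cannot balance")
  if (mode == "none") return(sample(c(pos, neg)))
  m <- if (mode == "oversample") max(length(pos), length(neg))
       else min(length(pos), length(neg))
  take <- function(x) if (length(x) == m) x
                      else sample(x, m, replace = m > length(x))
  sample(c(take(pos), take(neg)))
}

#' Seed every stochastic component
#'
#' All randomness in the package (data generation, weight initialization,
#' balancing, batching) flows through R's global RNG, so one call makes an
#' end-to-end run reproducible.
#'
#' @param seed integer seed.
#' @export
set_global_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(NULL)
}

#' Early-stopping trace over a validation-loss sequence
#'
#' Pure bookkeeping of the stopping rule: training stops after the first
#' epoch whose distance from the best validation loss reaches the patience,
#' and the best epoch's parameters are the ones kept.
#'
#' @param val_losses per-epoch validation losses, in order.
#' @param patience epochs to wait without improvement.
#' @return list with `stop_epoch` (last epoch run) and `best_epoch`.
#' @export
early_stop_trace <- function(val_losses, patience) {
  best <- Inf; best_epoch <- 0L; wait <- 0L
  for (i in seq_along(val_losses)) {
    if (val_losses[i] < best - 1e-12) {
      best <- val_losses[i]; best_epoch <- i; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(list(stop_epoch = i,
                                        best_epoch = best_epoch))
    }
  }
  list(stop_epoch = length(val_losses), best_epoch = best_epoch)
}

# ---- internal: tensors for one split ---------------------------------------
# Flattens a list of labeled samples into the arrays the trainer consumes:
# per-graph embedding matrices and validator labels, plus one long link table
# (parent graph index, candidate embedding, label).
prepare_split <- function(samples, F) {
  emb <- lapply(samples, `[[`, "emb")
  v_labels <- vapply(samples, `[[`, 0L, "valid")
  nlk <- vapply(samples, function(s) length(s$link_label), 1L)
  l_parent <- rep(seq_along(samples), nlk)
  l_emb <- do.call(rbind, lapply(samples, `[[`, "link_emb"))
  if (is.null(l_emb)) l_emb <- matrix(0, 0, F)
  l_labels <- as.integer(unlist(lapply(samples, `[[`, "link_label")))
  list(emb = emb, v_labels = v_labels, l_parent = l_parent,
       l_emb = l_emb, l_labels = l_labels)
}

# forward + analytic backward for one joint batch; v_rows / l_parent index
# into emb_list. Returns parameter gradients with the multi-task routing:
# head gradients from their own loss only, embedding-block gradients from
# the sum.
model_gradients <- function(model, emb_list, v_rows, v_labels,
                            l_parent, l_emb, l_labels) {
  b <- build_batch(emb_list, model)
  fw <- gat_forward(model, b$X, b$gidx, b$last_idx, b$nG)
  E <- fw$E
  dE <- matrix(0, b$nG, model$out_width)
  loss_V <- 0; loss_L <- 0
  grads_V <- zero_grads(model$params$V)
  grads_L <- zero_grads(model$params$L)
  v_probs <- numeric(0); l_probs <- numeric(0)

  if (length(v_rows)) {
    fwV <- mlp_forward(model$params$V, E[v_rows, , drop = FALSE])
    v_probs <- fwV$prob
    loss_V <- bce_loss(v_probs, v_labels)
    dlogit <- (v_probs - v_labels) / length(v_labels)
    bwV <- mlp_backward(model$params$V, fwV$caches, dlogit)
    grads_V <- bwV$grads
    for (i in seq_along(v_rows))
      dE[v_rows[i], ] <- dE[v_rows[i], ] + bwV$dX[i, ]
  }
  if (length(l_parent)) {
    inp <- cbind(E[l_parent, , drop = FALSE], l_emb)
    fwL <- mlp_forward(model$params$L, inp)
    l_probs <- fwL$prob
    loss_L <- bce_loss(l_probs, l_labels)
    dlogit <- (l_probs - l_labels) / length(l_labels)
    bwL <- mlp_backward(model$params$L, fwL$caches, dlogit)
    grads_L <- bwL$grads
    dE_l <- rowsum(bwL$dX[, seq_len(model$out_width), drop = FALSE],
                   l_parent)
    rows <- as.integer(rownames(dE_l))
    dE[rows, ] <- dE[rows, ] + dE_l
  }
  grads_gat <- gat_backward(model, fw$cache, dE)
  list(grads = list(gat = grads_gat, V = grads_V, L = grads_L),
       loss_V = loss_V, loss_L = loss_L,
       v_probs = v_probs, l_probs = l_probs)
}

# full-split losses at the current parameters (natural distribution)
split_losses <- function(model, prep) {
  b <- build_batch(prep$emb, model)
  E <- gat_forward(model, b$X, b$gidx, b$last_idx, b$nG)$E
  v_probs <- mlp_forward(model$params$V, E)$prob
  lv <- bce_loss(v_probs, prep$v_labels)
  ll <- 0
  if (length(prep$l_labels)) {
    inp <- cbind(E[prep$l_parent, , drop = FALSE], prep$l_emb)
    ll <- bce_loss(mlp_forward(model$params$L, inp)$prob, prep$l_labels)
  }
  list(loss_V = lv, loss_L = ll, loss_E = lv + ll)
}

chunk_indices <- function(x, n_chunks) {
  sizes <- diff(round(seq(0, length(x), length.out = n_chunks + 1L)))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-n_chunks] + 1L)
  lapply(seq_len(n_chunks), function(i)
    if (sizes[i] > 0L) x[starts[i]:ends[i]] else integer(0))
}

#' Train the multi-task model
#'
#' Joint training of the embedding block and both heads: every optimization
#' step takes one balanced batch of validator samples and one balanced batch
#' of link samples, computes each head's binary cross-entropy, updates the
#' heads on their own losses and the shared embedding block on the summed
#' loss, all with Adam. Per-epoch class balancing undersamples each task's
#' majority class with reshuffling. Early stopping monitors the validation
#' `loss_V + loss_L` on the natural (unbalanced) distribution and restores
#' the best parameters seen.
#'
#' @param model a [maglink_model()].
#' @param dataset a [generate_dataset()] result, or any list with `train` and
#'   `val` lists of samples in the same format.
#' @param config a [train_config()].
#' @param verbose print a line per epoch.
#' @return list with `model` (best parameters restored) and `history`
#'   (data.frame of per-epoch train/validation losses), `stop_epoch`,
#'   `best_epoch`.
#' @export
train <- function(model, dataset, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "maglink_model"))
  if (!length(dataset$train) || !length(dataset$val))
    stop("dataset needs non-empty train and val splits")
  tr <- prepare_split(dataset$train, model$F)
  va <- prepare_split(dataset$val, model$F)
  set.seed(config$seed)
  state <- adam_init(model$params)
  bs <- config$batch_size
  best <- Inf; best_epoch <- 0L; wait <- 0L
  best_params <- model$params
  hist <- list()

  for (epoch in seq_len(config$max_epochs)) {
    vi <- balance_indices(tr$v_labels, config$balance, "validator")
    li <- balance_indices(tr$l_labels, config$balance, "link predictor")
    n_steps <- max(ceiling(length(vi) / bs), ceiling(length(li) / bs), 1L)
    v_chunks <- chunk_indices(vi, n_steps)
    l_chunks <- chunk_indices(li, n_steps)
    ep_lv <- 0; ep_ll <- 0
    for (s in seq_len(n_steps)) {
      vids <- v_chunks[[s]]
      lids <- l_chunks[[s]]
      parents <- tr$l_parent[lids]
      ug <- unique(c(vids, parents))
      res <- model_gradients(
        model, tr$emb[ug],
        v_rows = match(vids, ug), v_labels = tr$v_labels[vids],
        l_parent = match(parents, ug),
        l_emb = tr$l_emb[lids, , drop = FALSE],
        l_labels = tr$l_labels[lids])
      if (!is.finite(res$loss_V + res$loss_L))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      upd <- adam_step(model$params, res$grads, state, lr = config$lr)
      model$params <- upd$params
      state <- upd$state
      ep_lv <- ep_lv + res$loss_V; ep_ll <- ep_ll + res$loss_L
    }
    vl <- split_losses(model, va)
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss_V = ep_lv / n_steps,
      train_loss_L = ep_ll / n_steps, val_loss_V = vl$loss_V,
      val_loss_L = vl$loss_L, val_loss_E = vl$loss_E)
    if (verbose)
      message(sprintf("epoch %3d  train V %.4f L %.4f | val V %.4f L %.4f",
                      epoch, ep_lv / n_steps, ep_ll / n_steps,
                      vl$loss_V, vl$loss_L))
    if (vl$loss_E < best - 1e-12) {
      best <- vl$loss_E; best_epoch <- epoch; wait <- 0L
      best_params <- model$params
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model$params <- best_params
  list(model = model, history = do.call(rbind, hist),
       stop_epoch = length(hist), best_epoch = best_epoch)
}
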