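#' Binary classification metrics
#'
#' Accuracy and macro F1 (the unweighted mean of the per-class F1 of class 1
#' and class 0) with the full confusion counts. A class with zero predicted
#' and zero true members contributes an F1 of 0.
#'
#' @param labels 0/1 true labels.
#' @param preds 0/1 predicted labels.
#' @return list with `accuracy`, `macro_f1`, `f1_pos`, `f1_neg`, `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
binary_metrics <- function(labels, preds) {
  stopifnot(length(labels) == length(preds), length(labels) > 0L)
  labels <- as.integer(labels); preds <- as.integer(preds)
  tp <- sum(labels == 1L & preds == 1L)
  fp <- sum(labels == 0L & preds == 1L)
  tn <- sum(labels == 0L & preds == 0L)
  fn <- sum(labels == 1L & preds == 0L)
  f1 <- function(tp, fp, fn) {
    denom <- 2 * tp + fp + fn
    if (denom == 0) 0 else 2 * tp / denom
  }
  f1_pos <- f1(tp, fp, fn)
  f1_neg <- f1(tn, fn, fp)   # class 0 as the positive class
  list(accuracy = (tp + tn) / length(labels),
       macro_f1 = (f1_pos + f1_neg) / 2,
       f1_pos = f1_pos, f1_neg = f1_neg,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Evaluate a model on a list of labeled samples
#'
#' Computes validator and link-predictor decisions at the 0.5 threshold over
#' every sample (natural label distribution) and reports accuracy, macro F1
#' and confusion counts per task.
#'
#' @param model a [maglink_model()].
#' @param samples list of labeled samples (e.g. a dataset's `test` split).
#' @param threshold decision threshold (default 0.5).
#' @return list with elements `validator` and `link`, each a
#'   [binary_metrics()] result (a task absent from the split is reported as
#'   `NULL` with a warning).
#' @export
evaluate <- function(model, samples, threshold = 0.5) {
  stopifnot(inherits(model, "maglink_model"))
  if (!length(samples)) stop("empty sample list")
  prep <- prepare_split(samples, model$F)
  b <- build_batch(prep$emb, model)
  E <- gat_forward(model, b$X, b$gidx, b$last_idx, b$nG)$E
  v_probs <- mlp_forward(model$params$V, E)$prob
  validator <- binary_metrics(prep$v_labels, as.integer(v_probs >= threshold))
  link <- NULL
  if (length(prep$l_labels)) {
    inp <- cbind(E[prep$l_parent, , drop = FALSE], prep$l_emb)
    l_probs <- mlp_forward(model$params$L, inp)$prob
    link <- binary_metrics(prep$l_labels, as.integer(l_probs >= threshold))
  } else {
    warning("no link samples in this split; link metrics omitted")
  }
  list(validator = validator, link = link)
}

#' Sweep configuration
#'
#' The evaluation grid varies the embedding dimension F, the generator noise
#' sigma, the positional-encoding switch and the RNG seed; each cell
#' generates its own dataset, trains a model and evaluates it on the test
#' split. Budget knobs (`repetitions`, `max_epochs`) default to the full
#' study values but accept reduced values for desk-scale runs; the result
#' records the budget used.
#'
#' @param F_values,sigma_values,pe_values,seeds grid axes.
#' @param repetitions generator repetitions per macro sequence.
#' @param max_epochs,batch_size,patience,lr training budget.
#' @param make_prototypes function(F, sigma, seed) returning a
#'   [prototype_set()]; the default draws random means with minimum pairwise
#'   distance 10 * sigma (at least 1).
#' @return list of class `sweep_config`.
#' @export
sweep_config <- function(F_values = c(5L, 15L, 25L),
                         sigma_values = c(0.05, 0.15, 0.25),
                         pe_values = c(TRUE, FALSE),
                         seeds = c(1L, 2L, 3L),
                         repetitions = 30L, max_epochs = 500L,
                         batch_size = 128L, patience = 10L, lr = 0.001,
                         make_prototypes = NULL) {
  structure(list(F_values = F_values, sigma_values = sigma_values,
                 pe_values = pe_values, seeds = seeds,
                 repetitions = as.integer(repetitions),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), lr = lr,
                 make_prototypes = make_prototypes),
            class = "sweep_config")
}

#' Run the evaluation grid
#'
#' For every grid cell (F, sigma, PE, seed): generate a dataset from the
#' grammar with that cell's prototypes and noise, train a model with or
#' without positional encodings, and evaluate both tasks on the test split.
#' PE-on and PE-off cells differ only in the positional-encoding step. A
#' failed cell is recorded and the sweep continues.
#'
#' @param grammar a [micro_grammar()].
#' @param config a [sweep_config()].
#' @param verbose print one line per cell.
#' @return list with `cells` (one row per cell x task: F, sigma, pe, seed,
#'   task, accuracy, macro_f1), `aggregate` (mean and sd over seeds per
#'   cell x task) and `errors` (character vector of failed-cell messages).
#' @export
run_sweep <- function(grammar, config = sweep_config(), verbose = FALSE) {
  make_protos <- config$make_prototypes %||% function(F, sigma, seed) {
    set.seed(seed)
    random_prototypes(n_classes(grammar), F, sigma,
                      min_dist = max(10 * sigma, 1))
  }
  rows <- list(); errors <- character(0)
  grid <- expand.grid(F = config$F_values, sigma = config$sigma_values,
                      pe = config$pe_values, seed = config$seeds)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- tryCatch({
      protos <- make_protos(g$F, g$sigma, g$seed)
      if (protos$n != n_classes(grammar))
        stop("prototype factory produced ", protos$n, " classes")
      ds <- generate_dataset(grammar, protos,
                             generator_config(config$repetitions,
                                              seed = g$seed))
      model <- maglink_model(g$F, pe = g$pe, seed = g$seed)
      tc <- train_config(lr = config$lr, batch_size = config$batch_size,
                         patience = config$patience,
                         max_epochs = config$max_epochs, seed = g$seed)
      fit <- train(model, ds, tc)
      ev <- evaluate(fit$model, ds$test)
      do.call(rbind, lapply(c("validator", "link"), function(task)
        if (is.null(ev[[task]])) NULL else
          data.frame(F = g$F, sigma = g$sigma, pe = g$pe, seed = g$seed,
                     task = task, accuracy = ev[[task]]$accuracy,
                     macro_f1 = ev[[task]]$macro_f1)))
    }, error = function(e) {
      errors <<- c(errors, sprintf("F=%s sigma=%s pe=%s seed=%s: %s",
                                   g$F, g$sigma, g$pe, g$seed,
                                   conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    if (verbose && !is.null(res))
      message(sprintf("cell F=%d sigma=%.2f pe=%s seed=%d done",
                      g$F, g$sigma, g$pe, g$seed))
  }
  cells <- do.call(rbind, rows)
  aggregate <- NULL
  if (!is.null(cells)) {
    aggregate <- do.call(rbind, by(cells,
      cells[, c("F", "sigma", "pe", "task")], function(d)
        data.frame(F = d$F[1], sigma = d$sigma[1], pe = d$pe[1],
                   task = d$task[1], n_seeds = nrow(d),
                   mean_accuracy = mean(d$accuracy),
                   sd_accuracy = stats::sd(d$accuracy),
                   mean_macro_f1 = mean(d$macro_f1),
                   sd_macro_f1 = stats::sd(d$macro_f1))))
    rownames(aggregate) <- NULL
  }
  list(cells = cells, aggregate = aggregate, errors = errors)
}

#' Write sweep results as tidy CSVs
#'
#' @param sweep a [run_sweep()] result.
#' @param dir output directory; writes `cells.csv` and `aggregate.csv`.
#' @export
write_sweep <- function(sweep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sweep$cells, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  utils::write.csv(sweep$aggregate, file.path(dir, "aggregate.csv"),
                   row.names = FALSE)
  invisible(dir)
}
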