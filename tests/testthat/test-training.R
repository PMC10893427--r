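test_that("multi-task loss sums the per-task cross-entropies", {
  l <- multitask_loss(c(0.5, 0.5), c(1, 0), c(0.5), c(1))
  expect_equal(l$loss_V, log(2))
  expect_equal(l$loss_L, log(2))
  expect_equal(l$loss_E, l$loss_V + l$loss_L)
  near <- multitask_loss(c(1 - 1e-7), c(1), c(1e-7), c(0))
  expect_lt(near$loss_E, 1e-6)
  # an empty task contributes zero
  empty <- multitask_loss(numeric(0), numeric(0), c(0.5), c(0))
  expect_identical(empty$loss_V, 0)
  expect_equal(empty$loss_E, empty$loss_L)
})

test_that("gradients are isolated between heads but shared in the embedding", {
  set.seed(20)
  model <- maglink_model(3L, heads = 2L, seed = 20)
  emb <- list(matrix(rnorm(6), 2), matrix(rnorm(9), 3))
  # validator-only batch: link head must receive zero gradient
  v_only <- maglink:::model_gradients(model, emb, 1:2, c(1, 0),
                                      integer(0), matrix(0, 0, 3), integer(0))
  expect_true(all(unlist(v_only$grads$L) == 0))
  expect_gt(max(abs(unlist(v_only$grads$V))), 0)
  expect_gt(max(abs(unlist(v_only$grads$gat))), 0)
  # link-only batch: validator head must receive zero gradient
  lemb <- matrix(rnorm(6), 2)
  l_only <- maglink:::model_gradients(model, emb, integer(0), integer(0),
                                      c(1L, 2L), lemb, c(1, 0))
  expect_true(all(unlist(l_only$grads$V) == 0))
  expect_gt(max(abs(unlist(l_only$grads$L))), 0)
  expect_gt(max(abs(unlist(l_only$grads$gat))), 0)
  # embedding-block gradient of a joint batch is the sum of the two routes
  joint <- maglink:::model_gradients(model, emb, 1:2, c(1, 0),
                                     c(1L, 2L), lemb, c(1, 0))
  expect_equal(unlist(joint$grads$gat),
               unlist(v_only$grads$gat) + unlist(l_only$grads$gat),
               tolerance = 1e-10)
})

test_that("balancing equalizes classes under each mode", {
  set.seed(21)
  labels <- c(rep(1L, 10), rep(0L, 100))
  over <- balance_indices(labels, "oversample")
  expect_length(over, 200L)
  expect_equal(sum(labels[over] == 1L), 100L)
  under <- balance_indices(labels, "undersample")
  expect_length(under, 20L)
  expect_equal(sum(labels[under] == 1L), 10L)
  none <- balance_indices(labels, "none")
  expect_setequal(none, seq_along(labels))
  expect_error(balance_indices(rep(1L, 5), task = "validator"),
               "validator: class 0 absent")
  # successive draws differ under a moving RNG
  expect_false(identical(balance_indices(labels, "undersample"),
                         balance_indices(labels, "undersample")))
})

test_that("the early-stopping rule stops at patience and keeps the best epoch", {
  # strictly worsening from epoch 1: stop at patience + 1, best = 1
  tr <- early_stop_trace(seq(1, 2, length.out = 50), patience = 10L)
  expect_identical(tr$stop_epoch, 11L)
  expect_identical(tr$best_epoch, 1L)
  # improvement resets the wait counter
  tr2 <- early_stop_trace(c(3, 2, 2.5, 2.4, 1.9, 2, 2, 2), patience = 3L)
  expect_identical(tr2$best_epoch, 5L)
  expect_identical(tr2$stop_epoch, 8L)
  tr3 <- early_stop_trace(c(5, 4, 3), patience = 10L)
  expect_identical(tr3$stop_epoch, 3L)
  expect_identical(tr3$best_epoch, 3L)
})

test_that("training is reproducible and respects the epoch cap", {
  g <- toy_abc()
  set.seed(22)
  protos <- random_prototypes(3, 4, 0.05, min_dist = 1)
  ds <- generate_dataset(g, protos, generator_config(5L, seed = 22))
  run <- function() {
    model <- maglink_model(4L, heads = 2L, seed = 22)
    train(model, ds, train_config(max_epochs = 5L, seed = 22))
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$stop_epoch, 5L)
  one <- train(maglink_model(4L, heads = 2L, seed = 22), ds,
               train_config(max_epochs = 1L, seed = 22))
  expect_identical(nrow(one$history), 1L)
})

test_that("training restores the best-validation parameters", {
  g <- toy_abc()
  set.seed(23)
  protos <- random_prototypes(3, 4, 0.05, min_dist = 1)
  ds <- generate_dataset(g, protos, generator_config(5L, seed = 23))
  fit <- train(maglink_model(4L, heads = 2L, seed = 23), ds,
               train_config(max_epochs = 15L, seed = 23))
  expect_identical(fit$best_epoch, which.min(fit$history$val_loss_E))
  va <- maglink:::prepare_split(ds$val, 4L)
  expect_equal(maglink:::split_losses(fit$model, va)$loss_E,
               min(fit$history$val_loss_E), tolerance = 1e-12)
})

test_that("a separable toy task is learned to perfect training accuracy", {
  g <- micro_grammar(c("a", "b"), list(c("a", "b")))
  protos <- prototype_set(rbind(c(5, 0, 0, 0), c(0, 5, 0, 0)), 0)
  ds <- generate_dataset(g, protos, generator_config(10L, seed = 24))
  fit <- train(maglink_model(4L, heads = 2L, seed = 24), ds,
               train_config(max_epochs = 200L, seed = 24))
  ev <- evaluate(fit$model, ds$train)
  expect_equal(ev$validator$accuracy, 1)
  expect_equal(ev$link$accuracy, 1)
  # loss trends downward over training
  h <- fit$history
  expect_lt(mean(tail(h$train_loss_V + h$train_loss_L, 3)),
            mean(head(h$train_loss_V + h$train_loss_L, 3)))
})
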