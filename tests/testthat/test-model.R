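test_that("attention coefficients normalize and embedding width is 2F", {
  for (F in c(5L, 15L, 25L)) {
    model <- maglink_model(F, seed = 2)
    emb <- matrix(rnorm(4 * F), 4, F)
    b <- maglink:::build_batch(list(emb), model)
    fw <- maglink:::gat_forward(model, b$X, b$gidx, b$last_idx, 1L)
    expect_length(drop(fw$E), 2L * F)
    for (hc in fw$cache$heads)
      expect_equal(sum(hc$alpha), 1, tolerance = 1e-6)
  }
})

test_that("a single vertex attends only to itself", {
  model <- maglink_model(3L, heads = 2L, seed = 4)
  g <- build_graph(matrix(rnorm(3), 1, 3))
  fw <- maglink:::gat_forward(model, g$V, 1L, 1L, 1L)
  for (hc in fw$cache$heads) expect_equal(hc$alpha, 1)
})

test_that("identical vertices receive uniform attention", {
  model <- maglink_model(4L, heads = 2L, pe = FALSE, seed = 5)
  emb <- matrix(rep(c(1, -1, 0.5, 2), each = 3), 3, 4)
  b <- maglink:::build_batch(list(emb), model)
  fw <- maglink:::gat_forward(model, b$X, b$gidx, b$last_idx, 1L)
  for (hc in fw$cache$heads)
    expect_equal(hc$alpha, rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("single-graph attention agrees with an independent step-by-step computation", {
  set.seed(6)
  F <- 4L
  model <- maglink_model(F, heads = 2L, pe = FALSE, seed = 6)
  X <- matrix(rnorm(3 * F), 3, F)
  # independent dense computation of the same attention layer
  p <- model$params$gat
  dh <- model$head_width
  want <- c()
  for (h in 1:2) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Z <- X %*% p$W[, cols]
    scores <- numeric(3)
    for (i in 1:3) {
      s <- sum(Z[i, ] * p$a_src[, h]) + sum(Z[3, ] * p$a_dst[, h])
      scores[i] <- if (s > 0) s else model$slope * s
    }
    a <- exp(scores - max(scores)); a <- a / sum(a)
    want <- c(want, drop(t(a) %*% Z))
  }
  want <- want + p$b
  expect_equal(embed_sequence(model, X), want, tolerance = 1e-12)
})

test_that("last vertex pooling returns exactly row T", {
  M <- rbind(c(1, 2), c(3, 4), c(5, 6))
  expect_identical(last_vertex_pool(M), c(5, 6))
  expect_identical(last_vertex_pool(c(7, 8)), c(7, 8))
})

test_that("star symmetry: without PE the embedding ignores non-final order", {
  model <- maglink_model(5L, pe = FALSE, seed = 7)
  set.seed(7)
  emb <- matrix(rnorm(4 * 5), 4, 5)
  perm <- emb[c(3, 1, 2, 4), ]  # permute all but the last vertex
  expect_equal(embed_sequence(model, emb), embed_sequence(model, perm),
               tolerance = 1e-10)
  # with PE the same permutation of underlying activities is visible
  model_pe <- maglink_model(5L, pe = TRUE, seed = 7)
  expect_gt(max(abs(embed_sequence(model_pe, emb) -
                    embed_sequence(model_pe, perm))), 1e-4)
})

test_that("zero-weight heads output probability one half", {
  model <- maglink_model(3L, seed = 8)
  model$params$V <- maglink:::zero_grads(model$params$V)
  model$params$L <- maglink:::zero_grads(model$params$L)
  e <- rnorm(6)
  expect_equal(validate_graph(model, e), 0.5)
  expect_equal(predict_link(model, e, rnorm(3)), 0.5)
  # and sigmoid outputs always live strictly inside (0, 1)
  model2 <- maglink_model(3L, seed = 9)
  p <- validate_graph(model2, matrix(rnorm(60), 10, 6))
  expect_true(all(p > 0 & p < 1))
})

test_that("link head consumes the 3F concatenation and checks widths", {
  model <- maglink_model(4L, seed = 10)
  expect_length(model$params$L[[1]]$W[, 1], 12L)
  expect_error(predict_link(model, rnorm(8), rnorm(5)), "width mismatch")
  expect_error(validate_graph(model, rnorm(7)), "does not match")
  expect_error(embed_graph(model, build_graph(matrix(0, 2, 3))),
               "does not match")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(12)
  F <- 3L
  model <- maglink_model(F, heads = 2L, seed = 12)
  # jitter every parameter (including the zero-initialized biases) so no
  # rectifier pre-activation sits exactly on its kink, where forward
  # differences and subgradients legitimately disagree
  jitter_params <- function(p) {
    if (is.list(p)) lapply(p, jitter_params)
    else p + stats::rnorm(length(p), sd = 0.05)
  }
  model$params <- jitter_params(model$params)
  emb <- list(matrix(rnorm(2 * F), 2), matrix(rnorm(3 * F), 3))
  vlab <- c(1, 0)
  l_parent <- c(1L, 2L, 2L)
  l_emb <- matrix(rnorm(3 * F), 3)
  l_lab <- c(0, 1, 0)
  res <- maglink:::model_gradients(model, emb, 1:2, vlab, l_parent, l_emb,
                                   l_lab)
  base <- res$loss_V + res$loss_L
  eps <- 1e-6
  for (blk in c("gat", "V", "L")) {
    flat <- unlist(res$grads[[blk]])
    u0 <- unlist(model$params[[blk]])
    idx <- round(seq(1, length(u0), length.out = 15))
    for (k in idx) {
      m2 <- model
      u <- u0; u[k] <- u[k] + eps
      m2$params[[blk]] <- utils::relist(u, model$params[[blk]])
      r2 <- maglink:::model_gradients(m2, emb, 1:2, vlab, l_parent, l_emb,
                                      l_lab)
      expect_equal(unname(flat[k]), (r2$loss_V + r2$loss_L - base) / eps,
                   tolerance = 1e-3)
    }
  }
})

test_that("forward pass is deterministic and checkpoints round-trip", {
  model <- maglink_model(4L, seed = 13)
  emb <- matrix(rnorm(3 * 4), 3, 4)
  e1 <- embed_sequence(model, emb)
  e2 <- embed_sequence(model, emb)
  expect_identical(e1, e2)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  m2 <- load_model(path)
  expect_equal(embed_sequence(m2, emb), e1)
  expect_equal(validate_graph(m2, e1), validate_graph(model, e1))
  expect_identical(m2$pe, model$pe)
  expect_identical(m2$heads, model$heads)
})

test_that("batched embedding equals one-graph-at-a-time embedding", {
  model <- maglink_model(5L, seed = 14)
  set.seed(14)
  embs <- lapply(c(1, 3, 6), function(T) matrix(rnorm(T * 5), T, 5))
  b <- maglink:::build_batch(embs, model)
  E <- maglink:::gat_forward(model, b$X, b$gidx, b$last_idx, b$nG)$E
  for (i in seq_along(embs))
    expect_equal(E[i, ], embed_sequence(model, embs[[i]]), tolerance = 1e-12)
})
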