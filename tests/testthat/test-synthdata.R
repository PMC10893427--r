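test_that("similarity matches hand values and a double-loop oracle", {
  p2 <- prototype_set(rbind(c(0, 0), c(1, 0)), 0.1)
  expect_equal(embedding_similarity(p2), 0.25)      # (1/4) * 1/1
  p3 <- prototype_set(rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)), 0.1)
  expect_equal(embedding_similarity(p3), 1 / 3)     # (1/9) * 3
  set.seed(8)
  means <- matrix(rnorm(8 * 5), 8, 5)
  s_loop <- 0
  for (i in 1:7) for (j in (i + 1):8)
    s_loop <- s_loop + 1 / sqrt(sum((means[i, ] - means[j, ])^2))
  s_loop <- s_loop / 64
  expect_equal(embedding_similarity(prototype_set(means, 0.1)), s_loop)
  expect_error(embedding_similarity(prototype_set(rbind(c(1, 1), c(1, 1)),
                                                  0)), "identical means")
})

test_that("similarity is invariant under rigid rotation of the means", {
  set.seed(9)
  means <- matrix(rnorm(6 * 2), 6, 2)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expect_equal(embedding_similarity(prototype_set(means %*% R, 0.1)),
               embedding_similarity(prototype_set(means, 0.1)))
})

test_that("adding uninformative embedding dimensions lowers similarity", {
  # same pairwise structure, larger F via zero-padding: distances unchanged
  # in this construction, but spreading the same spacing over more axes
  # cannot raise s; use scaled copies where the effect is exact
  means5 <- matrix(seq(0, 7), 8, 1) %*% t(rep(1, 5)) / sqrt(5)
  means15 <- matrix(seq(0, 7), 8, 1) %*% t(rep(1, 15)) / sqrt(15)
  s5 <- embedding_similarity(prototype_set(means5, 0.1))
  s15 <- embedding_similarity(prototype_set(means15, 0.1))
  expect_equal(s5, s15)  # equal spacing: equality is the boundary case
  # now genuinely larger spread with more features
  set.seed(10)
  base <- matrix(rnorm(8 * 5), 8, 5)
  wide <- cbind(base, matrix(rnorm(8 * 10), 8, 10))
  expect_lt(embedding_similarity(prototype_set(wide, 0.1)),
            embedding_similarity(prototype_set(base, 0.1)))
})

test_that("sampling is Gaussian around the class mean and seed-stable", {
  p <- prototype_set(rbind(c(1, -2, 0.5), c(0, 0, 0)), 0)
  expect_identical(sample_embedding(p, 0), c(1, -2, 0.5))  # sigma 0 exact
  p2 <- prototype_set(rbind(c(1, -2, 0.5), c(0, 0, 0)), 0.25)
  set.seed(3)
  draws <- t(replicate(10000, sample_embedding(p2, 0)))
  se <- 0.25 / sqrt(10000)
  expect_true(all(abs(colMeans(draws) - c(1, -2, 0.5)) < 3 * se + 1e-9))
  set.seed(11); a <- sample_embedding(p2, 1)
  set.seed(11); b <- sample_embedding(p2, 1)
  expect_identical(a, b)
  expect_error(sample_embedding(p2, 5), "unknown class")
})

test_that("prototype fitting averages projected windows per class", {
  # identity projector on already-F-dimensional features
  win <- rbind(c(0, 0), c(2, 2), c(1, 5))
  cls <- c(0L, 0L, 1L)
  ps <- fit_class_prototypes(win, cls, 2L, sigma = 0.1)
  expect_equal(ps$means[1, ], c(1, 1))
  expect_equal(ps$means[2, ], c(1, 5))
  expect_equal(ps$sigma, 0.1)
  # column-truncation projector drops trailing features before averaging
  win3 <- cbind(win, 99)
  ps2 <- fit_class_prototypes(win3, cls, 2L, sigma = 0.1, F = 2L)
  expect_equal(ps2$means, ps$means)
  expect_error(fit_class_prototypes(win, c(0L, 0L, 0L), 2L, 0.1),
               "class id\\(s\\): 1")
})

test_that("subsequence embeddings are nested prefixes of one draw", {
  p <- prototype_set(matrix(rnorm(12), 4, 3), 0.2)
  set.seed(21)
  subs <- generate_subsequence_embeddings(c(0, 2, 3), p)
  expect_length(subs, 3L)
  expect_identical(vapply(subs, nrow, 1L), 1:3)
  expect_equal(subs[[1]], subs[[3]][1, , drop = FALSE])
  expect_equal(subs[[2]], subs[[3]][1:2, , drop = FALSE])
  p0 <- prototype_set(matrix(1:12, 4, 3), 0)
  subs0 <- generate_subsequence_embeddings(c(1, 0), p0)
  expect_equal(subs0[[2]], p0$means[c(2, 1), ])
  expect_length(generate_subsequence_embeddings(0, p), 1L)
})

test_that("impossible-link counts follow the base-rate rule", {
  expect_identical(n_impossible(0, 100, 5), 10L)
  expect_identical(n_impossible(3, 100, 5), 5L)
  expect_identical(n_impossible(0, 0, 5), 0L)
  expect_identical(n_impossible(0, 105, 5), 11L)  # round half up: 10.5 -> 11
  expect_error(n_impossible(-1, 10, 2), "non-negative")
})

test_that("repetition apportionment uses largest remainders", {
  expect_identical(split_counts(5), c(3L, 1L, 1L))
  expect_identical(split_counts(30), c(18L, 6L, 6L))
  expect_identical(split_counts(10), c(6L, 2L, 2L))
  expect_identical(split_counts(1), c(1L, 0L, 0L))
  expect_identical(sum(split_counts(7, c(0.5, 0.3, 0.2))), 7L)
  expect_identical(split_counts(10, c(1, 0, 0)), c(10L, 0L, 0L))
})

test_that("dataset labels all agree with the grammar oracle", {
  g <- benchmark_grammar("separable")
  set.seed(31)
  protos <- random_prototypes(8, 5, 0.1, min_dist = 1)
  ds <- generate_dataset(g, protos, generator_config(5L, seed = 31))
  for (sp in c("train", "val", "test")) for (x in ds[[sp]]) {
    expect_identical(x$valid, as.integer(is_valid_macro(g, x$prefix)))
    if (length(x$link_label))
      expect_identical(x$link_label,
                       vapply(x$link_class, function(c)
                         as.integer(is_possible_link(g, x$prefix, c)), 0L))
    expect_identical(nrow(x$emb), length(x$prefix))
  }
})

test_that("dataset counts and split sizes obey the generation scheme", {
  g <- toy_abc()
  p <- prototype_set(matrix(rnorm(9), 3, 3), 0.1)
  ds <- generate_dataset(g, p, generator_config(5L, seed = 1))
  # 5 reps x 3 prefixes, split 3/1/1 repetitions
  expect_length(ds$train, 9L)
  expect_length(ds$val, 3L)
  expect_length(ds$test, 3L)
  reps_by_split <- lapply(c("train", "val", "test"), function(sp)
    unique(vapply(ds[[sp]], `[[`, 0L, "rep")))
  expect_length(unlist(reps_by_split), 5L)
  expect_identical(anyDuplicated(unlist(reps_by_split)), 0L)

  ds10 <- generate_dataset(g, p, generator_config(10L, seed = 2))
  s <- dataset_summary(ds10)
  expect_identical(s$count[s$split == "train" & s$label == "valid"], 6L)
  expect_identical(s$count[s$split == "train" & s$label == "invalid"], 12L)
  # conservation: validator counts sum to the number of samples per split
  for (sp in c("train", "val", "test"))
    expect_identical(sum(s$count[s$split == sp & s$task == "validator"]),
                     length(ds10[[sp]]))
})

test_that("same-repetition successors reuse the next drawn vector", {
  g <- toy_abc()
  p <- prototype_set(matrix(rnorm(9), 3, 3), 0.1)
  ds <- generate_dataset(g, p, generator_config(3L, seed = 7))
  for (sp in c("train", "val", "test")) {
    by_rep <- split(ds[[sp]], vapply(ds[[sp]], `[[`, 0L, "rep"))
    for (grp in by_rep) {
      lens <- vapply(grp, function(x) length(x$prefix), 1L)
      full <- grp[[which.max(lens)]]
      for (x in grp) {
        t <- length(x$prefix)
        if (t < 3L) {
          # the possible link for the continuing class is row t+1 of the draw
          i <- which(x$link_class == full$prefix[t + 1L] & x$link_label == 1L)
          expect_equal(x$link_emb[i[1L], ], full$emb[t + 1L, ])
        }
      }
    }
  }
})

test_that("datasets round-trip through the plain-text container", {
  g <- micro_grammar(c("a", "b"), list(c("a", "b"), "b"))
  p <- prototype_set(matrix(rnorm(4), 2, 2), 0.15)
  ds <- generate_dataset(g, p, generator_config(4L, seed = 5))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- read_dataset(dir)
  expect_identical(lengths(ds2[c("train", "val", "test")]),
                   lengths(ds[c("train", "val", "test")]))
  for (sp in c("train", "val", "test"))
    for (i in seq_along(ds[[sp]])) {
      expect_identical(ds2[[sp]][[i]]$prefix, ds[[sp]][[i]]$prefix)
      expect_equal(ds2[[sp]][[i]]$emb, ds[[sp]][[i]]$emb)
      expect_identical(ds2[[sp]][[i]]$valid, ds[[sp]][[i]]$valid)
      expect_identical(ds2[[sp]][[i]]$link_label, ds[[sp]][[i]]$link_label)
      expect_equal(ds2[[sp]][[i]]$link_emb, ds[[sp]][[i]]$link_emb)
    }
  expect_equal(ds2$prototypes$means, ds$prototypes$means,
               ignore_attr = TRUE)
  expect_identical(unclass(ds2$config), unclass(ds$config))
})
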