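#' Generator configuration
#'
#' Bundles the knobs of the synthetic sequence generator: how many times each
#' macro-activity sequence is re-drawn (repetitions), how repetitions are
#' divided into train/validation/test, the impossible-link base rate used
#' when a graph has no possible successor, and the RNG seed.
#'
#' @param repetitions draws per macro-activity sequence (default 30).
#' @param split train/validation/test fractions, must sum to 1
#'   (default 60/20/20).
#' @param imp_rate impossible-link base rate applied to the pool size when a
#'   graph has no possible successors (default 0.1).
#' @param seed integer RNG seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(repetitions = 30L, split = c(0.6, 0.2, 0.2),
                             imp_rate = 0.1, seed = 1L) {
  if (repetitions < 1L) stop("repetitions must be >= 1")
  if (length(split) != 3L || any(split < 0) ||
      abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (imp_rate < 0) stop("imp_rate must be non-negative")
  structure(list(repetitions = as.integer(repetitions),
                 split = as.numeric(split), imp_rate = as.numeric(imp_rate),
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Embeddings of all prefixes of one sequence draw
#'
#' Draws one embedding per position of the macro-activity sequence and
#' returns its T prefix slices, shortest first. All prefixes of the same
#' draw share the identical sampled vectors: the length-t output is an exact
#' row-wise prefix of the length-(t+1) output.
#'
#' @param seq integer vector of class ids (length T >= 1).
#' @param prototypes a [prototype_set()].
#' @return list of T matrices; element t is t x F.
#' @export
generate_subsequence_embeddings <- function(seq, prototypes) {
  seq <- as.integer(seq)
  if (length(seq) < 1L) stop("sequence must be non-empty")
  E <- draw_sequence(seq, prototypes)
  lapply(seq_along(seq), function(t) E[seq_len(t), , drop = FALSE])
}

round_half_up <- function(x) floor(x + 0.5)

# one row per position, in sequence order
draw_sequence <- function(seq, prototypes) {
  E <- matrix(0, length(seq), prototypes$F)
  for (i in seq_along(seq)) E[i, ] <- sample_embedding(prototypes, seq[i])
  E
}

#' Number of impossible links for one graph
#'
#' A graph with possible successors receives the split-wide average possible
#' count; a graph with none (a complete macro-activity with no extension)
#' receives a fixed fraction of the whole embedding pool, rounded half-up.
#'
#' @param n_pos number of possible successor classes of this graph.
#' @param n_total total number of previously generated embeddings (the pool).
#' @param n_pos_mean average possible-link count over graphs that have any.
#' @param imp_rate base rate applied to `n_total` when `n_pos` is 0.
#' @return integer count.
#' @export
n_impossible <- function(n_pos, n_total, n_pos_mean, imp_rate = 0.1) {
  if (n_pos < 0 || n_total < 0 || n_pos_mean < 0)
    stop("counts must be non-negative")
  if (n_pos == 0L) as.integer(round_half_up(imp_rate * n_total))
  else as.integer(n_pos_mean)
}

#' Largest-remainder apportionment of repetitions to splits
#'
#' @param R number of repetitions.
#' @param fractions length-3 fractions summing to 1.
#' @return integer vector of length 3 summing to `R`.
#' @export
split_counts <- function(R, fractions = c(0.6, 0.2, 0.2)) {
  exact <- R * fractions
  base <- floor(exact)
  left <- R - sum(base)
  if (left > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a fully labeled synthetic dataset
#'
#' For every macro-activity sequence and every repetition, one embedding is
#' drawn per position and all prefix graphs are emitted as samples. Each
#' sample carries its validator label (is the prefix a complete
#' macro-activity?) and a set of link samples: one possible link per
#' successor class (the same repetition's next drawn embedding when the
#' successor continues this sequence, otherwise a same-split embedding of
#' that class) and `n_impossible` embeddings drawn from the same split's
#' pool restricted to non-successor classes. Repetitions are apportioned to
#' train/validation/test per sequence with largest-remainder rounding, and
#' all prefixes of one repetition stay in one split, so no drawn vector ever
#' crosses splits.
#'
#' @param grammar a [micro_grammar()].
#' @param prototypes a [prototype_set()] with one mean per grammar class.
#' @param config a [generator_config()].
#' @return object of class `labeled_dataset`: `train`/`val`/`test` lists of
#'   samples plus provenance (`grammar`, `prototypes`, `config`). Each sample
#'   is a list with `seq_index`, `rep`, `prefix` (class ids), `emb`
#'   (t x F matrix), `valid` (0/1), `link_emb` (k x F matrix), `link_label`
#'   and `link_class` (length-k vectors).
#' @export
generate_dataset <- function(grammar, prototypes, config = generator_config()) {
  stopifnot(inherits(grammar, "micro_grammar"),
            inherits(prototypes, "prototype_set"))
  if (prototypes$n != n_classes(grammar))
    stop("prototype set and grammar disagree on the number of classes")
  set.seed(config$seed)
  R <- config$repetitions
  split_names <- c("train", "val", "test")

  # phase 1: draw all embeddings and assign repetitions to splits
  draws <- list()   # one entry per (sequence, repetition): full T x F matrix
  for (si in seq_along(grammar$sequences)) {
    s <- grammar$sequences[[si]]
    counts <- split_counts(R, config$split)
    rep_split <- rep(split_names, counts)
    for (r in seq_len(R)) {
      E <- draw_sequence(s, prototypes)
      draws[[length(draws) + 1L]] <-
        list(si = si, rep = r, split = rep_split[r], E = E, classes = s)
    }
  }

  # per-split pools of individual drawn embeddings
  pools <- lapply(split_names, function(sp) {
    sel <- Filter(function(d) d$split == sp, draws)
    if (!length(sel)) return(list(emb = matrix(0, 0, prototypes$F),
                                  class = integer(0)))
    list(emb = do.call(rbind, lapply(sel, `[[`, "E")),
         class = unlist(lapply(sel, `[[`, "classes")))
  })
  names(pools) <- split_names

  # successor structure shared by all repetitions of one sequence
  seq_succ <- lapply(grammar$sequences, function(s)
    lapply(seq_along(s), function(t) successors(grammar, s[seq_len(t)])))

  # split-wide mean possible-link count over graphs that have any successors
  n_pos_mean <- sapply(split_names, function(sp) {
    np <- unlist(lapply(Filter(function(d) d$split == sp, draws), function(d)
      vapply(seq_succ[[d$si]], length, 1L)))
    np <- np[np > 0]
    if (!length(np)) 1L else max(1L, round_half_up(mean(np)))
  })

  out <- list(train = list(), val = list(), test = list())
  for (d in draws) {
    s <- d$classes
    pool <- pools[[d$split]]
    for (t in seq_along(s)) {
      prefix <- s[seq_len(t)]
      succ <- seq_succ[[d$si]][[t]]
      link_emb <- matrix(0, 0, prototypes$F)
      link_label <- integer(0)
      link_class <- integer(0)
      for (c in succ) {
        emb <- if (t < length(s) && c == s[t + 1L]) {
          d$E[t + 1L, ]                      # this repetition's next draw
        } else {
          cand <- which(pool$class == c)
          if (length(cand)) pool$emb[cand[sample.int(length(cand), 1L)], ]
          else sample_embedding(prototypes, c)   # class absent from split
        }
        link_emb <- rbind(link_emb, emb)
        link_label <- c(link_label, 1L)
        link_class <- c(link_class, c)
      }
      n_imp <- n_impossible(length(succ), nrow(pool$emb),
                            n_pos_mean[[d$split]], config$imp_rate)
      imp_cand <- which(!(pool$class %in% succ))
      if (n_imp > 0L && !length(imp_cand)) {
        warning("no impossible-link candidates for a graph ",
                "(all classes are successors); emitting none")
      } else if (n_imp > 0L) {
        take <- imp_cand[sample.int(length(imp_cand), min(n_imp,
                                                          length(imp_cand)))]
        link_emb <- rbind(link_emb, pool$emb[take, , drop = FALSE])
        link_label <- c(link_label, rep(0L, length(take)))
        link_class <- c(link_class, pool$class[take])
      }
      dimnames(link_emb) <- NULL
      out[[d$split]][[length(out[[d$split]]) + 1L]] <- list(
        seq_index = d$si, rep = d$rep, prefix = prefix,
        emb = d$E[seq_len(t), , drop = FALSE],
        valid = as.integer(is_valid_macro(grammar, prefix)),
        link_emb = link_emb, link_label = link_label,
        link_class = link_class)
    }
  }
  structure(c(out, list(grammar = grammar, prototypes = prototypes,
                        config = config)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d train / %d val / %d test samples\n",
              length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

#' Label counts per task and split
#'
#' @param dataset a [generate_dataset()] result.
#' @return data.frame with columns `split`, `task`, `label`, `count`.
#' @export
dataset_summary <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  rows <- list()
  for (sp in c("train", "val", "test")) {
    samples <- dataset[[sp]]
    v <- vapply(samples, `[[`, 0L, "valid")
    l <- unlist(lapply(samples, `[[`, "link_label"))
    rows[[sp]] <- data.frame(
      split = sp,
      task = rep(c("validator", "validator", "link", "link")),
      label = c("valid", "invalid", "possible", "impossible"),
      count = c(sum(v == 1L), sum(v == 0L),
                sum(l == 1L), sum(l == 0L)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a labeled dataset as plain-text files
#'
#' A dataset directory holds four files: `samples.csv` (one row per graph
#' sample with split, ids and validator label), `embeddings.csv` (one row per
#' vertex), `links.csv` (one row per link sample) and `meta.json` (generator
#' config plus grammar and prototypes). Reading the directory back restores
#' an identical dataset.
#'
#' @param dataset a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samp <- list(); emb <- list(); lnk <- list(); id <- 0L
  for (sp in c("train", "val", "test")) for (x in dataset[[sp]]) {
    id <- id + 1L
    samp[[id]] <- data.frame(sample_id = id, split = sp,
                             seq_index = x$seq_index, rep = x$rep,
                             prefix = paste(x$prefix, collapse = ","),
                             valid = x$valid)
    emb[[id]] <- data.frame(sample_id = id, pos = seq_len(nrow(x$emb)),
                            x$emb)
    if (nrow(x$link_emb))
      lnk[[id]] <- data.frame(sample_id = id, class = x$link_class,
                              label = x$link_label, x$link_emb)
  }
  fcols <- paste0("f", seq_len(dataset$prototypes$F) - 1L)
  emb <- do.call(rbind, emb); colnames(emb)[-(1:2)] <- fcols
  lnk <- do.call(rbind, lnk)
  if (is.null(lnk)) {
    lnk <- as.data.frame(matrix(numeric(0), 0, 3 + length(fcols)))
    colnames(lnk) <- c("sample_id", "class", "label", fcols)
  } else colnames(lnk)[-(1:3)] <- fcols
  utils::write.csv(do.call(rbind, samp), file.path(dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(emb, file.path(dir, "embeddings.csv"), row.names = FALSE)
  utils::write.csv(lnk, file.path(dir, "links.csv"), row.names = FALSE)
  write_grammar(dataset$grammar, file.path(dir, "grammar.json"))
  write_prototypes(dataset$prototypes, file.path(dir, "prototypes.csv"))
  jsonlite::write_json(unclass(dataset$config), file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  samp <- utils::read.csv(file.path(dir, "samples.csv"),
                          colClasses = c(prefix = "character"))
  emb <- utils::read.csv(file.path(dir, "embeddings.csv"))
  lnk <- utils::read.csv(file.path(dir, "links.csv"))
  grammar <- read_grammar(file.path(dir, "grammar.json"))
  prototypes <- read_prototypes(file.path(dir, "prototypes.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  config <- generator_config(meta$repetitions, meta$split, meta$imp_rate,
                             meta$seed)
  out <- list(train = list(), val = list(), test = list())
  for (i in seq_len(nrow(samp))) {
    id <- samp$sample_id[i]
    e <- as.matrix(emb[emb$sample_id == id, -(1:2), drop = FALSE])
    storage.mode(e) <- "double"; dimnames(e) <- NULL
    li <- lnk[lnk$sample_id == id, , drop = FALSE]
    le <- as.matrix(li[, -(1:3), drop = FALSE])
    storage.mode(le) <- "double"; dimnames(le) <- NULL
    prefix <- as.integer(strsplit(samp$prefix[i], ",")[[1L]])
    sp <- samp$split[i]
    out[[sp]][[length(out[[sp]]) + 1L]] <- list(
      seq_index = samp$seq_index[i], rep = samp$rep[i], prefix = prefix,
      emb = e, valid = samp$valid[i],
      link_emb = le, link_label = as.integer(li$label),
      link_class = as.integer(li$class))
  }
  structure(c(out, list(grammar = grammar, prototypes = prototypes,
                        config = config)),
            class = "labeled_dataset")
}
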