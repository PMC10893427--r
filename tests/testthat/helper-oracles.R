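# Brute-force reference implementations, kept deliberately independent of the
# package's trie / batched code paths.

bf_is_valid <- function(seqs, x) {
  any(vapply(seqs, function(s) identical(as.integer(s), as.integer(x)), TRUE))
}

bf_is_possible <- function(seqs, prefix, nxt) {
  cand <- c(as.integer(prefix), as.integer(nxt))
  any(vapply(seqs, function(s)
    length(s) >= length(cand) &&
      identical(as.integer(s[seq_along(cand)]), cand), TRUE))
}

bf_successors <- function(seqs, prefix, n_classes) {
  which(vapply(0:(n_classes - 1L), function(c)
    bf_is_possible(seqs, prefix, c), TRUE)) - 1L
}

# independent confusion-matrix metrics via explicit counting loops
bf_metrics <- function(labels, preds) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(labels)) {
    if (labels[i] == 1 && preds[i] == 1) tp <- tp + 1L
    if (labels[i] == 0 && preds[i] == 1) fp <- fp + 1L
    if (labels[i] == 0 && preds[i] == 0) tn <- tn + 1L
    if (labels[i] == 1 && preds[i] == 0) fn <- fn + 1L
  }
  f1 <- function(tp, fp, fn) if (2 * tp + fp + fn == 0) 0
                             else 2 * tp / (2 * tp + fp + fn)
  list(accuracy = (tp + tn) / length(labels),
       macro_f1 = (f1(tp, fp, fn) + f1(tn, fn, fp)) / 2)
}

random_grammar <- function(n_classes = 5L, n_seqs = 6L, max_len = 8L) {
  seqs <- list(); keys <- character(0)
  while (length(seqs) < n_seqs) {
    s <- sample.int(n_classes, sample.int(max_len, 1L), replace = TRUE) - 1L
    k <- paste(s, collapse = ",")
    if (!(k %in% keys)) { keys <- c(keys, k); seqs[[length(seqs) + 1L]] <- s }
  }
  list(grammar = micro_grammar(paste0("c", seq_len(n_classes) - 1L), seqs),
       seqs = seqs, n_classes = n_classes)
}

toy_abc <- function() micro_grammar(c("a", "b", "c"), list(c("a", "b", "c")))
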