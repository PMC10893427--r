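#' Macro-activity grammars
#'
#' A grammar is the set of valid micro-activity sequences (macro-activities)
#' over an alphabet of micro-activity classes. It is the exact combinatorial
#' oracle used both to label synthetic training data and to test the learned
#' model: a sequence is *valid* when it equals a complete macro-activity, and
#' appending a class to a sequence is a *possible link* when the result is a
#' prefix (proper or full) of at least one macro-activity. Possibility is
#' judged against the whole grammar, not a single macro-activity, because
#' different macro-activities may share prefixes and a streaming recognizer
#' cannot know which one is underway.
#'
#' Internally the sequences are indexed by a prefix trie (hashed prefix keys
#' with child sets) so that validity, possibility and successor queries cost
#' one lookup; all queries agree with a brute-force scan of the sequence list.
#'
#' @param classes character vector of unique micro-activity class names.
#'   Classes receive contiguous integer ids starting at 0, in the given order.
#' @param sequences list of macro-activity sequences; each element is either a
#'   character vector of class names or an integer vector of class ids.
#'   Sequences must be non-empty and mutually distinct.
#' @return An object of class `micro_grammar` with elements `classes`
#'   (data.frame of `id`, `name`), `sequences` (list of integer id vectors)
#'   and the prefix index.
#' @examples
#' g <- micro_grammar(c("a", "b", "c"), list(c("a", "b", "c")))
#' is_valid_macro(g, c(0L, 1L, 2L))      # TRUE
#' is_possible_link(g, c(0L, 1L), 2L)    # TRUE
#' successors(g, 0L)                     # 1
#' @export
micro_grammar <- function(classes, sequences) {
  classes <- as.character(classes)
  if (length(classes) < 1L) stop("grammar needs at least one class")
  if (anyDuplicated(classes)) stop("class names must be unique")
  if (length(sequences) < 1L) stop("grammar needs at least one sequence")

  to_ids <- function(s) {
    if (is.character(s)) {
      idx <- match(s, classes)
      if (anyNA(idx)) stop("unknown class name(s): ",
                           paste(s[is.na(idx)], collapse = ", "))
      idx - 1L
    } else {
      s <- as.integer(s)
      if (length(s) && (min(s) < 0L || max(s) >= length(classes)))
        stop("class id out of range")
      s
    }
  }
  seqs <- lapply(sequences, to_ids)
  if (any(vapply(seqs, length, 1L) < 1L)) stop("sequences must be non-empty")
  keys <- vapply(seqs, function(s) paste(s, collapse = ","), "")
  if (anyDuplicated(keys)) stop("duplicate macro-activity sequence")

  # prefix trie: hashed prefix keys -> set of successor ids; plus the set of
  # complete sequences for exact validity lookups
  children <- new.env(parent = emptyenv(), hash = TRUE)
  complete <- new.env(parent = emptyenv(), hash = TRUE)
  for (s in seqs) {
    assign(trie_key(s), TRUE, envir = complete)
    for (t in seq_along(s)) {
      k <- trie_key(s[seq_len(t - 1L)])
      kids <- if (exists(k, envir = children, inherits = FALSE))
        get(k, envir = children) else integer(0)
      if (!(s[t] %in% kids)) assign(k, c(kids, s[t]), envir = children)
    }
  }

  structure(
    list(classes = data.frame(id = seq_along(classes) - 1L, name = classes,
                              stringsAsFactors = FALSE),
         sequences = seqs,
         .children = children, .complete = complete),
    class = "micro_grammar")
}

#' @export
print.micro_grammar <- function(x, ...) {
  lens <- vapply(x$sequences, length, 1L)
  cat(sprintf("micro_grammar: %d classes, %d macro sequences (lengths %d-%d)\n",
              nrow(x$classes), length(x$sequences), min(lens), max(lens)))
  invisible(x)
}

#' @export
n_classes <- function(grammar) UseMethod("n_classes")

#' @export
n_classes.micro_grammar <- function(grammar) nrow(grammar$classes)

# environment keys cannot be empty strings, so prefix keys carry a root marker
trie_key <- function(ids) paste(c("r", ids), collapse = ",")

check_ids <- function(grammar, ids, what = "sequence") {
  ids <- as.integer(ids)
  if (length(ids) && (anyNA(ids) || min(ids) < 0L ||
                      max(ids) >= nrow(grammar$classes)))
    stop("unknown class id in ", what)
  ids
}

#' Is a sequence a complete macro-activity?
#'
#' A micro-activity sequence is valid exactly when it is equal to one of the
#' grammar's macro-activity sequences; every proper subsequence (and every
#' non-member) is invalid.
#'
#' @param grammar a [micro_grammar()].
#' @param seq integer vector of class ids (may be empty; the empty sequence is
#'   never valid).
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_macro <- function(grammar, seq) {
  seq <- check_ids(grammar, seq)
  if (length(seq) == 0L) return(FALSE)
  exists(trie_key(seq), envir = grammar$.complete, inherits = FALSE)
}

#' Can a class extend a sequence into a possible one?
#'
#' Appending `next_class` to `prefix` is a possible link when the result is a
#' prefix (proper or full) of at least one macro-activity in the grammar; the
#' empty prefix means the start of a new sequence.
#'
#' @param grammar a [micro_grammar()].
#' @param prefix integer vector of class ids, possibly empty.
#' @param next_class single class id.
#' @return `TRUE` or `FALSE`.
#' @export
is_possible_link <- function(grammar, prefix, next_class) {
  prefix <- check_ids(grammar, prefix, "prefix")
  next_class <- check_ids(grammar, next_class, "next_class")
  if (length(next_class) != 1L) stop("next_class must be a single id")
  next_class %in% successors(grammar, prefix)
}

#' Set of classes that can extend a prefix
#'
#' Returns every class id `c` for which `prefix` followed by `c` is still a
#' prefix of some macro-activity; an empty result means no macro-activity
#' extends the prefix (for a complete sequence this is the "no possible
#' subsequent micro-activities" case of the label generator).
#'
#' @inheritParams is_possible_link
#' @return integer vector of class ids (possibly empty).
#' @export
successors <- function(grammar, prefix) {
  prefix <- check_ids(grammar, prefix, "prefix")
  k <- trie_key(prefix)
  if (exists(k, envir = grammar$.children, inherits = FALSE))
    sort(get(k, envir = grammar$.children)) else integer(0)
}

#' All prefixes of a macro-activity sequence, shortest first
#'
#' @param seq non-empty integer vector of class ids.
#' @return list of `length(seq)` integer vectors `seq[1:1], ..., seq[1:T]`.
#' @export
enumerate_prefixes <- function(seq) {
  seq <- as.integer(seq)
  if (length(seq) < 1L) stop("sequence must be non-empty")
  lapply(seq_along(seq), function(t) seq[seq_len(t)])
}

class_names <- function(grammar, ids) {
  grammar$classes$name[match(as.integer(ids), grammar$classes$id)]
}

#' Read / write grammar files
#'
#' Grammars are stored as JSON (or YAML, by file extension) with two fields:
#' `classes`, the list of class names, and `sequences`, a list of lists of
#' class names. The reader validates names and rejects duplicate sequences;
#' writing then reading gives back an identical grammar.
#'
#' @param path file path; `.yaml`/`.yml` selects YAML, anything else JSON.
#' @return `read_grammar` returns a [micro_grammar()]; `write_grammar`
#'   invisibly returns `path`.
#' @export
read_grammar <- function(path) {
  if (!file.exists(path)) stop("grammar file not found: ", path)
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML grammars")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  }
  if (is.null(obj$classes) || is.null(obj$sequences))
    stop("grammar file must contain 'classes' and 'sequences'")
  seqs <- lapply(obj$sequences, function(s) as.character(unlist(s)))
  micro_grammar(as.character(unlist(obj$classes)), seqs)
}

#' @rdname read_grammar
#' @param grammar a [micro_grammar()] to serialize.
#' @export
write_grammar <- function(grammar, path) {
  stopifnot(inherits(grammar, "micro_grammar"))
  obj <- list(classes = grammar$classes$name,
              sequences = lapply(grammar$sequences,
                                 function(s) class_names(grammar, s)))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to write YAML grammars")
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}
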