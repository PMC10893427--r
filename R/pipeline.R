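#' Streaming state for macro-activity segmentation
#'
#' The streaming recognizer consumes one micro-activity embedding at a time
#' and maintains the current (growing) micro-activity sequence plus an
#' archive of embeddings of interrupted sequences. A fresh stream is
#' initialized by placing the first embedding directly into the sequence —
#' the model is never evaluated on an empty sequence.
#'
#' @param first_emb embedding vector of the first micro-activity.
#' @param first_class optional class id, carried alongside the embeddings so
#'   that oracle heads (and diagnostics) can see the true classes.
#' @param max_archive maximum number of archived interrupted sequences; the
#'   oldest entries are evicted first (FIFO). Default unbounded.
#' @return list of class `stream_state` with `emb` (T x F matrix), `classes`
#'   (int vector or NULL), `archive` (list), `step`.
#' @export
stream_state <- function(first_emb, first_class = NULL, max_archive = Inf) {
  structure(list(emb = as_row_matrix(first_emb),
                 classes = if (is.null(first_class)) NULL
                           else as.integer(first_class),
                 archive = list(), step = 0L, max_archive = max_archive),
            class = "stream_state")
}

#' Decision heads backed by a trained model
#'
#' Adapts a [maglink_model()] to the head interface of [stream_step()]: the
#' graph embedding comes from [embed_sequence()], and both decisions use the
#' model's sigmoid outputs at the 0.5 threshold.
#'
#' @param model a trained [maglink_model()].
#' @param threshold decision threshold (default 0.5).
#' @return head list with functions `embed`, `valid`, `link`.
#' @export
model_heads <- function(model, threshold = 0.5) {
  list(
    embed = function(emb) embed_sequence(model, emb),
    valid = function(e, classes) validate_graph(model, e) >= threshold,
    link = function(e, classes, next_emb, next_class)
      predict_link(model, e, next_emb) >= threshold)
}

#' Oracle decision heads backed by a grammar
#'
#' Replaces the learned heads with the exact grammar oracle so the streaming
#' case logic can be exercised (and tested) independently of any learned
#' weights. Requires the stream to carry class ids alongside the embeddings.
#' The emitted "embedding" is a deterministic summary (the vertex mean) since
#' no embedding block is involved.
#'
#' @param grammar a [micro_grammar()].
#' @param embed optional replacement embedding function.
#' @return head list with functions `embed`, `valid`, `link`.
#' @export
mock_oracle_heads <- function(grammar, embed = NULL) {
  list(
    embed = embed %||% function(emb) colMeans(rbind(emb)),
    valid = function(e, classes) {
      if (is.null(classes)) stop("oracle heads need class ids in the stream")
      is_valid_macro(grammar, classes)
    },
    link = function(e, classes, next_emb, next_class) {
      if (is.null(classes) || is.null(next_class))
        stop("oracle heads need class ids in the stream")
      is_possible_link(grammar, classes, next_class)
    })
}

archive_push <- function(state, record) {
  state$archive[[length(state$archive) + 1L]] <- record
  while (length(state$archive) > state$max_archive)
    state$archive[[1L]] <- NULL
  state
}

#' One step of the streaming state machine
#'
#' Embeds the current sequence, asks the validator whether it is a complete
#' macro-activity (v) and the link predictor whether the incoming embedding
#' can extend it (l), then fires exactly one of four cases:
#' \itemize{
#'   \item not v, l: append the new micro-activity (CONTINUE);
#'   \item v, not l: emit the sequence embedding and start a new sequence
#'     with the incoming micro-activity (EMIT);
#'   \item v, l: emit the sequence embedding *and* keep growing — the valid
#'     macro-activity is also a prefix of a longer one (EMIT + CONTINUE);
#'   \item not v, not l: the sequence is interrupted or unknown — archive its
#'     embedding and start over with the incoming micro-activity (INTERRUPT).
#' }
#' The four predicates partition all (v, l) combinations, so exactly one
#' case fires per step.
#'
#' @param state a [stream_state()].
#' @param heads a head list from [model_heads()] or [mock_oracle_heads()].
#' @param next_emb embedding vector of the incoming micro-activity.
#' @param next_class optional class id of the incoming micro-activity.
#' @return list with `state` (updated) and `events` (list of event records
#'   with `kind` in EMIT/CONTINUE/INTERRUPT, `step`, `embedding`, `classes`).
#' @export
stream_step <- function(state, heads, next_emb, next_class = NULL) {
  stopifnot(inherits(state, "stream_state"), nrow(state$emb) >= 1L)
  next_emb <- as.numeric(next_emb)
  if (length(next_emb) != ncol(state$emb))
    stop("embedding width mismatch: stream has ", ncol(state$emb),
         ", got ", length(next_emb))
  state$step <- state$step + 1L
  E <- heads$embed(state$emb)
  v <- isTRUE(as.logical(heads$valid(E, state$classes)))
  l <- isTRUE(as.logical(heads$link(E, state$classes, next_emb, next_class)))
  events <- list()
  push_event <- function(kind, embedding = NULL) {
    events[[length(events) + 1L]] <<- list(kind = kind, step = state$step,
                                           embedding = embedding,
                                           classes = state$classes)
  }
  append_next <- function() {
    state$emb <<- rbind(state$emb, next_emb)
    if (!is.null(state$classes))
      state$classes <<- c(state$classes, as.integer(next_class))
  }
  reset_to_next <- function() {
    state$emb <<- rbind(next_emb)
    if (!is.null(state$classes))
      state$classes <<- as.integer(next_class)
  }
  if (!v && l) {                    # (a) grow the sequence
    push_event("CONTINUE")
    append_next()
  } else if (v && !l) {             # (b) closed macro-activity
    push_event("EMIT", E)
    reset_to_next()
  } else if (v && l) {              # (c) complete but still extendable
    push_event("EMIT", E)
    append_next()
  } else {                          # (d) interrupted / unknown
    state <- archive_push(state, list(embedding = E, classes = state$classes,
                                      step = state$step))
    push_event("INTERRUPT", E)
    reset_to_next()
  }
  list(state = state, events = events)
}

#' Run the state machine over a finite embedding stream
#'
#' Repeatedly applies [stream_step()]; at stream end a final validator check
#' on the residual sequence produces a terminal EMIT (valid) or INTERRUPT
#' (not valid).
#'
#' @param heads a head list from [model_heads()] or [mock_oracle_heads()].
#' @param emb matrix of embeddings, one per row, in stream order.
#' @param classes optional class ids per row (required for oracle heads).
#' @param state optional pre-existing [stream_state()] to continue from; by
#'   default the first stream row initializes a fresh state.
#' @param max_archive passed to [stream_state()] for a fresh state.
#' @return list with `state` (final) and `events` (ordered event log).
#' @export
run_stream <- function(heads, emb, classes = NULL, state = NULL,
                       max_archive = Inf) {
  emb <- as_row_matrix(emb)
  events <- list()
  start <- 1L
  if (is.null(state)) {
    if (nrow(emb) == 0L) return(list(state = NULL, events = list()))
    state <- stream_state(emb[1L, ], if (!is.null(classes)) classes[1L],
                          max_archive = max_archive)
    start <- 2L
  }
  for (i in seq_len(nrow(emb))[-seq_len(start - 1L)]) {
    r <- stream_step(state, heads, emb[i, ],
                     if (!is.null(classes)) classes[i])
    state <- r$state
    events <- c(events, r$events)
  }
  # terminal check on the residual sequence
  state$step <- state$step + 1L
  E <- heads$embed(state$emb)
  if (isTRUE(as.logical(heads$valid(E, state$classes)))) {
    events[[length(events) + 1L]] <- list(kind = "EMIT", step = state$step,
                                          embedding = E,
                                          classes = state$classes)
  } else {
    state <- archive_push(state, list(embedding = E, classes = state$classes,
                                      step = state$step))
    events[[length(events) + 1L]] <- list(kind = "INTERRUPT",
                                          step = state$step, embedding = E,
                                          classes = state$classes)
  }
  list(state = state, events = events)
}

#' Event log as a data.frame
#'
#' @param events event list from [run_stream()].
#' @return data.frame with columns `kind` and `step`.
#' @export
event_log <- function(events) {
  data.frame(kind = vapply(events, `[[`, "", "kind"),
             step = vapply(events, `[[`, 0L, "step"))
}
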