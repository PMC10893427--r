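#' Multi-task graph network for macro-activity recognition
#'
#' Builds the three-component network: a graph embedding block `E` (one
#' multi-head graph attention layer followed by Last Vertex Pooling), a graph
#' validator head `V` and a link predictor head `L`. The attention layer has
#' `heads` attention heads and a total output width of `2F`; head outputs are
#' concatenated when `2F` is divisible by the head count (per-head width
#' `2F/heads`), otherwise each head produces the full `2F` and heads are
#' averaged. Because the star adjacency directs every vertex (including the
#' self-loop) into the last vertex, only the last vertex aggregates the
#' sequence, and Last Vertex Pooling reads the graph embedding off that row.
#' Both heads are perceptrons with 3 hidden ReLU layers of width `2F` and a
#' sigmoid output; the validator consumes `E(G)` (width `2F`), the link
#' predictor the concatenation of `E(G)` with a candidate next embedding
#' (width `3F`). Decisions use a 0.5 threshold.
#'
#' @param F micro-activity embedding dimension.
#' @param heads number of attention heads (default 5).
#' @param pe logical: add sinusoidal positional encodings to vertex features
#'   before the attention layer (default TRUE). Encodings are never added to
#'   the candidate next-link embedding.
#' @param seed integer seed for weight initialization.
#' @param slope negative slope of the leaky rectifier inside the attention
#'   score (default 0.2).
#' @return object of class `maglink_model`.
#' @export
maglink_model <- function(F, heads = 5L, pe = TRUE, seed = 1L, slope = 0.2) {
  if (F < 1L || heads < 1L) stop("F and heads must be positive")
  out_w <- 2L * F
  concat <- out_w %% heads == 0L
  dh <- if (concat) out_w %/% heads else out_w
  set.seed(seed)
  params <- list(
    gat = list(W = xavier_uniform(F, dh * heads),
               a_src = xavier_uniform(dh, heads),
               a_dst = xavier_uniform(dh, heads),
               b = numeric(out_w)),
    V = mlp_init(c(out_w, out_w, out_w, out_w, 1L)),
    L = mlp_init(c(3L * F, out_w, out_w, out_w, 1L)))
  structure(list(F = as.integer(F), heads = as.integer(heads),
                 out_width = out_w, head_width = dh, concat = concat,
                 pe = isTRUE(pe), slope = slope, seed = as.integer(seed),
                 params = params),
            class = "maglink_model")
}

#' @export
print.maglink_model <- function(x, ...) {
  cat(sprintf(paste0("maglink_model: F = %d, %d attention heads (%s), ",
                     "embedding width %d, PE %s\n"),
              x$F, x$heads, if (x$concat) "concatenated" else "averaged",
              x$out_width, if (x$pe) "on" else "off"))
  invisible(x)
}

# ---- batched embedding block -----------------------------------------------
# X: stacked vertex features (N x F, positional encodings already applied);
# gidx: graph index per vertex (1..nG, every graph contiguous and present);
# last_idx: row index of each graph's last vertex.
gat_forward <- function(model, X, gidx, last_idx, nG) {
  p <- model$params$gat
  H <- model$heads; dh <- model$head_width
  Z <- X %*% p$W
  gfac <- factor(gidx, levels = seq_len(nG))
  heads_out <- vector("list", H)
  hcache <- vector("list", H)
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    zh <- Z[, cols, drop = FALSE]
    s_src <- drop(zh %*% p$a_src[, h])
    s_dst <- drop(Z[last_idx, cols, drop = FALSE] %*% p$a_dst[, h])
    pre <- s_src + s_dst[gidx]
    e <- ifelse(pre > 0, pre, model$slope * pre)
    m <- as.numeric(tapply(e, gfac, max))
    ex <- exp(e - m[gidx])
    den <- as.numeric(rowsum(ex, gidx))
    alpha <- ex / den[gidx]
    heads_out[[h]] <- rowsum(alpha * zh, gidx)
    hcache[[h]] <- list(cols = cols, alpha = alpha, pre = pre)
  }
  U <- if (model$concat) do.call(cbind, heads_out)
       else Reduce(`+`, heads_out) / H
  U <- sweep(U, 2L, p$b, `+`)
  E <- U
  list(E = E,
       cache = list(X = X, Z = Z, gidx = gidx, last_idx = last_idx, nG = nG,
                    heads = hcache, U = U))
}

# dE: nG x 2F gradient w.r.t. the pooled embeddings. Returns gat grads.
gat_backward <- function(model, cache, dE) {
  p <- model$params$gat
  H <- model$heads; dh <- model$head_width
  dU <- dE
  db <- colSums(dU)
  gidx <- cache$gidx; last_idx <- cache$last_idx
  dW <- array(0, dim = dim(p$W))
  da_src <- array(0, dim = dim(p$a_src))
  da_dst <- array(0, dim = dim(p$a_dst))
  for (h in seq_len(H)) {
    hc <- cache$heads[[h]]
    cols <- hc$cols
    zh <- cache$Z[, cols, drop = FALSE]
    dH <- if (model$concat) dU[, cols, drop = FALSE] else dU / H
    alpha <- hc$alpha
    # through the weighted sum H = sum_i alpha_i z_i
    dHg <- dH[gidx, , drop = FALSE]
    dalpha <- rowSums(zh * dHg)
    dz <- alpha * dHg
    # softmax backward within each graph
    S <- as.numeric(rowsum(alpha * dalpha, gidx))
    de <- alpha * (dalpha - S[gidx])
    ds <- de * ifelse(hc$pre > 0, 1, model$slope)
    da_src[, h] <- drop(crossprod(zh, ds))
    sum_ds <- as.numeric(rowsum(ds, gidx))
    da_dst[, h] <- drop(crossprod(cache$Z[last_idx, cols, drop = FALSE],
                                  sum_ds))
    dz <- dz + outer(ds, p$a_src[, h])
    dz[last_idx, ] <- dz[last_idx, ] + outer(sum_ds, p$a_dst[, h])
    dW[, cols] <- dW[, cols] + crossprod(cache$X, dz)
  }
  list(W = dW, a_src = da_src, a_dst = da_dst, b = db)
}

# promote a bare embedding vector to a 1-row matrix without picking up names
as_row_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1L)
}

# stack a list of embedding matrices into one batch, applying positional
# encodings per graph when the model asks for them
build_batch <- function(emb_list, model) {
  Ts <- vapply(emb_list, nrow, 1L)
  X <- do.call(rbind, lapply(emb_list, function(e) {
    if (model$pe) e + positional_encoding(nrow(e), ncol(e)) else e
  }))
  gidx <- rep(seq_along(emb_list), Ts)
  last_idx <- cumsum(Ts)
  list(X = X, gidx = gidx, last_idx = last_idx, nG = length(emb_list))
}

#' Embed one micro-activity graph
#'
#' Runs the attention layer over the star graph and pools the last vertex.
#' The graph's vertex features are used as given; callers wanting the
#' model's positional-encoding convention should use [embed_sequence()].
#'
#' @param model a [maglink_model()].
#' @param graph a [build_graph()] result with `F` matching the model.
#' @return numeric vector of length `2F`.
#' @export
embed_graph <- function(model, graph) {
  stopifnot(inherits(graph, "micro_graph"))
  if (graph$F != model$F)
    stop("graph feature width ", graph$F, " does not match model F ", model$F)
  fw <- gat_forward(model, graph$V, rep(1L, graph$T), graph$T, 1L)
  drop(fw$E)
}

#' Embed a raw embedding sequence with the model's conventions
#'
#' Builds the star graph, applies positional encodings when the model was
#' configured with them, and returns the pooled graph embedding.
#'
#' @param model a [maglink_model()].
#' @param emb T x F matrix of micro-activity embeddings in temporal order.
#' @return numeric vector of length `2F`.
#' @export
embed_sequence <- function(model, emb) {
  emb <- as_row_matrix(emb)
  b <- build_batch(list(emb), model)
  drop(gat_forward(model, b$X, b$gidx, b$last_idx, 1L)$E)
}

#' Last Vertex Pooling
#'
#' Extracts the final vertex's features as the whole-graph embedding; with
#' the star adjacency only the last vertex aggregates the sequence, so its
#' row is the graph representation.
#'
#' @param node_features T x W matrix of post-attention vertex features.
#' @return numeric vector of length W (row T).
#' @export
last_vertex_pool <- function(node_features) {
  node_features <- as_row_matrix(node_features)
  if (nrow(node_features) < 1L) stop("empty node feature table")
  node_features[nrow(node_features), ]
}

#' Graph validator probability
#'
#' @param model a [maglink_model()].
#' @param e graph embedding vector (length `2F`) or a matrix of embeddings,
#'   one per row.
#' @return probability (or vector of probabilities) that the embedded
#'   sequence is a complete macro-activity; decide with a 0.5 threshold.
#' @export
validate_graph <- function(model, e) {
  e <- as_row_matrix(e)
  if (ncol(e) != model$out_width)
    stop("embedding width ", ncol(e), " does not match 2F = ",
         model$out_width)
  mlp_forward(model$params$V, e)$prob
}

#' Link predictor probability
#'
#' Concatenates the graph embedding with the candidate next micro-activity
#' embedding (total width `3F`) and scores whether appending it keeps the
#' sequence possible.
#'
#' @param model a [maglink_model()].
#' @param e graph embedding vector (length `2F`) or matrix, one per row.
#' @param next_emb candidate embedding vector (length `F`) or matrix.
#' @return probability (or vector) of the link being possible.
#' @export
predict_link <- function(model, e, next_emb) {
  e <- as_row_matrix(e); next_emb <- as_row_matrix(next_emb)
  if (ncol(e) != model$out_width) stop("embedding width mismatch")
  if (ncol(next_emb) != model$F) stop("next embedding width mismatch")
  mlp_forward(model$params$L, cbind(e, next_emb))$prob
}

#' Save / load a model checkpoint
#'
#' A checkpoint is one self-describing JSON file holding the configuration
#' (F, heads, PE flag, slope, seed) and all weights of the embedding block
#' and both heads at full precision; loading restores an identical model.
#'
#' @param model a [maglink_model()].
#' @param path file path for the JSON checkpoint.
#' @export
save_model <- function(model, path) {
  enc <- function(x) {
    if (is.list(x)) lapply(x, enc)
    else list(dim = dim(x) %||% length(x), data = as.numeric(x))
  }
  obj <- list(F = model$F, heads = model$heads, pe = model$pe,
              slope = model$slope, seed = model$seed,
              params = enc(model$params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  dec <- function(x) {
    if (is.list(x) && !is.null(x$dim) && !is.null(x$data)) {
      if (length(x$dim) == 2L) matrix(x$data, x$dim[1L], x$dim[2L])
      else as.numeric(x$data)
    } else lapply(x, dec)
  }
  model <- maglink_model(obj$F, obj$heads, obj$pe, obj$seed, obj$slope)
  model$params <- dec(obj$params)
  model
}
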