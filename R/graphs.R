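#' Star graph of a micro-activity sequence
#'
#' Encodes an ordered sequence of T micro-activity embeddings as a directed
#' star graph: every vertex carries the F-dimensional embedding of one
#' micro-activity and has a single outgoing edge to the last (T-th) vertex,
#' which also carries a self-loop. The adjacency matrix is therefore all
#' zeros except for a final column of ones, and the graph has exactly T
#' edges. Message passing along this topology aggregates the whole sequence
#' into the last vertex, but the topology alone is blind to temporal order —
#' the sinusoidal positional encodings of [positional_encoding()] restore it.
#'
#' @param seq a T x F numeric matrix (row t = embedding of the t-th
#'   micro-activity) or a list of equal-length numeric vectors.
#' @return An object of class `micro_graph`: list with `V` (T x F vertex
#'   feature matrix), `A` (T x T adjacency), `T` and `F`.
#' @examples
#' g <- build_graph(matrix(rnorm(6), nrow = 3))
#' g$A             # last column all ones
#' @export
build_graph <- function(seq) {
  if (is.list(seq)) {
    if (length(seq) == 0L) stop("sequence must contain at least one embedding")
    lens <- vapply(seq, length, 1L)
    if (length(unique(lens)) != 1L)
      stop("all embeddings must have the same length")
    seq <- do.call(rbind, lapply(seq, as.numeric))
  }
  seq <- as.matrix(seq)
  if (nrow(seq) < 1L) stop("sequence must contain at least one embedding")
  if (!is.numeric(seq) || anyNA(seq)) stop("embeddings must be numeric")
  T <- nrow(seq)
  A <- matrix(0L, T, T)
  A[, T] <- 1L
  structure(list(V = seq, A = A, T = T, F = ncol(seq)), class = "micro_graph")
}

#' @export
print.micro_graph <- function(x, ...) {
  cat(sprintf("micro_graph: T = %d vertices, F = %d features, %d edges\n",
              x$T, x$F, sum(x$A)))
  invisible(x)
}

#' Edge list of a star graph
#'
#' @param graph a [build_graph()] result.
#' @return data.frame with columns `from`, `to` (1-based vertex indices).
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "micro_graph"))
  idx <- which(graph$A == 1L, arr.ind = TRUE)
  data.frame(from = idx[, 1L], to = idx[, 2L])[order(idx[, 1L]), ,
                                               drop = FALSE]
}

#' Sinusoidal positional encodings for graph vertices
#'
#' Deterministic T x F table with
#' \deqn{PE(t,f) = \cos(t / 10000^{2f/F})} for even feature index f and
#' \deqn{PE(t,f) = \sin(t / 10000^{2f/F})} for odd f, with t the 1-based
#' temporal vertex index and f the 0-based feature index. Note two deliberate
#' departures from the classic transformer table, kept exactly as used here:
#' cosine goes to the even features (sine to the odd ones), and the exponent
#' uses the raw feature index f rather than the pair index floor(f/2).
#'
#' @param T number of vertices (>= 1).
#' @param F embedding dimension (>= 1).
#' @param t_offset added to the 1-based temporal index; 0 (default) keeps
#'   t in 1..T, -1 switches to 0-based indexing for ablations.
#' @return T x F numeric matrix with all entries in [-1, 1].
#' @export
positional_encoding <- function(T, F, t_offset = 0) {
  if (T < 1L || F < 1L) stop("T and F must be positive")
  t <- seq_len(T) + t_offset
  f <- 0:(F - 1L)
  angle <- outer(t, 10000^(2 * f / F), `/`)
  pe <- matrix(0, T, F)
  even <- f %% 2L == 0L
  pe[, even] <- cos(angle[, even])
  pe[, !even] <- sin(angle[, !even])
  pe
}

#' Add positional encodings to a graph's vertex features
#'
#' Element-wise sum of the vertex feature table and the positional-encoding
#' table; the adjacency is untouched. Applying then subtracting the same
#' table is the identity. Encodings are added to graph vertices only, never
#' to a candidate next-link embedding.
#'
#' @param graph a [build_graph()] result.
#' @param t_offset passed to [positional_encoding()].
#' @return the graph with updated `V`.
#' @export
apply_positional_encoding <- function(graph, t_offset = 0) {
  stopifnot(inherits(graph, "micro_graph"))
  graph$V <- graph$V + positional_encoding(graph$T, graph$F, t_offset)
  graph
}

#' Export a graph as plain-text edge list plus vertex-feature CSV
#'
#' @param graph a [build_graph()] result.
#' @param edges_path,vertices_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_graph <- function(graph, edges_path, vertices_path) {
  utils::write.table(graph_edges(graph), edges_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(graph$V), vertices_path, row.names = FALSE)
  invisible(c(edges_path, vertices_path))
}
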