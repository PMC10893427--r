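#' Class-conditional embedding prototypes
#'
#' A prototype set holds one mean embedding vector per micro-activity class
#' together with a shared, pre-defined standard deviation. Micro-activity
#' embeddings are modelled as isotropic Gaussians N(mu_i, sigma): independent
#' per-coordinate normals with common sigma around the class mean. Prototypes
#' either come from real windowed sensor features via [fit_class_prototypes()]
#' or are constructed directly (e.g. random well-separated means for synthetic
#' studies).
#'
#' @param means n x F numeric matrix of class means, rows in class-id order
#'   (row i = class id i-1); row names, if present, are class names.
#' @param sigma shared standard deviation, >= 0.
#' @return object of class `prototype_set` with `means`, `sigma`, `F`, `n`.
#' @export
prototype_set <- function(means, sigma) {
  means <- as.matrix(means)
  if (!is.numeric(means) || anyNA(means)) stop("means must be numeric")
  if (sigma < 0) stop("sigma must be non-negative")
  structure(list(means = means, sigma = as.numeric(sigma),
                 F = ncol(means), n = nrow(means)),
            class = "prototype_set")
}

#' @export
print.prototype_set <- function(x, ...) {
  cat(sprintf("prototype_set: %d classes, F = %d, sigma = %g\n",
              x$n, x$F, x$sigma))
  invisible(x)
}

#' Fit per-class prototypes from windowed feature data
#'
#' Projects each fixed-length window of sensor features to F dimensions with a
#' pluggable projector (a stand-in for a seeded UMAP or any other
#' dimensionality reducer), then averages the projected windows per class to
#' obtain the class means. The standard deviation is supplied by the caller —
#' it is a pre-defined generator parameter, not estimated from the windows.
#'
#' @param features numeric matrix, one window per row.
#' @param class_ids integer class id (0-based) per window.
#' @param n_classes total number of classes; every class needs >= 1 window.
#' @param sigma shared standard deviation for the resulting prototype set.
#' @param projector function(features, F, seed) -> matrix with F columns;
#'   must be deterministic given `seed`. The default projects onto the first
#'   F columns (identity when the features are already F-dimensional).
#' @param F target embedding dimension.
#' @param seed passed to the projector.
#' @return a [prototype_set()].
#' @export
fit_class_prototypes <- function(features, class_ids, n_classes, sigma,
                                 projector = project_columns,
                                 F = ncol(features), seed = 1L) {
  features <- as.matrix(features)
  class_ids <- as.integer(class_ids)
  stopifnot(length(class_ids) == nrow(features))
  missing <- setdiff(0:(n_classes - 1L), unique(class_ids))
  if (length(missing))
    stop("no windows for class id(s): ", paste(missing, collapse = ", "))
  proj <- projector(features, F, seed)
  proj <- as.matrix(proj)
  if (ncol(proj) != F) stop("projector returned ", ncol(proj),
                            " columns, expected ", F)
  means <- t(vapply(0:(n_classes - 1L), function(c)
    colMeans(proj[class_ids == c, , drop = FALSE]), numeric(F)))
  prototype_set(means, sigma)
}

#' Deterministic column-truncation projector
#'
#' Keeps the first F feature columns; the identity map when the input already
#' has F columns. Used as the default deterministic projector in tests and
#' examples; swap in any reducer with the same signature for real data.
#'
#' @param features numeric matrix.
#' @param F number of components.
#' @param seed ignored (the projector is deterministic).
#' @export
project_columns <- function(features, F, seed = NULL) {
  if (ncol(features) < F) stop("fewer feature columns than components")
  as.matrix(features)[, seq_len(F), drop = FALSE]
}

#' Similarity score of a prototype set
#'
#' s = (1/n^2) * sum over unordered class pairs of 1 / ||mu_i - mu_j||, the
#' mean inverse Euclidean distance between class means with an n^2 (not
#' choose(n,2)) normalization. Lower values mean better-separated, more
#' distinguishable micro-activity classes. The score is invariant under rigid
#' rotations and translations of the mean vectors.
#'
#' @param prototypes a [prototype_set()] with >= 2 classes.
#' @return non-negative scalar.
#' @export
embedding_similarity <- function(prototypes) {
  stopifnot(inherits(prototypes, "prototype_set"))
  n <- prototypes$n
  if (n < 2L) stop("similarity needs at least two classes")
  d <- as.matrix(stats::dist(prototypes$means))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  if (any(d[pairs] == 0)) {
    bad <- pairs[which(d[pairs] == 0)[1L], ]
    stop(sprintf("classes %d and %d have identical means (zero distance)",
                 bad[1L] - 1L, bad[2L] - 1L))
  }
  sum(1 / d[pairs]) / n^2
}

#' Draw one embedding for a class
#'
#' One draw from the isotropic Gaussian N(mu_i, sigma); with sigma = 0 the
#' class mean is returned exactly. Uses R's global RNG stream, so results are
#' reproducible under `set.seed()`.
#'
#' @param prototypes a [prototype_set()].
#' @param class_id 0-based class id.
#' @return numeric vector of length F.
#' @export
sample_embedding <- function(prototypes, class_id) {
  class_id <- as.integer(class_id)
  if (class_id < 0L || class_id >= prototypes$n) stop("unknown class id")
  mu <- prototypes$means[class_id + 1L, ]
  if (prototypes$sigma == 0) return(as.numeric(mu))
  stats::rnorm(prototypes$F, mean = mu, sd = prototypes$sigma)
}

#' Random well-separated prototype means
#'
#' Draws class means uniformly in a hypercube and rejects configurations whose
#' minimum pairwise distance falls below `min_dist`, rescaling the cube until
#' the constraint holds. Convenient for synthetic studies where class
#' separation (relative to sigma) is the controlled variable.
#'
#' @param n_classes number of classes.
#' @param F embedding dimension.
#' @param sigma shared standard deviation of the resulting set.
#' @param min_dist required minimum pairwise distance between means.
#' @param half_width half-width of the sampling hypercube.
#' @return a [prototype_set()].
#' @export
random_prototypes <- function(n_classes, F, sigma, min_dist = 10 * sigma,
                              half_width = max(1, min_dist * n_classes / 4)) {
  for (i in 1:200) {
    means <- matrix(stats::runif(n_classes * F, -half_width, half_width),
                    nrow = n_classes)
    if (n_classes < 2L || min(stats::dist(means)) >= min_dist)
      return(prototype_set(means, sigma))
    half_width <- half_width * 1.25
  }
  stop("could not place ", n_classes, " means at min distance ", min_dist)
}

#' Read / write prototype CSV files
#'
#' One row per class: `class` (name or id) followed by the F mean
#' coordinates; sigma travels in a sidecar JSON file `<path>.meta.json`.
#'
#' @param prototypes a [prototype_set()].
#' @param path CSV file path.
#' @export
write_prototypes <- function(prototypes, path) {
  df <- data.frame(class = rownames(prototypes$means) %||%
                     as.character(0:(prototypes$n - 1L)),
                   prototypes$means, check.names = FALSE)
  colnames(df) <- c("class", paste0("f", seq_len(prototypes$F) - 1L))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(sigma = prototypes$sigma),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_prototypes
#' @export
read_prototypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  means <- as.matrix(df[, -1L, drop = FALSE])
  rownames(means) <- as.character(df[[1L]])
  prototype_set(means, meta$sigma)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
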