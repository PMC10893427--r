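# Minimal dense-network machinery used by the graph embedding block and the
# two task heads: Xavier-uniform initialization, ReLU multilayer perceptrons
# with a sigmoid output, exact analytic backprop, and an Adam optimizer that
# walks arbitrary nested parameter lists. Everything draws from R's global
# RNG so a single set.seed() makes runs reproducible.

xavier_uniform <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

# layers: list of list(W, b); all hidden activations ReLU, output linear
# (the sigmoid is fused with the cross-entropy in the loss gradient)
mlp_init <- function(dims) {
  lapply(seq_len(length(dims) - 1L), function(i)
    list(W = xavier_uniform(dims[i], dims[i + 1L]),
         b = numeric(dims[i + 1L])))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_forward <- function(layers, X) {
  k <- length(layers)
  caches <- vector("list", k)
  A <- X
  for (i in seq_len(k)) {
    pre <- sweep(A %*% layers[[i]]$W, 2L, layers[[i]]$b, `+`)
    caches[[i]] <- list(input = A, pre = pre)
    A <- if (i < k) pmax(pre, 0) else pre
  }
  list(logit = drop(A), prob = drop(sigmoid(A)), caches = caches)
}

# dlogit: gradient of the loss w.r.t. the output pre-activation (n-vector).
# Returns per-layer gradients plus the gradient w.r.t. the network input.
mlp_backward <- function(layers, caches, dlogit) {
  k <- length(layers)
  grads <- vector("list", k)
  dA <- matrix(dlogit, ncol = 1L)
  for (i in rev(seq_len(k))) {
    dpre <- if (i < k) dA * (caches[[i]]$pre > 0) else dA
    grads[[i]] <- list(W = crossprod(caches[[i]]$input, dpre),
                       b = colSums(dpre))
    dA <- dpre %*% t(layers[[i]]$W)
  }
  list(grads = grads, dX = dA)
}

# binary cross-entropy with probability clipping for numerical stability
bce_loss <- function(prob, label, clip = 1e-7) {
  if (length(prob) == 0L) return(0)
  p <- pmin(pmax(prob, clip), 1 - clip)
  -mean(label * log(p) + (1 - label) * log(1 - p))
}

# Adam over a nested list of numeric arrays (mirror-structured state)
adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk)
    else list(m = array(0, dim = dim(p) %||% length(p)),
              v = array(0, dim = dim(p) %||% length(p)))
  }
  list(moments = walk(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.001, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, s) {
    if (is.list(p)) {
      for (nm in seq_along(p)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p; s[[nm]] <- r$s
      }
      list(p = p, s = s)
    } else {
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mh <- s$m / (1 - beta1^t)
      vh <- s$v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
    }
  }
  r <- walk(params, grads, state$moments)
  list(params = r$p, state = list(moments = r$s, t = t))
}

# element-wise sum of two mirror-structured gradient lists
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) mapply(grad_add, a, b, SIMPLIFY = FALSE) else a + b
}

zero_grads <- function(params) {
  if (is.list(params)) lapply(params, zero_grads)
  else array(0, dim = dim(params) %||% length(params))
}
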