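# CART-style regression trees, grown greedily with variance-reduction
# splits. One splitter serves both ensemble families: for 0/1 responses
# variance reduction is equivalent to the Gini criterion (both are
# n * p * (1 - p) up to a constant), and gradient boosting fits trees to
# residuals with an optional Newton (hessian-weighted) leaf value.
# No tree package is available in the target environment, so this is a
# self-contained implementation sized for desk-scale feature tables.

# Find the best variance-reducing split of (x, y); returns NULL when no
# admissible split exists.
best_split <- function(X, y, min_leaf) {
  n <- length(y)
  best <- NULL
  best_score <- Inf
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]; ys <- y[ord]
    cs <- cumsum(ys); css <- cumsum(ys^2)
    i <- seq_len(n - 1L)
    ok <- which(xs[i] < xs[i + 1L] & i >= min_leaf & (n - i) >= min_leaf)
    if (!length(ok)) next
    nl <- ok; nr <- n - ok
    sse_l <- css[ok] - cs[ok]^2 / nl
    sse_r <- (css[n] - css[ok]) - (cs[n] - cs[ok])^2 / nr
    score <- sse_l + sse_r
    k <- which.min(score)
    if (score[k] < best_score - 1e-12) {
      best_score <- score[k]
      best <- list(var = j, split = (xs[ok[k]] + xs[ok[k] + 1L]) / 2,
                   score = score[k])
    }
  }
  best
}

# Grow one tree. `h` are per-row hessian weights for Newton-step leaves
# (leaf value = sum(y) / sum(h)); with h = 1 the leaf is the plain mean.
grow_tree <- function(X, y, h = rep(1, length(y)), max_depth = 4L,
                      min_split = 4L, min_leaf = 2L, depth = 0L) {
  leaf_value <- sum(y) / max(sum(h), 1e-12)
  if (depth >= max_depth || length(y) < max(min_split, 2L) ||
      stats::var(y) <= 1e-12)
    return(list(leaf = TRUE, value = leaf_value))
  sp <- best_split(X, y, min_leaf)
  if (is.null(sp)) return(list(leaf = TRUE, value = leaf_value))
  left <- X[, sp$var] <= sp$split
  list(leaf = FALSE, var = sp$var, split = sp$split,
       left = grow_tree(X[left, , drop = FALSE], y[left], h[left],
                        max_depth, min_split, min_leaf, depth + 1L),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], h[!left],
                         max_depth, min_split, min_leaf, depth + 1L))
}

predict_tree <- function(node, X) {
  out <- numeric(nrow(X))
  recurse <- function(node, idx) {
    if (!length(idx)) return()
    if (isTRUE(node$leaf)) {
      out[idx] <<- node$value
      return()
    }
    left <- X[idx, node$var] <= node$split
    recurse(node$left, idx[left])
    recurse(node$right, idx[!left])
  }
  recurse(node, seq_len(nrow(X)))
  out
}

# Bagged trees: bootstrap-resampled trees on 0/1 labels, probabilities
# averaged across trees.
fit_bagged <- function(X, y, n_trees = 100L, max_depth = 4L, seed = 1L) {
  n <- nrow(X)
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    grow_tree(X[idx, , drop = FALSE], y[idx], max_depth = max_depth)
  }))
  structure(list(trees = trees, type = "bag"), class = "tree_ensemble_fit")
}

# Gradient boosting with logistic loss and Newton-step leaf values.
fit_boosted <- function(X, y, n_trees = 100L, max_depth = 2L,
                        learning_rate = 0.1, seed = 1L) {
  p0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
  f0 <- log(p0 / (1 - p0))
  f <- rep(f0, length(y))
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    p <- stats::plogis(f)
    g <- y - p
    h <- pmax(p * (1 - p), 1e-6)
    tr <- grow_tree(X, g, h, max_depth = max_depth)
    trees[[b]] <- tr
    f <- f + learning_rate * predict_tree(tr, X)
  }
  structure(list(trees = trees, type = "boost", f0 = f0,
                 learning_rate = learning_rate),
            class = "tree_ensemble_fit")
}

predict_fit <- function(fit, X) {
  if (fit$type == "bag") {
    probs <- vapply(fit$trees, function(tr) predict_tree(tr, X),
                    numeric(nrow(X)))
    if (nrow(X) == 1L) probs <- matrix(probs, nrow = 1L)
    pmin(pmax(rowMeans(probs), 0), 1)
  } else {
    f <- rep(fit$f0, nrow(X))
    for (tr in fit$trees) f <- f + fit$learning_rate * predict_tree(tr, X)
    stats::plogis(f)
  }
}
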