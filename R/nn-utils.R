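# Small numerical helpers shared by the encoder, predictor and hypernetwork.
# All parameters live in nested named lists of numeric matrices/vectors; the
# helpers below flatten such trees for the optimizer and gradient checks.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Row-wise softmax, numerically stabilized.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Add a bias vector to every row of a matrix.
add_bias <- function(x, b) x + rep(b, each = nrow(x))

# Kaiming-style initialization for a fan_in x fan_out weight matrix.
he_init <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
}

# Sum rows of `x` into an accumulator by (possibly duplicated) row index.
# Plain `acc[idx, ] <- acc[idx, ] + x` silently drops duplicate additions.
accumulate_rows <- function(acc, idx, x) {
  rs <- rowsum(x, group = idx)
  rows <- as.integer(rownames(rs))
  acc[rows, ] <- acc[rows, , drop = FALSE] + rs
  acc
}

# Scatter-sum `x` rows into an n_out-row matrix of zeros by index.
scatter_sum <- function(x, idx, n_out) {
  out <- matrix(0, n_out, ncol(x))
  if (nrow(x) > 0) out <- accumulate_rows(out, idx, x)
  out
}

## ---- parameter trees -------------------------------------------------------

# Flatten a nested list of numeric arrays into a named flat list
# ("a.b.W" = matrix). Non-numeric leaves are skipped.
tree_leaves <- function(tree, prefix = "") {
  out <- list()
  for (nm in names(tree)) {
    x <- tree[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(x)) {
      out <- c(out, tree_leaves(x, key))
    } else if (is.numeric(x)) {
      out[[key]] <- x
    }
  }
  out
}

# Write flat named leaves back into a tree of the same shape.
tree_set_leaves <- function(tree, leaves, prefix = "") {
  for (nm in names(tree)) {
    x <- tree[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(x)) {
      tree[[nm]] <- tree_set_leaves(x, leaves, key)
    } else if (is.numeric(x) && key %in% names(leaves)) {
      val <- leaves[[key]]
      stopifnot(length(val) == length(x))
      tree[[nm]][] <- val
    }
  }
  tree
}

# Elementwise a + s * b over two flat leaf lists with matching names.
leaves_axpy <- function(a, b, s = 1) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + s * b[[nm]]
  a
}

leaves_global_norm <- function(leaves) {
  sqrt(sum(vapply(leaves, function(x) sum(x^2), numeric(1))))
}

# Scale gradients so their global L2 norm is at most `max_norm`.
clip_global_norm <- function(leaves, max_norm) {
  gn <- leaves_global_norm(leaves)
  if (is.finite(gn) && gn > max_norm) {
    leaves <- lapply(leaves, function(x) x * (max_norm / gn))
  }
  leaves
}

## ---- Adam optimizer --------------------------------------------------------

adam_init <- function(leaves) {
  list(
    m = lapply(leaves, function(x) x * 0),
    v = lapply(leaves, function(x) x * 0),
    t = 0L
  )
}

# One Adam step; returns list(leaves = updated parameters, state = state).
adam_step <- function(leaves, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    leaves[[nm]] <- leaves[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(leaves = leaves, state = state)
}

## ---- misc ------------------------------------------------------------------

# Mean softmax cross-entropy from logits against integer labels in {0,1};
# optional class balancing reweights so both classes contribute equally.
# Loss is computed through log-sum-exp so it stays finite and exactly
# consistent with the returned gradient even for saturated logits. Returns
# list(loss, dlogits) with dlogits the gradient with respect to the logits.
cross_entropy <- function(logits, labels, balanced = TRUE) {
  n <- nrow(logits)
  y <- cbind(1 - labels, labels)
  if (balanced) {
    n1 <- sum(labels)
    n0 <- n - n1
    w <- ifelse(labels == 1, if (n1 > 0) n / (2 * n1) else 0,
                if (n0 > 0) n / (2 * n0) else 0)
  } else {
    w <- rep(1, n)
  }
  wsum <- sum(w)
  zmax <- apply(logits, 1L, max)
  zc <- logits - zmax
  lse <- log(rowSums(exp(zc)))
  loglik <- zc[cbind(seq_len(n), labels + 1L)] - lse
  loss <- sum(w * (-loglik)) / wsum
  probs <- exp(zc) / rowSums(exp(zc))
  dlogits <- (probs - y) * (w / wsum)
  list(loss = loss, dlogits = dlogits)
}
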