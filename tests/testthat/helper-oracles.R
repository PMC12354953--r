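# Independent reference implementations (explicit per-node/per-row loops)
# used as oracles against the vectorized code paths, plus small fixture
# builders. These deliberately share no code with the package internals.

# random typed graph as a molecule_graph, exercising the full categorical
# vocabulary (chirality, bond types, bond directions)
random_test_graph <- function(n_nodes, p_edge = 0.3) {
  stopifnot(n_nodes >= 1)
  atom <- sample(c(6L, 7L, 8L, 16L, 9L, 119L), n_nodes, replace = TRUE)
  chir <- sample(1:4, n_nodes, replace = TRUE)
  from <- integer(0); to <- integer(0)
  if (n_nodes >= 2) {
    for (i in 2:n_nodes) { # random spanning tree keeps the graph connected
      j <- sample(i - 1L, 1)
      from <- c(from, j); to <- c(to, i)
    }
    extra <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    keep <- stats::runif(nrow(extra)) < p_edge / n_nodes
    for (r in which(keep)) {
      a <- extra[r, 1]; b <- extra[r, 2]
      if (!any(from == a & to == b)) { from <- c(from, a); to <- c(to, b) }
    }
  }
  m <- length(from)
  bt <- sample(1:3, m, replace = TRUE)
  bd_f <- sample(1:3, m, replace = TRUE)
  bd_r <- sample(1:3, m, replace = TRUE)
  molecule_graph(
    node_atom_type = atom, node_chirality = chir,
    edge_index = cbind(c(from, to), c(to, from)),
    edge_bond_type = c(bt, bt), edge_bond_dir = c(bd_f, bd_r)
  )
}

# relabel the nodes of a molecule_graph by a permutation
permute_graph <- function(g, perm) {
  inv <- order(perm) # inv[old] = new position
  molecule_graph(
    node_atom_type = g$node_atom_type[perm],
    node_chirality = g$node_chirality[perm],
    edge_index = matrix(inv[g$edge_index], ncol = 2),
    edge_bond_type = g$edge_bond_type,
    edge_bond_dir = g$edge_bond_dir
  )
}

# loop-based reference encoder; assumes norm = "none", dropout = 0
ref_encode <- function(g, p) {
  n <- g$n_nodes
  d <- p$d
  h <- matrix(0, n, d)
  for (v in seq_len(n)) {
    h[v, ] <- p$atom_embed[g$node_atom_type[v], ] +
      p$chir_embed[g$node_chirality[v], ]
  }
  for (k in seq_len(p$K)) {
    hn <- matrix(0, n, d)
    for (v in seq_len(n)) {
      s <- h[v, ]
      if (nrow(g$edge_index) > 0) {
        for (e in seq_len(nrow(g$edge_index))) {
          if (g$edge_index[e, 2] == v) {
            u <- g$edge_index[e, 1]
            s <- s + h[u, ] + p$bond_embed[g$edge_bond_type[e], ] +
              p$dir_embed[g$edge_bond_dir[e], ]
          }
        }
      }
      l <- p$layers[[k]]
      a1 <- as.vector(s %*% l$W1) + l$b1
      h1 <- pmax(a1, 0)
      a2 <- as.vector(h1 %*% l$W2) + l$b2
      hn[v, ] <- if (k < p$K) pmax(a2, 0) else a2
    }
    h <- hn
  }
  if (p$pool == "sum") {
    out <- numeric(d)
    for (v in seq_len(n)) out <- out + h[v, ]
    out
  } else if (p$pool == "mean") {
    out <- numeric(d)
    for (v in seq_len(n)) out <- out + h[v, ]
    out / n
  } else {
    s <- numeric(n)
    for (v in seq_len(n)) s[v] <- sum(h[v, ] * p$attn$Wg) + p$attn$bg
    w <- exp(s - max(s)); w <- w / sum(w)
    out <- numeric(d)
    for (v in seq_len(n)) out <- out + w[v] * h[v, ]
    out
  }
}

# loop-based reference classifier head
ref_head_probs <- function(x, head) {
  L <- length(head$layers)
  out <- matrix(0, nrow(x), head$n_classes)
  for (r in seq_len(nrow(x))) {
    z <- x[r, ]
    for (i in seq_len(L)) {
      l <- head$layers[[i]]
      z <- as.vector(z %*% l$W)
      if (!is.null(l$b)) z <- z + l$b
      if (i < L) z <- pmax(z, 0)
    }
    e <- exp(z - max(z))
    out[r, ] <- e / sum(e)
  }
  out
}

# loop-based reference hypernetwork posterior for a single task
ref_posterior <- function(rows, hp) {
  n <- nrow(rows)
  enc <- matrix(0, n, hp$hidden)
  for (r in seq_len(n)) {
    a1 <- pmax(as.vector(rows[r, ] %*% hp$Wr1) + hp$br1, 0)
    enc[r, ] <- pmax(as.vector(a1 %*% hp$Wr2) + hp$br2, 0)
  }
  y <- rows[, ncol(rows)]
  m0 <- numeric(hp$hidden); m1 <- numeric(hp$hidden)
  for (r in seq_len(n)) {
    if (y[r] == 0) m0 <- m0 + enc[r, ] / sum(y == 0)
    else m1 <- m1 + enc[r, ] / sum(y == 1)
  }
  t1 <- pmax(as.vector(c(m0, m1) %*% hp$Wt1) + hp$bt1, 0)
  t2 <- pmax(as.vector(t1 %*% hp$Wt2) + hp$bt2, 0)
  u <- as.vector(t2 %*% hp$Wu) + hp$bu
  lv <- pmin(pmax(as.vector(t2 %*% hp$Wl) + hp$bl, hp$lv_min), hp$lv_max)
  list(u = u, logvar = lv)
}

# brute-force AUROC over all positive-negative pairs, ties counted 1/2
ref_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# brute-force step-wise PR curve area
ref_pr_auc <- function(scores, labels) {
  np <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / np
    area <- area + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  area
}

# an encoder whose per-layer MLP is the identity map:
# relu([x, -x]) %*% rbind(I, -I) = x
identity_mlp_encoder <- function(d, n_layers = 1, pool = "mean") {
  p <- encoder_params(d = d, n_layers = n_layers, pool = pool,
                      norm = "none", dropout = 0)
  for (k in seq_len(n_layers)) {
    p$layers[[k]]$W1 <- cbind(diag(d), -diag(d))
    p$layers[[k]]$b1 <- numeric(2 * d)
    p$layers[[k]]$W2 <- rbind(diag(d), -diag(d))
    p$layers[[k]]$b2 <- numeric(d)
  }
  p
}

# tiny deterministic property matrix written to a temp CSV
write_test_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# a small in-memory task pool (no chemistry) for sampler tests
toy_task <- function(name, n_pos, n_neg, offset = 0L) {
  list(name = name,
       molecule_ids = offset + seq_len(n_pos + n_neg),
       labels = c(rep(1L, n_pos), rep(0L, n_neg)))
}

toy_pool <- function(train_tasks, test_tasks = list()) {
  structure(list(meta_train = train_tasks, meta_test = test_tasks),
            class = "task_pool")
}
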