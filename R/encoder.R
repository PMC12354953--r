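# Atom-bond graph-isomorphism encoder.
#
# Message passing (K rounds): h_v^(k) = MLP^(k)( h_v^(k-1) +
#   sum_{u in N(v)} ( h_u^(k-1) + e_vu ) ), with e_vu the sum of bond-type and
# bond-direction embeddings and h_v^(0) the sum of atom-type and chirality
# embeddings. Between layers (not after the last) an optional batch
# normalization, a ReLU, and optional dropout are applied; node states are
# then pooled (sum / mean / gated attention) into a graph embedding.

#' Create encoder parameters
#'
#' @param d embedding width (all vocabulary tables and node states share it).
#' @param n_layers number of message-passing rounds K (>= 1).
#' @param pool pooling over node states: `"mean"`, `"sum"` or `"attention"`
#'   (a learned scalar gate, softmax-normalized within each graph).
#' @param norm `"batch"` for batch normalization between layers, `"none"` to
#'   disable.
#' @param dropout dropout probability between layers during training; always
#'   disabled at evaluation.
#' @return an object of class `encoder_params`.
#' @export
encoder_params <- function(d = 300, n_layers = 5,
                           pool = c("mean", "sum", "attention"),
                           norm = c("batch", "none"), dropout = 0.5) {
  pool <- match.arg(pool)
  norm <- match.arg(norm)
  stopifnot(n_layers >= 1, d >= 1, dropout >= 0, dropout < 1)
  emb <- function(n) matrix(stats::rnorm(n * d, sd = 1 / sqrt(d)), n, d)
  layers <- vector("list", n_layers)
  bn_state <- vector("list", n_layers)
  for (k in seq_len(n_layers)) {
    layers[[k]] <- list(
      W1 = he_init(d, 2 * d), b1 = numeric(2 * d),
      W2 = he_init(2 * d, d), b2 = numeric(d),
      bn = list(gamma = rep(1, d), beta = numeric(d))
    )
    bn_state[[k]] <- list(mean = numeric(d), var = rep(1, d))
  }
  p <- list(
    d = d, K = n_layers, pool = pool, norm = norm, dropout = dropout,
    atom_embed = emb(ATOM_VOCAB_SIZE),
    chir_embed = emb(length(CHIRALITY_LEVELS)),
    bond_embed = emb(length(BOND_TYPE_LEVELS)),
    dir_embed  = emb(length(BOND_DIR_LEVELS)),
    layers = layers,
    bn_state = bn_state,
    attn = if (pool == "attention") list(Wg = he_init(d, 1), bg = 0) else NULL
  )
  structure(p, class = "encoder_params")
}

#' @export
print.encoder_params <- function(x, ...) {
  cat(sprintf("<encoder_params> d=%d, K=%d, pool=%s, norm=%s, dropout=%g\n",
              x$d, x$K, x$pool, x$norm, x$dropout))
  invisible(x)
}

## ---- batching --------------------------------------------------------------

#' Concatenate molecule graphs into one batch
#'
#' Stacks node and edge fields of several graphs with node-index offsets so
#' the whole batch is processed with a handful of matrix operations.
#'
#' @param graphs list of [molecule_graph()] objects.
#' @return a `graph_batch` object.
#' @export
graph_batch <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  nn <- vapply(graphs, function(g) g$n_nodes, integer(1))
  offs <- cumsum(c(0L, nn[-length(nn)]))
  atom <- unlist(lapply(graphs, function(g) g$node_atom_type))
  chir <- unlist(lapply(graphs, function(g) g$node_chirality))
  src <- integer(0); dst <- integer(0); bt <- integer(0); bd <- integer(0)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (nrow(g$edge_index) > 0) {
      src <- c(src, g$edge_index[, 1] + offs[i])
      dst <- c(dst, g$edge_index[, 2] + offs[i])
      bt <- c(bt, g$edge_bond_type)
      bd <- c(bd, g$edge_bond_dir)
    }
  }
  structure(list(
    atom = atom, chir = chir,
    graph_id = rep(seq_along(graphs), nn),
    n_nodes = nn,
    edge_src = src, edge_dst = dst,
    edge_btype = bt, edge_bdir = bd,
    n_graphs = length(graphs),
    n_nodes_total = sum(nn)
  ), class = "graph_batch")
}

check_vocab <- function(idx, n, what) {
  if (length(idx) > 0 && (min(idx) < 1L || max(idx) > n)) {
    stop(sprintf("vocabulary error: %s index out of range [1, %d]", what, n))
  }
}

## ---- exported per-graph operations ----------------------------------------

#' Initial node states from atom and chirality embeddings
#'
#' `h_v^(0) = atom_embed[atom_type(v)] + chir_embed[chirality(v)]`.
#'
#' @param g a [molecule_graph()].
#' @param p an [encoder_params()].
#' @return an `n_nodes x d` matrix of initial node states.
#' @export
init_node_states <- function(g, p) {
  check_vocab(g$node_atom_type, nrow(p$atom_embed), "atom type")
  check_vocab(g$node_chirality, nrow(p$chir_embed), "chirality")
  p$atom_embed[g$node_atom_type, , drop = FALSE] +
    p$chir_embed[g$node_chirality, , drop = FALSE]
}

#' Edge embedding from bond type and bond direction
#'
#' `e_vu = bond_embed[type] + dir_embed[dir]` (vectorized over edges).
#'
#' @param bond_type integer vector of bond-type indices.
#' @param bond_dir integer vector of bond-direction indices.
#' @param p an [encoder_params()].
#' @return a matrix with one d-vector per edge.
#' @export
embed_edge <- function(bond_type, bond_dir, p) {
  check_vocab(bond_type, nrow(p$bond_embed), "bond type")
  check_vocab(bond_dir, nrow(p$dir_embed), "bond direction")
  p$bond_embed[bond_type, , drop = FALSE] +
    p$dir_embed[bond_dir, , drop = FALSE]
}

#' One graph-isomorphism message-passing round
#'
#' Applies `h_v <- MLP^(k)( h_v + sum_{u in N(v)} (h_u + e_vu) )`; nodes with
#' no neighbors contribute an empty (zero) sum. This is the bare update; the
#' full encoder inserts normalization/ReLU/dropout between rounds.
#'
#' @param states `n_nodes x d` matrix of node states.
#' @param g the [molecule_graph()] supplying edges.
#' @param layer 1-based layer index (`<= p$K`).
#' @param p an [encoder_params()].
#' @return the updated node-state matrix.
#' @export
gin_layer <- function(states, g, layer, p) {
  stopifnot(ncol(states) == p$d, nrow(states) == g$n_nodes,
            layer >= 1, layer <= p$K)
  n <- g$n_nodes
  if (nrow(g$edge_index) > 0) {
    E <- embed_edge(g$edge_bond_type, g$edge_bond_dir, p)
    msg <- states[g$edge_index[, 1], , drop = FALSE] + E
    agg <- scatter_sum(msg, g$edge_index[, 2], n)
  } else {
    agg <- matrix(0, n, p$d)
  }
  z <- states + agg
  l <- p$layers[[layer]]
  add_bias(relu(add_bias(z %*% l$W1, l$b1)) %*% l$W2, l$b2)
}

#' Pool node states into a graph embedding
#'
#' @param states `n_nodes x d` matrix of node states for one graph.
#' @param p an [encoder_params()]; `p$pool` selects sum, mean, or gated
#'   attention (softmax weights over nodes, summing to 1).
#' @return a length-d numeric vector.
#' @export
pool_nodes <- function(states, p) {
  if (is.null(dim(states)) || nrow(states) < 1) {
    stop("empty-input error: cannot pool an empty graph")
  }
  switch(p$pool,
    sum = colSums(states),
    mean = colMeans(states),
    attention = {
      s <- as.vector(states %*% p$attn$Wg) + p$attn$bg
      w <- exp(s - max(s))
      w <- w / sum(w)
      as.vector(crossprod(states, w))
    }
  )
}

#' Encode one molecule graph
#'
#' Runs initialization, K message-passing rounds (evaluation mode: running
#' batch-norm statistics, no dropout) and pooling.
#'
#' @param g a [molecule_graph()].
#' @param p an [encoder_params()].
#' @return a length-d graph embedding.
#' @export
encode <- function(g, p) {
  as.vector(encoder_forward(graph_batch(list(g)), p, train = FALSE)$h_G)
}

#' Encode a list of molecule graphs
#'
#' @param graphs list of [molecule_graph()] objects.
#' @param p an [encoder_params()].
#' @param train logical; training mode enables batch statistics and dropout.
#' @return an `n_graphs x d` embedding matrix.
#' @export
encode_graphs <- function(graphs, p, train = FALSE) {
  encoder_forward(graph_batch(graphs), p, train = train)$h_G
}

## ---- batched forward/backward ----------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_forward <- function(x, gamma, beta, state, train) {
  if (train) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = nrow(x))
    v <- colMeans(xc^2)
    state$mean <- (1 - BN_MOMENTUM) * state$mean + BN_MOMENTUM * mu
    state$var <- (1 - BN_MOMENTUM) * state$var + BN_MOMENTUM * v
  } else {
    mu <- state$mean
    v <- state$var
    xc <- x - rep(mu, each = nrow(x))
  }
  istd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * rep(istd, each = nrow(x))
  y <- xhat * rep(gamma, each = nrow(x)) + rep(beta, each = nrow(x))
  list(y = y, xhat = xhat, istd = istd, state = state)
}

bn_backward <- function(dy, cache, gamma) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * rep(gamma, each = n)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- (dxhat - rep(s1 / n, each = n) -
           cache$xhat * rep(s2 / n, each = n)) * rep(cache$istd, each = n)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Full batched forward pass. In training mode batch-norm uses batch
# statistics (and updates the running ones, returned in cache$bn_state) and
# dropout masks are drawn from the ambient RNG.
encoder_forward <- function(batch, p, train = FALSE) {
  check_vocab(batch$atom, nrow(p$atom_embed), "atom type")
  check_vocab(batch$chir, nrow(p$chir_embed), "chirality")
  check_vocab(batch$edge_btype, nrow(p$bond_embed), "bond type")
  check_vocab(batch$edge_bdir, nrow(p$dir_embed), "bond direction")
  n <- batch$n_nodes_total
  has_edges <- length(batch$edge_src) > 0
  X <- p$atom_embed[batch$atom, , drop = FALSE] +
    p$chir_embed[batch$chir, , drop = FALSE]
  E <- if (has_edges) {
    p$bond_embed[batch$edge_btype, , drop = FALSE] +
      p$dir_embed[batch$edge_bdir, , drop = FALSE]
  } else NULL
  layer_cache <- vector("list", p$K)
  bn_state <- p$bn_state
  for (k in seq_len(p$K)) {
    if (has_edges) {
      msg <- X[batch$edge_src, , drop = FALSE] + E
      agg <- scatter_sum(msg, batch$edge_dst, n)
    } else {
      agg <- matrix(0, n, p$d)
    }
    Z <- X + agg
    l <- p$layers[[k]]
    A1 <- add_bias(Z %*% l$W1, l$b1)
    H1 <- relu(A1)
    A2 <- add_bias(H1 %*% l$W2, l$b2)
    cache_k <- list(Z = Z, A1 = A1, H1 = H1)
    if (k < p$K) {
      if (p$norm == "batch") {
        bn <- bn_forward(A2, l$bn$gamma, l$bn$beta, bn_state[[k]], train)
        bn_state[[k]] <- bn$state
        Y <- bn$y
        cache_k$bn <- bn[c("xhat", "istd")]
      } else {
        Y <- A2
      }
      cache_k$Y <- Y
      R <- relu(Y)
      if (train && p$dropout > 0) {
        mask <- (matrix(stats::runif(n * p$d), n, p$d) >= p$dropout) /
          (1 - p$dropout)
        cache_k$dropmask <- mask
        R <- R * mask
      }
      X <- R
    } else {
      X <- A2
    }
    layer_cache[[k]] <- cache_k
  }
  # pooling
  gid <- batch$graph_id
  pool_cache <- NULL
  if (p$pool == "sum") {
    h_G <- rowsum(X, gid)
  } else if (p$pool == "mean") {
    h_G <- rowsum(X, gid) / batch$n_nodes
  } else {
    s <- as.vector(X %*% p$attn$Wg) + p$attn$bg
    smax <- unsplit(lapply(split(s, gid), max), gid)
    e <- exp(s - smax)
    w <- e / unsplit(lapply(split(e, gid), sum), gid)
    h_G <- rowsum(X * w, gid)
    pool_cache <- list(w = w)
  }
  list(h_G = h_G, node_states = X,
       cache = list(layers = layer_cache, X_final = X, pool = pool_cache,
                    bn_state = bn_state, train = train))
}

# Backward pass from d(loss)/d(h_G); returns gradients shaped like
# encoder_trainable(p).
encoder_backward <- function(batch, p, fwd, dHG) {
  n <- batch$n_nodes_total
  gid <- batch$graph_id
  cache <- fwd$cache
  grads <- encoder_trainable(p, zero = TRUE)
  # pooling backward
  if (p$pool == "sum") {
    dX <- dHG[gid, , drop = FALSE]
  } else if (p$pool == "mean") {
    dX <- dHG[gid, , drop = FALSE] / batch$n_nodes[gid]
  } else {
    X <- cache$X_final
    w <- cache$pool$w
    dXw <- dHG[gid, , drop = FALSE]
    dw <- rowSums(X * dXw)
    swdw <- unsplit(lapply(split(w * dw, gid), sum), gid)
    ds <- w * (dw - swdw)
    dX <- dXw * w + ds %*% t(p$attn$Wg)
    grads$attn$Wg <- crossprod(X, matrix(ds, ncol = 1))
    grads$attn$bg <- sum(ds)
  }
  has_edges <- length(batch$edge_src) > 0
  dE_total <- if (has_edges) matrix(0, length(batch$edge_src), p$d) else NULL
  for (k in rev(seq_len(p$K))) {
    l <- p$layers[[k]]
    ck <- cache$layers[[k]]
    if (k < p$K) {
      d <- dX
      if (!is.null(ck$dropmask)) d <- d * ck$dropmask
      d <- d * (ck$Y > 0)
      if (p$norm == "batch") {
        bnb <- bn_backward(d, ck$bn, l$bn$gamma)
        grads$layers[[k]]$bn$gamma <- bnb$dgamma
        grads$layers[[k]]$bn$beta <- bnb$dbeta
        dA2 <- bnb$dx
      } else {
        dA2 <- d
      }
    } else {
      dA2 <- dX
    }
    grads$layers[[k]]$W2 <- crossprod(ck$H1, dA2)
    grads$layers[[k]]$b2 <- colSums(dA2)
    dH1 <- dA2 %*% t(l$W2)
    dA1 <- dH1 * (ck$A1 > 0)
    grads$layers[[k]]$W1 <- crossprod(ck$Z, dA1)
    grads$layers[[k]]$b1 <- colSums(dA1)
    dZ <- dA1 %*% t(l$W1)
    dX <- dZ
    if (has_edges) {
      dmsg <- dZ[batch$edge_dst, , drop = FALSE]
      dX <- dX + scatter_sum(dmsg, batch$edge_src, n)
      dE_total <- dE_total + dmsg
    }
  }
  grads$atom_embed <- scatter_sum(dX, batch$atom, nrow(p$atom_embed))
  grads$chir_embed <- scatter_sum(dX, batch$chir, nrow(p$chir_embed))
  if (has_edges) {
    grads$bond_embed <- scatter_sum(dE_total, batch$edge_btype,
                                    nrow(p$bond_embed))
    grads$dir_embed <- scatter_sum(dE_total, batch$edge_bdir,
                                   nrow(p$dir_embed))
  }
  grads
}

# The trainable subtree of encoder parameters (running BN stats excluded).
encoder_trainable <- function(p, zero = FALSE) {
  z <- function(x) if (zero) x * 0 else x
  out <- list(
    atom_embed = z(p$atom_embed), chir_embed = z(p$chir_embed),
    bond_embed = z(p$bond_embed), dir_embed = z(p$dir_embed),
    layers = lapply(p$layers, function(l) {
      ll <- list(W1 = z(l$W1), b1 = z(l$b1), W2 = z(l$W2), b2 = z(l$b2))
      if (!is.null(l$bn)) {
        ll$bn <- list(gamma = z(l$bn$gamma), beta = z(l$bn$beta))
      }
      ll
    })
  )
  if (!is.null(p$attn)) out$attn <- list(Wg = z(p$attn$Wg), bg = z(p$attn$bg))
  out
}

encoder_set_trainable <- function(p, tree) {
  p$atom_embed <- tree$atom_embed
  p$chir_embed <- tree$chir_embed
  p$bond_embed <- tree$bond_embed
  p$dir_embed <- tree$dir_embed
  for (k in seq_along(p$layers)) {
    p$layers[[k]]$W1 <- tree$layers[[k]]$W1
    p$layers[[k]]$b1 <- tree$layers[[k]]$b1
    p$layers[[k]]$W2 <- tree$layers[[k]]$W2
    p$layers[[k]]$b2 <- tree$layers[[k]]$b2
    if (!is.null(p$layers[[k]]$bn)) {
      p$layers[[k]]$bn$gamma <- tree$layers[[k]]$bn$gamma
      p$layers[[k]]$bn$beta <- tree$layers[[k]]$bn$beta
    }
  }
  if (!is.null(p$attn)) {
    p$attn$Wg <- tree$attn$Wg
    p$attn$bg <- tree$attn$bg
  }
  p
}

## ---- pretrained-weight loading ---------------------------------------------

#' Load externally pretrained encoder weights
#'
#' Reads a JSON container of named arrays and writes them into an existing
#' [encoder_params()] with strict shape checking. Recognized keys:
#' `atom_embed`, `chir_embed`, `bond_embed`, `dir_embed`, and a `layers`
#' array of objects with `W1`, `b1`, `W2`, `b2` and optional `bn_gamma`,
#' `bn_beta`, `bn_running_mean`, `bn_running_var`; optionally `attn` with
#' `Wg`, `bg`. Matrices are stored row-major (nested JSON arrays).
#'
#' @param p an [encoder_params()] with matching architecture.
#' @param path path to the JSON weight container.
#' @return `p` with weights replaced.
#' @export
load_encoder_weights <- function(p, path) {
  w <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  unmatched <- character(0)
  put <- function(cur, val, key) {
    val <- if (is.list(val)) do.call(rbind, val) else val
    if (is.null(val) || length(val) != length(cur) ||
        (!is.null(dim(cur)) && !identical(dim(cur), dim(as.matrix(val))))) {
      unmatched <<- c(unmatched, key)
      return(cur)
    }
    cur[] <- as.numeric(val)
    cur
  }
  for (nm in c("atom_embed", "chir_embed", "bond_embed", "dir_embed")) {
    if (!is.null(w[[nm]])) p[[nm]] <- put(p[[nm]], w[[nm]], nm)
    else unmatched <- c(unmatched, nm)
  }
  n_found <- if (is.data.frame(w$layers)) nrow(w$layers) else length(w$layers)
  if (is.null(w$layers) || n_found != p$K) {
    stop(sprintf("weight container has %d layers, encoder expects %d",
                 n_found, p$K))
  }
  wl <- w$layers
  for (k in seq_len(p$K)) {
    lk <- if (is.data.frame(wl)) lapply(wl, function(col) col[[k]]) else wl[[k]]
    for (f in c("W1", "b1", "W2", "b2")) {
      key <- sprintf("layers[%d].%s", k, f)
      if (!is.null(lk[[f]])) {
        p$layers[[k]][[f]] <- put(p$layers[[k]][[f]], lk[[f]], key)
      } else unmatched <- c(unmatched, key)
    }
    if (!is.null(lk$bn_gamma)) {
      p$layers[[k]]$bn$gamma <- put(p$layers[[k]]$bn$gamma, lk$bn_gamma,
                                    sprintf("layers[%d].bn_gamma", k))
    }
    if (!is.null(lk$bn_beta)) {
      p$layers[[k]]$bn$beta <- put(p$layers[[k]]$bn$beta, lk$bn_beta,
                                   sprintf("layers[%d].bn_beta", k))
    }
    if (!is.null(lk$bn_running_mean)) {
      p$bn_state[[k]]$mean <- put(p$bn_state[[k]]$mean, lk$bn_running_mean,
                                  sprintf("layers[%d].bn_running_mean", k))
    }
    if (!is.null(lk$bn_running_var)) {
      p$bn_state[[k]]$var <- put(p$bn_state[[k]]$var, lk$bn_running_var,
                                 sprintf("layers[%d].bn_running_var", k))
    }
  }
  if (length(unmatched) > 0) {
    stop("load_encoder_weights: unmatched or mis-shaped keys: ",
         paste(unmatched, collapse = ", "))
  }
  p
}

#' Save encoder weights to the JSON container format
#'
#' @param p an [encoder_params()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_encoder_weights <- function(p, path) {
  layers <- lapply(seq_len(p$K), function(k) {
    l <- p$layers[[k]]
    list(W1 = l$W1, b1 = l$b1, W2 = l$W2, b2 = l$b2,
         bn_gamma = l$bn$gamma, bn_beta = l$bn$beta,
         bn_running_mean = p$bn_state[[k]]$mean,
         bn_running_var = p$bn_state[[k]]$var)
  })
  out <- list(atom_embed = p$atom_embed, chir_embed = p$chir_embed,
              bond_embed = p$bond_embed, dir_embed = p$dir_embed,
              layers = layers)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
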