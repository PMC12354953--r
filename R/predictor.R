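# Task-adaptable classifier head: a fully connected network with ReLU between
# layers and a softmax over the final logits. The flattened parameter vector
# (layer-major, weights before bias, row-major within a weight matrix) is the
# object the hypernetwork perturbs.

#' Create classifier-head parameters
#'
#' A fully connected classification head `d_in -> hidden ... -> n_classes`
#' with ReLU between layers and none after the last. Weights use
#' Kaiming-normal initialization, biases start at zero.
#'
#' @param d_in input width (the encoder embedding width).
#' @param hidden integer vector of hidden-layer widths; may be empty for a
#'   single linear layer.
#' @param n_classes number of output classes (2 for binary tasks).
#' @param bias logical, include bias vectors.
#' @return an object of class `predictor_params`.
#' @export
predictor_params <- function(d_in, hidden = 128, n_classes = 2, bias = TRUE) {
  dims <- c(d_in, hidden, n_classes)
  layers <- vector("list", length(dims) - 1L)
  for (i in seq_along(layers)) {
    layers[[i]] <- list(W = he_init(dims[i], dims[i + 1L]),
                        b = if (bias) numeric(dims[i + 1L]) else NULL)
  }
  structure(list(layers = layers, d_in = d_in, n_classes = n_classes),
            class = "predictor_params")
}

#' Total scalar parameter count of a head
#' @param head a [predictor_params()].
#' @return integer count of the flattened parameter vector.
#' @export
head_n_params <- function(head) {
  sum(vapply(head$layers,
             function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Flatten head parameters
#'
#' Flattening is layer-major, weights before bias, row-major within each
#' weight matrix; [unflatten_head()] is its exact inverse.
#'
#' @param head a [predictor_params()].
#' @return numeric vector of length [head_n_params()].
#' @export
flatten_head <- function(head) {
  unlist(lapply(head$layers, function(l) {
    c(as.vector(t(l$W)), l$b)
  }), use.names = FALSE)
}

#' Rebuild a head from a flat parameter vector
#' @param flat numeric vector in [flatten_head()] order.
#' @param skeleton a [predictor_params()] providing the layer shapes.
#' @return a [predictor_params()] with the given parameters.
#' @export
unflatten_head <- function(flat, skeleton) {
  stopifnot(length(flat) == head_n_params(skeleton))
  pos <- 0L
  for (i in seq_along(skeleton$layers)) {
    l <- skeleton$layers[[i]]
    nw <- length(l$W)
    skeleton$layers[[i]]$W <- matrix(flat[pos + seq_len(nw)],
                                     nrow(l$W), ncol(l$W), byrow = TRUE)
    pos <- pos + nw
    nb <- length(l$b)
    if (nb > 0) {
      skeleton$layers[[i]]$b <- flat[pos + seq_len(nb)]
      pos <- pos + nb
    }
  }
  skeleton
}

#' Apply a weight delta to a head
#'
#' Returns a new head whose flattened parameters equal
#' `flatten_head(head) + delta`; the input head is unchanged.
#'
#' @param head a [predictor_params()].
#' @param delta numeric vector of length [head_n_params()].
#' @return a new [predictor_params()].
#' @export
apply_delta <- function(head, delta) {
  if (length(delta) != head_n_params(head)) {
    stop("apply_delta: delta length does not match head parameter count")
  }
  unflatten_head(flatten_head(head) + delta, head)
}

# Forward pass keeping the per-layer inputs needed for backprop.
head_forward <- function(x, head) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == head$d_in)
  L <- length(head$layers)
  zs <- vector("list", L)  # input to each layer
  z <- x
  for (i in seq_len(L)) {
    zs[[i]] <- z
    l <- head$layers[[i]]
    z <- z %*% l$W
    if (!is.null(l$b)) z <- add_bias(z, l$b)
    if (i < L) z <- relu(z)
  }
  list(logits = z, probs = softmax_rows(z), zs = zs)
}

# Backward pass from d(loss)/d(logits). Returns the gradient with respect to
# the flattened head parameters and the input rows.
head_backward <- function(cache, dlogits, head) {
  L <- length(head$layers)
  gW <- vector("list", L)
  gb <- vector("list", L)
  d <- dlogits
  for (i in rev(seq_len(L))) {
    l <- head$layers[[i]]
    z <- cache$zs[[i]]
    # for hidden layers the stored input of layer i+1 is relu(out of i)
    gW[[i]] <- crossprod(z, d)
    gb[[i]] <- if (!is.null(l$b)) colSums(d) else NULL
    d <- tcrossprod(d, l$W)
    if (i > 1L) d <- d * (cache$zs[[i]] > 0)
  }
  flat <- unlist(lapply(seq_len(L), function(i) {
    c(as.vector(t(gW[[i]])), gb[[i]])
  }), use.names = FALSE)
  list(dflat = flat, dx = d)
}

#' Predict class probabilities from graph embeddings
#'
#' @param h_G a numeric embedding vector, or a matrix with one embedding per
#'   row.
#' @param head a [predictor_params()].
#' @return a probability matrix (rows sum to 1), one row per input embedding.
#' @examples
#' head <- predictor_params(4, hidden = 8)
#' predict_head(rnorm(4), head)
#' @export
predict_head <- function(h_G, head) {
  head_forward(h_G, head)$probs
}
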