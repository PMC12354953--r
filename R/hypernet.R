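# Bayesian hypernetwork: reads the support set (embeddings, universal-model
# predictions, labels), emits a Gaussian posterior (mean, log-variance) over
# the flattened classifier-head weight delta, and supplies reparameterized
# samples plus the closed-form KL to the standard-normal prior.
#
# Set aggregation is deep-sets style: a shared row encoder maps each support
# example to a feature vector; per-class mean pooling and concatenation of
# the two class summaries give a fixed-size, permutation-invariant task
# representation regardless of the shot count K.

#' Create hypernetwork parameters
#'
#' @param d encoder embedding width (support rows have width `d + 4`).
#' @param n_params flattened parameter count of the classifier head the
#'   posterior is defined over (see [head_n_params()]).
#' @param hidden width of the row encoder and trunk layers.
#' @param logvar_bias_init initial bias of the log-variance head. The default
#'   -10 (initial sd about 0.007) makes early adaptation near-deterministic:
#'   sampled-weight noise enters the logits multiplied by the embedding
#'   norms, so a large initial variance rewards collapsing the embeddings
#'   to zero before any signal can form.
#' @param logvar_clamp length-2 numeric, clamp range for the emitted
#'   log-variance.
#' @param out_init_sd sd of the near-zero initialization of the mean and
#'   log-variance output maps, so training starts close to the universal
#'   (unperturbed) model.
#' @return an object of class `hypernet_params`.
#' @export
hypernet_params <- function(d, n_params, hidden = 256,
                            logvar_bias_init = -10,
                            logvar_clamp = c(-12, 4),
                            out_init_sd = 1e-3) {
  d_row <- d + 4L
  structure(list(
    d = d, n_params = n_params, hidden = hidden,
    lv_min = logvar_clamp[1], lv_max = logvar_clamp[2],
    Wr1 = he_init(d_row, hidden), br1 = numeric(hidden),
    Wr2 = he_init(hidden, hidden), br2 = numeric(hidden),
    Wt1 = he_init(2 * hidden, hidden), bt1 = numeric(hidden),
    Wt2 = he_init(hidden, hidden), bt2 = numeric(hidden),
    Wu = matrix(stats::rnorm(hidden * n_params, sd = out_init_sd),
                hidden, n_params),
    bu = numeric(n_params),
    Wl = matrix(stats::rnorm(hidden * n_params, sd = out_init_sd),
                hidden, n_params),
    bl = rep(logvar_bias_init, n_params)
  ), class = "hypernet_params")
}

#' @export
print.hypernet_params <- function(x, ...) {
  cat(sprintf("<hypernet_params> d=%d, hidden=%d, n_params=%d\n",
              x$d, x$hidden, x$n_params))
  invisible(x)
}

#' Posterior parameters over head-weight deltas
#'
#' @param u numeric mean vector.
#' @param logvar numeric log-variance vector of the same length.
#' @return an object of class `posterior_params`.
#' @export
posterior_params <- function(u, logvar) {
  stopifnot(length(u) == length(logvar),
            all(is.finite(u)), all(is.finite(logvar)))
  structure(list(u = as.numeric(u), logvar = as.numeric(logvar)),
            class = "posterior_params")
}

#' Build the hypernetwork input matrix from a support set
#'
#' One row per support example: `[embedding | predicted class probabilities |
#' one-hot label]`, width `d + 4` for binary tasks.
#'
#' @param support_embeddings `2K x d` matrix (or list) of support embeddings.
#' @param support_probs `2K x 2` matrix (or list) of predicted class
#'   probabilities from the universal model.
#' @param support_labels integer vector of `{0, 1}` labels; both classes must
#'   be present.
#' @return a `2K x (d + 4)` feature matrix.
#' @export
build_input <- function(support_embeddings, support_probs, support_labels) {
  if (is.list(support_embeddings)) {
    support_embeddings <- do.call(rbind, support_embeddings)
  }
  if (is.list(support_probs)) support_probs <- do.call(rbind, support_probs)
  support_probs <- as.matrix(support_probs)
  n <- length(support_labels)
  if (nrow(support_embeddings) != n || nrow(support_probs) != n) {
    stop("build_input: embeddings, probabilities and labels must have equal length")
  }
  if (!all(support_labels %in% c(0, 1)) ||
      length(unique(support_labels)) < 2) {
    stop("build_input: support labels must contain both classes 0 and 1")
  }
  out <- cbind(support_embeddings, support_probs,
               1 - support_labels, support_labels)
  dimnames(out) <- NULL
  out
}

# Batched forward over the stacked support rows of several tasks.
# rows: (sum_i 2K_i) x (d+4); task_id: task index per row; y: {0,1} per row.
hypernet_forward <- function(rows, task_id, y, hp) {
  stopifnot(ncol(rows) == hp$d + 4L)
  n_tasks <- max(task_id)
  A1 <- add_bias(rows %*% hp$Wr1, hp$br1); R1 <- relu(A1)
  A2 <- add_bias(R1 %*% hp$Wr2, hp$br2); R2 <- relu(A2)
  grp <- (task_id - 1L) * 2L + y + 1L
  cnt <- tabulate(grp, nbins = 2L * n_tasks)
  if (any(cnt == 0)) {
    stop("hypernet_forward: every task needs support examples of both classes")
  }
  Pm <- rowsum(R2, grp) / cnt
  Tin <- cbind(Pm[seq(1, 2 * n_tasks, by = 2), , drop = FALSE],
               Pm[seq(2, 2 * n_tasks, by = 2), , drop = FALSE])
  B1 <- add_bias(Tin %*% hp$Wt1, hp$bt1); T1 <- relu(B1)
  B2 <- add_bias(T1 %*% hp$Wt2, hp$bt2); T2 <- relu(B2)
  U <- add_bias(T2 %*% hp$Wu, hp$bu)
  LVraw <- add_bias(T2 %*% hp$Wl, hp$bl)
  LV <- pmin(pmax(LVraw, hp$lv_min), hp$lv_max)
  list(U = U, LV = LV,
       cache = list(rows = rows, A1 = A1, R1 = R1, A2 = A2, R2 = R2,
                    grp = grp, cnt = cnt, Tin = Tin, B1 = B1, T1 = T1,
                    B2 = B2, T2 = T2, LVraw = LVraw,
                    task_id = task_id, y = y, n_tasks = n_tasks))
}

# Backward from (dU, dLV); returns parameter gradients and the gradient with
# respect to the input rows.
hypernet_backward <- function(hp, fwd, dU, dLV) {
  ch <- fwd$cache
  n_tasks <- ch$n_tasks
  h <- hp$hidden
  mask <- (ch$LVraw > hp$lv_min) & (ch$LVraw < hp$lv_max)
  dLVr <- dLV * mask
  g <- list()
  g$Wu <- crossprod(ch$T2, dU); g$bu <- colSums(dU)
  g$Wl <- crossprod(ch$T2, dLVr); g$bl <- colSums(dLVr)
  dT2 <- (tcrossprod(dU, hp$Wu) + tcrossprod(dLVr, hp$Wl)) * (ch$B2 > 0)
  g$Wt2 <- crossprod(ch$T1, dT2); g$bt2 <- colSums(dT2)
  dT1 <- tcrossprod(dT2, hp$Wt2) * (ch$B1 > 0)
  g$Wt1 <- crossprod(ch$Tin, dT1); g$bt1 <- colSums(dT1)
  dTin <- tcrossprod(dT1, hp$Wt1)
  # un-concatenate the class summaries, then un-pool the means
  dPm <- matrix(0, 2L * n_tasks, h)
  dPm[seq(1, 2 * n_tasks, by = 2), ] <- dTin[, 1:h, drop = FALSE]
  dPm[seq(2, 2 * n_tasks, by = 2), ] <- dTin[, (h + 1):(2 * h), drop = FALSE]
  dR2 <- (dPm / ch$cnt)[ch$grp, , drop = FALSE] * (ch$A2 > 0)
  g$Wr2 <- crossprod(ch$R1, dR2); g$br2 <- colSums(dR2)
  dR1 <- tcrossprod(dR2, hp$Wr2) * (ch$A1 > 0)
  g$Wr1 <- crossprod(ch$rows, dR1); g$br1 <- colSums(dR1)
  drows <- tcrossprod(dR1, hp$Wr1)
  list(grads = g, drows = drows)
}

hypernet_trainable <- function(hp, zero = FALSE) {
  keys <- c("Wr1", "br1", "Wr2", "br2", "Wt1", "bt1", "Wt2", "bt2",
            "Wu", "bu", "Wl", "bl")
  out <- hp[keys]
  if (zero) out <- lapply(out, function(x) x * 0)
  out
}

hypernet_set_trainable <- function(hp, tree) {
  for (nm in names(tree)) hp[[nm]] <- tree[[nm]]
  hp
}

#' Evaluate the hypernetwork posterior for one task
#'
#' Feeds the support feature matrix (from [build_input()]) through the shared
#' row encoder, pools the encoded rows per class (mean), concatenates the two
#' class summaries, and maps them through the trunk to the posterior mean and
#' clamped log-variance over the head-weight delta. The result is invariant
#' to the order of support examples.
#'
#' @param rows support feature matrix from [build_input()].
#' @param hp a [hypernet_params()].
#' @return a [posterior_params()].
#' @export
hypernet_posterior <- function(rows, hp) {
  if (nrow(rows) < 2) stop("hypernet_posterior: need at least 2 support rows")
  y <- rows[, ncol(rows)]
  if (length(unique(y)) < 2) {
    stop("hypernet_posterior: support must contain both classes")
  }
  fwd <- hypernet_forward(rows, rep(1L, nrow(rows)), y, hp)
  posterior_params(as.vector(fwd$U), as.vector(fwd$LV))
}

#' Sample task-specific head weights by reparameterization
#'
#' Draws `delta = u + exp(logvar / 2) * eps` with `eps` standard normal and
#' returns `apply_delta(theta_head, delta)`. Because the sample is an affine
#' function of `(u, logvar)`, gradients flow through it (reparameterization
#' trick); the trainer exploits this by recording `eps`.
#'
#' @param theta_head the universal [predictor_params()].
#' @param post a [posterior_params()].
#' @param eps optional fixed standard-normal vector (drawn from the ambient
#'   RNG when omitted).
#' @return the adapted [predictor_params()], with the drawn `delta` and `eps`
#'   attached as attributes.
#' @export
sample_weights <- function(theta_head, post, eps = NULL) {
  np <- head_n_params(theta_head)
  stopifnot(length(post$u) == np)
  if (is.null(eps)) eps <- stats::rnorm(np)
  delta <- post$u + exp(post$logvar / 2) * eps
  out <- apply_delta(theta_head, delta)
  attr(out, "delta") <- delta
  attr(out, "eps") <- eps
  out
}

#' KL divergence of the weight posterior from the standard-normal prior
#'
#' Closed form, summed over coordinates:
#' `0.5 * sum(m^2 + exp(logvar) - 1 - logvar)`. In `"delta"` mode (default)
#' `m = u`, regularizing the perturbation toward N(0, I); in `"literal"` mode
#' `m = theta_flat + u`, penalizing the shifted weights themselves.
#'
#' @param post a [posterior_params()].
#' @param mode `"delta"` or `"literal"`.
#' @param theta_flat flattened universal head weights (required for
#'   `"literal"`).
#' @return a nonnegative scalar.
#' @export
kl_to_prior <- function(post, mode = c("delta", "literal"),
                        theta_flat = NULL) {
  mode <- match.arg(mode)
  if (!all(is.finite(post$u)) || !all(is.finite(post$logvar))) {
    stop("kl_to_prior: non-finite posterior parameters")
  }
  m <- if (mode == "literal") {
    if (is.null(theta_flat)) stop("kl_to_prior: literal mode needs theta_flat")
    theta_flat + post$u
  } else {
    post$u
  }
  0.5 * sum(m^2 + exp(post$logvar) - 1 - post$logvar)
}

# Gradient of gamma * kl_to_prior with respect to (u, logvar); in literal
# mode also with respect to theta_flat (equal to du).
kl_grads <- function(post, gamma, mode = "delta", theta_flat = NULL) {
  m <- if (mode == "literal") theta_flat + post$u else post$u
  list(du = gamma * m, dlogvar = gamma * 0.5 * (exp(post$logvar) - 1))
}
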