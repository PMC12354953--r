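# Bi-level meta-learning: hypernetwork-based task adaptation, the
# KL-regularized meta-objective, the outer Adam loop, and a first-order
# gradient-based MAML baseline.

#' Bundle universal model weights
#'
#' @param encoder an [encoder_params()].
#' @param head a [predictor_params()] whose input width equals the encoder
#'   embedding width.
#' @return an object of class `model_weights`.
#' @export
model_weights <- function(encoder, head) {
  stopifnot(inherits(encoder, "encoder_params"),
            inherits(head, "predictor_params"))
  if (encoder$d != head$d_in) {
    stop("model_weights: encoder width and head input width differ")
  }
  structure(list(encoder = encoder, head = head), class = "model_weights")
}

#' Meta-training configuration
#'
#' @param Ns tasks sampled per episode.
#' @param K shots per class in every support set.
#' @param P posterior samples per task during training.
#' @param P_eval posterior samples per task at evaluation.
#' @param gamma KL regularization weight (its full value; see `kl_anneal`).
#' @param kl_anneal fraction of the epoch budget over which the effective KL
#'   weight ramps linearly from 0 to `gamma`. Annealing lets the adaptation
#'   pathway form before the prior pulls the posterior toward zero deltas;
#'   with an adaptive optimizer the KL's small but consistently signed
#'   gradient otherwise collapses training into the trivial
#'   no-adaptation solution. Set 0 to disable.
#' @param lr outer Adam learning rate.
#' @param lr_decay multiplicative decay applied at each milestone.
#' @param milestones epochs at which the learning rate decays; default 40%
#'   and 70% of `epochs`.
#' @param epochs training epochs.
#' @param episodes_per_epoch episodes (one optimizer step each) per epoch.
#' @param query_per_class query examples per class during meta-training.
#' @param inner_lr step size of the MAML baseline inner loop.
#' @param inner_steps gradient steps of the MAML baseline inner loop.
#' @param mode `"hypernet"` (posterior-sampled adaptation), `"maml"`
#'   (gradient inner loop), or `"plain"` (no adaptation; episodic training of
#'   the universal model).
#' @param kl_mode `"delta"` or `"literal"` (see [kl_to_prior()]).
#' @param freeze_encoder if `TRUE` the encoder receives no outer-loop
#'   gradients.
#' @param zero_posterior diagnostic flag: clamp the posterior to zero
#'   mean/variance so adaptation is the identity.
#' @param clip global gradient-norm clip.
#' @param balanced_loss class-balanced cross-entropy.
#' @param seed integer seed controlling episode composition, dropout and
#'   posterior sampling.
#' @return an object of class `meta_config`.
#' @export
meta_config <- function(Ns = 5, K = 10, P = 5, P_eval = 10, gamma = 1e-4,
                        kl_anneal = 0.5,
                        lr = 1e-3, lr_decay = 0.3, milestones = NULL,
                        epochs = 2500, episodes_per_epoch = 20,
                        query_per_class = 16, inner_lr = 0.01,
                        inner_steps = 5,
                        mode = c("hypernet", "maml", "plain"),
                        kl_mode = c("delta", "literal"),
                        freeze_encoder = FALSE, zero_posterior = FALSE,
                        clip = 5, balanced_loss = TRUE, seed = 1) {
  mode <- match.arg(mode)
  kl_mode <- match.arg(kl_mode)
  stopifnot(Ns >= 1, K >= 1, P >= 1, P_eval >= 1, gamma >= 0, lr > 0,
            lr_decay > 0, lr_decay < 1, epochs >= 1,
            episodes_per_epoch >= 1, query_per_class >= 1, clip > 0,
            kl_anneal >= 0, kl_anneal <= 1)
  if (is.null(milestones)) {
    milestones <- unique(pmax(1L, ceiling(epochs * c(0.4, 0.7))))
  }
  structure(as.list(environment()), class = "meta_config")
}

lr_at_epoch <- function(cfg, epoch) {
  cfg$lr * cfg$lr_decay^sum(epoch > cfg$milestones)
}

# linear KL-weight ramp over the first kl_anneal fraction of epochs
gamma_at_epoch <- function(cfg, epoch) {
  warm <- floor(cfg$kl_anneal * cfg$epochs)
  if (warm <= 0 || epoch > warm) return(cfg$gamma)
  cfg$gamma * (epoch - 1) / warm
}

head_trainable <- function(head, zero = FALSE) {
  list(layers = lapply(head$layers, function(l) {
    out <- list(W = if (zero) l$W * 0 else l$W)
    if (!is.null(l$b)) out$b <- if (zero) l$b * 0 else l$b
    out
  }))
}

head_set_trainable <- function(head, tree) {
  for (i in seq_along(head$layers)) {
    head$layers[[i]]$W <- tree$layers[[i]]$W
    if (!is.null(head$layers[[i]]$b)) head$layers[[i]]$b <- tree$layers[[i]]$b
  }
  head
}

# d(loss)/d(probs) -> d(loss)/d(logits) through a row-wise softmax.
softmax_vjp <- function(probs, dprobs) {
  probs * (dprobs - rowSums(dprobs * probs))
}

## ---- episode forward/backward ----------------------------------------------

# One full episode pass. Returns the loss report, gradients for every
# trainable group, and the updated encoder batch-norm state.
episode_pass <- function(enc, head, hyp, episode, graphs, cfg,
                         train = TRUE) {
  d <- enc$d
  np <- head_n_params(head)
  flat_head <- flatten_head(head)
  ids_all <- unique(unlist(lapply(episode, function(t) {
    c(t$support$molecule_ids, t$query$molecule_ids)
  })))
  batch <- graph_batch(graphs[ids_all])
  fwd <- encoder_forward(batch, enc, train = train)
  H <- fwd$h_G
  dH <- matrix(0, nrow(H), d)

  Ns <- length(episode)
  s_idx <- lapply(episode, function(t) match(t$support$molecule_ids, ids_all))
  q_idx <- lapply(episode, function(t) match(t$query$molecule_ids, ids_all))
  s_y <- lapply(episode, function(t) t$support$labels)
  q_y <- lapply(episode, function(t) t$query$labels)

  dhead_flat <- numeric(np)
  task_loss <- numeric(Ns)
  task_kl <- numeric(Ns)
  q_sizes <- vapply(q_idx, length, integer(1))
  grads <- list()

  if (cfg$mode == "hypernet") {
    # universal predictions on all support rows (one stacked pass)
    s_rows_idx <- unlist(s_idx)
    s_y_all <- unlist(s_y)
    task_id <- rep(seq_len(Ns), vapply(s_idx, length, integer(1)))
    HS <- H[s_rows_idx, , drop = FALSE]
    uhf <- head_forward(HS, head)
    rows <- cbind(HS, uhf$probs, 1 - s_y_all, s_y_all)
    hfwd <- hypernet_forward(rows, task_id, s_y_all, hyp)
    U <- hfwd$U; LV <- hfwd$LV
    dU <- matrix(0, Ns, np); dLV <- matrix(0, Ns, np)
    use_posterior <- !isTRUE(cfg$zero_posterior)
    for (i in seq_len(Ns)) {
      HQ <- H[q_idx[[i]], , drop = FALSE]
      yq <- q_y[[i]]
      if (use_posterior) {
        sd_i <- exp(LV[i, ] / 2)
        P <- cfg$P
        for (s in seq_len(P)) {
          eps <- stats::rnorm(np)
          head_s <- unflatten_head(flat_head + U[i, ] + sd_i * eps, head)
          hf <- head_forward(HQ, head_s)
          ce <- cross_entropy(hf$logits, yq, balanced = cfg$balanced_loss)
          task_loss[i] <- task_loss[i] + ce$loss / P
          hb <- head_backward(hf, ce$dlogits / P, head_s)
          dU[i, ] <- dU[i, ] + hb$dflat
          dLV[i, ] <- dLV[i, ] + hb$dflat * eps * 0.5 * sd_i
          dhead_flat <- dhead_flat + hb$dflat
          dH <- accumulate_rows(dH, q_idx[[i]], hb$dx)
        }
        post_i <- posterior_params(U[i, ], LV[i, ])
        task_kl[i] <- kl_to_prior(post_i, mode = cfg$kl_mode,
                                  theta_flat = flat_head)
        if (cfg$gamma > 0) {
          kg <- kl_grads(post_i, cfg$gamma, mode = cfg$kl_mode,
                         theta_flat = flat_head)
          dU[i, ] <- dU[i, ] + kg$du
          dLV[i, ] <- dLV[i, ] + kg$dlogvar
          if (cfg$kl_mode == "literal") dhead_flat <- dhead_flat + kg$du
        }
      } else {
        hf <- head_forward(HQ, head)
        ce <- cross_entropy(hf$logits, yq, balanced = cfg$balanced_loss)
        task_loss[i] <- ce$loss
        hb <- head_backward(hf, ce$dlogits, head)
        dhead_flat <- dhead_flat + hb$dflat
        dH <- accumulate_rows(dH, q_idx[[i]], hb$dx)
      }
    }
    if (use_posterior) {
      hbk <- hypernet_backward(hyp, hfwd, dU, dLV)
      grads$hyp <- hbk$grads
      dH <- accumulate_rows(dH, s_rows_idx,
                            hbk$drows[, 1:d, drop = FALSE])
      dprobs_S <- hbk$drows[, d + (1:2), drop = FALSE]
      dlogits_S <- softmax_vjp(uhf$probs, dprobs_S)
      ub <- head_backward(uhf, dlogits_S, head)
      dhead_flat <- dhead_flat + ub$dflat
      dH <- accumulate_rows(dH, s_rows_idx, ub$dx)
    }
  } else if (cfg$mode == "maml") {
    for (i in seq_len(Ns)) {
      HS <- H[s_idx[[i]], , drop = FALSE]
      HQ <- H[q_idx[[i]], , drop = FALSE]
      head_i <- head
      for (step in seq_len(cfg$inner_steps)) {
        hf <- head_forward(HS, head_i)
        ce <- cross_entropy(hf$logits, s_y[[i]], balanced = cfg$balanced_loss)
        hb <- head_backward(hf, ce$dlogits, head_i)
        head_i <- apply_delta(head_i, -cfg$inner_lr * hb$dflat)
      }
      hf <- head_forward(HQ, head_i)
      ce <- cross_entropy(hf$logits, q_y[[i]], balanced = cfg$balanced_loss)
      task_loss[i] <- ce$loss
      # first-order outer gradient: adapted-head gradient applied to the
      # universal initialization; encoder gradient through the query pass
      hb <- head_backward(hf, ce$dlogits, head_i)
      dhead_flat <- dhead_flat + hb$dflat
      dH <- accumulate_rows(dH, q_idx[[i]], hb$dx)
    }
  } else { # plain episodic training of the universal model
    for (i in seq_len(Ns)) {
      HQ <- H[q_idx[[i]], , drop = FALSE]
      hf <- head_forward(HQ, head)
      ce <- cross_entropy(hf$logits, q_y[[i]], balanced = cfg$balanced_loss)
      task_loss[i] <- ce$loss
      hb <- head_backward(hf, ce$dlogits, head)
      dhead_flat <- dhead_flat + hb$dflat
      dH <- accumulate_rows(dH, q_idx[[i]], hb$dx)
    }
  }

  grads$head <- head_trainable(unflatten_head(dhead_flat,
                                              head_trainable_skeleton(head)))
  if (!cfg$freeze_encoder) {
    grads$enc <- encoder_backward(batch, enc, fwd, dH)
  }
  total <- sum(task_loss) + cfg$gamma * sum(task_kl)
  report <- list(
    total_loss = total,
    per_task = data.frame(
      task = vapply(episode, function(t) t$name, character(1)),
      loss = task_loss, kl = task_kl, query_size = q_sizes),
    bn_state = fwd$cache$bn_state
  )
  list(report = report, grads = grads)
}

# zero-valued head used as an unflatten skeleton for gradients
head_trainable_skeleton <- function(head) head

#' Evaluate the meta-objective on one episode
#'
#' Adapts on every support set, averages the query cross-entropy over the
#' posterior samples, and adds the gamma-weighted KL (Bayesian mode). The
#' returned report decomposes the total into per-task loss and KL terms.
#'
#' @param weights a [model_weights()].
#' @param hyp a [hypernet_params()] (ignored in `"maml"`/`"plain"` modes).
#' @param episode an episode from [sample_episode()].
#' @param graphs list of [molecule_graph()]s indexed by molecule id.
#' @param cfg a [meta_config()].
#' @return `list(total_loss, per_task)`; `total_loss` equals
#'   `sum(per_task$loss) + gamma * sum(per_task$kl)`.
#' @export
meta_objective <- function(weights, hyp, episode, graphs, cfg) {
  out <- episode_pass(weights$encoder, weights$head, hyp, episode, graphs,
                      cfg, train = FALSE)
  out$report[c("total_loss", "per_task")]
}

#' Adapt the classifier head to a task support set
#'
#' Encodes the support molecules, predicts with the universal head, builds
#' the hypernetwork input, evaluates the posterior and draws `P` heads by
#' reparameterized sampling.
#'
#' @param weights a [model_weights()].
#' @param hyp a [hypernet_params()].
#' @param support `list(molecule_ids, labels)` with balanced classes.
#' @param graphs list of [molecule_graph()]s indexed by molecule id.
#' @param P number of sampled heads.
#' @return `list(heads, posterior)`: `P` sampled [predictor_params()] and the
#'   [posterior_params()] used.
#' @export
adapt <- function(weights, hyp, support, graphs, P = 10) {
  emb <- encode_graphs(graphs[support$molecule_ids], weights$encoder)
  probs <- predict_head(emb, weights$head)
  rows <- build_input(emb, probs, support$labels)
  post <- hypernet_posterior(rows, hyp)
  heads <- lapply(seq_len(P), function(s) sample_weights(weights$head, post))
  list(heads = heads, posterior = post)
}

## ---- training loop ---------------------------------------------------------

#' Meta-train the model on a task pool
#'
#' Per epoch, `episodes_per_epoch` episodes are sampled dynamically (fresh
#' support/query composition every time) and one Adam step is taken per
#' episode on the gradient of the meta-objective with respect to encoder,
#' head and hypernetwork jointly. The learning rate follows a multi-step
#' decay. Fully reproducible given `cfg$seed`.
#'
#' @param pool a `task_pool` from [split_tasks()].
#' @param graphs list of [molecule_graph()]s indexed by the molecule ids the
#'   pool's tasks reference.
#' @param cfg a [meta_config()].
#' @param weights optional initial [model_weights()]; drawn fresh when
#'   omitted (encoder defaults d = 64, 3 layers for desk-scale runs).
#' @param hyp optional initial [hypernet_params()].
#' @param d,n_layers encoder size used when `weights` is omitted.
#' @param head_hidden,hypernet_hidden hidden widths used when `weights` /
#'   `hyp` are omitted (desk-scale defaults; benchmark-scale constructors
#'   default to 128 and 256).
#' @param verbose print a line per epoch.
#' @return `list(weights, hyp, trace, cfg)`; `trace` is a data frame with
#'   one row per episode (epoch, episode, total loss, mean task loss, mean
#'   KL, learning rate).
#' @export
meta_train <- function(pool, graphs, cfg, weights = NULL, hyp = NULL,
                       d = 64, n_layers = 3, head_hidden = 64,
                       hypernet_hidden = 128, verbose = FALSE) {
  stopifnot(length(pool$meta_train) >= 1)
  set.seed(cfg$seed)
  if (is.null(weights)) {
    enc <- encoder_params(d = d, n_layers = n_layers, pool = "mean",
                          norm = "batch", dropout = 0)
    head <- predictor_params(d, hidden = head_hidden, n_classes = 2)
    weights <- model_weights(enc, head)
  }
  enc <- weights$encoder
  head <- weights$head
  if (is.null(hyp) && cfg$mode == "hypernet") {
    hyp <- hypernet_params(enc$d, head_n_params(head),
                           hidden = hypernet_hidden)
  }

  param_tree <- list(head = head_trainable(head))
  if (!cfg$freeze_encoder) param_tree$enc <- encoder_trainable(enc)
  if (cfg$mode == "hypernet") param_tree$hyp <- hypernet_trainable(hyp)
  leaves <- tree_leaves(param_tree)
  opt <- adam_init(leaves)

  n_rows <- cfg$epochs * cfg$episodes_per_epoch
  trace <- data.frame(epoch = integer(n_rows), episode = integer(n_rows),
                      total = numeric(n_rows), task_loss = numeric(n_rows),
                      kl = numeric(n_rows), lr = numeric(n_rows))
  row <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    lr_e <- lr_at_epoch(cfg, epoch)
    cfg_ep <- cfg
    cfg_ep$gamma <- gamma_at_epoch(cfg, epoch)
    for (ep in seq_len(cfg$episodes_per_epoch)) {
      episode <- sample_episode(pool, cfg$Ns, cfg$K, cfg$query_per_class)
      out <- episode_pass(enc, head, hyp, episode, graphs, cfg_ep,
                          train = TRUE)
      if (!is.finite(out$report$total_loss)) {
        stop(sprintf(
          "numerical error: non-finite loss at epoch %d episode %d (tasks: %s)",
          epoch, ep, paste(out$report$per_task$task, collapse = ", ")))
      }
      enc$bn_state <- out$report$bn_state
      gl <- tree_leaves(out$grads[names(param_tree)])
      gl <- clip_global_norm(gl, cfg$clip)
      st <- adam_step(leaves, gl, opt, lr_e)
      leaves <- st$leaves; opt <- st$state
      param_tree <- tree_set_leaves(param_tree, leaves)
      head <- head_set_trainable(head, param_tree$head)
      if (!cfg$freeze_encoder) enc <- encoder_set_trainable(enc, param_tree$enc)
      if (cfg$mode == "hypernet") hyp <- hypernet_set_trainable(hyp, param_tree$hyp)
      row <- row + 1L
      trace[row, ] <- list(epoch, ep, out$report$total_loss,
                           mean(out$report$per_task$loss),
                           mean(out$report$per_task$kl), lr_e)
    }
    if (verbose) {
      recent <- trace$total[max(1, row - cfg$episodes_per_epoch + 1):row]
      message(sprintf("epoch %4d/%d  lr %.2e  loss %.4f",
                      epoch, cfg$epochs, lr_e, mean(recent)))
    }
  }
  list(weights = model_weights(enc, head), hyp = hyp, trace = trace,
       cfg = cfg)
}

#' Moving average of a loss trace
#'
#' @param x numeric vector.
#' @param window window size (default 40).
#' @return the windowed simple moving average (shorter than `x` by
#'   `window - 1`).
#' @export
smooth_trace <- function(x, window = 40) {
  if (length(x) < window) return(mean(x))
  as.numeric(stats::filter(x, rep(1 / window, window), sides = 1))[window:length(x)]
}

## ---- MAML baseline ---------------------------------------------------------

#' Gradient-descent inner loop
#'
#' Performs `steps` updates `theta <- theta - alpha * grad_fn(theta)`. This
#' is the generic inner-loop primitive of the gradient-based baseline.
#'
#' @param theta numeric parameter vector.
#' @param grad_fn function returning the loss gradient at `theta`.
#' @param alpha step size.
#' @param steps number of updates.
#' @return the updated parameter vector.
#' @examples
#' # one step on 0.5 * (theta - 1)^2 from 0 with alpha = 0.5 gives 0.5
#' maml_inner_loop(0, function(t) t - 1, alpha = 0.5, steps = 1)
#' @export
maml_inner_loop <- function(theta, grad_fn, alpha, steps) {
  for (s in seq_len(steps)) theta <- theta - alpha * grad_fn(theta)
  theta
}

#' MAML-style task adaptation of the classifier head
#'
#' Runs `steps` gradient-descent updates of the head on the support-set
#' cross-entropy with step size `alpha`; the encoder stays frozen.
#'
#' @param weights a [model_weights()].
#' @param support `list(molecule_ids, labels)`.
#' @param graphs list of [molecule_graph()]s indexed by molecule id.
#' @param alpha inner-loop step size.
#' @param steps number of inner updates.
#' @param balanced class-balanced support loss.
#' @return the adapted [predictor_params()].
#' @export
maml_adapt <- function(weights, support, graphs, alpha = 0.01, steps = 5,
                       balanced = TRUE) {
  emb <- encode_graphs(graphs[support$molecule_ids], weights$encoder)
  y <- support$labels
  head <- weights$head
  grad_fn <- function(flat) {
    h <- unflatten_head(flat, head)
    hf <- head_forward(emb, h)
    ce <- cross_entropy(hf$logits, y, balanced = balanced)
    head_backward(hf, ce$dlogits, h)$dflat
  }
  flat <- maml_inner_loop(flatten_head(head), grad_fn, alpha, steps)
  unflatten_head(flat, head)
}

## ---- evaluation ------------------------------------------------------------

#' Few-shot evaluation on meta-test tasks
#'
#' Per repeat and per meta-test task: draw a balanced `K`-shot adaptation
#' split ([make_adaptation_split()]), adapt (posterior sampling, MAML inner
#' loop, or no adaptation depending on `cfg$mode`), average the class
#' probabilities of the `P_eval` sampled heads on the query set, and score.
#' Tasks whose query ends up single-class are skipped with a warning.
#'
#' @param weights a [model_weights()].
#' @param hyp a [hypernet_params()] (hypernet mode only).
#' @param pool a `task_pool`; its `meta_test` tasks are evaluated.
#' @param graphs list of [molecule_graph()]s indexed by molecule id.
#' @param cfg a [meta_config()].
#' @param shots K used at adaptation time (defaults to `cfg$K`).
#' @param repeats number of independent adaptation repeats.
#' @return `list(table, aggregate, n_skipped)`: the per-cell metric table
#'   (task, repeat, metric, value), its [aggregate_metrics()] summary, and
#'   the skipped-task count.
#' @export
evaluate <- function(weights, hyp, pool, graphs, cfg, shots = NULL,
                     repeats = 10) {
  stopifnot(length(pool$meta_test) >= 1)
  K <- if (is.null(shots)) cfg$K else shots
  rows <- list()
  n_skipped <- 0L
  for (r in seq_len(repeats)) {
    for (task in pool$meta_test) {
      if (!task_eligible(task, K)) {
        n_skipped <- n_skipped + 1L
        next
      }
      sq <- make_adaptation_split(task, K)
      if (length(unique(sq$query$labels)) < 2) {
        warning(sprintf("task '%s': single-class query; skipped", task$name))
        n_skipped <- n_skipped + 1L
        next
      }
      scores <- predict_task(weights, hyp, sq$support, sq$query, graphs, cfg)
      y <- sq$query$labels
      vals <- c(auroc = auroc(scores, y),
                pr_auc = pr_auc(scores, y),
                mcc = mcc(as.integer(scores > 0.5), y))
      rows[[length(rows) + 1L]] <- data.frame(
        task = task$name, repeat_idx = r,
        metric = names(vals), value = as.numeric(vals))
    }
  }
  if (length(rows) == 0) stop("evaluate: every meta-test task was skipped")
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, aggregate = aggregate_metrics(table),
       n_skipped = n_skipped)
}

# Positive-class query probabilities for one adaptation split, averaged over
# the P_eval posterior samples in hypernet mode (Bayesian model averaging on
# the probability scale).
predict_task <- function(weights, hyp, support, query, graphs, cfg) {
  ids <- c(support$molecule_ids, query$molecule_ids)
  emb <- encode_graphs(graphs[ids], weights$encoder)
  ns <- length(support$molecule_ids)
  emb_s <- emb[seq_len(ns), , drop = FALSE]
  emb_q <- emb[-seq_len(ns), , drop = FALSE]
  if (cfg$mode == "hypernet" && !isTRUE(cfg$zero_posterior)) {
    probs_s <- predict_head(emb_s, weights$head)
    post <- hypernet_posterior(
      build_input(emb_s, probs_s, support$labels), hyp)
    acc <- matrix(0, nrow(emb_q), 2)
    for (s in seq_len(cfg$P_eval)) {
      hs <- sample_weights(weights$head, post)
      acc <- acc + predict_head(emb_q, hs)
    }
    (acc / cfg$P_eval)[, 2]
  } else if (cfg$mode == "maml") {
    head_a <- maml_adapt(weights, support, graphs,
                         alpha = cfg$inner_lr, steps = cfg$inner_steps,
                         balanced = cfg$balanced_loss)
    predict_head(emb_q, head_a)[, 2]
  } else {
    predict_head(emb_q, weights$head)[, 2]
  }
}
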