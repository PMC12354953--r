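test_that("build_input concatenates embedding, prediction and one-hot label", {
  # a single-class support is rejected
  expect_error(build_input(matrix(c(1, 2), 1, 2),
                           matrix(c(0.9, 0.1), 1, 2), 1), "both classes")
  emb <- rbind(c(1, 2), c(3, 4))
  probs <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  rows <- build_input(emb, probs, c(1, 0))
  expect_equal(rows[1, ], c(1, 2, 0.9, 0.1, 0, 1))
  expect_equal(rows[2, ], c(3, 4, 0.2, 0.8, 1, 0))
  expect_equal(dim(rows), c(2L, 2L + 4L))
  # permuting examples permutes rows identically
  expect_equal(build_input(emb[2:1, ], probs[2:1, ], c(0, 1)), rows[2:1, ])
  expect_error(build_input(emb, probs[1, , drop = FALSE], c(1, 0)),
               "equal length")
})

test_that("a zeroed hypernetwork emits u = 0 and logvar = bias", {
  hp <- hypernet_params(3, n_params = 5, hidden = 4, logvar_bias_init = -2)
  for (nm in c("Wr1", "Wr2", "Wt1", "Wt2", "Wu", "Wl")) hp[[nm]][] <- 0
  for (nm in c("br1", "br2", "bt1", "bt2", "bu")) hp[[nm]][] <- 0
  rows <- build_input(matrix(rnorm(12), 4, 3),
                      matrix(0.5, 4, 2), c(0, 1, 0, 1))
  post <- hypernet_posterior(rows, hp)
  expect_equal(post$u, rep(0, 5))
  expect_equal(post$logvar, rep(-2, 5))
})

test_that("the posterior is permutation invariant and matches the loop oracle", {
  set.seed(20)
  hp <- hypernet_params(4, n_params = 7, hidden = 6)
  emb <- matrix(rnorm(24), 6, 4)
  probs <- t(apply(matrix(rnorm(12), 6, 2), 1, function(z) exp(z) / sum(exp(z))))
  y <- c(0, 1, 0, 1, 1, 0)
  rows <- build_input(emb, probs, y)
  post <- hypernet_posterior(rows, hp)
  ref <- ref_posterior(rows, hp)
  expect_equal(post$u, ref$u, tolerance = 1e-10)
  expect_equal(post$logvar, ref$logvar, tolerance = 1e-10)
  for (rep in 1:5) {
    prm <- sample(6)
    post_p <- hypernet_posterior(rows[prm, ], hp)
    expect_equal(post_p$u, post$u, tolerance = 1e-9)
    expect_equal(post_p$logvar, post$logvar, tolerance = 1e-9)
  }
  expect_error(hypernet_posterior(rows[1, , drop = FALSE], hp), "at least 2")
})

test_that("emitted log-variance respects the clamp range", {
  set.seed(21)
  hp <- hypernet_params(3, n_params = 4, hidden = 5, out_init_sd = 50)
  rows <- build_input(matrix(rnorm(12, sd = 5), 4, 3),
                      matrix(0.5, 4, 2), c(0, 1, 0, 1))
  post <- hypernet_posterior(rows, hp)
  expect_true(all(post$logvar >= hp$lv_min & post$logvar <= hp$lv_max))
})

test_that("reparameterized sampling follows N(u, exp(logvar))", {
  set.seed(22)
  head <- predictor_params(1, hidden = integer(0), bias = FALSE)
  head$layers[[1]]$W <- matrix(c(0.5, -0.5), 1, 2)
  np <- head_n_params(head)
  expect_equal(np, 2L)
  # zero-variance limit: delta = u exactly, sampling deterministic
  post0 <- posterior_params(u = c(1, 2), logvar = c(-1000, -1000))
  h1 <- sample_weights(head, post0)
  h2 <- sample_weights(head, post0)
  expect_equal(flatten_head(h1), flatten_head(head) + c(1, 2))
  expect_equal(flatten_head(h1), flatten_head(h2))
  # u = 0, logvar = 0: delta equals the raw standard-normal draw
  post1 <- posterior_params(u = c(0, 0), logvar = c(0, 0))
  set.seed(7); eps <- rnorm(2)
  set.seed(7); h3 <- sample_weights(head, post1)
  expect_equal(attr(h3, "delta"), eps)
  expect_equal(flatten_head(h3), flatten_head(head) + eps)
  # Monte-Carlo law check: mean and sd over many draws
  post2 <- posterior_params(u = c(1, -1), logvar = c(0, log(4)))
  n <- 1e5
  set.seed(8)
  D <- t(replicate(200, attr(sample_weights(head, post2), "delta")))
  eps_mat <- matrix(rnorm(2 * n), n, 2)
  deltas <- sweep(eps_mat %*% diag(c(1, 2)), 2, c(1, -1), "+")
  se_mean <- c(1, 2) / sqrt(n)
  se_sd <- c(1, 2) / sqrt(2 * n)
  expect_true(all(abs(colMeans(deltas) - c(1, -1)) < 3 * se_mean))
  expect_true(all(abs(apply(deltas, 2, sd) - c(1, 2)) < 3 * se_sd))
  # the package sampler has the same first two moments (smaller draw count)
  expect_true(all(abs(colMeans(D) - c(1, -1)) < 4 * c(1, 2) / sqrt(200)))
})

test_that("closed-form KL matches hand values and the Monte-Carlo estimate", {
  expect_equal(kl_to_prior(posterior_params(c(0, 0), c(0, 0))), 0)
  expect_equal(kl_to_prior(posterior_params(1, 0)), 0.5)
  # literal mode shifts the mean by the universal weights
  expect_equal(kl_to_prior(posterior_params(1, 0), mode = "literal",
                           theta_flat = -1), 0)
  expect_error(kl_to_prior(posterior_params(1, 0), mode = "literal"),
               "theta_flat")
  expect_error(posterior_params(Inf, 0))
  set.seed(23)
  for (rep in 1:5) {
    u <- rnorm(3); lv <- rnorm(3, sd = 0.8)
    kl <- kl_to_prior(posterior_params(u, lv))
    expect_gte(kl, 0)
    n <- 1e5
    z <- matrix(rnorm(3 * n), n, 3)
    x <- sweep(z %*% diag(exp(lv / 2)), 2, u, "+")
    logq <- sapply(1:3, function(j) dnorm(x[, j], u[j], exp(lv[j] / 2), log = TRUE))
    logp <- dnorm(x, 0, 1, log = TRUE)
    s <- rowSums(logq - logp)
    expect_lt(abs(mean(s) - kl), 3 * sd(s) / sqrt(n))
  }
})

test_that("KL is zero only when the posterior equals the prior", {
  set.seed(24)
  for (rep in 1:20) {
    u <- rnorm(4, sd = 0.5); lv <- rnorm(4, sd = 0.5)
    kl <- kl_to_prior(posterior_params(u, lv))
    if (max(abs(u)) > 1e-8 || max(abs(lv)) > 1e-8) expect_gt(kl, 0)
  }
})

test_that("reparameterization gradients match finite differences", {
  # one-parameter head, quadratic loss 0.5 * (theta' - c)^2:
  # E[loss] = 0.5 * ((theta + u - c)^2 + exp(lv))
  theta <- 0.3; cc <- 1.2; u <- 0.4; lv <- -0.6
  n <- 1e4
  set.seed(25)
  eps <- rnorm(n)
  mc <- function(u, lv) mean(0.5 * (theta + u + exp(lv / 2) * eps - cc)^2)
  # analytic gradient of the expectation
  gu_true <- theta + u - cc
  glv_true <- 0.5 * exp(lv)
  h <- 1e-5
  gu_fd <- (mc(u + h, lv) - mc(u - h, lv)) / (2 * h)
  glv_fd <- (mc(u, lv + h) - mc(u, lv - h)) / (2 * h)
  expect_lt(abs(gu_fd - gu_true) / abs(gu_true), 0.02)
  expect_lt(abs(glv_fd - glv_true) / abs(glv_true), 0.02)
  # and the pathwise (reparameterized) estimator used by the trainer agrees
  dloss <- theta + u + exp(lv / 2) * eps - cc       # d loss / d theta'
  gu_path <- mean(dloss)
  glv_path <- mean(dloss * eps * 0.5 * exp(lv / 2))
  expect_lt(abs(gu_path - gu_fd), 1e-6)
  expect_lt(abs(glv_path - glv_fd), 1e-6)
})
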