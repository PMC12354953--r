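test_that("initial node states sum atom and chirality embeddings", {
  set.seed(1)
  p <- encoder_params(d = 2, n_layers = 1, norm = "none", dropout = 0)
  p$atom_embed[6, ] <- c(1, 2)
  p$chir_embed[1, ] <- c(0.5, -1)
  g <- molecule_graph(6L, 1L, matrix(integer(0), ncol = 2),
                      integer(0), integer(0))
  expect_equal(init_node_states(g, p), matrix(c(1.5, 1), 1, 2))
  # identical (type, chirality) pairs give identical rows
  g2 <- molecule_graph(c(6L, 6L), c(1L, 1L), cbind(c(1L, 2L), c(2L, 1L)),
                       c(1L, 1L), c(1L, 1L))
  h0 <- init_node_states(g2, p)
  expect_equal(h0[1, ], h0[2, ])
  g_bad <- molecule_graph(999L, 1L, matrix(integer(0), ncol = 2),
                          integer(0), integer(0))
  expect_error(init_node_states(g_bad, p), "vocabulary error")
})

test_that("edge embeddings sum bond-type and direction embeddings", {
  set.seed(2)
  p <- encoder_params(d = 2, n_layers = 1, norm = "none", dropout = 0)
  p$bond_embed[1, ] <- c(1, 0)
  p$dir_embed[1, ] <- c(0, 1)
  expect_equal(embed_edge(1L, 1L, p), matrix(c(1, 1), 1, 2))
  expect_equal(embed_edge(c(2L, 2L), c(3L, 3L), p)[1, ],
               embed_edge(2L, 3L, p)[1, ])
  expect_error(embed_edge(9L, 1L, p), "vocabulary error")
  # exhaustive: every (type, dir) pair equals the two table rows summed
  for (bt in 1:4) for (bd in 1:3) {
    expect_equal(as.vector(embed_edge(bt, bd, p)),
                 p$bond_embed[bt, ] + p$dir_embed[bd, ])
  }
})

test_that("one message-passing round matches hand-computed cases", {
  d <- 2
  p <- identity_mlp_encoder(d, n_layers = 1)
  # isolated node: empty neighbor sum + identity MLP leaves the state as is
  g1 <- molecule_graph(6L, 1L, matrix(integer(0), ncol = 2),
                       integer(0), integer(0))
  h0 <- matrix(c(3, -1), 1, 2)
  expect_equal(gin_layer(h0, g1, 1, p), h0)
  # two-node single-bond graph with e = (1,1) on both directions
  g2 <- molecule_graph(c(6L, 6L), c(1L, 1L), cbind(c(1L, 2L), c(2L, 1L)),
                       c(1L, 1L), c(1L, 1L))
  p$bond_embed[1, ] <- c(1, 1)
  p$dir_embed[1, ] <- c(0, 0)
  h0 <- rbind(c(1, 0), c(0, 1))
  expect_equal(gin_layer(h0, g2, 1, p), rbind(c(2, 2), c(2, 2)))
})

test_that("vectorized encoder equals the per-node loop reference", {
  set.seed(33)
  for (rep in 1:20) {
    p <- encoder_params(d = 8, n_layers = 3, norm = "none", dropout = 0,
                        pool = sample(c("mean", "sum", "attention"), 1))
    g <- random_test_graph(sample(2:12, 1))
    expect_equal(encode(g, p), ref_encode(g, p), tolerance = 1e-10)
  }
  # batched encoding agrees with one-at-a-time encoding
  set.seed(34)
  p <- encoder_params(d = 8, n_layers = 2, norm = "none", dropout = 0)
  gs <- lapply(1:6, function(i) random_test_graph(sample(1:10, 1)))
  H <- encode_graphs(gs, p)
  for (i in seq_along(gs)) {
    expect_equal(H[i, ], encode(gs[[i]], p), tolerance = 1e-12)
  }
})

test_that("graph embeddings are invariant to node relabeling", {
  set.seed(44)
  for (pool in c("mean", "sum", "attention")) {
    p <- encoder_params(d = 8, n_layers = 3, pool = pool, norm = "batch",
                        dropout = 0.5) # eval mode: dropout inactive
    g <- random_test_graph(9)
    h <- encode(g, p)
    for (rep in 1:10) {
      perm <- sample(g$n_nodes)
      hp <- encode(permute_graph(g, perm), p)
      expect_equal(hp, h, tolerance = 1e-6)
    }
  }
})

test_that("K message rounds only propagate information K hops", {
  set.seed(55)
  n <- 7
  # path graph 1-2-...-7
  from <- 1:(n - 1); to <- 2:n
  mk <- function(types) molecule_graph(
    types, rep(1L, n), cbind(c(from, to), c(to, from)),
    rep(1L, 2 * (n - 1)), rep(1L, 2 * (n - 1)))
  p <- encoder_params(d = 6, n_layers = 2, norm = "none", dropout = 0)
  t1 <- rep(6L, n)
  t2 <- t1; t2[1] <- 8L # change the endpoint's atom type
  s1 <- encoder_forward(graph_batch(list(mk(t1))), p)$node_states
  s2 <- encoder_forward(graph_batch(list(mk(t2))), p)$node_states
  # nodes within 2 hops of node 1 change; nodes beyond do not
  expect_false(isTRUE(all.equal(s1[1:3, ], s2[1:3, ])))
  expect_equal(s1[4:7, ], s2[4:7, ], tolerance = 1e-12)
})

test_that("pooling variants compute their stated aggregates", {
  set.seed(66)
  p_mean <- encoder_params(d = 2, n_layers = 1, pool = "mean",
                           norm = "none", dropout = 0)
  states <- rbind(c(2, 0), c(0, 2))
  expect_equal(pool_nodes(states, p_mean), c(1, 1))
  p_sum <- encoder_params(d = 2, n_layers = 1, pool = "sum",
                          norm = "none", dropout = 0)
  expect_equal(pool_nodes(states, p_sum), c(2, 2))
  p_att <- encoder_params(d = 2, n_layers = 1, pool = "attention",
                          norm = "none", dropout = 0)
  same <- rbind(c(1, 3), c(1, 3), c(1, 3))
  expect_equal(pool_nodes(same, p_att), c(1, 3)) # uniform weights 1/n
  expect_error(pool_nodes(matrix(numeric(0), 0, 2), p_mean), "empty-input")
})

test_that("encoder weights round-trip through the JSON container", {
  set.seed(77)
  p <- encoder_params(d = 4, n_layers = 2, norm = "batch", dropout = 0)
  path <- tempfile(fileext = ".json")
  save_encoder_weights(p, path)
  p2 <- encoder_params(d = 4, n_layers = 2, norm = "batch", dropout = 0)
  p2 <- load_encoder_weights(p2, path)
  g <- random_test_graph(6)
  expect_equal(encode(g, p2), encode(g, p), tolerance = 1e-12)
  # architecture mismatch is reported
  p3 <- encoder_params(d = 4, n_layers = 3, norm = "batch", dropout = 0)
  expect_error(load_encoder_weights(p3, path), "layers")
  p4 <- encoder_params(d = 5, n_layers = 2, norm = "batch", dropout = 0)
  expect_error(load_encoder_weights(p4, path), "unmatched")
})

test_that("composition: K=1 identity encoder returns pooled initial states", {
  set.seed(88)
  p <- identity_mlp_encoder(3, n_layers = 1, pool = "sum")
  g <- molecule_graph(6L, 1L, matrix(integer(0), ncol = 2),
                      integer(0), integer(0))
  expect_equal(encode(g, p), as.vector(init_node_states(g, p)))
})
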