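test_that("cost matches its dense-matrix definition", {
  # edgeless network has zero cost for any ordering
  # (interaction_network drops isolated nodes, so build a 2-node, 1-edge net
  # and check the clique instead)
  k3 <- clique_network(3)
  ords <- list(c("c1", "c2", "c3"), c("c2", "c1", "c3"), c("c3", "c1", "c2"))
  for (o in ords) {
    ord <- gene_ordering(o)
    # distance term of K3 is permutation-invariant: 1 + 1 + 2 = 4 at alpha 1
    expect_equal(ordering_cost(k3, ord, alpha = 1, beta = 0), 4)
    expect_equal(ordering_cost(k3, ord, alpha = 1, beta = 1),
                 cost_oracle(k3, ord, 1, 1))
  }

  # path graph: all 6 permutations against the dense oracle; the natural
  # order must be among the distance-term minimizers
  p3 <- path_network(3)
  perms <- list(c("n1","n2","n3"), c("n1","n3","n2"), c("n2","n1","n3"),
                c("n2","n3","n1"), c("n3","n1","n2"), c("n3","n2","n1"))
  dist_costs <- vapply(perms, function(p)
    ordering_cost(p3, gene_ordering(p), alpha = 1, beta = 0), numeric(1))
  full_costs <- vapply(perms, function(p)
    ordering_cost(p3, gene_ordering(p), alpha = 1, beta = 1), numeric(1))
  oracle <- vapply(perms, function(p)
    cost_oracle(p3, gene_ordering(p), 1, 1), numeric(1))
  expect_equal(full_costs, oracle)
  expect_equal(dist_costs[1], min(dist_costs))
})

test_that("incremental delta equals full recomputation on random instances", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(4:30, 1)
    net <- random_network(n, p = runif(1, 0.1, 0.5), seed = rep)
    nn <- length(net$nodes)
    ord <- random_ordering(net, seed = rep + 500)
    p <- sample(nn, 1); q <- sample(nn, 1)
    alpha <- sample(c(0.5, 1, 2, 10), 1); beta <- sample(c(0, 0.5, 1, 3), 1)
    d <- ordering_delta_cost(net, ord, p, q, alpha, beta)
    swapped <- ord$gene
    swapped[c(p, q)] <- swapped[c(q, p)]
    d_oracle <- ordering_cost(net, gene_ordering(swapped), alpha, beta) -
      ordering_cost(net, ord, alpha, beta)
    expect_equal(d, d_oracle, tolerance = 1e-10)
  }
})

test_that("delta is zero for p == q and antisymmetric under re-swap", {
  net <- random_network(12, p = 0.3, seed = 2)
  ord <- random_ordering(net, seed = 20)
  expect_equal(ordering_delta_cost(net, ord, 5, 5), 0)
  d1 <- ordering_delta_cost(net, ord, 2, 9)
  swapped <- ord$gene; swapped[c(2, 9)] <- swapped[c(9, 2)]
  d2 <- ordering_delta_cost(net, gene_ordering(swapped), 2, 9)
  expect_equal(d1 + d2, 0, tolerance = 1e-12)
})

test_that("annealing is deterministic under a seed and never worsens the start", {
  net <- interaction_network(rbind(
    as.data.frame(clique_network(5, "a")), as.data.frame(clique_network(5, "b"))))
  f1 <- anneal_ordering(net, alpha = 1, seed = 3, max_mcs = 400)
  f2 <- anneal_ordering(net, alpha = 1, seed = 3, max_mcs = 400)
  expect_identical(f1$ordering$gene, f2$ordering$gene)
  expect_lte(f1$f_best, f1$f_init)
  # trace discipline: temperature halves on schedule
  expect_equal(f1$trace$temperature[101], f1$trace$temperature[1] / 2)
  expect_true(all(is.finite(f1$trace$cost)))
  # different seed gives an equally valid permutation of the same genes
  f3 <- anneal_ordering(net, alpha = 1, seed = 4, max_mcs = 400)
  expect_setequal(f3$ordering$gene, net$nodes)
})

test_that("annealing refuses an edgeless network", {
  f <- withr::local_tempfile()
  writeLines("A B 100", f)
  expect_warning(empty <- read_interactions(f, 800))
  expect_error(anneal_ordering(empty, seed = 1), class = "xgram_empty_network")
})

test_that("steep distance decay suppresses long-range association mass", {
  # with many cross-module edges, alpha ~ 10 forbids long-range placements
  # that alpha = 1 tolerates
  pl <- make_planted_network(5, 12, p_in = 0.6, p_out = 0.08, seed = 14)
  f1 <- anneal_ordering(pl$network, alpha = 1, seed = 14, max_mcs = 1500)
  f10 <- anneal_ordering(pl$network, alpha = 10, seed = 14, max_mcs = 1500)
  tail_mass <- function(fit) {
    g <- gamma_profile(pl$network, fit$ordering)
    sum(g$gamma[g$d > 30])
  }
  expect_lte(tail_mass(f10), tail_mass(f1))
})
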