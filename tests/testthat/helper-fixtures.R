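# fixtures built in code; no files ship with the tests

path_network <- function(n = 4) {
  interaction_network(data.frame(a = paste0("n", 1:(n - 1)),
                                 b = paste0("n", 2:n)))
}

clique_network <- function(n = 5, prefix = "c") {
  pairs <- t(utils::combn(paste0(prefix, 1:n), 2))
  interaction_network(data.frame(a = pairs[, 1], b = pairs[, 2]))
}

random_network <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  pairs <- t(utils::combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  # make sure no node is isolated: chain everything once
  edges <- rbind(pairs[keep, , drop = FALSE], cbind(1:(n - 1), 2:n))
  interaction_network(data.frame(a = paste0("v", edges[, 1]),
                                 b = paste0("v", edges[, 2])))
}

# direct per-window edge-count oracle for modularity
modularity_oracle <- function(network, ordering, r) {
  ord <- xgram::gene_ordering(ordering$gene)
  pos <- match(network$nodes, ord$gene)
  n <- nrow(ord)
  sapply(seq_len(n), function(i) {
    w <- max(1, i - r):min(n, i + r)
    inside <- pos %in% w
    a <- inside[network$edges[, 1]]
    b <- inside[network$edges[, 2]]
    e_in <- sum(a & b); e_touch <- sum(a | b)
    if (e_touch == 0) NA_real_ else e_in / e_touch
  })
}

# brute-force gamma by enumerating partner distances per gene
gamma_oracle <- function(network, ordering) {
  ord <- xgram::gene_ordering(ordering$gene)
  pos <- match(network$nodes, ord$gene)
  n <- nrow(ord)
  adj <- lapply(seq_along(network$nodes), function(i) {
    c(network$edges[network$edges[, 1] == i, 2],
      network$edges[network$edges[, 2] == i, 1])
  })
  gam <- numeric(n - 1)
  for (i in seq_along(adj)) {
    k <- length(adj[[i]])
    for (j in adj[[i]]) {
      d <- abs(pos[i] - pos[j])
      gam[d] <- gam[d] + 1 / k
    }
  }
  gam / length(network$nodes)
}

# dense evaluation of the seriation cost straight from its definition
cost_oracle <- function(network, ordering, alpha, beta) {
  ord <- xgram::gene_ordering(ordering$gene)
  pos <- match(network$nodes, ord$gene)
  n <- nrow(ord)
  A <- matrix(0, n, n)
  for (e in seq_len(nrow(network$edges))) {
    i <- pos[network$edges[e, 1]]; j <- pos[network$edges[e, 2]]
    A[i, j] <- 1; A[j, i] <- 1
  }
  fdist <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) if (A[i, j] == 1)
    fdist <- fdist + abs(i - j)^alpha
  d <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i + 1 <= n) d <- d + abs(A[i, j] - A[i + 1, j])
    if (j + 1 <= n) d <- d + abs(A[i, j] - A[i, j + 1])
  }
  fdist + beta * d
}

tmp_tsv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
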