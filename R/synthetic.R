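# -- planted-module networks and the three-component expression model ------

#' Generate a planted-partition association network
#'
#' `m` clusters of `c` nodes; each within-cluster pair becomes an edge with
#' probability `p_in` and each between-cluster pair with probability
#' `p_out`, independently.  This emulates the modular block structure of
#' curated association networks and provides ground-truth cluster labels for
#' ordering-recovery tests.  Nodes left isolated are re-wired to one random
#' partner in their own cluster, since seriation requires every node to have
#' at least one association.
#'
#' @param n_clusters,cluster_size number and size of planted clusters.
#' @param p_in,p_out within- and between-cluster edge probabilities;
#'   recovery needs `p_in > p_out` (warned, not enforced).
#' @param seed integer RNG seed.
#' @return A list with `network` (an [interaction_network()]) and `labels`
#'   (tibble `gene`, `cluster`).
#' @export
make_planted_network <- function(n_clusters, cluster_size, p_in, p_out, seed) {
  n <- n_clusters * cluster_size
  if (n < 2) abort("network needs at least 2 nodes")
  if (p_out >= p_in) warn("p_out >= p_in: planted structure is not recoverable")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  genes <- sprintf("g%04d", seq_len(n))
  cluster <- rep(seq_len(n_clusters), each = cluster_size)
  pairs <- utils::combn(n, 2)
  same <- cluster[pairs[1, ]] == cluster[pairs[2, ]]
  p <- ifelse(same, p_in, p_out)
  keep <- runif(ncol(pairs)) < p
  a <- pairs[1, keep]; b <- pairs[2, keep]

  isolated <- setdiff(seq_len(n), unique(c(a, b)))
  for (i in isolated) {
    mates <- setdiff(which(cluster == cluster[i]), i)
    j <- if (length(mates) == 1) mates else sample(mates, 1)
    a <- c(a, min(i, j)); b <- c(b, max(i, j))
  }
  net <- interaction_network(data.frame(genes[a], genes[b]))
  # keep label order aligned with the network's node order
  lab <- tibble(gene = net$nodes,
                cluster = cluster[match(net$nodes, genes)])
  list(network = net, labels = lab)
}

#' Simulate expression under the additive three-component model
#'
#' Every measurement is the sum of three terms: a deterministic signal
#' `s` that depends on the gene and the condition only; a biological
#' deviation with SD `sigma_b`, drawn once per (gene, biological replicate)
#' and shared by that replicate's technical replicates; and an independent
#' technical noise with SD `sigma_xi` per measurement.  Biological
#' deviations can be correlated within a planted cluster: with
#' `rho_bio = 0` genes vary independently, with `rho_bio = 1` a whole
#' cluster moves together (the two covariance limit cases that decide
#' whether windowing shrinks biological variance).  Correlation is realized
#' as `sqrt(rho) * shared-cluster draw + sqrt(1 - rho) * own draw`, which
#' preserves the marginal SD.
#'
#' By default condition differences are localized: the second and later
#' conditions shift `ceiling(m/5)` randomly chosen clusters by `delta`
#' (log2 units) on top of a common baseline, mimicking peaked differential
#' profiles.  Pass `signal` to override the layout entirely.
#'
#' @param labels cluster-label tibble from [make_planted_network()] (or any
#'   tibble with `gene` and `cluster`).
#' @param conditions character vector of condition names.
#' @param n_b,n_a biological and technical replicates per condition.
#' @param sigma_b,sigma_xi biological and technical SDs (log2 units).
#' @param rho_bio within-cluster correlation of biological deviations, in
#'   [0, 1].
#' @param delta condition shift applied to the selected clusters (log2
#'   units).
#' @param shifted_clusters optional integer vector of cluster IDs to shift
#'   (default: `ceiling(m/5)` chosen at random).
#' @param baseline common expected signal level (log2 units).
#' @param signal optional genes x conditions matrix of expected signals
#'   overriding the default layout.
#' @param seed integer RNG seed.
#' @return A list with `expression` (wide tibble: `gene` + one column per
#'   sample), `design` (tibble `sample`, `condition`, `bio_rep`,
#'   `tech_rep`), and `truth` (list: `signal` matrix, `bio` array of
#'   per-(gene, condition, bio rep) deviations, `shifted_clusters` and all
#'   parameters).
#' @export
make_expression <- function(labels, conditions = c("A", "B"), n_b = 5,
                            n_a = 4, sigma_b = 0.3, sigma_xi = 0.5,
                            rho_bio = 0, delta = 0.5,
                            shifted_clusters = NULL, baseline = 8,
                            signal = NULL, seed) {
  if (sigma_b < 0 || sigma_xi < 0) abort("SDs must be >= 0")
  if (rho_bio < 0 || rho_bio > 1) abort("`rho_bio` must be in [0, 1]")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  genes <- labels$gene
  cluster <- labels$cluster
  n <- length(genes)
  m <- max(cluster)

  if (is.null(signal)) {
    if (is.null(shifted_clusters))
      shifted_clusters <- sample(m, ceiling(m / 5))
    signal <- matrix(baseline, n, length(conditions),
                     dimnames = list(genes, conditions))
    if (length(conditions) > 1)
      signal[cluster %in% shifted_clusters, -1] <- baseline + delta
  } else {
    signal <- as.matrix(signal)
    if (nrow(signal) != n || ncol(signal) != length(conditions))
      abort("`signal` must be genes x conditions")
    dimnames(signal) <- list(genes, conditions)
    shifted_clusters <- shifted_clusters %||% integer(0)
  }

  design <- tidyr::expand_grid(condition = conditions,
                               bio_rep = seq_len(n_b),
                               tech_rep = seq_len(n_a))
  design <- dplyr::mutate(design,
    sample = sprintf("%s_b%d_t%d", .data$condition, .data$bio_rep, .data$tech_rep),
    .before = 1)

  bio <- array(0, dim = c(n, length(conditions), n_b),
               dimnames = list(genes, conditions, NULL))
  for (ci in seq_along(conditions)) for (b in seq_len(n_b)) {
    shared <- rnorm(m, 0, sigma_b)[cluster]   # one draw per cluster
    own <- rnorm(n, 0, sigma_b)
    bio[, ci, b] <- sqrt(rho_bio) * shared + sqrt(1 - rho_bio) * own
  }

  vals <- matrix(NA_real_, n, nrow(design),
                 dimnames = list(genes, design$sample))
  for (s in seq_len(nrow(design))) {
    ci <- match(design$condition[s], conditions)
    b <- design$bio_rep[s]
    vals[, s] <- signal[, ci] + bio[, ci, b] + rnorm(n, 0, sigma_xi)
  }

  list(
    expression = dplyr::bind_cols(tibble(gene = genes),
                                  as_tibble(as.data.frame(vals, check.names = FALSE))),
    design = validate_design(design),
    truth = list(signal = signal, bio = bio,
                 shifted_clusters = sort(shifted_clusters),
                 params = list(conditions = conditions, n_b = n_b, n_a = n_a,
                               sigma_b = sigma_b, sigma_xi = sigma_xi,
                               rho_bio = rho_bio, delta = delta,
                               baseline = baseline, seed = as.integer(seed)))
  )
}
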