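#' Seriation cost of an ordering
#'
#' The cost being minimized has two terms, both computed on the association
#' matrix written in ordering coordinates.  The first sums `|i - j|^alpha`
#' over all associated pairs, so associations between distant list positions
#' are expensive and `alpha` sets how steeply distance is punished.  The
#' second, weighted by `beta`, is the L1 difference between adjacent rows and
#' adjacent columns of the 0/1 matrix: it falls when genes sharing partners
#' sit next to each other, smoothing the block structure of the matrix.
#'
#' @param network an [interaction_network()].
#' @param ordering a [gene_ordering()] over the network nodes.
#' @param alpha distance-decay exponent (>= 0); `alpha = 1` is the standard
#'   choice, large values (~10) forbid long-range associations entirely.
#' @param beta weight of the neighbor-smoothness term (>= 0, default 1).
#' @return A single non-negative number; 0 for an edgeless network.
#' @export
ordering_cost <- function(network, ordering, alpha = 1, beta = 1) {
  perm0 <- perm_for(network, ordering)
  cpp_cost(n_nodes(network), network$edges[, 1] - 1L, network$edges[, 2] - 1L,
           perm0, alpha, beta)
}

#' @describeIn ordering_cost Exact cost change for swapping list positions
#'   `p` and `q`, computed incrementally (touching only the swapped nodes'
#'   neighborhoods, not the whole matrix).
#' @param p,q list positions to swap (1-based).
#' @export
ordering_delta_cost <- function(network, ordering, p, q, alpha = 1, beta = 1) {
  n <- n_nodes(network)
  if (p < 1 || p > n || q < 1 || q > n) abort("swap positions out of range")
  perm0 <- perm_for(network, ordering)
  cpp_delta_cost(n, network$edges[, 1] - 1L, network$edges[, 2] - 1L,
                 perm0, alpha, beta, as.integer(p) - 1L, as.integer(q) - 1L)
}

# 0-based permutation (position -> node index) for the C++ kernels
perm_for <- function(network, ordering) {
  pos <- node_positions(network, ordering)   # node index -> position
  if (length(pos) != nrow(validate_ordering(ordering)))
    abort("ordering and network must cover the same genes")
  perm <- integer(length(pos))
  perm[pos] <- seq_along(pos)
  perm - 1L
}

#' Order a gene list by simulated annealing
#'
#' Metropolis Monte Carlo over permutations: at each step two random list
#' positions are swapped; the move is kept when the cost decreases and
#' otherwise with probability `exp(-dF/T)`.  The temperature starts at
#' `t0_frac` times the initial cost (0.01% by default) and is halved every
#' `halve_every` Monte Carlo steps (one MCS = `mcs_size` attempted swaps,
#' defaulting to N), a schedule that escapes metastable states early and
#' quenches quickly.  The run stops when fewer than `stop_accept_floor` of
#' proposals were accepted over `stop_window` consecutive MCS (acceptance has
#' stabilized), when the temperature underflows, or at `max_mcs`.  The
#' best-seen ordering, not the final state, is returned.
#'
#' @inheritParams ordering_cost
#' @param seed integer RNG seed; a single seeded generator drives the initial
#'   shuffle, proposals and acceptance, so identical inputs and seed give
#'   identical output.
#' @param t0_frac initial temperature as a fraction of the initial cost.
#' @param halve_every MCS between temperature halvings.
#' @param mcs_size attempted swaps per MCS (default: number of nodes).
#' @param stop_window,stop_accept_floor stopping rule: stop when the accepted
#'   fraction over `stop_window` consecutive MCS drops below
#'   `stop_accept_floor`.
#' @param max_mcs hard cap on MCS.
#' @param initial optional starting `gene_ordering` (default: seeded random
#'   shuffle of the nodes).
#' @return An object of class `anneal_fit`: list with `ordering` (a
#'   [gene_ordering()]), `trace` (tibble of per-MCS temperature, cost and
#'   acceptance), `f_init`, `f_best` and `config`.
#' @export
anneal_ordering <- function(network, alpha = 1, beta = 1, seed,
                            t0_frac = 1e-4, halve_every = 100L,
                            mcs_size = NULL, stop_window = 50L,
                            stop_accept_floor = 1e-4, max_mcs = 5000L,
                            initial = NULL) {
  if (nrow(network$edges) == 0)
    abort("cannot order an edgeless network", class = "xgram_empty_network")
  if (missing(seed)) abort("`seed` is required for a reproducible ordering")
  n <- n_nodes(network)
  mcs_size <- as.integer(mcs_size %||% n)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  start <- if (is.null(initial)) gene_ordering(sample(network$nodes))
           else validate_ordering(initial)
  perm0 <- perm_for(network, start)

  res <- cpp_anneal(n, network$edges[, 1] - 1L, network$edges[, 2] - 1L,
                    perm0, alpha, beta, t0_frac, as.integer(halve_every),
                    mcs_size, as.integer(stop_window), stop_accept_floor,
                    as.integer(max_mcs))

  ordering <- gene_ordering(network$nodes[res$perm + 1L],
                            alpha = alpha, seed = as.integer(seed))
  structure(
    list(ordering = ordering,
         trace = as_tibble(res$trace),
         f_init = res$f_init, f_best = res$f_best,
         config = list(alpha = alpha, beta = beta, seed = as.integer(seed),
                       t0_frac = t0_frac, halve_every = halve_every,
                       mcs_size = mcs_size, stop_window = stop_window,
                       stop_accept_floor = stop_accept_floor,
                       max_mcs = max_mcs)),
    class = "anneal_fit"
  )
}

#' @export
print.anneal_fit <- function(x, ...) {
  cat(sprintf("<anneal_fit> N = %d, alpha = %g, F: %.4g -> %.4g (%d MCS)\n",
              nrow(x$ordering), x$config$alpha, x$f_init, x$f_best,
              nrow(x$trace)))
  invisible(x)
}
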