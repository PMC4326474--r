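#' Occupation fraction of association partners by list distance
#'
#' For each gene, the fraction of its k_i association partners found at list
#' distance d (counting both directions along the ordering) is averaged over
#' all N genes.  The resulting gamma(d) sums to 1 over d = 1..N-1 -- each
#' gene's partners partition across distances -- and a mass concentrated at
#' small d is the signature of a good seriation: associated genes sit close
#' together on the list.
#'
#' @param network an [interaction_network()].
#' @param ordering a [gene_ordering()] covering every network node.
#' @return A tibble with columns `d` (1..N-1) and `gamma`.
#' @export
gamma_profile <- function(network, ordering) {
  pos <- node_positions(network, ordering)
  n <- length(validate_ordering(ordering)$gene)
  gam <- numeric(max(n - 1L, 1L))
  if (nrow(network$edges)) {
    dd <- abs(pos[network$edges[, 1]] - pos[network$edges[, 2]])
    ku <- network$degree[network$edges[, 1]]
    kv <- network$degree[network$edges[, 2]]
    # each undirected edge is seen once from each endpoint
    w <- 1 / ku + 1 / kv
    acc <- rowsum(w, group = dd)
    gam[as.integer(rownames(acc))] <- acc[, 1] / n_nodes(network)
  }
  tibble(d = seq_along(gam), gamma = gam)
}

#' Window modularity along an ordering
#'
#' For the window of radius r centred at each position, the ratio of the
#' number of associations with both endpoints inside the window to the
#' number touching the window at all.  M = 1 means the window is an isolated
#' cluster; M = 0 means every incident association leaves the window.
#' Windows touched by no association are reported as `NA` (undefined), which
#' is distinct from 0.
#'
#' @param network an [interaction_network()].
#' @param ordering a [gene_ordering()] covering every network node.
#' @param r window radius (window spans `max(1, i-r) .. min(N, i+r)`,
#'   truncated at the list ends).
#' @return A tibble with columns `position`, `gene`, `e_in`, `e_touch`,
#'   `modularity`.
#' @export
window_modularity <- function(network, ordering, r) {
  if (r < 0) abort("`r` must be >= 0", class = "xgram_bad_radius")
  ord <- validate_ordering(ordering)
  pos <- node_positions(network, ordering)
  n <- nrow(ord)
  # difference-array accumulation: an edge with endpoint positions a <= b is
  # inside the window centred at i iff i in [b - r, a + r], and touches it
  # iff i in [a - r, b + r] (intervals clipped to 1..N)
  d_in <- numeric(n + 1L)
  d_touch <- numeric(n + 1L)
  if (nrow(network$edges)) {
    a <- pmin(pos[network$edges[, 1]], pos[network$edges[, 2]])
    b <- pmax(pos[network$edges[, 1]], pos[network$edges[, 2]])
    lo_in <- pmax(1L, b - r); hi_in <- pmin(n, a + r)
    ok <- lo_in <= hi_in
    d_in <- tabulate(lo_in[ok], nbins = n + 1L) -
      tabulate(hi_in[ok] + 1L, nbins = n + 1L)
    # the touch region is the union of the two endpoint neighborhoods; when
    # the endpoints are more than 2r apart it is two disjoint intervals
    joined <- (b - a) <= 2L * r
    lo1 <- pmax(1L, a - r)
    hi1 <- ifelse(joined, pmin(n, b + r), pmin(n, a + r))
    lo2 <- pmax(1L, b - r)[!joined]
    hi2 <- pmin(n, b + r)[!joined]
    d_touch <- tabulate(lo1, nbins = n + 1L) -
      tabulate(hi1 + 1L, nbins = n + 1L) +
      tabulate(lo2, nbins = n + 1L) -
      tabulate(hi2 + 1L, nbins = n + 1L)
  }
  e_in <- cumsum(d_in)[seq_len(n)]
  e_touch <- cumsum(d_touch)[seq_len(n)]
  m <- ifelse(e_touch > 0, e_in / e_touch, NA_real_)
  tibble(position = seq_len(n), gene = ord$gene,
         e_in = as.integer(e_in), e_touch = as.integer(e_touch),
         modularity = m)
}

#' Local maxima of a modularity (or any per-position) profile
#'
#' A position is a local maximum when its value equals the maximum over the
#' surrounding window of half-width `span` and exceeds the profile median;
#' plateaus contribute their central position.  Used to count recovered
#' clusters after seriation.
#'
#' @param profile numeric vector (NAs allowed).
#' @param span neighborhood half-width.
#' @return Integer vector of peak positions.
#' @export
profile_peaks <- function(profile, span = 10L) {
  n <- length(profile)
  x <- ifelse(is.na(profile), -Inf, profile)
  med <- stats::median(profile, na.rm = TRUE)
  is_peak <- vapply(seq_len(n), function(i) {
    w <- x[max(1L, i - span):min(n, i + span)]
    x[i] > med && x[i] >= max(w)
  }, logical(1))
  runs <- rle(is_peak)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  as.integer(round((starts[runs$values] + ends[runs$values]) / 2))
}
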