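#' Construct a gene ordering
#'
#' A gene ordering is a permutation of network nodes: position 1..N along the
#' seriated list, together with the relative position (position - 1)/(N - 1)
#' used on figure axes.  It is represented as a tibble so it pipes into the
#' profiling verbs directly.
#'
#' @param genes character vector of gene/protein IDs in list order.
#' @param alpha,seed provenance metadata recorded as attributes (the
#'   distance-decay exponent and RNG seed used to produce the ordering).
#' @return A tibble of class `gene_ordering` with columns `position`, `gene`,
#'   `rel_position`.
#' @export
gene_ordering <- function(genes, alpha = NA_real_, seed = NA_integer_) {
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    abort("ordering contains duplicated gene IDs", class = "xgram_bad_ordering")
  n <- length(genes)
  if (n < 1) abort("ordering is empty", class = "xgram_bad_ordering")
  out <- tibble(
    position = seq_len(n),
    gene = genes,
    rel_position = if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  )
  attr(out, "alpha") <- alpha
  attr(out, "seed") <- seed
  class(out) <- c("gene_ordering", class(out))
  out
}

validate_ordering <- function(ordering) {
  if (inherits(ordering, "gene_ordering")) return(ordering)
  if (is.character(ordering)) return(gene_ordering(ordering))
  if (is.data.frame(ordering) && all(c("position", "gene") %in% names(ordering))) {
    ord <- ordering[order(ordering$position), ]
    if (!identical(as.integer(ord$position), seq_len(nrow(ord))))
      abort("ordering positions must be consecutive 1..N",
            class = "xgram_bad_ordering")
    return(gene_ordering(ord$gene))
  }
  abort("`ordering` must be a gene_ordering, a character vector, or a data frame with position/gene columns")
}

#' Seeded random permutation of an ordering or network
#'
#' Used as the null baseline throughout: a random list destroys the
#' neighborhood structure the seriation builds, so windowed profiles lose
#' contrast while keeping the same marginal values.
#'
#' @param x a `gene_ordering`, `interaction_network`, or character vector.
#' @param seed integer RNG seed.
#' @return A `gene_ordering` with the same genes in shuffled order.
#' @export
random_ordering <- function(x, seed) {
  genes <- if (inherits(x, "interaction_network")) x$nodes
           else validate_ordering(x)$gene
  withr_seed <- function(code) { # local RNG scope, do not disturb caller
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  gene_ordering(withr_seed(sample(genes)), seed = as.integer(seed))
}
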