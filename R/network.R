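#' Build an undirected association network from an edge table
#'
#' The network is the substrate for gene-list seriation: nodes are gene or
#' protein identifiers and an (unweighted) edge records that the two products
#' are functionally associated.  Duplicate pairs, reversed duplicates and
#' self-loops are collapsed or dropped, and only nodes with at least one
#' surviving partner are retained -- genes without any association cannot be
#' placed meaningfully on the ordered list.
#'
#' @param edges data frame whose first two columns hold node identifiers
#'   (one row per association).
#' @return An `interaction_network`: a list with `nodes` (character),
#'   `edges` (integer matrix, 1-based node indices, one row per undirected
#'   edge) and `degree` (named integer vector).
#' @examples
#' net <- interaction_network(data.frame(a = c("x", "y"), b = c("y", "z")))
#' net$degree
#' @export
interaction_network <- function(edges) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) abort("`edges` needs two columns of node IDs")
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  loops <- a == b
  if (any(loops)) {
    warn(sprintf("dropped %d self-association(s)", sum(loops)))
    a <- a[!loops]; b <- b[!loops]
  }
  g <- igraph::simplify(
    igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE),
    remove.multiple = TRUE, remove.loops = TRUE
  )
  nodes <- igraph::V(g)$name
  em <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(em) <- "integer"
  deg <- igraph::degree(g)
  structure(
    list(nodes = nodes, edges = em, degree = setNames(as.integer(deg), nodes)),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

n_nodes <- function(network) length(network$nodes)

#' @export
as.data.frame.interaction_network <- function(x, ...) {
  data.frame(node_a = x$nodes[x$edges[, 1]], node_b = x$nodes[x$edges[, 2]])
}

# positions (1-based) of each node under an ordering; errors if any node of
# the network is missing from the ordering
node_positions <- function(network, ordering) {
  ord <- validate_ordering(ordering)
  pos <- match(network$nodes, ord$gene)
  if (anyNA(pos)) {
    missing <- network$nodes[is.na(pos)][1]
    abort(sprintf("node '%s' is missing from the ordering", missing),
          class = "xgram_missing_node")
  }
  pos
}
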