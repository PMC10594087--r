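# Node centrality (strength, closeness, betweenness) and global strength.
# Shortest paths use edge lengths 1/|e_ij|, the conventional distance
# transform for partial-correlation networks.

.network_igraph <- function(net, use_abs = TRUE) {
  W <- .network_weights(.as_network(net))
  A <- if (use_abs) abs(W) else W
  igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Node strength
#'
#' `strength_i = sum_j |e_ij|`: the summed absolute weight of edges
#' incident to each node.  The signed variant (sum of raw weights, also
#' called expected influence) is available via [expected_influence()].
#'
#' @param net a [pc_network].
#' @return Named numeric vector.
#' @export
node_strength <- function(net) {
  W <- .network_weights(.as_network(net))
  rowSums(abs(W))
}

#' Signed node strength (expected influence)
#'
#' @param net a [pc_network].
#' @return Named numeric vector of summed raw (signed) incident weights.
#' @export
expected_influence <- function(net) {
  rowSums(.network_weights(.as_network(net)))
}

#' Global strength (overall connectivity)
#'
#' The weighted absolute sum of all edges, each undirected edge counted
#' once: `g = sum_{i<j} |e_ij|`.
#'
#' @param net a [pc_network].
#' @return Scalar.
#' @export
global_strength <- function(net) {
  W <- .network_weights(.as_network(net))
  sum(abs(W[upper.tri(W)]))
}

#' All-pairs shortest-path distance matrix
#'
#' Edge lengths are `1/|e_ij|` for nonzero edges; unreachable pairs get
#' `Inf`.
#'
#' @param net a [pc_network].
#' @return p x p numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(net) {
  net <- .as_network(net)
  g <- .network_igraph(net)
  w <- igraph::E(g)$weight
  D <- igraph::distances(g, weights = if (length(w)) 1 / w else NULL)
  D[colnames(net), colnames(net), drop = FALSE]
}

#' Closeness centrality
#'
#' `closeness_i = 1 / sum_{j != i} d_ij` with `d` the shortest-path
#' distances of [distance_matrix()].  Nodes with any unreachable partner
#' get closeness 0 (disconnected convention; reported via a message).
#'
#' @param net a [pc_network].
#' @return Named numeric vector.
#' @export
closeness_centrality <- function(net) {
  D <- distance_matrix(net)
  p <- nrow(D)
  if (p == 1L) return(setNames(0, rownames(D)))
  tot <- rowSums(D)
  out <- ifelse(is.finite(tot) & tot > 0, 1 / tot, 0)
  if (any(!is.finite(tot)))
    message("closeness: disconnected node(s) assigned closeness 0: ",
            paste(rownames(D)[!is.finite(tot)], collapse = ", "))
  setNames(out, rownames(D))
}

#' Betweenness centrality
#'
#' For each unordered pair (s, t), a node v not in {s, t} receives credit
#' `sigma_st(v) / sigma_st` (the fraction of shortest s-t paths through v),
#' summed over pairs.  Shortest paths use lengths `1/|e_ij|`.
#'
#' @param net a [pc_network].
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(net) {
  net <- .as_network(net)
  g <- .network_igraph(net)
  w <- igraph::E(g)$weight
  b <- igraph::betweenness(g, directed = FALSE,
                           weights = if (length(w)) 1 / w else NULL)
  b[colnames(net)]
}

#' Centrality table
#'
#' Strength, closeness, betweenness and expected influence per node, plus
#' z-standardized versions of each index (columns prefixed `z_`).  When an
#' index is constant its z-column is set to 0.
#'
#' @param net a [pc_network].
#' @return A data frame with one row per item.
#' @export
centrality_table <- function(net) {
  net <- .as_network(net)
  df <- data.frame(item = colnames(net),
                   strength = node_strength(net),
                   closeness = closeness_centrality(net),
                   betweenness = betweenness_centrality(net),
                   expected_influence = expected_influence(net),
                   row.names = NULL, stringsAsFactors = FALSE)
  for (col in c("strength", "closeness", "betweenness")) {
    s <- sd(df[[col]])
    df[[paste0("z_", col)]] <-
      if (is.na(s) || s == 0) rep(0, nrow(df)) else
        (df[[col]] - mean(df[[col]])) / s
  }
  df
}
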