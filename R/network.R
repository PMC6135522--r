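#' Build a directed weighted social interaction network
#'
#' Tallies touch interactions into an N x N adjacency matrix of counts
#' (row = interactor, column = interacted; the diagonal is zero - no
#' self-interaction is defined) and stores the max-normalized weight matrix
#' used by all network parameters.
#'
#' @param events tibble (interactor_id, interacted_id, ...), one row per
#'   touch interaction, e.g. from [extract_interactions()].
#' @param n_flies number of nodes.
#' @return A `social_network` object: list with `counts` (integer matrix),
#'   `weights` (counts / max(counts)) and `n`.
#' @export
#' @examples
#' ev <- tibble::tibble(interactor_id = c(1, 1, 2), interacted_id = c(2, 2, 3))
#' net <- build_adjacency(ev, n_flies = 3)
#' net$counts[1, 2]  # 2 interactions fly 1 -> fly 2
build_adjacency <- function(events, n_flies) {
  stopifnot(n_flies >= 1)
  counts <- matrix(0L, n_flies, n_flies)
  if (nrow(events)) {
    i <- as.integer(events$interactor_id)
    j <- as.integer(events$interacted_id)
    if (any(i < 1 | i > n_flies | j < 1 | j > n_flies))
      abort("event fly ids outside 1..n_flies", class = "flynet_bad_event")
    if (any(i == j))
      abort("self-interaction events are not defined", class = "flynet_bad_event")
    for (r in seq_along(i)) counts[i[r], j[r]] <- counts[i[r], j[r]] + 1L
  }
  social_network(counts)
}

#' Construct a social network from a count matrix
#' @param counts square non-negative matrix of interaction counts with zero
#'   diagonal.
#' @return a `social_network`.
#' @export
social_network <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (any(diag(counts) != 0))
    abort("self-interactions (non-zero diagonal) are not defined",
          class = "flynet_bad_event")
  mx <- max(counts)
  structure(list(counts = counts,
                 weights = if (mx > 0) counts / mx else counts * 0,
                 n = nrow(counts)),
            class = "social_network")
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf("<social_network: %d flies, %d interactions, %d directed edges>\n",
              x$n, sum(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' Per-node degrees and strengths
#'
#' Binary degrees count directed edges (non-zero off-diagonal entries);
#' weighted degrees (strengths) sum the max-normalized weights. The degree is
#' the sum of the in-degree and out-degree.
#'
#' @param net a `social_network`.
#' @return tibble, one row per fly: in_degree, out_degree, degree,
#'   weighted_in_degree, weighted_out_degree, weighted_degree.
#' @export
degrees <- function(net) {
  A <- (net$counts > 0) * 1
  W <- net$weights
  tibble(
    fly_id = seq_len(net$n),
    in_degree = colSums(A),
    out_degree = rowSums(A),
    degree = colSums(A) + rowSums(A),
    weighted_in_degree = colSums(W),
    weighted_out_degree = rowSums(W),
    weighted_degree = colSums(W) + rowSums(W)
  )
}

#' Weighted directed clustering coefficient (Fagiolo)
#'
#' Per-node triangle intensity for a weighted directed graph: with
#' \eqn{\hat W = W^{1/3}} (element-wise), \deqn{C_i = \frac{[(\hat W + \hat
#' W^T)^3]_{ii}}{2[d^{tot}_i (d^{tot}_i - 1) - 2 d^{\leftrightarrow}_i]}}
#' where \eqn{d^{tot}} is the total binary degree and
#' \eqn{d^{\leftrightarrow}} the number of reciprocated neighbours. Nodes
#' with a zero denominator get 0.
#'
#' @param net a `social_network`.
#' @return numeric vector, one value per node.
#' @export
clustering_coefficient <- function(net) {
  A <- (net$counts > 0) * 1
  What <- net$weights^(1 / 3)
  S <- What + t(What)
  num <- diag(S %*% S %*% S)
  d_tot <- rowSums(A) + colSums(A)
  d_bi <- diag(A %*% A)
  den <- 2 * (d_tot * (d_tot - 1) - 2 * d_bi)
  ifelse(den > 0, num / den, 0)
}

#' Betweenness centrality (weighted directed)
#'
#' Fraction of all-pairs shortest paths passing through each node (endpoints
#' excluded), with equal splitting among equally short paths. Edge lengths
#' are the inverse of the normalized weights, the usual convention for
#' connectivity-style weighted networks.
#'
#' @param net a `social_network`.
#' @return numeric vector, one value per node.
#' @export
betweenness_centrality <- function(net) {
  n <- net$n
  if (n <= 2 || all(net$weights == 0)) return(numeric(n))
  g <- weights_to_igraph(net$weights)
  b <- igraph::betweenness(g, directed = TRUE,
                           weights = igraph::E(g)$length)
  b / ((n - 1) * (n - 2))
}

weights_to_igraph <- function(W) {
  g <- igraph::graph_from_adjacency_matrix(W, mode = "directed", weighted = TRUE)
  igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

#' Global network parameters
#'
#' The five global parameters: assortativity (Pearson correlation of total
#' binary degrees across directed edges; `NA` when degenerate), global
#' efficiency (mean inverse shortest-path length over ordered node pairs,
#' lengths = 1/weight), transitivity (closed over total directed triplets on
#' the binarized graph), density (realized directed edges over N(N-1)) and
#' weighted total interaction (sum of normalized weights; the raw count sum
#' is also returned).
#'
#' @param net a `social_network`.
#' @return one-row tibble with columns assortativity, global_efficiency,
#'   transitivity, density, weighted_total_interaction, total_interactions.
#' @export
global_metrics <- function(net) {
  n <- net$n
  A <- (net$counts > 0) * 1
  W <- net$weights
  # assortativity over directed edges
  d_tot <- rowSums(A) + colSums(A)
  eidx <- which(A == 1, arr.ind = TRUE)
  assort <- if (nrow(eidx) < 2) NA_real_ else {
    ds <- d_tot[eidx[, 1]]; dt <- d_tot[eidx[, 2]]
    if (stats::sd(ds) == 0 || stats::sd(dt) == 0) NA_real_ else cor(ds, dt)
  }
  # global efficiency from shortest path lengths
  eff <- if (n < 2 || all(W == 0)) 0 else {
    g <- weights_to_igraph(W)
    D <- igraph::distances(g, mode = "out", weights = igraph::E(g)$length)
    diag(D) <- Inf
    mean(1 / D[row(D) != col(D)])
  }
  # directed triplet transitivity
  P2 <- A %*% A
  open_closed <- sum(P2) - sum(diag(P2))
  trans <- if (open_closed > 0) sum(P2 * A) / open_closed else NA_real_
  tibble(
    assortativity = assort,
    global_efficiency = eff,
    transitivity = trans,
    density = sum(A) / (n * (n - 1)),
    weighted_total_interaction = sum(W),
    total_interactions = sum(net$counts)
  )
}

#' All nine network parameters
#'
#' Convenience wrapper returning the per-node parameters (degrees,
#' strengths, clustering coefficient, betweenness centrality) and the global
#' parameters of a network.
#'
#' @param net a `social_network`.
#' @return list with `nodes` (tibble, one row per fly) and `global`
#'   (one-row tibble).
#' @export
network_params <- function(net) {
  nodes <- degrees(net)
  nodes$clustering_coefficient <- clustering_coefficient(net)
  nodes$betweenness_centrality <- betweenness_centrality(net)
  list(nodes = nodes, global = global_metrics(net))
}

#' Relabel flies by outgoing activity
#'
#' Renumbers nodes in ascending order of weighted out-degree (ties broken by
#' weighted in-degree, then original index), so that flies with similar
#' network ranking occupy similar positions across repeats - the standard
#' presentation before graph matching and averaging.
#'
#' @param net a `social_network`.
#' @return list with `net` (relabelled `social_network`) and `perm` (integer
#'   vector: original index of the fly now labelled k).
#' @export
relabel_by_outgoing <- function(net) {
  W <- net$weights
  out_s <- rowSums(W); in_s <- colSums(W)
  perm <- order(out_s, in_s, seq_len(net$n))
  list(net = social_network(net$counts[perm, perm, drop = FALSE]), perm = perm)
}

#' @export
tidy.social_network <- function(x, ...) {
  idx <- which(x$counts > 0, arr.ind = TRUE)
  tibble(interactor_id = as.integer(idx[, 1]),
         interacted_id = as.integer(idx[, 2]),
         count = x$counts[idx],
         weight = x$weights[idx]) |>
    dplyr::arrange(.data$interactor_id, .data$interacted_id)
}

#' @export
glance.social_network <- function(x, ...) global_metrics(x)

#' @export
autoplot.social_network <- function(object, ...) {
  df <- tidyr::expand_grid(interactor_id = seq_len(object$n),
                           interacted_id = seq_len(object$n))
  df$count <- object$counts[cbind(df$interactor_id, df$interacted_id)]
  ggplot2::ggplot(df, ggplot2::aes(.data$interacted_id, .data$interactor_id,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse(breaks = seq_len(object$n)) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$n), position = "top") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "interacted fly", y = "interactor fly", fill = "touches",
                  title = "Touch interaction adjacency matrix") +
    ggplot2::theme_minimal()
}
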