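# weight matrix from a symptom_network or a plain matrix
weight_matrix <- function(network) {
  W <- if (inherits(network, "symptom_network")) network$W else network
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  W
}

#' Node strength
#'
#' Sum of the absolute weights of a node's incident edges (signed sum
#' available with `signed = TRUE`).
#'
#' @param network A `symptom_network` or weight matrix.
#' @param signed Sum signed weights instead of absolute values?
#' @return Numeric vector of length p.
#' @export
strength <- function(network, signed = FALSE) {
  W <- weight_matrix(network)
  if (signed) rowSums(W) else rowSums(abs(W))
}

# igraph view of the weighted network with Dijkstra edge lengths 1/|w|
network_graph <- function(W) {
  A <- abs(W)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$length <- 1 / igraph::E(g)$weight
  }
  g
}

#' All-pairs shortest-path distances
#'
#' Edge lengths are `1 / |w|`, so stronger edges are shorter; distances are
#' Dijkstra shortest paths and unreachable pairs are `Inf`.
#'
#' @inheritParams strength
#' @return A p x p distance matrix with zero diagonal.
#' @export
shortest_path_distances <- function(network) {
  W <- weight_matrix(network)
  g <- network_graph(W)
  if (igraph::ecount(g) == 0) {
    D <- matrix(Inf, nrow(W), ncol(W))
    diag(D) <- 0
    return(D)
  }
  D <- igraph::distances(g, weights = igraph::E(g)$length,
                         algorithm = "dijkstra")
  dimnames(D) <- NULL
  D
}

#' Closeness centrality
#'
#' Inverse of the average shortest-path distance to the node's *reachable*
#' peers; an isolated node has closeness 0. Restricting the average to
#' reachable nodes keeps closeness finite in near-empty networks.
#'
#' @inheritParams strength
#' @return Numeric vector of length p.
#' @export
closeness_centrality <- function(network) {
  D <- shortest_path_distances(network)
  p <- nrow(D)
  vapply(seq_len(p), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else 1 / mean(d)
  }, numeric(1))
}

#' Betweenness centrality
#'
#' Brandes betweenness on the `1/|w|` distance graph, with fractional credit
#' shared over equal-length shortest paths. Returned as raw (unordered-pair)
#' counts; the percentage form divides by the `(p-1)(p-2)/2` pairs a node
#' could bridge.
#'
#' @inheritParams strength
#' @param percent Return the percentage form instead of raw counts?
#' @return Numeric vector of length p.
#' @export
betweenness_centrality <- function(network, percent = FALSE) {
  W <- weight_matrix(network)
  g <- network_graph(W)
  b <- if (igraph::ecount(g) == 0) {
    rep(0, nrow(W))
  } else {
    as.numeric(igraph::betweenness(g, weights = igraph::E(g)$length,
                                   directed = FALSE))
  }
  if (percent) {
    p <- nrow(W)
    pairs <- (p - 1) * (p - 2) / 2
    if (pairs > 0) b <- 100 * b / pairs
  }
  b
}

#' Standardize columns to z-scores
#'
#' `(x - mean) / sd` with the sample SD (denominator n-1). A constant column
#' yields all-zero z-scores with a warning.
#'
#' @param x Numeric vector.
#' @return z-scored vector.
#' @export
z_standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    warning("z_standardize: constant column, returning zeros")
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Centrality table of a network
#'
#' Strength, closeness and betweenness per node, with standardized z-scores
#' per measure (computed across the p nodes).
#'
#' @inheritParams strength
#' @param items Optional item labels (defaults to `item_1 ... item_p`).
#' @return A tibble of class `centrality_tbl` with columns `item`,
#'   `strength`, `closeness`, `betweenness` and the matching `*_z` columns.
#' @export
#' @examples
#' W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- 0.5
#' centrality_table(W)
centrality_table <- function(network, items = NULL, signed = FALSE) {
  W <- weight_matrix(network)
  p <- nrow(W)
  if (is.null(items)) items <- paste0("item_", seq_len(p))
  stopifnot(length(items) == p, p >= 2)
  out <- tibble::tibble(
    item = items,
    strength = strength(W, signed = signed),
    closeness = closeness_centrality(W),
    betweenness = betweenness_centrality(W)
  )
  for (m in c("strength", "closeness", "betweenness")) {
    out[[paste0(m, "_z")]] <- suppressWarnings(z_standardize(out[[m]]))
  }
  class(out) <- c("centrality_tbl", class(out))
  out
}

#' Long-format centrality table for several groups
#'
#' @param networks Named list of `symptom_network`s.
#' @param standardize_within `"group"` (default; z-scores within each group's
#'   network) or `"all"` (z-scores pooled across groups per measure).
#' @return Tibble `group`, `item`, `measure`, `value`, `z`.
#' @export
centrality_by_group <- function(networks,
                                standardize_within = c("group", "all")) {
  standardize_within <- match.arg(standardize_within)
  tabs <- purrr::imap(networks, function(net, g) {
    ct <- centrality_table(net)
    long <- tidyr::pivot_longer(
      ct[, c("item", "strength", "closeness", "betweenness")],
      cols = c("strength", "closeness", "betweenness"),
      names_to = "measure", values_to = "value"
    )
    zs <- tidyr::pivot_longer(
      ct[, c("item", "strength_z", "closeness_z", "betweenness_z")],
      cols = dplyr::ends_with("_z"), names_to = "measure", values_to = "z"
    )
    long$z <- zs$z
    long$group <- g
    long
  })
  out <- dplyr::bind_rows(tabs)[, c("group", "item", "measure", "value", "z")]
  if (standardize_within == "all") {
    out <- out |>
      dplyr::group_by(.data$measure) |>
      dplyr::mutate(z = suppressWarnings(z_standardize(.data$value))) |>
      dplyr::ungroup()
  }
  out
}
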