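#' Bridge centrality of symptom-network nodes
#'
#' Four indices of how strongly each node connects the two symptom
#' communities (here the MD and CF sub-networks):
#' * **bridge strength** — sum of absolute coupling weights to the other
#'   community;
#' * **bridge expected influence** — the signed sum of those weights;
#' * **bridge closeness** — reciprocal of the mean weighted geodesic
#'   distance to the other community's nodes, with edge length `1/|weight|`
#'   (strong associations are short); unreachable targets are skipped and a
#'   node that reaches none scores 0;
#' * **bridge betweenness** — how often the node lies strictly inside
#'   weighted geodesics between cross-community pairs, tied geodesics
#'   splitting credit equally.
#'
#' @param model An [ising_model()] (or any object with `labels`, `omega`).
#' @param partition Community labels per node (exactly two communities);
#'   defaults to the model's own partition.
#' @return A tibble of class `bridge_indices`: `node`, `community`,
#'   `bridge_strength`, `bridge_expected_influence`, `bridge_closeness`,
#'   `bridge_betweenness`.
#' @export
bridge_indices <- function(model, partition = NULL) {
  partition <- partition %||% model$partition
  if (is.null(partition)) abort("a community partition is required")
  labels <- model$labels
  if (is.null(names(partition))) names(partition) <- labels
  if (!setequal(names(partition), labels)) abort("partition must cover every node")
  partition <- partition[labels]
  if (length(unique(partition)) != 2) abort("exactly two communities are required")
  omega <- model$omega
  n <- length(labels)
  other <- outer(partition, partition, "!=")

  strength <- vapply(seq_len(n), function(i) sum(abs(omega[i, other[i, ]])), 0.0)
  ei <- vapply(seq_len(n), function(i) sum(omega[i, other[i, ]]), 0.0)

  g <- igraph_from_omega(omega, labels)
  D <- igraph::distances(g, weights = igraph::E(g)$length)
  closeness <- vapply(seq_len(n), function(i) {
    d <- D[i, other[i, ]]
    d <- d[is.finite(d)]
    if (length(d) == 0 || mean(d) == 0) 0 else 1 / mean(d)
  }, 0.0)

  betweenness <- bridge_betweenness_all(g, partition)

  structure(
    tibble(
      node = labels, community = unname(partition),
      bridge_strength = strength,
      bridge_expected_influence = ei,
      bridge_closeness = closeness,
      bridge_betweenness = betweenness
    ),
    class = c("bridge_indices", class(tibble()))
  )
}

igraph_from_omega <- function(omega, labels) {
  idx <- which(upper.tri(omega) & omega != 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labels)
  if (nrow(idx) > 0) {
    g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2]))
    g <- igraph::set_edge_attr(g, "length", value = 1 / abs(omega[idx]))
  }
  g
}

# Credit each node for lying strictly inside geodesics between
# cross-community pairs; equal split over tied geodesics.
bridge_betweenness_all <- function(g, partition) {
  n <- igraph::vcount(g)
  score <- numeric(n)
  comms <- unique(partition)
  a_idx <- which(partition == comms[1])
  b_idx <- which(partition == comms[2])
  for (i in a_idx) {
    paths <- suppressWarnings(igraph::all_shortest_paths(
      g, from = i, to = b_idx, weights = igraph::E(g)$length
    )$res)
    if (length(paths) == 0) next
    ends <- vapply(paths, function(p) as.integer(p[length(p)]), 0L)
    mult <- table(ends)
    for (p in paths) {
      v <- as.integer(p)
      if (length(v) > 2) {
        inner <- v[-c(1, length(v))]
        score[inner] <- score[inner] + 1 / mult[[as.character(v[length(v)])]]
      }
    }
  }
  score
}

#' Single-node bridge index accessors
#'
#' Convenience wrappers around [bridge_indices()] for one node.
#'
#' @inheritParams bridge_indices
#' @param node Node label.
#' @return A single number.
#' @export
bridge_strength <- function(model, partition = NULL, node) {
  bi <- bridge_indices(model, partition)
  bi$bridge_strength[match_node(bi, node)]
}

#' @rdname bridge_strength
#' @export
bridge_expected_influence <- function(model, partition = NULL, node) {
  bi <- bridge_indices(model, partition)
  bi$bridge_expected_influence[match_node(bi, node)]
}

#' @rdname bridge_strength
#' @export
bridge_closeness <- function(model, partition = NULL, node) {
  bi <- bridge_indices(model, partition)
  bi$bridge_closeness[match_node(bi, node)]
}

#' @rdname bridge_strength
#' @export
bridge_betweenness <- function(model, partition = NULL, node) {
  bi <- bridge_indices(model, partition)
  bi$bridge_betweenness[match_node(bi, node)]
}

match_node <- function(bi, node) {
  i <- match(node, bi$node)
  if (anyNA(i)) abort(paste0("unknown node: ", node))
  i
}

#' Rank nodes by a bridge-centrality index
#'
#' @param indices A [bridge_indices()] tibble.
#' @param by Index column to rank on (e.g. `"bridge_expected_influence"`).
#' @param community Optional filter to one community (e.g. rank only CF
#'   nodes).
#' @return The tibble sorted by the chosen index descending, ties broken by
#'   node label.
#' @export
rank_bridge_nodes <- function(indices, by = "bridge_strength", community = NULL) {
  valid <- c(
    "bridge_strength", "bridge_expected_influence",
    "bridge_closeness", "bridge_betweenness"
  )
  if (!by %in% valid) {
    abort(paste0("unknown index: ", by, "; use one of ", paste(valid, collapse = ", ")))
  }
  out <- indices
  if (!is.null(community)) out <- dplyr::filter(out, .data$community %in% !!community)
  dplyr::arrange(out, dplyr::desc(.data[[by]]), .data$node)
}
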