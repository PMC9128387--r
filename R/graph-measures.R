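#' All-pairs shortest path lengths of a fast-ripple network
#'
#' Converts edge weights to lengths by network kind -- for `distance` and
#' `rate_distance` networks the weight is already a length; for `mi`
#' networks (correlational weights) the length is the reciprocal weight,
#' with zero-weight pairs carrying no edge -- and returns the all-pairs
#' shortest-path matrix. Unreachable pairs are `Inf`.
#'
#' @param net An [fr_network()].
#' @return Symmetric numeric matrix of shortest-path lengths (zero
#'   diagonal), dimension `n_nodes x n_nodes`.
#' @export
net_shortest_paths <- function(net) {
  n <- n_nodes(net)
  if (n == 0L) return(matrix(numeric(0), 0, 0))
  L <- edge_length_matrix(net$adjacency, net$kind)
  g <- lengths_to_igraph(L)
  sp <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(sp) <- dimnames(net$adjacency)
  sp
}

# Weight-to-length conversion; Inf marks "no edge".
edge_length_matrix <- function(w, kind) {
  L <- if (kind == "mi") ifelse(w > 0, 1 / w, Inf) else ifelse(w > 0, w, Inf)
  diag(L) <- 0
  L
}

# Dense all-pairs shortest paths (Floyd-Warshall, vectorized over k); used
# for the small per-neighbourhood subproblems where per-call graph
# construction would dominate.
fw_shortest <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n)) {
    via <- outer(D[, k], D[k, ], `+`)
    smaller <- via < D
    if (any(smaller)) D[smaller] <- via[smaller]
  }
  D
}

lengths_to_igraph <- function(L) {
  Ladj <- L
  Ladj[!is.finite(Ladj)] <- 0
  igraph::graph_from_adjacency_matrix(Ladj, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# Node indices of the largest connected component (positive-weight edges);
# ties broken by the earliest node order.
largest_component <- function(net) {
  n <- n_nodes(net)
  if (n == 0L) return(integer(0))
  g <- lengths_to_igraph(edge_length_matrix(net$adjacency, net$kind))
  comp <- igraph::components(g)
  which(comp$membership == which.max(comp$csize))
}

#' Graph radius of a fast-ripple network
#'
#' The eccentricity of a node is its maximum shortest-path length to any
#' other node; the radius is the minimum eccentricity. By convention an
#' empty or single-node network has radius 0 (so a patient with no fast
#' ripples above threshold contributes the minimal network extent rather
#' than a missing value), and a disconnected network is measured on its
#' largest connected component.
#'
#' The default uses the shortest-path metric. `definition = "adjacency"`
#' computes eccentricities on direct edge weights instead; the two coincide
#' for Euclidean distance networks but not in general for rate-distance
#' networks.
#'
#' @param net An [fr_network()], or `NULL` (treated as empty, radius 0).
#' @param definition `"shortest_path"` (default) or `"adjacency"`.
#' @return Non-negative scalar radius.
#' @export
net_radius <- function(net, definition = c("shortest_path", "adjacency")) {
  definition <- match.arg(definition)
  if (is.null(net) || n_nodes(net) < 2L) return(0)
  comp <- largest_component(net)
  if (length(comp) < 2L) return(0)
  if (definition == "shortest_path") {
    sp <- net_shortest_paths(net)[comp, comp]
  } else {
    sp <- edge_length_matrix(net$adjacency, net$kind)[comp, comp]
    diag(sp) <- 0
  }
  ecc <- apply(sp, 1, max)
  min(ecc)
}

#' Characteristic path length
#'
#' The average shortest-path length over distinct node pairs. Infinite
#' (unreachable) pairs are excluded, which equals restricting to connected
#' components; a network with fewer than two nodes, or with no finite
#' pair, is undefined (`NA`).
#'
#' @param net An [fr_network()] or `NULL`.
#' @return Mean finite off-diagonal shortest-path length, or `NA_real_`.
#' @export
char_path_length <- function(net) {
  if (is.null(net) || n_nodes(net) < 2L) return(NA_real_)
  sp <- net_shortest_paths(net)
  v <- sp[upper.tri(sp)]
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Weighted local efficiency of a node
#'
#' Efficiency of the subgraph induced by a node's neighbours, in the
#' standard weighted (cube-root) formulation: with `N(i)` the neighbours of
#' node i, `w` the edge weights and `d_jh(N_i)` the shortest-path length
#' between j and h computed on the neighbour subgraph (lengths from the
#' network's weight-to-length conversion),
#' \deqn{E_loc(i) = \frac{1}{k_i (k_i - 1)} \sum_{j \ne h \in N(i)}
#'   \left( w_{ij} w_{ih} / d_{jh}(N_i) \right)^{1/3}}
#' summed over ordered neighbour pairs. Nodes with fewer than two
#' neighbours have local efficiency 0; unreachable neighbour pairs
#' contribute 0.
#'
#' @param net An [fr_network()].
#' @param node Node index or contact id; `NULL` returns all nodes.
#' @return Numeric vector of local efficiencies.
#' @export
local_efficiency <- function(net, node = NULL) {
  w <- net$adjacency
  n <- n_nodes(net)
  idx <- resolve_nodes(net, node)
  out <- numeric(length(idx))
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2L) { out[ii] <- 0; next }
    dsub <- fw_shortest(edge_length_matrix(w[nb, nb, drop = FALSE], net$kind))
    inv_d <- ifelse(is.finite(dsub) & dsub > 0, 1 / dsub, 0)
    wi <- w[i, nb]
    contrib <- (outer(wi, wi) * inv_d)^(1 / 3)
    diag(contrib) <- 0
    out[ii] <- sum(contrib) / (k * (k - 1))
  }
  names(out) <- net$nodes$contact_id[idx]
  out
}

#' Nodal strength
#'
#' Sum of the edge weights incident to a node.
#'
#' @param net An [fr_network()].
#' @param node Node index or contact id; `NULL` returns all nodes.
#' @return Named numeric vector of strengths.
#' @export
node_strength <- function(net, node = NULL) {
  idx <- resolve_nodes(net, node)
  out <- rowSums(net$adjacency)[idx]
  names(out) <- net$nodes$contact_id[idx]
  out
}

resolve_nodes <- function(net, node) {
  if (is.null(node)) return(seq_len(n_nodes(net)))
  if (is.character(node)) {
    idx <- match(node, net$nodes$contact_id)
    if (anyNA(idx)) stop_integrity("unknown node: ",
                                   paste(node[is.na(idx)], collapse = ", "))
    return(idx)
  }
  as.integer(node)
}

#' Per-patient global network measures
#'
#' Computes the feature vector used for outcome classification: the radius
#' of the SOZ distance network, the radii of the FR distance and
#' rate-distance networks (plus the rate-distance radius restricted to
#' non-SOZ contacts), and three global measures of the FR
#' mutual-information network -- the characteristic path length, the mean
#' local efficiency of the non-SOZ nodes, and the difference in summed
#' nodal strength between non-SOZ and SOZ nodes. When the MI network is not
#' constructible the three MI measures are `NA`; when it contains no
#' non-SOZ node, the non-SOZ mean local efficiency is 0 (no non-SOZ
#' participation) and the strength difference reduces to minus the summed
#' SOZ strength.
#'
#' @param record A [patient_record()].
#' @param event_filter An [fr_filter()]; default fast ripples > 350 Hz.
#' @param config An [mi_config()].
#' @param radius_definition Passed to [net_radius()].
#' @param normalize_strength_diff If `TRUE`, each strength sum is divided
#'   by its node count before differencing (non-default variant).
#' @return One-row data frame of class `global_measures`.
#' @export
global_measures <- function(record, event_filter = fr_filter(),
                            config = mi_config(),
                            radius_definition = "shortest_path",
                            normalize_strength_diff = FALSE) {
  soz_contacts <- record$contacts[record$contacts$is_soz, , drop = FALSE]
  fr_nodes <- select_nodes(record, event_filter)
  fr_nodes_nonsoz <- select_nodes(record, event_filter, nonsoz_only = TRUE)
  rates <- compute_rates(record, event_filter)

  soz_net <- distance_network(soz_contacts)
  dist_net <- distance_network(fr_nodes)
  rd_net <- rate_distance_network(fr_nodes, rates)
  rd_net_nonsoz <- rate_distance_network(fr_nodes_nonsoz, rates)
  mi_net <- mi_network(record, event_filter, config)

  if (is.null(mi_net)) {
    mi_cpl <- NA_real_; mi_eff <- NA_real_; mi_sdiff <- NA_real_
  } else {
    mi_cpl <- char_path_length(mi_net)
    s <- node_strength(mi_net)
    soz <- mi_net$nodes$is_soz
    eff <- local_efficiency(mi_net)
    mi_eff <- if (any(!soz)) mean(eff[!soz]) else 0
    if (normalize_strength_diff) {
      m_non <- if (any(!soz)) mean(s[!soz]) else 0
      m_soz <- if (any(soz)) mean(s[soz]) else 0
      mi_sdiff <- m_non - m_soz
    } else {
      mi_sdiff <- sum(s[!soz]) - sum(s[soz])
    }
  }

  out <- data.frame(
    patient_id = record$patient_id,
    outcome = record$outcome,
    soz_radius = net_radius(soz_net, radius_definition),
    fr_distance_radius = net_radius(dist_net, radius_definition),
    fr_rate_distance_radius = net_radius(rd_net, radius_definition),
    fr_rate_distance_radius_nonsoz = net_radius(rd_net_nonsoz, radius_definition),
    mi_charpath = mi_cpl,
    mi_mean_local_eff_nonsoz = mi_eff,
    mi_strength_diff = mi_sdiff,
    mi_constructible = !is.null(mi_net))
  class(out) <- c("global_measures", class(out))
  out
}
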