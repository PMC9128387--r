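#' Weighted fast-ripple network container
#'
#' A network is a symmetric non-negative weighted graph over an ordered set
#' of contacts. Three kinds are used: `distance` (edge = Euclidean distance
#' in mm between contacts), `rate_distance` (edge = distance times the mean
#' filtered-event rate of the two contacts, mm * events/min), and `mi`
#' (edge = mutual information between the two contacts' event onset trains,
#' bits). The adjacency is validated to be symmetric with a zero diagonal
#' and non-negative weights.
#'
#' @param nodes Data frame with at least `contact_id` and `is_soz`.
#' @param adjacency Symmetric numeric matrix, one row/column per node.
#' @param kind One of `"distance"`, `"rate_distance"`, `"mi"`.
#' @return An object of class `fr_network`.
#' @export
fr_network <- function(nodes, adjacency, kind) {
  kind <- match.arg(kind, c("distance", "rate_distance", "mi"))
  adjacency <- as.matrix(adjacency)
  n <- nrow(nodes)
  stopifnot(nrow(adjacency) == n, ncol(adjacency) == n)
  if (n) {
    if (max(abs(adjacency - t(adjacency))) > 1e-9)
      stop_integrity("adjacency must be symmetric")
    adjacency <- (adjacency + t(adjacency)) / 2
    if (any(diag(adjacency) != 0)) stop_integrity("adjacency diagonal must be zero")
    if (any(adjacency < 0)) stop_integrity("edge weights must be non-negative")
    dimnames(adjacency) <- list(nodes$contact_id, nodes$contact_id)
  }
  structure(list(nodes = as.data.frame(nodes), adjacency = adjacency,
                 kind = kind),
            class = "fr_network")
}

#' @export
print.fr_network <- function(x, ...) {
  cat(sprintf("<fr_network %s: %d nodes, %d positive edges>\n", x$kind,
              nrow(x$nodes), sum(x$adjacency[upper.tri(x$adjacency)] > 0)))
  invisible(x)
}

n_nodes <- function(net) nrow(net$nodes)

#' Select network nodes: contacts generating filtered events
#'
#' Nodes of the FR networks are the contacts that recorded at least one
#' event passing the filter (by default at least a single fast ripple with
#' peak frequency > 350 Hz), in contact-table order. Optionally restricted
#' to contacts outside the seizure onset zone.
#'
#' @param record A [patient_record()].
#' @param event_filter An [fr_filter()].
#' @param nonsoz_only If `TRUE`, keep only non-SOZ contacts.
#' @return Contact data frame subset (possibly empty).
#' @export
select_nodes <- function(record, event_filter = fr_filter(),
                         nonsoz_only = FALSE) {
  rates <- compute_rates(record, event_filter)
  keep <- rates$n_events >= 1L
  if (nonsoz_only) keep <- keep & !record$contacts$is_soz
  out <- record$contacts[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a Euclidean distance network
#'
#' Complete graph over the given contacts with edge weights equal to the
#' Euclidean distance (mm) between contact positions in normalized MNI
#' space.
#'
#' @param contacts Contact data frame (needs `contact_id`, `x`, `y`, `z`,
#'   `is_soz`).
#' @return An [fr_network()] of kind `distance`.
#' @export
distance_network <- function(contacts) {
  xyz <- as.matrix(contacts[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  if (!nrow(contacts)) d <- matrix(numeric(0), 0, 0)
  fr_network(contacts, d, "distance")
}

#' Build a rate-distance network
#'
#' Edge weight between contacts i and j is the Euclidean distance d_ij (mm)
#' multiplied by the average filtered-event rate of the two contacts,
#' `d_ij * (r_i + r_j) / 2` (mm * events/min).
#'
#' @param contacts Contact data frame.
#' @param rates Rate table from [compute_rates()]; every contact must have
#'   a rate entry.
#' @return An [fr_network()] of kind `rate_distance`.
#' @export
rate_distance_network <- function(contacts, rates) {
  idx <- match(contacts$contact_id, rates$contact_id)
  if (anyNA(idx))
    stop_integrity("missing rate for contact(s): ",
                   paste(contacts$contact_id[is.na(idx)], collapse = ", "))
  r <- rates$rate[idx]
  d <- distance_network(contacts)$adjacency
  w <- d * outer(r, r, function(a, b) (a + b) / 2)
  fr_network(contacts, w, "rate_distance")
}

#' Build a mutual-information network over FR-generating contacts
#'
#' Nodes are the contacts with at least `min_events_per_contact` filtered
#' events; edges are pairwise mutual information between event onset trains
#' estimated with [estimate_mi()]. Patients with fewer than two eligible
#' contacts have no constructible MI network and `NULL` is returned; the
#' downstream measures then carry missing-value markers.
#'
#' @param record A [patient_record()].
#' @param event_filter An [fr_filter()].
#' @param config An [mi_config()].
#' @return An [fr_network()] of kind `mi`, or `NULL` when not constructible.
#' @export
mi_network <- function(record, event_filter = fr_filter(),
                       config = mi_config()) {
  ev <- filter_events(record, event_filter)
  rates <- compute_rates(record, event_filter)
  eligible <- rates$contact_id[rates$n_events >= config$min_events_per_contact]
  if (length(eligible) < 2L) return(NULL)
  contacts <- record$contacts[record$contacts$contact_id %in% eligible, ,
                              drop = FALSE]
  rownames(contacts) <- NULL
  dur_s <- record$duration_min * 60
  trains <- split(ev$onset_s, factor(ev$contact_id, levels = contacts$contact_id))
  trains <- lapply(trains, sort)
  n <- nrow(contacts)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      mi <- estimate_mi(trains[[i]], trains[[j]], dur_s, config)
      w[i, j] <- w[j, i] <- if (is.na(mi)) 0 else mi
    }
  }
  fr_network(contacts, w, "mi")
}

#' Serialize a network to an edge-list CSV plus node table
#'
#' Writes `<stem>_edges.csv` (`node_i,node_j,weight,kind`, upper triangle)
#' and `<stem>_nodes.csv` (`contact_id,is_soz`). [read_network()] restores
#' the network exactly.
#'
#' @param net An [fr_network()].
#' @param stem Output path stem.
#' @return `write_network()` invisibly returns the two paths;
#'   `read_network()` returns the network.
#' @export
write_network <- function(net, stem) {
  n <- n_nodes(net)
  ut <- which(upper.tri(net$adjacency), arr.ind = TRUE)
  edges <- data.frame(node_i = net$nodes$contact_id[ut[, 1]],
                      node_j = net$nodes$contact_id[ut[, 2]],
                      weight = net$adjacency[ut],
                      kind = rep(net$kind, nrow(ut)))
  paths <- paste0(stem, c("_edges.csv", "_nodes.csv"))
  write.csv(edges, paths[1], row.names = FALSE, quote = FALSE)
  write.csv(data.frame(contact_id = net$nodes$contact_id,
                       is_soz = as.integer(net$nodes$is_soz)),
            paths[2], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' @rdname write_network
#' @export
read_network <- function(stem) {
  edges <- read.csv(paste0(stem, "_edges.csv"), stringsAsFactors = FALSE)
  nodes <- read.csv(paste0(stem, "_nodes.csv"), stringsAsFactors = FALSE)
  nodes$contact_id <- as.character(nodes$contact_id)
  nodes$is_soz <- nodes$is_soz == 1
  n <- nrow(nodes)
  w <- matrix(0, n, n)
  if (nrow(edges)) {
    i <- match(as.character(edges$node_i), nodes$contact_id)
    j <- match(as.character(edges$node_j), nodes$contact_id)
    w[cbind(i, j)] <- edges$weight
    w[cbind(j, i)] <- edges$weight
  }
  kind <- if (nrow(edges)) edges$kind[1] else "distance"
  fr_network(nodes, w, kind)
}
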