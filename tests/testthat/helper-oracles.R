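# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (igraph, vectorized Floyd-Warshall,
# tabulate-based entropy) so that implementation and check stay decoupled.

# Naive triple-loop Floyd-Warshall on a length matrix (Inf = no edge).
fw_oracle <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

length_matrix_oracle <- function(net) {
  w <- net$adjacency
  L <- matrix(Inf, nrow(w), ncol(w))
  pos <- w > 0
  L[pos] <- if (net$kind == "mi") 1 / w[pos] else w[pos]
  diag(L) <- 0
  L
}

radius_oracle <- function(net) {
  n <- nrow(net$adjacency)
  if (n < 2) return(0)
  D <- fw_oracle(length_matrix_oracle(net))
  # largest connected component by reachability
  reach <- is.finite(D)
  comp_sizes <- rowSums(reach)
  members <- which(reach[which.max(comp_sizes), ])
  if (length(members) < 2) return(0)
  ecc <- sapply(members, function(i) max(D[i, members]))
  min(ecc)
}

charpath_oracle <- function(net) {
  if (nrow(net$adjacency) < 2) return(NA_real_)
  D <- fw_oracle(length_matrix_oracle(net))
  v <- D[upper.tri(D)]
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  sum(v) / length(v)
}

# Direct evaluation of the cube-root weighted local-efficiency formula.
local_eff_oracle <- function(net, i) {
  w <- net$adjacency
  nb <- which(w[i, ] > 0)
  k <- length(nb)
  if (k < 2) return(0)
  Lsub <- length_matrix_oracle(
    frnet::fr_network(net$nodes[nb, , drop = FALSE],
                      w[nb, nb, drop = FALSE], net$kind))
  Dsub <- fw_oracle(Lsub)
  total <- 0
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a == b) next
    d <- Dsub[a, b]
    if (is.finite(d) && d > 0)
      total <- total + (w[i, nb[a]] * w[i, nb[b]] / d)^(1 / 3)
  }
  total / (k * (k - 1))
}

# Shannon entropy (bits) of a sample of counts, via table().
entropy_oracle <- function(counts) {
  p <- as.numeric(table(counts)) / length(counts)
  -sum(p * log2(p))
}

# AUC by exhaustive pair enumeration, ties counted one half.
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Random symmetric weighted graph for property tests.
random_net <- function(n, kind = "mi", p_edge = 0.6, max_w = 5) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- ifelse(runif(sum(ut)) < p_edge, runif(sum(ut), 0.01, max_w), 0)
  w[ut] <- vals
  w <- w + t(w)
  nodes <- data.frame(contact_id = sprintf("C%02d", seq_len(n)),
                      is_soz = seq_len(n) <= n %/% 2)
  frnet::fr_network(nodes, w, kind)
}

# Minimal hand-built patient for unit tests: 3 contacts, two SOZ.
make_test_record <- function(duration_min = 10) {
  contacts <- data.frame(
    contact_id = c("A", "B", "C"),
    x = c(0, 3, 0), y = c(0, 4, 10), z = c(0, 0, 0),
    region = c("frontal", "frontal", "mesial_temporal"),
    is_soz = c(TRUE, TRUE, FALSE))
  events <- data.frame(
    contact_id = c("A", "A", "B", "C", "C"),
    onset_s = c(10, 50, 100, 200, 300),
    subtype = c("fRonO", "fRonS", "fRonO", "RonO", "fRonO"),
    peak_freq_hz = c(400, 360, 340, 120, 500),
    peak_power = rep(1, 5),
    duration_ms = rep(20, 5))
  frnet::patient_record("P1", contacts, events, duration_min, "responder")
}

# Homogeneous Poisson train on [0, duration_s].
poisson_train <- function(rate_per_s, duration_s) {
  sort(runif(rpois(1, rate_per_s * duration_s), 0, duration_s))
}

# Coupled pair with matched marginal rates: y is a p-thinning of x (with
# timing jitter) plus independent background topping the rate back up, so
# varying p changes only the dependence, never the marginals.
coupled_pair <- function(rate, p, duration_s, jitter_s = 0.01) {
  x <- poisson_train(rate, duration_s)
  kept <- x[runif(length(x)) < p]
  kept <- pmin(pmax(kept + rnorm(length(kept), 0, jitter_s), 0), duration_s)
  y <- sort(c(kept, poisson_train(rate * (1 - p), duration_s)))
  list(x = x, y = y)
}
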