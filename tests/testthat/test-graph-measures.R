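chain_mi_net <- function() {
  # MI weights 0.5 on A-B and B-C only: lengths AB = BC = 2, AC = 4
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.5
  fr_network(data.frame(contact_id = c("A", "B", "C"), is_soz = FALSE),
             w, "mi")
}

test_that("shortest paths follow the kind-specific length conversion", {
  # collinear contacts: metric closure cannot shorten a Euclidean graph
  contacts <- data.frame(contact_id = c("A", "B", "C"), x = c(0, 10, 20),
                         y = 0, z = 0, region = "frontal", is_soz = FALSE)
  dn <- distance_network(contacts)
  sp <- net_shortest_paths(dn)
  expect_equal(sp["A", "C"], 20)
  expect_equal(sp, fw_oracle(length_matrix_oracle(dn)), ignore_attr = TRUE)

  # rate-distance: AB=10, BC=30, AC=60 -> A..C shortest is 40 via B
  w <- matrix(c(0, 10, 60, 10, 0, 30, 60, 30, 0), 3)
  rd <- fr_network(data.frame(contact_id = c("A", "B", "C"), is_soz = FALSE),
                   w, "rate_distance")
  spr <- net_shortest_paths(rd)
  expect_equal(spr["A", "C"], 40)

  spm <- net_shortest_paths(chain_mi_net())
  expect_equal(spm["A", "B"], 2)
  expect_equal(spm["B", "C"], 2)
  expect_equal(spm["A", "C"], 4)
})

test_that("radius follows the min-eccentricity definition and conventions", {
  contacts <- data.frame(contact_id = c("A", "B"), x = c(0, 10), y = 0,
                         z = 0, region = "frontal", is_soz = FALSE)
  expect_equal(net_radius(distance_network(contacts)), 10)
  # rate-distance example: path lengths AB=10, BC=30, AC=40
  w <- matrix(c(0, 10, 60, 10, 0, 30, 60, 30, 0), 3)
  rd <- fr_network(data.frame(contact_id = c("A", "B", "C"), is_soz = FALSE),
                   w, "rate_distance")
  expect_equal(net_radius(rd), 30)  # eccentricities 40, 30, 40
  # the exposed direct-adjacency alternative (here it coincides)
  expect_equal(net_radius(rd, definition = "adjacency"), 30)
  # empty / singleton / NULL conventions: a patient with no fast ripples
  # above threshold has radius 0
  expect_equal(net_radius(NULL), 0)
  expect_equal(net_radius(distance_network(contacts[0, ])), 0)
  expect_equal(net_radius(distance_network(contacts[1, ])), 0)
})

test_that("characteristic path length averages finite shortest paths", {
  expect_equal(char_path_length(chain_mi_net()), 8 / 3)
  # complete unit-MI triangle: all lengths 1
  w <- matrix(1, 3, 3); diag(w) <- 0
  tri <- fr_network(data.frame(contact_id = c("A", "B", "C"),
                               is_soz = FALSE), w, "mi")
  expect_equal(char_path_length(tri), 1.0)
  expect_true(is.na(char_path_length(NULL)))
  one <- fr_network(data.frame(contact_id = "A", is_soz = FALSE),
                    matrix(0, 1, 1), "mi")
  expect_true(is.na(char_path_length(one)))
})

test_that("local efficiency matches the direct formula", {
  w <- matrix(1, 3, 3); diag(w) <- 0
  tri <- fr_network(data.frame(contact_id = c("A", "B", "C"),
                               is_soz = FALSE), w, "mi")
  expect_equal(unname(local_efficiency(tri)), rep(1, 3))
  # isolated node and degree-1 node have efficiency 0
  expect_equal(unname(local_efficiency(chain_mi_net(), "A")), 0)
  iso <- fr_network(data.frame(contact_id = c("A", "B"), is_soz = FALSE),
                    matrix(0, 2, 2), "mi")
  expect_equal(unname(local_efficiency(iso)), c(0, 0))
})

test_that("nodal strength sums incident weights (handshake identity)", {
  net <- chain_mi_net()
  expect_equal(node_strength(net, "B"), c(B = 1.0))
  expect_equal(node_strength(net, "A"), c(A = 0.5))
  set.seed(201)
  for (i in 1:20) {
    rnet <- random_net(sample(3:10, 1))
    expect_equal(sum(node_strength(rnet)),
                 2 * sum(rnet$adjacency[upper.tri(rnet$adjacency)]),
                 tolerance = 1e-12)
  }
})

test_that("path measures agree with brute-force oracles on random graphs", {
  set.seed(202)
  for (i in 1:60) {
    net <- random_net(sample(2:10, 1), sample(c("mi", "rate_distance"), 1),
                      p_edge = runif(1, 0.2, 1))
    expect_equal(net_radius(net), radius_oracle(net), tolerance = 1e-9)
    expect_equal(char_path_length(net), charpath_oracle(net),
                 tolerance = 1e-9)
    sp <- net_shortest_paths(net)
    expect_equal(sp, fw_oracle(length_matrix_oracle(net)),
                 ignore_attr = TRUE, tolerance = 1e-9)
    j <- sample(nrow(net$adjacency), 1)
    expect_equal(unname(local_efficiency(net, j)), local_eff_oracle(net, j),
                 tolerance = 1e-9)
    # radius <= diameter on the largest component
    fin <- sp[is.finite(sp)]
    if (length(fin) > 1)
      expect_lte(net_radius(net), max(fin))
  }
})

test_that("distance networks satisfy direct-edge shortest paths", {
  set.seed(203)
  for (i in 1:10) {
    contacts <- data.frame(contact_id = sprintf("C%d", 1:6),
                           x = runif(6, -50, 50), y = runif(6, -50, 50),
                           z = runif(6, -50, 50), region = "frontal",
                           is_soz = FALSE)
    dn <- distance_network(contacts)
    expect_equal(net_shortest_paths(dn), dn$adjacency,
                 ignore_attr = TRUE, tolerance = 1e-9)
  }
})

test_that("global measures assemble the classifier feature vector", {
  rec <- make_test_record()
  gm <- global_measures(rec, fr_filter(min_freq_hz = NULL),
                        mi_config(min_events_per_contact = 1))
  expect_true(gm$mi_constructible)
  expect_equal(gm$soz_radius, 5)          # two SOZ contacts 5 mm apart
  expect_gt(gm$fr_distance_radius, 0)
  # MI network of this record has SOZ nodes A, B and non-SOZ node C
  net <- mi_network(rec, fr_filter(min_freq_hz = NULL),
                    mi_config(min_events_per_contact = 1))
  s <- node_strength(net)
  expect_equal(gm$mi_strength_diff,
               sum(s[!net$nodes$is_soz]) - sum(s[net$nodes$is_soz]))
  # patient with no fast ripples above threshold: radii 0, MI missing
  quiet <- patient_record("Q", rec$contacts,
                          rec$events[rec$events$subtype == "RonO", ],
                          rec$duration_min)
  gq <- global_measures(quiet)
  expect_equal(gq$fr_distance_radius, 0)
  expect_equal(gq$fr_rate_distance_radius, 0)
  expect_false(gq$mi_constructible)
  expect_true(is.na(gq$mi_charpath))
  expect_true(is.na(gq$mi_strength_diff))
})

test_that("strength-difference symmetry and degenerate compositions", {
  # equal strengths, half the nodes SOZ: difference is 0
  w <- matrix(1, 4, 4); diag(w) <- 0
  nodes <- data.frame(contact_id = c("A", "B", "C", "D"),
                      is_soz = c(TRUE, TRUE, FALSE, FALSE))
  net <- fr_network(nodes, w, "mi")
  s <- node_strength(net)
  expect_equal(sum(s[!nodes$is_soz]) - sum(s[nodes$is_soz]), 0)
  # all nodes non-SOZ: difference equals total strength
  nodes2 <- transform(nodes, is_soz = FALSE)
  net2 <- fr_network(nodes2, w, "mi")
  s2 <- node_strength(net2)
  expect_equal(sum(s2[!nodes2$is_soz]), sum(s2))
})
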