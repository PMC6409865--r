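tg <- toy_graphs()

test_that("BFS distances match hand-derived values on fixtures", {
  expect_equal(bfs_distances(tg$p4, "a"),
               c(a = 0L, b = 1L, c = 2L, d = 3L))
  for (v in interactome_nodes(tg$k4)) {
    d <- bfs_distances(tg$k4, v)
    expect_equal(unname(d[v]), 0L)
    expect_true(all(d[names(d) != v] == 1L))
  }
  expect_error(bfs_distances(tg$p4, "zz"), "unknown")
  # unreachable nodes are absent from the result
  two <- read_edge_list(c("A B", "C D"))
  expect_named(bfs_distances(two, "A"), c("A", "B"))
})

test_that("BFS agrees with a Floyd-Warshall oracle on random graphs", {
  for (s in 1:10) {
    net <- random_interactome(5 + (s * 7) %% 26, p = 0.2, seed = s)
    d_fw <- oracle_floyd_warshall(net)
    for (v in interactome_nodes(net)) {
      d <- bfs_distances(net, v)
      reach <- names(which(is.finite(d_fw[v, ])))
      expect_identical(sort(names(d)), sort(reach))
      expect_equal(unname(d[reach]), unname(d_fw[v, reach]))
    }
  }
})

test_that("per-node average shortest path length matches closed forms", {
  expect_equal(node_aspl(tg$p4, "a"), 2)
  expect_equal(node_aspl(tg$p4, "b"), 4 / 3)
  expect_equal(node_aspl(tg$star, "hub"), 1)
})

test_that("network-level average path length supports both denominators", {
  expect_equal(network_apl(tg$p4, "conventional"), 5 / 3)
  # self-pairs contribute zero distance but enter the denominator
  expect_equal(network_apl(tg$p4, "self-inclusive"), 1)
  expect_equal(network_apl(tg$k4, "conventional"), 1)
  expect_error(network_apl(read_edge_list(c("A B", "C D"))),
               "disconnected")
})

test_that("mean per-node aspl equals the conventional network average", {
  for (s in 1:5) {
    net <- largest_connected_component(
      random_interactome(20, p = 0.2, seed = s))
    per_node <- vapply(interactome_nodes(net),
                       function(v) node_aspl(net, v), numeric(1))
    expect_equal(mean(per_node), network_apl(net, "conventional"))
  }
})

test_that("clustering coefficient matches closed forms and stays in [0,1]", {
  for (v in interactome_nodes(tg$k4)) {
    expect_equal(clustering_coefficient(tg$k4, v), 1)
  }
  expect_equal(clustering_coefficient(tg$star, "hub"), 0)
  expect_equal(clustering_coefficient(tg$star, "leaf1"), 0)  # degree < 2
  expect_equal(clustering_coefficient(tg$triangle_pendant, "a"), 1 / 3)
  for (s in 1:5) {
    net <- random_interactome(20, p = 0.3, seed = 100 + s)
    cc <- vapply(interactome_nodes(net),
                 function(v) clustering_coefficient(net, v), numeric(1))
    expect_true(all(cc >= 0 & cc <= 1))
  }
})

test_that("betweenness matches hand enumeration on fixtures", {
  bc_p4 <- betweenness_centrality(tg$p4)
  expect_equal(unname(bc_p4[c("a", "b", "c", "d")]),
               c(0, 2 / 3, 2 / 3, 0))
  bc_star <- betweenness_centrality(tg$star)
  expect_equal(unname(bc_star["hub"]), 1)
  expect_true(all(bc_star[paste0("leaf", 1:4)] == 0))
  expect_true(all(betweenness_centrality(tg$k4) == 0))
  # barbell: the bridge endpoints carry the two largest values
  bc_bar <- betweenness_centrality(tg$barbell)
  expect_setequal(names(sort(bc_bar, decreasing = TRUE))[1:2],
                  c("c", "d"))
  # unnormalized values are (N-1)(N-2)/2 times larger
  raw <- betweenness_centrality(tg$p4, normalized = FALSE)
  expect_equal(unname(raw["b"]), 2)
})

test_that("Brandes accumulation equals the brute-force oracle", {
  for (s in 1:20) {
    n <- 5 + (s * 11) %% 26
    net <- random_interactome(n, p = 0.2, seed = 200 + s)
    expect_equal(betweenness_centrality(net), oracle_betweenness(net),
                 tolerance = 1e-9)
    expect_equal(betweenness_centrality(net, normalized = FALSE),
                 oracle_betweenness(net, normalized = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("Brandes agrees with igraph on a moderate random graph", {
  net <- random_interactome(40, p = 0.15, seed = 7)
  g <- igraph::graph_from_data_frame(interactome_edges(net),
                                     directed = FALSE,
                                     vertices = interactome_nodes(net))
  ours <- betweenness_centrality(net, normalized = FALSE)
  theirs <- igraph::betweenness(g, directed = FALSE)
  expect_equal(ours[interactome_nodes(net)],
               theirs[interactome_nodes(net)], tolerance = 1e-9)
})

test_that("on trees, unnormalized betweenness counts pairs through a node", {
  for (s in 1:5) {
    n <- 10 + s * 8
    tr <- random_tree(n, seed = s)
    bc <- betweenness_centrality(tr, normalized = FALSE)
    d <- oracle_floyd_warshall(tr)
    nodes <- interactome_nodes(tr)
    for (v in nodes[c(1, n %/% 2, n)]) {
      cnt <- 0
      others <- setdiff(nodes, v)
      for (i in seq_along(others)) for (j in seq_len(i - 1)) {
        a <- others[i]; b <- others[j]
        if (d[a, v] + d[v, b] == d[a, b]) cnt <- cnt + 1
      }
      expect_equal(unname(bc[v]), cnt)
    }
  }
})

test_that("normalized betweenness and cc are bounded on random graphs", {
  for (s in 1:5) {
    net <- random_interactome(25, p = 0.25, seed = 300 + s)
    bc <- betweenness_centrality(net)
    expect_true(all(bc >= 0 & bc <= 1))
  }
})

test_that("adding an edge never increases any shortest-path distance", {
  for (s in 1:5) {
    net <- largest_connected_component(
      random_interactome(15, p = 0.25, seed = 400 + s))
    d0 <- oracle_floyd_warshall(net)
    nodes <- interactome_nodes(net)
    e <- interactome_edges(net)
    have <- paste(e$from, e$to)
    cand <- utils::combn(nodes, 2)
    free <- which(!(paste(cand[1, ], cand[2, ]) %in% have))
    if (length(free) == 0) next
    pick <- free[[1 + (s %% length(free))]]
    aug <- interactome(c(e$from, cand[1, pick]), c(e$to, cand[2, pick]))
    d1 <- oracle_floyd_warshall(aug)[nodes, nodes]
    expect_true(all(d1 <= d0[nodes, nodes]))
  }
})

test_that("compute_all_metrics assembles the four parameters coherently", {
  all_k4 <- compute_all_metrics(tg$k4)
  expect_equal(all_k4$degree, rep(3L, 4))
  expect_equal(all_k4$aspl, rep(1, 4))
  expect_equal(all_k4$cc, rep(1, 4))
  expect_equal(all_k4$bc, rep(0, 4))

  mb <- compute_all_metrics(tg$p4, "b")
  expect_equal(mb$degree, 2L)
  expect_equal(mb$aspl, 4 / 3)
  expect_equal(mb$cc, 0)
  expect_equal(mb$bc, 2 / 3)

  expect_warning(sub <- compute_all_metrics(tg$p4, c("a", "nope")),
                 "skipped")
  expect_identical(sub$gene, "a")
  expect_error(suppressWarnings(compute_all_metrics(tg$p4, "nope")),
               "no target")

  # the packaged reference fixture is loaded, not recomputed
  t2 <- table2_fixture()
  tp53 <- t2[t2$gene == "TP53", ]
  expect_equal(tp53$degree, 178)
  expect_equal(tp53$aspl, 2.57)
  expect_equal(tp53$cc, 0.39)
  expect_equal(tp53$bc, 0.117)
})
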