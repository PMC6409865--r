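test_that("random set sampling is seeded, exclusive and size-checked", {
  net <- random_interactome(120, p = 0.05, seed = 3)
  excl <- gene_set("excl", interactome_nodes(net)[1:20])
  sets <- sample_random_sets(net, size = 10, replicates = 10,
                             exclude = excl, seed = 11)
  expect_length(sets, 10)
  for (s in sets) {
    expect_length(s$members, 10)
    expect_length(intersect(s$members, excl$members), 0)
  }
  again <- sample_random_sets(net, size = 10, replicates = 10,
                              exclude = excl, seed = 11)
  expect_identical(sets, again)
  other <- sample_random_sets(net, size = 10, replicates = 10,
                              exclude = excl, seed = 12)
  expect_false(identical(sets, other))
  expect_error(
    sample_random_sets(net, size = 10, replicates = 1,
                       exclude = interactome_nodes(net), seed = 1),
    "pool")
})

test_that("grouping splits near-equally with a seeded shuffle", {
  g46 <- partition_into_groups(gene_set("dm", sprintf("g%02d", 1:46)), 10,
                               seed = 2)
  sizes46 <- sort(lengths(lapply(g46, `[[`, "members")))
  expect_equal(sizes46, c(4, 4, 4, 4, 5, 5, 5, 5, 5, 5))

  g171 <- partition_into_groups(gene_set("ad", sprintf("g%03d", 1:171)), 10,
                                seed = 2)
  sizes171 <- lengths(lapply(g171, `[[`, "members"))
  expect_equal(sort(sizes171), c(rep(17, 9), 18))
  expect_setequal(unlist(lapply(g171, `[[`, "members")),
                  sprintf("g%03d", 1:171))

  one <- partition_into_groups(gene_set("s", letters[1:10]), 1, seed = 1)
  expect_length(one, 1)
  expect_setequal(one[[1]]$members, letters[1:10])

  expect_error(partition_into_groups(gene_set("s", letters[1:3]), 5),
               "more groups")
})

test_that("Mann-Whitney U matches the textbook cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6), method = "exact")
  expect_equal(r$u, 0)
  expect_equal(r$p, 0.1)  # 2 / C(6,3)

  same <- mann_whitney_u(c(2, 7, 7, 9), c(7, 9, 2, 7))
  expect_equal(same$p, 1)
  expect_equal(same$u, 8)  # mn/2

  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("exact Mann-Whitney p equals full enumeration on small samples", {
  for (s in 1:30) {
    mn <- withr::with_seed(s, sample(3:8, 2, replace = TRUE))
    vals <- withr::with_seed(1000 + s,
                             sample(seq_len(50), sum(mn)))  # tie-free
    xs <- vals[seq_len(mn[1])]
    ys <- vals[-seq_len(mn[1])]
    got <- mann_whitney_u(xs, ys, method = "exact")
    want <- oracle_mwu_exact(xs, ys)
    expect_equal(got$u, want$u)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("exact and normal approximations agree for moderate samples", {
  worst <- 0
  for (s in 1:100) {
    xs <- withr::with_seed(s, sample(seq_len(10000), 10))
    ys <- withr::with_seed(5000 + s, sample(seq_len(10000), 100))
    pe <- mann_whitney_u(xs, ys, method = "exact")$p
    pn <- mann_whitney_u(xs, ys, method = "normal")$p
    worst <- max(worst, abs(pe - pn))
  }
  expect_lt(worst, 0.02)
})

test_that("comparing a set against itself or a constant graph gives p = 1", {
  net <- largest_connected_component(random_interactome(60, 0.1, seed = 9))
  ds <- sample_random_sets(net, 8, 1, exclude = NULL, seed = 21)[[1]]
  cmp <- compare_gene_set(net, ds,
                          null_config(replicates = 1, seed = 21,
                                      exclude_disease = FALSE))
  for (p in c("degree", "aspl", "cc", "bc")) {
    expect_equal(cmp[[p]]$p_value, 1)
  }

  k8 <- interactome(utils::combn(letters[1:8], 2)[1, ],
                    utils::combn(letters[1:8], 2)[2, ])
  cmp_k <- compare_gene_set(k8, gene_set("d", letters[1:3]),
                            null_config(replicates = 2, seed = 4))
  for (p in c("degree", "aspl", "cc", "bc")) {
    expect_equal(cmp_k[[p]]$p_value, 1)
  }
})

test_that("comparison results are reproducible and well-formed", {
  sim <- plant_disease_genes(generator_spec(n_nodes = 60, seed = 5))
  cfg <- null_config(replicates = 5, seed = 17)
  a <- compare_gene_set(sim$network, sim$genes, cfg)
  b <- compare_gene_set(sim$network, sim$genes, cfg)
  expect_identical(a, b)
  sm <- summary(a)
  expect_identical(sm$parameter, c("degree", "aspl", "cc", "bc"))
  expect_true(all(sm$p_value >= 0 & sm$p_value <= 1))
  for (r in a) {
    expect_length(r$group_means, 5)
    expect_length(r$group_sds, 5)
    expect_length(r$per_replicate_p, 5)
  }
})

test_that("neighbor comparison contrasts seeds with their neighborhood", {
  tg <- toy_graphs()
  star <- tg$star
  # the hub is the disease set; its neighbors are the leaves
  cmp <- compare_neighbors(
    interactome(c(rep("hub", 4), "leaf1"), c(paste0("leaf", 1:4), "x")),
    gene_set("d", c("hub", "leaf1")))
  expect_equal(cmp$bc$direction, "+")

  # disease genes covering the whole graph leave no outside neighbors
  expect_error(compare_neighbors(tg$p4,
                                 gene_set("d", c("a", "b", "c", "d"))),
               "no neighbors")
})
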