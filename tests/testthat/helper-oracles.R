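# Independent brute-force oracles used to validate the package's
# traversal and statistics code.  These deliberately use different
# algorithms from the implementation: dynamic programming on the full
# distance matrix instead of single-source accumulation, and explicit
# enumeration instead of closed-form distributions.

# Erdos-Renyi style random interactome with at least one edge.
random_interactome <- function(n, p = 0.25, seed = 1) {
  stopifnot(n >= 2)
  labels <- sprintf("v%03d", seq_len(n))
  pairs <- utils::combn(n, 2)
  edges <- withr::with_seed(seed, which(stats::runif(ncol(pairs)) < p))
  if (length(edges) == 0) edges <- 1L  # guarantee a non-empty graph
  interactome(labels[pairs[1, edges]], labels[pairs[2, edges]])
}

# Random free tree on n nodes via a random Pruefer-like attachment.
random_tree <- function(n, seed = 1) {
  labels <- sprintf("t%03d", seq_len(n))
  parents <- withr::with_seed(seed,
    vapply(2:n, function(v) sample.int(v - 1L, 1L), integer(1)))
  interactome(labels[2:n], labels[parents])
}

# All-pairs shortest-path distances by Floyd-Warshall dynamic programming.
# Returns a symmetric matrix with Inf for unreachable pairs.
oracle_floyd_warshall <- function(net) {
  nodes <- interactome_nodes(net)
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  e <- interactome_edges(net)
  d[cbind(e$from, e$to)] <- 1
  d[cbind(e$to, e$from)] <- 1
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

# Shortest-path counts sigma[i, j] from the distance matrix: DP over nodes
# in increasing distance from each source.
oracle_path_counts <- function(net, d = oracle_floyd_warshall(net)) {
  nodes <- interactome_nodes(net)
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  e <- interactome_edges(net)
  adj[cbind(e$from, e$to)] <- TRUE
  adj[cbind(e$to, e$from)] <- TRUE
  sigma <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n)) {
    sigma[i, i] <- 1
    reach <- which(is.finite(d[i, ]))
    for (j in reach[order(d[i, reach])]) {
      if (j == i) next
      preds <- which(adj[, j] & d[i, ] == d[i, j] - 1)
      sigma[i, j] <- sum(sigma[i, preds])
    }
  }
  sigma
}

# Betweenness by direct evaluation of the defining sum: for every node v
# and unordered pair {i, j} (i != v != j), add
# sigma[i,v] * sigma[v,j] / sigma[i,j] when v lies on a shortest i-j path.
oracle_betweenness <- function(net, normalized = TRUE) {
  nodes <- interactome_nodes(net)
  n <- length(nodes)
  d <- oracle_floyd_warshall(net)
  sigma <- oracle_path_counts(net, d)
  bc <- stats::setNames(numeric(n), nodes)
  if (n >= 3) {
    for (vi in seq_len(n)) {
      for (i in seq_len(n - 1)) {
        if (i == vi) next
        for (j in seq.int(i + 1, n)) {
          if (j == vi || !is.finite(d[i, j])) next
          if (d[i, vi] + d[vi, j] == d[i, j]) {
            bc[vi] <- bc[vi] + sigma[i, vi] * sigma[vi, j] / sigma[i, j]
          }
        }
      }
    }
    if (normalized) bc <- bc / ((n - 1) * (n - 2) / 2)
  }
  bc
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# C(m+n, m) label assignments of the pooled sample (tie-free data only).
oracle_mwu_exact <- function(xs, ys) {
  pooled <- c(xs, ys)
  m <- length(xs); n <- length(ys)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  asg <- utils::combn(m + n, m)
  u_all <- colSums(matrix(r[asg], nrow = m)) - m * (m + 1) / 2
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  list(u = u_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Spearman's rho via explicitly constructed average ranks and the
# definitional Pearson formula (no calls to rank() or cor()).
oracle_spearman <- function(xs, ys) {
  avg_rank <- function(v) {
    n <- length(v)
    ord <- order(v)
    r <- numeric(n)
    pos <- 1
    while (pos <= n) {
      run <- pos
      while (run < n && v[ord[run + 1]] == v[ord[pos]]) run <- run + 1
      r[ord[pos:run]] <- mean(pos:run)
      pos <- run + 1
    }
    r
  }
  rx <- avg_rank(xs); ry <- avg_rank(ys)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Interactome invariant check used by property tests.
expect_valid_interactome <- function(net) {
  adj <- net$adjacency
  for (v in names(adj)) {
    expect_false(v %in% adj[[v]])                  # no self-loops
    expect_false(anyDuplicated(adj[[v]]) > 0)      # simple
    expect_true(all(adj[[v]] %in% names(adj)))     # closed node set
    for (w in adj[[v]]) expect_true(v %in% adj[[w]])  # symmetric
  }
  expect_equal(sum(lengths(adj)), 2 * interactome_edge_count(net))
}
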