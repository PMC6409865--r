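# Internal: adjacency as a list of integer index vectors, for the
# traversal-heavy routines.  Node order is the byte order of the symbols.
adjacency_index <- function(net) {
  nodes <- names(net$adjacency)
  lapply(net$adjacency, function(nb) match(nb, nodes))
}

# Single-source BFS over an integer adjacency list.  Returns integer
# distances with NA for unreachable nodes.
bfs_int <- function(adj_idx, s) {
  n <- length(adj_idx)
  dist <- rep(NA_integer_, n)
  dist[s] <- 0L
  queue <- integer(n)
  queue[1L] <- s
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    dv <- dist[v]
    for (w in adj_idx[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dv + 1L
        tail <- tail + 1L
        queue[tail] <- w
      }
    }
  }
  dist
}

#' Breadth-first shortest-path distances from one gene
#'
#' All edges count one hop (the interactome is unweighted), so breadth-first
#' search yields shortest-path distances.  The distance from a node to
#' itself is 0.
#'
#' @param net an `interactome`
#' @param source a gene symbol present in `net`
#' @return named integer vector of hop distances for every node reachable
#'   from `source` (including `source` itself at 0); unreachable nodes are
#'   absent
#' @export
bfs_distances <- function(net, source) {
  stopifnot(inherits(net, "interactome"))
  s <- node_index(net, source)
  if (length(s) != 1L || is.na(s)) stop(sprintf("unknown source '%s'", source))
  dist <- bfs_int(adjacency_index(net), s)
  ok <- !is.na(dist)
  stats::setNames(dist[ok], names(net$adjacency)[ok])
}

#' Per-gene average shortest path length
#'
#' The mean hop distance from gene `v` to every other reachable gene.  On a
#' connected network this is the per-gene quantity reported alongside
#' degree, clustering and betweenness; on a disconnected network
#' unreachable genes are simply excluded from the average.
#'
#' @param net an `interactome`
#' @param v a gene symbol in `net`
#' @return mean distance to reachable other nodes (>= 1 whenever `v` has a
#'   neighbor)
#' @export
node_aspl <- function(net, v) {
  d <- bfs_distances(net, v)
  d <- d[names(d) != v]
  if (length(d) == 0L) stop(sprintf("'%s' has no reachable partner", v))
  mean(d)
}

#' Network-level average path length
#'
#' Two normalizations of the all-pairs average distance are offered.
#' `conventional` is the mean over the N(N-1)/2 unordered pairs of distinct
#' nodes.  `self-inclusive` divides the same distance total by N(N+1)/2,
#' i.e. it counts each node's zero-distance self-pair in the denominator;
#' some texts print the formula this way, so both are exposed.
#'
#' @param net a connected `interactome` with at least 2 nodes (set
#'   `allow_disconnected = TRUE` to average over reachable pairs only)
#' @param normalization `"conventional"` or `"self-inclusive"`
#' @param allow_disconnected if `FALSE` (default), a disconnected network is
#'   an error
#' @return the average shortest path length
#' @export
network_apl <- function(net,
                        normalization = c("conventional", "self-inclusive"),
                        allow_disconnected = FALSE) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(net, "interactome"))
  adj_idx <- adjacency_index(net)
  n <- length(adj_idx)
  if (n < 2L) stop("network_apl needs at least 2 nodes")
  total <- 0
  pairs <- 0
  for (s in seq_len(n)) {
    d <- bfs_int(adj_idx, s)
    reach <- which(!is.na(d))
    if (length(reach) < n && !allow_disconnected) {
      stop("network is disconnected; use largest_connected_component() or allow_disconnected = TRUE")
    }
    total <- total + sum(d[reach])
    pairs <- pairs + length(reach) - 1L
  }
  total <- total / 2      # each unordered pair visited from both endpoints
  pairs <- pairs / 2
  switch(normalization,
    "conventional" = total / pairs,
    "self-inclusive" = 2 * total / (n * (n + 1))
  )
}

#' Local clustering coefficient
#'
#' For a gene with k neighbors and n edges among those neighbors,
#' CC = 2n / (k (k - 1)): the fraction of realized neighbor pairs.  The
#' neighbor-edge count is obtained from the symmetric adjacency structure
#' and halved, since each neighbor edge is seen from both endpoints.
#' Genes with fewer than 2 neighbors have no neighbor pair and get CC = 0.
#'
#' @param net an `interactome`
#' @param v a gene symbol in `net`
#' @return clustering coefficient in [0, 1]
#' @export
clustering_coefficient <- function(net, v) {
  stopifnot(inherits(net, "interactome"))
  if (!(v %in% names(net$adjacency))) stop(sprintf("unknown gene '%s'", v))
  nb <- net$adjacency[[v]]
  k <- length(nb)
  if (k < 2L) return(0)
  # incidences of neighbor-neighbor adjacency, counted from both ends
  inc <- sum(vapply(net$adjacency[nb],
                    function(x) sum(x %in% nb), numeric(1)))
  n_edges <- inc / 2
  2 * n_edges / (k * (k - 1))
}

#' Betweenness centrality of every gene (Brandes accumulation)
#'
#' For gene v, betweenness sums, over unordered pairs \{i, j\} with
#' i != v != j, the fraction of shortest i-j paths that pass through v.
#' Unreachable pairs contribute 0.  Computed with Brandes' single-source
#' dependency accumulation: one BFS per source with path counting, then a
#' reverse sweep in non-increasing distance order.  The raw accumulation
#' counts each unordered pair from both endpoints and is halved.
#'
#' @param net an `interactome`
#' @param normalized if `TRUE` (default), divide by (N-1)(N-2)/2, the number
#'   of unordered pairs excluding v, so values lie in [0, 1]
#' @return named numeric vector of betweenness values, one per node
#' @export
betweenness_centrality <- function(net, normalized = TRUE) {
  stopifnot(inherits(net, "interactome"))
  adj_idx <- adjacency_index(net)
  n <- length(adj_idx)
  bc <- numeric(n)
  if (n >= 3L) {
    for (s in seq_len(n)) {
      # BFS with shortest-path counting
      dist <- rep(NA_integer_, n)
      sigma <- numeric(n)
      dist[s] <- 0L
      sigma[s] <- 1
      order_out <- integer(n)
      queue <- integer(n)
      queue[1L] <- s
      head <- 1L; tail <- 1L
      while (head <= tail) {
        v <- queue[head]
        order_out[head] <- v
        head <- head + 1L
        dv <- dist[v]
        for (w in adj_idx[[v]]) {
          if (is.na(dist[w])) {
            dist[w] <- dv + 1L
            tail <- tail + 1L
            queue[tail] <- w
          }
          if (dist[w] == dv + 1L) sigma[w] <- sigma[w] + sigma[v]
        }
      }
      # reverse sweep: accumulate dependencies
      delta <- numeric(n)
      for (pos in seq(tail, 1L)) {
        w <- order_out[pos]
        dw <- dist[w]
        for (v in adj_idx[[w]]) {
          if (!is.na(dist[v]) && dist[v] == dw - 1L) {
            delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
          }
        }
        if (w != s) bc[w] <- bc[w] + delta[w]
      }
    }
    bc <- bc / 2
    if (normalized) bc <- bc / ((n - 1) * (n - 2) / 2)
  }
  stats::setNames(bc, names(net$adjacency))
}

#' Compute the four topological parameters for a set of genes
#'
#' Assembles degree, average shortest path length, clustering coefficient
#' and betweenness centrality into one record per gene.  Betweenness is a
#' whole-network quantity and is computed once, then looked up per gene.
#'
#' @param net an `interactome`
#' @param targets a `gene_set`, a character vector of symbols, or `NULL`
#'   for all nodes.  Absent symbols are skipped with a warning.
#' @param normalized_bc passed to [betweenness_centrality()]
#' @param bc_cache optional precomputed result of
#'   [betweenness_centrality()] on `net`, to avoid recomputation when
#'   calling repeatedly on the same network
#' @return data.frame with columns `gene`, `degree`, `aspl`, `cc`, `bc`,
#'   one row per present target in input order
#' @export
compute_all_metrics <- function(net, targets = NULL, normalized_bc = TRUE,
                                bc_cache = NULL) {
  stopifnot(inherits(net, "interactome"))
  nodes <- names(net$adjacency)
  want <- if (is.null(targets)) nodes
          else if (inherits(targets, "gene_set")) targets$members
          else as.character(targets)
  present <- want[want %in% nodes]
  absent <- setdiff(want, present)
  if (length(absent) > 0L) {
    warning(sprintf("skipped %d gene(s) absent from the network: %s",
                    length(absent), paste(absent, collapse = ", ")))
  }
  if (length(present) == 0L) stop("no target gene is present in the network")
  bc <- if (is.null(bc_cache)) betweenness_centrality(net, normalized_bc)
        else bc_cache
  adj_idx <- adjacency_index(net)
  aspl <- vapply(present, function(v) {
    d <- bfs_int(adj_idx, match(v, nodes))
    d <- d[!is.na(d)]
    if (length(d) < 2L) NA_real_ else sum(d) / (length(d) - 1L)
  }, numeric(1))
  data.frame(
    gene = present,
    degree = as.integer(lengths(net$adjacency[present])),
    aspl = unname(aspl),
    cc = vapply(present, function(v) clustering_coefficient(net, v),
                numeric(1), USE.NAMES = FALSE),
    bc = unname(bc[present]),
    stringsAsFactors = FALSE
  )
}
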