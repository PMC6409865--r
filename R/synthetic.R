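#' Specification for the synthetic interactome generator
#'
#' Defaults describe a two-community scale-free interactome of 200 genes
#' per community grown with 4 edges per new gene, bridged by 10 planted
#' connector genes with 3 links into each community.  Connectors bridge
#' otherwise-separate communities, so by construction they acquire high
#' betweenness, short average paths and low clustering — the topological
#' signature reported for complex-disease genes.  Their fixed degree
#' (`n_communities * connector_links_per_community` = 6 under the defaults)
#' sits at the median degree of a preferential-attachment community grown
#' with m = 4 (the median k solves k(k+1) = 2m(m+1)), so planted genes are
#' deliberately not degree-prominent.
#'
#' @param n_nodes genes per community (or total genes for
#'   [generate_scale_free()])
#' @param edges_per_new_node preferential-attachment parameter m: edges
#'   added by each new gene
#' @param n_communities number of independently grown communities
#' @param planted_count number of planted connector genes
#' @param connector_links_per_community links from each connector into each
#'   community
#' @param seed integer seed; all randomness flows through it
#' @return object of class `generator_spec`
#' @export
generator_spec <- function(n_nodes = 200L, edges_per_new_node = 4L,
                           n_communities = 2L, planted_count = 10L,
                           connector_links_per_community = 3L, seed = 1L) {
  spec <- list(
    n_nodes = as.integer(n_nodes),
    edges_per_new_node = as.integer(edges_per_new_node),
    n_communities = as.integer(n_communities),
    planted_count = as.integer(planted_count),
    connector_links_per_community = as.integer(connector_links_per_community),
    seed = as.integer(seed)
  )
  if (spec$n_nodes < 2L) stop("n_nodes must be at least 2")
  if (spec$edges_per_new_node < 1L || spec$edges_per_new_node >= spec$n_nodes) {
    stop("edges_per_new_node must be in [1, n_nodes)")
  }
  if (spec$n_communities < 1L) stop("n_communities must be >= 1")
  if (spec$planted_count < 0L) stop("planted_count must be >= 0")
  if (spec$planted_count >= spec$n_nodes) {
    stop("planted_count must be smaller than n_nodes")
  }
  if (spec$connector_links_per_community < 1L) {
    stop("connector_links_per_community must be >= 1")
  }
  structure(spec, class = "generator_spec")
}

# Label helper: zero-padded gene names, byte-sortable.
gene_labels <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(4L, nchar(n)), seq_len(n))
}

# Preferential-attachment edge growth under the CURRENT RNG state.
# Starts from a complete graph on m nodes; each subsequent node attaches m
# distinct edges to existing nodes with probability proportional to their
# current degree.  Total edges: C(m,2) + m * (n - m).  Returns a two-column
# character matrix of edges over `labels` (length n).
pa_edges <- function(n, m, labels) {
  stopifnot(n >= m + 1L || n == m, length(labels) == n)
  deg <- integer(n)
  # seed clique
  from <- integer(0); to <- integer(0)
  if (m >= 2L) {
    cmb <- utils::combn(m, 2L)
    from <- cmb[1L, ]; to <- cmb[2L, ]
    deg[seq_len(m)] <- m - 1L
  }
  if (n > m) {
    for (v in seq.int(m + 1L, n)) {
      existing <- seq_len(v - 1L)
      w <- deg[existing]
      # the very first attachment of the m = 1 process has no degree mass
      if (all(w == 0L)) w <- rep(1, length(existing))
      targets <- sample(existing, m, prob = w)
      from <- c(from, rep(v, m)); to <- c(to, targets)
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m
    }
  }
  cbind(labels[from], labels[to])
}

#' Generate a scale-free interactome by preferential attachment
#'
#' Growth starts from a complete graph on m = `edges_per_new_node` genes;
#' each new gene attaches m distinct edges to existing genes with
#' probability proportional to their current degree.  The result is
#' connected and simple with C(m,2) + m (n - m) edges and a heavy-tailed
#' degree distribution, emulating the degree structure of real
#' biomolecular interactomes.
#'
#' @param spec a [generator_spec()]; only `n_nodes`, `edges_per_new_node`
#'   and `seed` are used
#' @param prefix gene-name prefix
#' @return an `interactome` with `n_nodes` genes, reproducible from
#'   `spec$seed`
#' @export
generate_scale_free <- function(spec = generator_spec(), prefix = "G") {
  stopifnot(inherits(spec, "generator_spec"))
  labels <- gene_labels(prefix, spec$n_nodes)
  e <- with_seed(spec$seed,
                 pa_edges(spec$n_nodes, spec$edges_per_new_node, labels))
  interactome(e[, 1L], e[, 2L])
}

#' Generate a community interactome with a planted connector gene set
#'
#' Builds `n_communities` independent preferential-attachment communities,
#' then adds `planted_count` connector genes, each linked to
#' `connector_links_per_community` uniformly chosen low-degree genes in
#' every community (low-degree = the smallest degree values present, so
#' connectors never attach to hubs).  Bridging all inter-community routes
#' gives connectors high betweenness, short average paths and near-zero
#' clustering, at a fixed moderate degree of
#' `n_communities * connector_links_per_community`.
#'
#' @param spec a [generator_spec()] with `n_communities >= 2`
#' @return list with elements `network` (an `interactome`; connected
#'   whenever `planted_count >= 1`) and `genes` (the planted `gene_set`;
#'   zero-member when `planted_count = 0`, in which case the network is
#'   disconnected)
#' @export
plant_disease_genes <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$n_communities < 2L) stop("plant_disease_genes needs >= 2 communities")
  m <- spec$edges_per_new_node
  links <- spec$connector_links_per_community
  if (links > spec$n_nodes) stop("more connector links than community nodes")
  connectors <- if (spec$planted_count > 0L) {
    gene_labels("DIS", spec$planted_count)
  } else character(0)
  edges <- with_seed(spec$seed, {
    comm_edges <- vector("list", spec$n_communities)
    comm_labels <- vector("list", spec$n_communities)
    for (cidx in seq_len(spec$n_communities)) {
      labels <- gene_labels(sprintf("C%d_", cidx), spec$n_nodes)
      comm_labels[[cidx]] <- labels
      comm_edges[[cidx]] <- pa_edges(spec$n_nodes, m, labels)
    }
    con_edges <- NULL
    if (length(connectors) > 0L) {
      for (cidx in seq_len(spec$n_communities)) {
        e <- comm_edges[[cidx]]
        deg <- table(factor(c(e[, 1L], e[, 2L]),
                            levels = comm_labels[[cidx]]))
        # pool of low-degree genes: smallest degree values, widened until
        # at least `links` candidates are available
        dvals <- sort(unique(as.integer(deg)))
        pool <- character(0)
        for (d in dvals) {
          pool <- names(deg)[as.integer(deg) <= d]
          if (length(pool) >= links) break
        }
        for (con in connectors) {
          tg <- sample(pool, links)
          con_edges <- rbind(con_edges, cbind(con, tg))
        }
      }
    }
    do.call(rbind, c(comm_edges, list(con_edges)))
  })
  genes <- structure(list(name = "planted", members = connectors),
                     class = "gene_set")
  list(network = interactome(edges[, 1L], edges[, 2L]), genes = genes)
}

#' Published per-gene topology values for the ten most-studied disease genes
#'
#' The packaged fixture of degree, average shortest path length, clustering
#' coefficient and normalized betweenness centrality for the ten most
#' frequently studied human disease genes (TP53, TNF, EGFR, VEGFA, APOE,
#' IL6, TGFB1, MTHFR, ESR1, AKT1), as measured on a 7018-gene integrated
#' interactome.  These are loaded verbatim at the printed precision, not
#' recomputed: the underlying interactome is not redistributable.
#'
#' @return data.frame with columns `gene`, `degree`, `aspl`, `cc`, `bc`
#'   (10 rows)
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "topten_gene_metrics.tsv",
                      package = "netloci", mustWork = TRUE)
  read_metrics_table(path)
}

#' Small fixture graphs with closed-form topology values
#'
#' @return named list of `interactome`s:
#' \describe{
#'   \item{p4}{path a-b-c-d; inner-node normalized betweenness 2/3,
#'     endpoint aspl 2, inner aspl 4/3}
#'   \item{star}{hub plus 4 leaves; hub betweenness 1, aspl 1, cc 0}
#'   \item{k4}{complete graph on 4 nodes; cc 1, betweenness 0 everywhere}
#'   \item{triangle_pendant}{triangle a,b,c with pendant d on a;
#'     cc(a) = 1/3}
#'   \item{barbell}{two triangles joined by the bridge c-d; the bridge
#'     endpoints carry the two largest betweenness values}
#' }
#' @export
toy_graphs <- function() {
  list(
    p4 = interactome(c("a", "b", "c"), c("b", "c", "d")),
    star = interactome(rep("hub", 4), paste0("leaf", 1:4)),
    k4 = {
      cmb <- utils::combn(paste0("n", 1:4), 2L)
      interactome(cmb[1L, ], cmb[2L, ])
    },
    triangle_pendant = interactome(c("a", "b", "c", "a"),
                                   c("b", "c", "a", "d")),
    barbell = interactome(c("a", "b", "c", "d", "e", "f", "c"),
                          c("b", "c", "a", "e", "f", "d", "d"))
  )
}
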