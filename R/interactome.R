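# Gene symbols are compared and ordered byte-wise (radix sort) so that all
# outputs are locale-independent and byte-stable.
sort_symbols <- function(x) sort(unique(x), method = "radix")

#' Construct an interactome from an edge table
#'
#' An interactome is an undirected simple graph over gene symbols, stored as
#' a symmetric adjacency list.  Self-loops and duplicate (or reversed
#' duplicate) edges are not representable: they are rejected here and
#' collapsed/dropped by [read_edge_list()].
#'
#' @param from,to character vectors of equal length giving the two endpoints
#'   of each edge.  Symbols are case-sensitive and taken verbatim.
#' @return An object of class `interactome`: a list with elements
#'   `adjacency` (named list, one sorted character vector of neighbors per
#'   node, nodes in byte order) and `n_edges`.
#' @export
interactome <- function(from, to) {
  stopifnot(is.character(from), is.character(to), length(from) == length(to))
  if (length(from) == 0L) stop("interactome has no edges")
  if (any(!nzchar(from)) || any(!nzchar(to))) {
    stop("gene symbols must be non-empty strings")
  }
  if (any(from == to)) stop("self-loops are not allowed in an interactome")
  # canonical unordered representation (byte order, not locale order),
  # then dedupe
  nodes <- sort_symbols(c(from, to))
  fi <- match(from, nodes); ti <- match(to, nodes)
  ai <- pmin(fi, ti); bi <- pmax(fi, ti)
  keep <- !duplicated(ai * (length(nodes) + 1) + bi)
  a <- nodes[ai[keep]]; b <- nodes[bi[keep]]
  adj <- split(c(b, a), factor(c(a, b), levels = nodes))
  adj <- lapply(adj, sort, method = "radix")
  structure(
    list(adjacency = adj, n_edges = length(a)),
    class = "interactome"
  )
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome: %d nodes, %d edges>\n",
              length(x$adjacency), x$n_edges))
  invisible(x)
}

#' Node symbols of an interactome
#' @param net an `interactome`
#' @return character vector of gene symbols in byte order
#' @export
interactome_nodes <- function(net) {
  stopifnot(inherits(net, "interactome"))
  names(net$adjacency)
}

#' Edge count of an interactome
#' @param net an `interactome`
#' @return number of (undirected, simple) edges
#' @export
interactome_edge_count <- function(net) {
  stopifnot(inherits(net, "interactome"))
  net$n_edges
}

#' Edge list of an interactome
#' @param net an `interactome`
#' @return data.frame with columns `from`, `to`; each unordered edge appears
#'   once with `from` < `to` in byte order, rows sorted
#' @export
interactome_edges <- function(net) {
  stopifnot(inherits(net, "interactome"))
  nodes <- names(net$adjacency)
  from <- rep(nodes, lengths(net$adjacency))
  to <- unlist(net$adjacency, use.names = FALSE)
  keep <- match(from, nodes) < match(to, nodes)
  df <- data.frame(from = from[keep], to = to[keep],
                   stringsAsFactors = FALSE)
  df <- df[order(match(df$from, nodes), match(df$to, nodes)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

node_index <- function(net, symbols) {
  match(symbols, names(net$adjacency))
}

#' Node degrees
#' @param net an `interactome`
#' @param nodes optional character vector; defaults to all nodes
#' @return named integer vector of degrees
#' @export
node_degrees <- function(net, nodes = NULL) {
  stopifnot(inherits(net, "interactome"))
  d <- lengths(net$adjacency)
  if (is.null(nodes)) d else d[nodes]
}

#' Read an interactome from a two-column edge list
#'
#' Accepts the common tab- or whitespace-separated edge-list format used by
#' interaction databases: one interaction per line, first two tokens are the
#' gene symbols, any further columns (e.g. confidence scores) are ignored.
#' All edges are treated as undirected and unweighted.
#'
#' @param source path to a file, or a character vector of lines
#' @param comment_prefix lines starting with this prefix are skipped
#' @return an [interactome()].  Duplicate and reversed-duplicate lines
#'   collapse to a single edge; self-loop lines are dropped with a warning
#'   reporting the count.
#' @export
read_edge_list <- function(source, comment_prefix = "#") {
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  raw_no <- seq_along(lines)
  blank <- !nzchar(trimws(lines))
  comm <- startsWith(trimws(lines), comment_prefix)
  keep <- !(blank | comm)
  lines <- lines[keep]; raw_no <- raw_no[keep]
  if (length(lines) == 0L) stop("edge list contains no edges")
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge list: line %d has fewer than 2 fields",
                 raw_no[bad[1L]]))
  }
  from <- vapply(toks, `[[`, "", 1L)
  to <- vapply(toks, `[[`, "", 2L)
  loops <- from == to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop line(s)", sum(loops)))
    from <- from[!loops]; to <- to[!loops]
  }
  if (length(from) == 0L) stop("edge list contains no edges")
  interactome(from, to)
}

#' Write an interactome as a two-column tab-separated edge list
#' @param net an `interactome`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_edge_list <- function(net, path) {
  df <- interactome_edges(net)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Create a named gene set
#' @param name short label for the set
#' @param members character vector of gene symbols; duplicates removed
#'   keeping the first occurrence, order otherwise preserved
#' @return object of class `gene_set`
#' @export
gene_set <- function(name, members) {
  stopifnot(is.character(name), length(name) == 1L, is.character(members))
  members <- members[nzchar(members)]
  members <- members[!duplicated(members)]
  if (length(members) == 0L) stop("gene set is empty")
  structure(list(name = name, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s': %d genes>\n", x$name, length(x$members)))
  invisible(x)
}

#' Read a gene set (one symbol per line)
#' @param source path to a file, or a character vector of lines
#' @param name label for the set; defaults to the file name
#' @return a [gene_set()]
#' @export
read_gene_set <- function(source, name = NULL) {
  from_file <- length(source) == 1L && file.exists(source)
  lines <- if (from_file) readLines(source, warn = FALSE)
           else as.character(source)
  if (is.null(name)) {
    name <- if (from_file) sub("\\.[^.]*$", "", basename(source)) else "genes"
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("gene set source is empty")
  gene_set(name, lines)
}

#' Write a gene set, one symbol per line
#' @param genes a `gene_set`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_gene_set <- function(genes, path) {
  stopifnot(inherits(genes, "gene_set"))
  writeLines(genes$members, path)
  invisible(path)
}

# Connected components by repeated BFS; returns integer component id per node.
component_ids <- function(net) {
  adj <- net$adjacency
  n <- length(adj)
  idx <- stats::setNames(seq_len(n), names(adj))
  comp <- integer(n)
  cur <- 0L
  queue <- integer(n)
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    comp[s] <- cur
    queue[1L] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      for (w in idx[adj[[v]]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          tail <- tail + 1L
          queue[tail] <- w
        }
      }
    }
  }
  stats::setNames(comp, names(adj))
}

#' Induced subgraph on a set of nodes
#' @param net an `interactome`
#' @param nodes character vector of nodes to keep
#' @return an `interactome` on `nodes` with all edges among them
#' @export
induced_subgraph <- function(net, nodes) {
  stopifnot(inherits(net, "interactome"))
  nodes <- intersect(names(net$adjacency), nodes)
  if (length(nodes) == 0L) stop("no requested node is in the network")
  adj <- lapply(net$adjacency[nodes], intersect, nodes)
  from <- rep(nodes, lengths(adj))
  to <- unlist(adj, use.names = FALSE)
  keep <- match(from, nodes) < match(to, nodes)
  if (!any(keep)) stop("induced subgraph has no edges")
  interactome(from[keep], to[keep])
}

#' Largest connected component
#'
#' Per-node average shortest path length is only well-defined when every
#' other node is reachable, so the analysis restricts to the largest
#' component by default.  Ties in component size are broken by the component
#' containing the byte-wise smallest member symbol.
#'
#' @param net an `interactome`
#' @return the induced `interactome` on the largest component
#' @export
largest_connected_component <- function(net) {
  comp <- component_ids(net)
  sizes <- table(comp)
  best <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(best) > 1L) {
    # nodes are in byte order, so the first node among tied components wins
    first_of <- vapply(best, function(k) which(comp == k)[1L], integer(1))
    best <- best[which.min(first_of)]
  }
  keep <- names(comp)[comp == best]
  if (length(keep) == length(comp)) return(net)
  induced_subgraph(net, keep)
}

#' First-order neighbors of a gene set
#'
#' @param net an `interactome`
#' @param seeds a `gene_set`; members absent from the network are skipped
#'   with a warning
#' @param include_seeds if `FALSE` (default) seed genes are removed from the
#'   result so that neighbor statistics are not contaminated by the seed
#'   genes themselves
#' @return a `gene_set` named `<seeds>_neighbors`, members in byte order
#' @export
first_order_neighbors <- function(net, seeds, include_seeds = FALSE) {
  stopifnot(inherits(net, "interactome"), inherits(seeds, "gene_set"))
  present <- seeds$members[seeds$members %in% names(net$adjacency)]
  absent <- setdiff(seeds$members, present)
  if (length(absent) > 0L) {
    warning(sprintf("skipped %d seed gene(s) absent from the network: %s",
                    length(absent), paste(absent, collapse = ", ")))
  }
  if (length(present) == 0L) stop("no seed gene is present in the network")
  nb <- sort_symbols(unlist(net$adjacency[present], use.names = FALSE))
  if (include_seeds) nb <- sort_symbols(c(nb, present))
  else nb <- setdiff(nb, present)
  if (length(nb) == 0L) stop("seed genes have no neighbors outside the set")
  gene_set(paste0(seeds$name, "_neighbors"), nb)
}

#' Write a per-gene metrics table as TSV
#'
#' @param records a data.frame with columns `gene`, `degree`, `aspl`, `cc`,
#'   `bc` (as produced by [compute_all_metrics()] or [table2_fixture()])
#' @param path output file path
#' @return `path`, invisibly.  Row order is preserved; real values are
#'   rendered with 6 significant digits.
#' @export
write_metrics_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  need <- c("gene", "degree", "aspl", "cc", "bc")
  if (!all(need %in% names(records))) {
    stop("metrics table must have columns gene, degree, aspl, cc, bc")
  }
  if (nrow(records) == 0L) stop("metrics table is empty")
  out <- data.frame(
    gene = records$gene,
    degree = as.integer(records$degree),
    aspl = sprintf("%.6g", records$aspl),
    cc = sprintf("%.6g", records$cc),
    bc = sprintf("%.6g", records$bc),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a per-gene metrics table written by [write_metrics_table()]
#' @param path TSV file with header `gene degree aspl cc bc`
#' @return data.frame of per-gene metrics
#' @export
read_metrics_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "degree", "aspl", "cc", "bc")
  if (!all(need %in% names(df))) {
    stop("metrics table must have columns gene, degree, aspl, cc, bc")
  }
  df
}
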