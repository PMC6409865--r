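# Run code under a temporary RNG state seeded with `seed`, restoring any
# pre-existing state afterwards.  All randomness in the package flows
# through this helper, so results are reproducible from the seed alone and
# no global state leaks.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Configuration of the random-set null model
#'
#' @param replicates number of random gene sets to draw (>= 1)
#' @param group_count number of groups for the grouped analysis (>= 1); the
#'   disease set is partitioned into this many near-equal groups
#' @param seed integer seed controlling all sampling
#' @param exclude_disease if `TRUE` (default) random sets are drawn from the
#'   network excluding the disease genes, so the null and the disease set
#'   cannot overlap
#' @return object of class `null_config`
#' @export
null_config <- function(replicates = 10L, group_count = 10L, seed = 1L,
                        exclude_disease = TRUE) {
  stopifnot(replicates >= 1L, group_count >= 1L)
  structure(
    list(replicates = as.integer(replicates),
         group_count = as.integer(group_count),
         seed = as.integer(seed),
         exclude_disease = isTRUE(exclude_disease)),
    class = "null_config"
  )
}

#' Sample random gene sets from the network
#'
#' Each replicate is an independent uniform draw without replacement from
#' the network's nodes minus `exclude`; replicates may overlap each other
#' but never the excluded genes.
#'
#' @param net an `interactome`
#' @param size genes per set
#' @param replicates number of sets
#' @param exclude a `gene_set` or character vector to exclude (may be NULL)
#' @param seed integer seed; identical seeds give identical draws
#' @return list of `gene_set`s named `random_1 ... random_<replicates>`
#' @export
sample_random_sets <- function(net, size, replicates, exclude = NULL,
                               seed = 1L) {
  stopifnot(inherits(net, "interactome"), size >= 1L, replicates >= 1L)
  excl <- if (inherits(exclude, "gene_set")) exclude$members
          else as.character(exclude)
  pool <- setdiff(names(net$adjacency), excl)
  if (size > length(pool)) {
    stop(sprintf("cannot sample %d genes from a pool of %d", size,
                 length(pool)))
  }
  with_seed(seed, {
    lapply(seq_len(replicates), function(i) {
      gene_set(sprintf("random_%d", i), sample(pool, size))
    })
  })
}

#' Partition a gene set into near-equal groups
#'
#' Genes are shuffled by `seed` and split into `group_count` chunks whose
#' sizes differ by at most one (a set of 171 cannot be split into 10 truly
#' equal groups; the first `n %% group_count` groups get the extra gene).
#'
#' @param genes a `gene_set`
#' @param group_count number of groups
#' @param seed shuffle seed
#' @return list of `gene_set`s named `<name>_g1 ...`
#' @export
partition_into_groups <- function(genes, group_count, seed = 1L) {
  stopifnot(inherits(genes, "gene_set"), group_count >= 1L)
  n <- length(genes$members)
  if (group_count > n) stop("more groups than genes")
  shuffled <- with_seed(seed, sample(genes$members))
  base <- n %/% group_count
  extra <- n %% group_count
  sizes <- rep(base, group_count) + c(rep(1L, extra),
                                      rep(0L, group_count - extra))
  idx <- rep(seq_len(group_count), times = sizes)
  lapply(seq_len(group_count), function(g) {
    gene_set(sprintf("%s_g%d", genes$name, g), shuffled[idx == g])
  })
}

#' Mann-Whitney U test between two samples
#'
#' Thin, explicit wrapper around [stats::wilcox.test()] reporting the U
#' statistic for `xs` and the p-value.  With `method = "exact"` the exact
#' permutation null is used (only valid without ties; falls back to the
#' normal approximation with a warning if ties are present).  With
#' `method = "normal"` the Gaussian approximation with tie-corrected
#' variance and continuity correction is used.  `method = "auto"` picks
#' exact for tie-free samples when both sizes are <= 50.
#'
#' @param xs,ys numeric samples (non-empty)
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`
#' @param method `"auto"`, `"exact"`, or `"normal"`
#' @return list with elements `u` and `p`
#' @export
mann_whitney_u <- function(xs, ys,
                           alternative = c("two.sided", "greater", "less"),
                           method = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (length(xs) == 0L || length(ys) == 0L) stop("empty sample")
  # degenerate symmetric cases: constant pooled sample, or identical
  # multisets — the distributions coincide, so p = 1 by symmetry
  if (min(c(xs, ys)) == max(c(xs, ys)) ||
      (length(xs) == length(ys) && all(sort(xs) == sort(ys)))) {
    return(list(u = length(xs) * length(ys) / 2, p = 1))
  }
  exact <- switch(method,
    auto = NULL,                       # wilcox.test default rule
    exact = TRUE,
    normal = FALSE
  )
  ht <- suppressWarnings(
    stats::wilcox.test(xs, ys, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  list(u = unname(ht$statistic), p = min(1, unname(ht$p.value)))
}

param_names <- c("degree", "aspl", "cc", "bc")

direction_of <- function(xs, ys) {
  d <- stats::median(xs) - stats::median(ys)
  if (d > 0) "+" else if (d < 0) "-" else "0"
}

# Assemble one per-parameter comparison record.
comparison_result <- function(parameter, disease_values, null_values,
                              group_means, group_sds, per_replicate_p,
                              test) {
  structure(
    list(parameter = parameter,
         disease_values = disease_values,
         null_values = null_values,
         group_means = group_means,
         group_sds = group_sds,
         per_replicate_p = per_replicate_p,
         u_statistic = test$u,
         p_value = test$p,
         direction = direction_of(disease_values, null_values)),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%-6s  median %s vs %s  U = %.4g  p = %.4g  direction %s\n",
              x$parameter,
              format(stats::median(x$disease_values), digits = 4),
              format(stats::median(x$null_values), digits = 4),
              x$u_statistic, x$p_value, x$direction))
  invisible(x)
}

#' Compare a gene set's topology against a random-set null
#'
#' Computes the four topological parameters for the disease genes and for
#' `config$replicates` random same-size gene sets sampled from the network
#' (excluding the disease genes by default).  Per parameter, reports the
#' disease values, the pooled null values, per-replicate means and standard
#' deviations, and a two-sided Mann-Whitney p-value between the disease
#' values and the pooled null values.  Per-replicate p-values are also
#' emitted for transparency.
#'
#' @param net an `interactome`
#' @param disease a `gene_set`; at least 2 members must be present in `net`
#' @param config a [null_config()]
#' @param bc_cache optional precomputed [betweenness_centrality()] of `net`
#' @return object of class `topology_comparison`: a named list of four
#'   `comparison_result`s (degree, aspl, cc, bc), with attributes
#'   `disease_metrics` and `null_metrics` (data.frames)
#' @export
compare_gene_set <- function(net, disease, config = null_config(),
                             bc_cache = NULL) {
  stopifnot(inherits(net, "interactome"), inherits(disease, "gene_set"),
            inherits(config, "null_config"))
  present <- intersect(disease$members, names(net$adjacency))
  if (length(present) < 2L) {
    stop("fewer than 2 disease genes are present in the network")
  }
  excl <- if (config$exclude_disease) present else NULL
  nulls <- sample_random_sets(net, size = length(present),
                              replicates = config$replicates,
                              exclude = excl, seed = config$seed)
  bc <- if (is.null(bc_cache)) betweenness_centrality(net) else bc_cache
  dmet <- compute_all_metrics(net, present, bc_cache = bc)
  nmet <- lapply(nulls, function(g) {
    compute_all_metrics(net, g, bc_cache = bc)
  })
  pooled <- do.call(rbind, nmet)
  res <- lapply(param_names, function(p) {
    xs <- dmet[[p]]
    ys <- pooled[[p]]
    comparison_result(
      parameter = p,
      disease_values = stats::setNames(xs, dmet$gene),
      null_values = ys,
      group_means = vapply(nmet, function(m) mean(m[[p]]), numeric(1)),
      group_sds = vapply(nmet, function(m) stats::sd(m[[p]]), numeric(1)),
      per_replicate_p = vapply(nmet, function(m) {
        mann_whitney_u(xs, m[[p]])$p
      }, numeric(1)),
      test = mann_whitney_u(xs, ys)
    )
  })
  names(res) <- param_names
  structure(res, class = "topology_comparison",
            disease_metrics = dmet, null_metrics = pooled,
            comparison = "random-null")
}

#' Compare a gene set's topology against its first-order neighbors
#'
#' Same contract as [compare_gene_set()], but the comparison population is
#' the set of first-order neighbor genes (seed genes excluded) rather than
#' random draws.  No replicates are involved, so group summaries collapse
#' to the single neighbor population.
#'
#' @inheritParams compare_gene_set
#' @return a `topology_comparison` (see [compare_gene_set()])
#' @export
compare_neighbors <- function(net, disease, config = null_config(),
                              bc_cache = NULL) {
  stopifnot(inherits(net, "interactome"), inherits(disease, "gene_set"))
  present <- intersect(disease$members, names(net$adjacency))
  if (length(present) < 2L) {
    stop("fewer than 2 disease genes are present in the network")
  }
  nb <- first_order_neighbors(net, disease, include_seeds = FALSE)
  bc <- if (is.null(bc_cache)) betweenness_centrality(net) else bc_cache
  dmet <- compute_all_metrics(net, present, bc_cache = bc)
  nmet <- compute_all_metrics(net, nb, bc_cache = bc)
  res <- lapply(param_names, function(p) {
    xs <- dmet[[p]]
    ys <- nmet[[p]]
    comparison_result(
      parameter = p,
      disease_values = stats::setNames(xs, dmet$gene),
      null_values = stats::setNames(ys, nmet$gene),
      group_means = mean(ys),
      group_sds = stats::sd(ys),
      per_replicate_p = numeric(0),
      test = mann_whitney_u(xs, ys)
    )
  })
  names(res) <- param_names
  structure(res, class = "topology_comparison",
            disease_metrics = dmet, null_metrics = nmet,
            comparison = "first-order-neighbors")
}

#' Aggregate affinity of the neighbor population to null vs disease
#'
#' Scores whether the first-order-neighbor genes look more like random
#' genes than like the disease genes themselves.  For each parameter the
#' absolute difference between the neighbor median and the random-null
#' (resp. disease) median is standardized by the pooled-null standard
#' deviation; the four standardized distances are summed.  A neighbor
#' population topologically similar to random genes has a smaller distance
#' to the null than to the disease set.
#'
#' @param random a `topology_comparison` from [compare_gene_set()]
#' @param neighbors a `topology_comparison` from [compare_neighbors()] on
#'   the same network and disease set
#' @return list with `null_distance`, `disease_distance` (sums of
#'   standardized median distances) and `closer_to` (`"null"` or
#'   `"disease"`)
#' @export
neighbor_affinity <- function(random, neighbors) {
  stopifnot(inherits(random, "topology_comparison"),
            inherits(neighbors, "topology_comparison"))
  d <- vapply(param_names, function(p) {
    s <- stats::sd(random[[p]]$null_values)
    if (!is.finite(s) || s == 0) s <- 1
    nb <- stats::median(neighbors[[p]]$null_values)
    c(abs(nb - stats::median(random[[p]]$null_values)) / s,
      abs(nb - stats::median(random[[p]]$disease_values)) / s)
  }, numeric(2))
  null_d <- sum(d[1L, ])
  dis_d <- sum(d[2L, ])
  list(null_distance = null_d, disease_distance = dis_d,
       closer_to = if (null_d <= dis_d) "null" else "disease")
}

#' @export
print.topology_comparison <- function(x, ...) {
  cat(sprintf("Topology comparison (%s), %d disease genes vs %d comparison values\n",
              attr(x, "comparison"),
              length(x[[1L]]$disease_values),
              length(x[[1L]]$null_values)))
  for (r in x) print(r)
  invisible(x)
}

#' Summarize a topology comparison as a data.frame
#' @param object a `topology_comparison`
#' @param ... unused
#' @return data.frame with one row per parameter: medians, U, p, direction
#' @export
summary.topology_comparison <- function(object, ...) {
  data.frame(
    parameter = vapply(object, `[[`, "", "parameter"),
    disease_median = vapply(object, function(r) {
      stats::median(r$disease_values)
    }, numeric(1)),
    null_median = vapply(object, function(r) {
      stats::median(r$null_values)
    }, numeric(1)),
    u_statistic = vapply(object, `[[`, numeric(1), "u_statistic"),
    p_value = vapply(object, `[[`, numeric(1), "p_value"),
    direction = vapply(object, `[[`, "", "direction"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
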