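#' Configuration for an end-to-end analysis run
#'
#' @param network_path path to a two-column edge-list TSV
#' @param gene_set_paths named character vector of gene-set file paths (one
#'   symbol per line); names label the sets in every output
#' @param out_dir output directory, created if absent
#' @param replicates,group_count,seed see [null_config()]
#' @param use_lcc restrict the analysis to the largest connected component
#'   (default), so per-gene average path lengths are defined for every gene
#' @param neighbors also run the first-order-neighbor comparison
#' @return object of class `run_config`
#' @export
run_config <- function(network_path, gene_set_paths, out_dir,
                       replicates = 10L, group_count = 10L, seed = 1L,
                       use_lcc = TRUE, neighbors = TRUE) {
  if (!file.exists(network_path)) {
    stop(sprintf("network file not found: %s", network_path))
  }
  gene_set_paths <- unlist(gene_set_paths)
  if (is.null(names(gene_set_paths)) || any(!nzchar(names(gene_set_paths)))) {
    names(gene_set_paths) <- sub("\\.[^.]*$", "", basename(gene_set_paths))
  }
  missing <- gene_set_paths[!file.exists(gene_set_paths)]
  if (length(missing) > 0L) {
    stop(sprintf("gene set file not found: %s",
                 paste(missing, collapse = ", ")))
  }
  structure(
    list(network_path = network_path,
         gene_set_paths = gene_set_paths,
         out_dir = out_dir,
         replicates = as.integer(replicates),
         group_count = as.integer(group_count),
         seed = as.integer(seed),
         use_lcc = isTRUE(use_lcc),
         neighbors = isTRUE(neighbors)),
    class = "run_config"
  )
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

tests_as_list <- function(cmp) {
  lapply(cmp, function(r) {
    list(u = r$u_statistic, p = r$p_value, direction = r$direction,
         disease_median = stats::median(r$disease_values),
         null_median = stats::median(r$null_values),
         per_replicate_p = r$per_replicate_p)
  })
}

group_summary_frame <- function(cmp) {
  do.call(rbind, lapply(cmp, function(r) {
    k <- length(r$group_means)
    data.frame(parameter = rep(r$parameter, k),
               replicate = seq_len(k),
               mean = r$group_means,
               sd = r$group_sds,
               stringsAsFactors = FALSE)
  }))
}

stage <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", label, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full topology analysis for one or more gene sets
#'
#' Executes, in order: load network; restrict to the largest connected
#' component; per-gene metrics for each gene set; random-null comparison;
#' first-order-neighbor comparison; grouped analysis of the disease set
#' (when `group_count > 1`); pairwise Spearman correlations.  Writes, per
#' gene set, a metrics TSV, a null-group summary TSV, a disease-group
#' summary TSV, JSON test results for both comparisons, a correlation
#' JSON, and one plain-text Markdown summary for the whole run.  All
#' outputs are byte-deterministic given the seed; progress and skipped-gene
#' warnings go to the message stream only.
#'
#' @param config a [run_config()]
#' @return (invisibly) a named list per gene set with elements `metrics`,
#'   `random`, `neighbors`, `correlations`, plus `network`
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  n_warn <- 0L
  bundle <- withCallingHandlers({
    net <- stage("load-network", read_edge_list(config$network_path))
    if (config$use_lcc) {
      net <- stage("largest-component", largest_connected_component(net))
    }
    message(sprintf("network: %d nodes, %d edges%s",
                    length(net$adjacency), net$n_edges,
                    if (config$use_lcc) " (largest component)" else ""))
    bc <- stage("betweenness", betweenness_centrality(net))
    out <- list(network = net)
    for (set_name in names(config$gene_set_paths)) {
      genes <- stage("load-genes",
                     read_gene_set(config$gene_set_paths[[set_name]],
                                   name = set_name))
      cfg <- null_config(replicates = config$replicates,
                         group_count = config$group_count,
                         seed = config$seed)
      metrics <- stage("metrics",
                       compute_all_metrics(net, genes, bc_cache = bc))
      write_metrics_table(metrics,
                          file.path(config$out_dir,
                                    sprintf("%s_metrics.tsv", set_name)))
      random <- stage("random-null",
                      compare_gene_set(net, genes, cfg, bc_cache = bc))
      utils::write.table(
        group_summary_frame(random),
        file.path(config$out_dir, sprintf("%s_null_groups.tsv", set_name)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_json_file(tests_as_list(random),
                      file.path(config$out_dir,
                                sprintf("%s_random_tests.json", set_name)))
      nbcmp <- NULL
      if (config$neighbors) {
        nbcmp <- stage("neighbor-comparison",
                       compare_neighbors(net, genes, cfg, bc_cache = bc))
        write_json_file(tests_as_list(nbcmp),
                        file.path(config$out_dir,
                                  sprintf("%s_neighbor_tests.json",
                                          set_name)))
      }
      if (config$group_count > 1L &&
          config$group_count <= length(metrics$gene)) {
        groups <- stage("grouping",
                        partition_into_groups(gene_set(set_name,
                                                       metrics$gene),
                                              config$group_count,
                                              seed = config$seed))
        gs <- do.call(rbind, lapply(seq_along(groups), function(g) {
          sub <- metrics[metrics$gene %in% groups[[g]]$members, ]
          do.call(rbind, lapply(param_names, function(p) {
            data.frame(parameter = p, group = g, mean = mean(sub[[p]]),
                       sd = stats::sd(sub[[p]]), stringsAsFactors = FALSE)
          }))
        }))
        gs <- gs[order(match(gs$parameter, param_names), gs$group), ]
        utils::write.table(
          gs, file.path(config$out_dir,
                        sprintf("%s_disease_groups.tsv", set_name)),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      corr <- stage("correlations", pairwise_correlations(metrics))
      write_json_file(correlation_pairs(corr),
                      file.path(config$out_dir,
                                sprintf("%s_correlations.json", set_name)))
      out[[set_name]] <- list(metrics = metrics, random = random,
                              neighbors = nbcmp, correlations = corr)
    }
    out
  }, warning = function(w) {
    n_warn <<- n_warn + 1L
    message(sprintf("warning: %s", conditionMessage(w)))
    invokeRestart("muffleWarning")
  })
  summary_path <- file.path(config$out_dir, "summary.md")
  con <- file(summary_path, open = "wt")
  on.exit(close(con))
  first <- TRUE
  for (set_name in names(config$gene_set_paths)) {
    render_summary(bundle[[set_name]]$random,
                   neighbors = bundle[[set_name]]$neighbors,
                   correlations = bundle[[set_name]]$correlations,
                   sink = con, title = set_name, header = first)
    first <- FALSE
  }
  writeLines(sprintf("\n%d warning(s) during the run.", n_warn), con)
  message(sprintf("run complete: outputs in %s (%d warnings)",
                  config$out_dir, n_warn))
  invisible(bundle)
}

fmt <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", sprintf("%.*g", digits, x))
}

#' Render comparison results as a deterministic Markdown summary
#'
#' Emits, per parameter, the null-group means and standard deviations, the
#' Mann-Whitney U/p table with the direction of the disease-vs-null median
#' difference, and (when supplied) the neighbor-comparison table and the
#' 4 x 4 Spearman correlation table — 6 distinct coefficients.
#'
#' @param random a `topology_comparison` from [compare_gene_set()]
#' @param neighbors optional `topology_comparison` from
#'   [compare_neighbors()]
#' @param correlations optional `correlation_matrix`
#' @param sink a connection or file path
#' @param title label for the gene set
#' @param header include the top-level document header
#' @return invisibly, `NULL`
#' @export
render_summary <- function(random, neighbors = NULL, correlations = NULL,
                           sink = stdout(), title = "gene set",
                           header = TRUE) {
  if (is.null(random) || length(random) == 0L) stop("empty results")
  own <- is.character(sink)
  con <- if (own) file(sink, open = "wt") else sink
  if (own) on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  if (header) w("# Network topology analysis summary")
  w("\n## Gene set: %s\n", title)
  w("### Disease vs random-null comparison\n")
  w("| parameter | disease median | null median | U | p | direction |")
  w("|---|---|---|---|---|---|")
  for (r in random) {
    w("| %s | %s | %s | %s | %s | %s |", r$parameter,
      fmt(stats::median(r$disease_values)),
      fmt(stats::median(r$null_values)),
      fmt(r$u_statistic), fmt(r$p_value), r$direction)
  }
  w("\n### Null replicate group means (mean ± sd)\n")
  w("| parameter | %s |",
    paste(sprintf("rep %d", seq_along(random[[1L]]$group_means)),
          collapse = " | "))
  w("|%s|", paste(rep("---", length(random[[1L]]$group_means) + 1L),
                  collapse = "|"))
  for (r in random) {
    w("| %s | %s |", r$parameter,
      paste(sprintf("%s ± %s", fmt(r$group_means, 4),
                    fmt(r$group_sds, 4)), collapse = " | "))
  }
  if (!is.null(neighbors)) {
    w("\n### Disease vs first-order neighbors\n")
    w("| parameter | disease median | neighbor median | U | p | direction |")
    w("|---|---|---|---|---|---|")
    for (r in neighbors) {
      w("| %s | %s | %s | %s | %s | %s |", r$parameter,
        fmt(stats::median(r$disease_values)),
        fmt(stats::median(r$null_values)),
        fmt(r$u_statistic), fmt(r$p_value), r$direction)
    }
  }
  if (!is.null(correlations)) {
    w("\n### Spearman correlations between parameters (n = %d)\n",
      attr(correlations, "n"))
    w("| | %s |", paste(param_names, collapse = " | "))
    w("|%s|", paste(rep("---", 5), collapse = "|"))
    for (i in 1:4) {
      w("| %s | %s |", param_names[i],
        paste(fmt(correlations[i, ], 4), collapse = " | "))
    }
  }
  invisible(NULL)
}
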