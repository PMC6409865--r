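#' Ascending ranks with tied values averaged
#'
#' Ranks 1..n with every block of tied values receiving the mean of the
#' rank positions it occupies — the rank transform on which Spearman's
#' coefficient is defined when ties are present.
#'
#' @param values non-empty numeric vector
#' @return numeric vector of (possibly fractional) ranks
#' @export
rank_with_ties <- function(values) {
  if (length(values) == 0L) stop("empty input")
  rank(values, ties.method = "average")
}

#' Spearman rank correlation with tie-averaged ranks
#'
#' Computed as the Pearson product-moment correlation of the tie-averaged
#' ranks of the two inputs.  With ties this differs from the popular
#' shortcut 1 - 6 * sum(d^2) / (n (n^2 - 1)), which is only valid for
#' tie-free data; the two agree exactly when there are no ties.  Rounded
#' published metric tables are full of ties (e.g. two-decimal clustering
#' coefficients), so the tie-correct form matters in practice.
#'
#' @param xs,ys numeric vectors of equal length >= 3, each with at least
#'   two distinct values
#' @return Spearman's rho in [-1, 1]
#' @export
spearman_rho <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("inputs differ in length")
  if (length(xs) < 3L) stop("need at least 3 observations")
  if (min(xs) == max(xs) || min(ys) == max(ys)) {
    stop("constant input: rank correlation undefined")
  }
  stats::cor(rank_with_ties(xs), rank_with_ties(ys))
}

#' All-against-all Spearman correlations among the four parameters
#'
#' Builds the 4 x 4 matrix of Spearman coefficients over degree, average
#' shortest path length, clustering coefficient and betweenness centrality
#' for the given genes — C(4,2) = 6 distinct off-diagonal values.  A
#' parameter that is constant across the records has no defined rank
#' correlation: entries touching it are set to `NA` with a warning rather
#' than silently zeroed.
#'
#' @param metrics data.frame of per-gene metrics (columns `degree`, `aspl`,
#'   `cc`, `bc`), at least 3 rows
#' @return object of class `correlation_matrix`: a symmetric 4 x 4 numeric
#'   matrix with unit diagonal and attribute `n` (number of genes used)
#' @export
pairwise_correlations <- function(metrics) {
  stopifnot(is.data.frame(metrics))
  if (!all(param_names %in% names(metrics))) {
    stop("metrics must have columns degree, aspl, cc, bc")
  }
  if (nrow(metrics) < 3L) stop("need at least 3 gene records")
  m <- diag(1, 4)
  dimnames(m) <- list(param_names, param_names)
  constant <- vapply(param_names, function(p) {
    min(metrics[[p]]) == max(metrics[[p]])
  }, logical(1))
  for (i in 1:3) for (j in (i + 1):4) {
    pi <- param_names[i]; pj <- param_names[j]
    if (constant[i] || constant[j]) {
      m[i, j] <- m[j, i] <- NA_real_
    } else {
      m[i, j] <- m[j, i] <- spearman_rho(metrics[[pi]], metrics[[pj]])
    }
  }
  if (any(constant)) {
    warning(sprintf("constant parameter(s) %s: correlations undefined (NA)",
                    paste(param_names[constant], collapse = ", ")))
  }
  structure(m, class = c("correlation_matrix", "matrix"),
            n = nrow(metrics))
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("Spearman correlations over %d genes:\n", attr(x, "n")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Flatten a correlation matrix to its 6 named pairs
#' @param m a `correlation_matrix`
#' @return named list of the 6 off-diagonal coefficients plus `n`
#' @export
correlation_pairs <- function(m) {
  stopifnot(inherits(m, "correlation_matrix"))
  out <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    out[[paste(param_names[i], param_names[j], sep = "~")]] <- m[i, j]
  }
  out$n <- attr(m, "n")
  out
}
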