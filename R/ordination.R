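#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{BC(i,j) = \sum_o |x_{oi} - x_{oj}| / \sum_o (x_{oi} + x_{oj})} over
#' organisms; 0 for identical samples, 1 for samples sharing no organisms.
#'
#' @param mat Abundance matrix (organisms x samples), non-negative.
#' @return A \code{dist} object over samples.
#' @export
bray_curtis <- function(mat) {
  if (any(mat < 0)) stop("negative abundances")
  if (any(colSums(mat) == 0)) stop("all-zero sample: Bray-Curtis undefined")
  vegan::vegdist(t(mat), method = "bray")
}

#' Non-metric multidimensional scaling of a sample dissimilarity matrix
#'
#' Rank-based ordination minimizing Kruskal stress-1, run from multiple
#' random starts plus a metric-scaling start; the best solution is kept and
#' its coordinates centered.
#'
#' @param d A \code{dist} or symmetric dissimilarity matrix.
#' @param k Target dimensionality (default 2).
#' @param n_starts Number of random starts (default 20).
#' @param max_iter Maximum iterations per start (default 200).
#' @param seed Random seed for the starts.
#' @return An \code{ordination_result}: list with \code{points} (samples x
#'   k, centered), \code{stress} (stress-1 in [0, 1]), \code{converged},
#'   \code{seed}.
#' @export
nmds <- function(d, k = 2L, n_starts = 20L, max_iter = 200L, seed = 1L) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) stop("dissimilarity matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  if (attr(d, "Size") < k + 1L) stop("need at least k + 1 samples")
  set.seed(seed)
  fit <- suppressWarnings(vegan::metaMDS(
    d, k = k, try = n_starts, trymax = n_starts, maxit = max_iter,
    trace = FALSE, autotransform = FALSE, wascores = FALSE))
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  # metaMDS counts convergent restarts; near-zero stress solutions are
  # accepted even when restarts never agree bitwise
  conv <- (is.numeric(fit$converged) && fit$converged > 0) ||
    isTRUE(fit$converged) || fit$stress < 0.01
  structure(list(points = pts, stress = fit$stress, converged = conv,
                 seed = seed),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %d samples in %d dims, stress %.4f (%s)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' BioENV: environmental variable subsets best explaining community
#' structure
#'
#' Standardizes each continuous environmental variable to zero mean and
#' unit variance, then, for every variable subset up to
#' \code{max_subset_size}, computes Euclidean inter-sample distances on the
#' subset and their Spearman rank correlation with the community
#' dissimilarities. The best subset maximizes the correlation; the search
#' is exhaustive. Constant variables are excluded with a warning. Ties in
#' the Spearman ranks are handled by average ranks.
#'
#' @param community_d Community dissimilarity (\code{dist} or symmetric
#'   matrix), samples aligned with the rows of \code{env}.
#' @param env Data frame of continuous environmental variables (one row per
#'   sample).
#' @param max_subset_size Largest subset evaluated; default all variables
#'   (capped at 15 with a warning beyond that).
#' @return A \code{bioenv_result}: list with \code{best_subset},
#'   \code{best_rho}, and \code{results} (data frame of every evaluated
#'   subset with its size and rho, sorted by rho descending).
#' @export
bioenv_screen <- function(community_d, env, max_subset_size = NULL) {
  if (is.matrix(community_d)) community_d <- stats::as.dist(community_d)
  n <- attr(community_d, "Size")
  stopifnot(nrow(env) == n)
  env <- as.data.frame(env)
  keep <- vapply(env, function(v) is.numeric(v) && stats::sd(v) > 0, logical(1))
  if (any(!keep))
    warning("excluding constant or non-numeric variables: ",
            paste(names(env)[!keep], collapse = ", "))
  env <- env[, keep, drop = FALSE]
  if (ncol(env) == 0L) stop("no usable environmental variables")
  if (is.null(max_subset_size)) max_subset_size <- ncol(env)
  if (max_subset_size > 15L) {
    warning("capping exhaustive subset search at size 15")
    max_subset_size <- 15L
  }
  z <- scale(env)
  dvec <- as.vector(community_d)

  results <- do.call(rbind, lapply(seq_len(min(max_subset_size, ncol(z))), function(size) {
    subsets <- utils::combn(colnames(z), size, simplify = FALSE)
    do.call(rbind, lapply(subsets, function(vars) {
      ed <- as.vector(stats::dist(z[, vars, drop = FALSE]))
      data.frame(subset = paste(vars, collapse = "+"), size = size,
                 rho = stats::cor(dvec, ed, method = "spearman"),
                 stringsAsFactors = FALSE)
    }))
  }))
  results <- results[order(-results$rho), ]
  rownames(results) <- NULL
  structure(list(
    best_subset = strsplit(results$subset[1L], "+", fixed = TRUE)[[1]],
    best_rho = results$rho[1L],
    results = results
  ), class = "bioenv_result")
}

#' @export
print.bioenv_result <- function(x, ...) {
  cat(sprintf("<bioenv_result> best subset {%s}, Spearman rho %.3f (%d subsets evaluated)\n",
              paste(x$best_subset, collapse = ", "), x$best_rho, nrow(x$results)))
  invisible(x)
}
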