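#' Pearson correlation of two abundance trajectories
#'
#' Sample Pearson correlation with a two-sided p-value from the
#' t-distribution, \eqn{t = r \sqrt{(n-2)/(1-r^2)}} at n - 2 degrees of
#' freedom — the linear correlation used to relate host and symbiont
#' abundance trajectories across the eruption cycle. A zero-variance series
#' yields an NA result with a \code{degenerate} flag rather than an error,
#' since constant organisms are expected in community-wide screens.
#'
#' @param x,y Numeric abundance series, length >= 3, finite.
#' @return List with \code{r}, \code{p}, \code{n}, \code{degenerate}.
#' @export
pearson_linear <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  r <- stats::cor(x, y)
  p <- r_to_p(r, n)
  list(r = r, p = p, n = n, degenerate = FALSE)
}

r_to_p <- function(r, n) {
  r2 <- pmin(r^2, 1 - .Machine$double.eps)
  t <- abs(r) * sqrt((n - 2) / (1 - r2))
  2 * stats::pt(t, df = n - 2, lower.tail = FALSE)
}

#' Screen organism pairs for correlated abundance trajectories
#'
#' Tests every unordered organism pair (or every pair involving a focus
#' organism) for Pearson correlation of their abundance trajectories, with
#' Benjamini-Hochberg correction over the tested pairs. Zero-variance
#' organisms are dropped from testing. The ranked output (ascending FDR,
#' then descending |r|) is the candidate list for putative host-symbiont
#' relationships.
#'
#' @param mat Abundance matrix (organisms x samples), >= 3 samples.
#' @param focus Optional organism id: restrict to pairs involving it.
#' @param alpha Significance level recorded in the \code{significant}
#'   column (default 0.05).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return Data frame of \code{CorrelationResult} rows: \code{organism_a},
#'   \code{organism_b}, \code{r}, \code{p}, \code{fdr_q},
#'   \code{n_samples}, \code{significant}, sorted by \code{fdr_q} then
#'   |r| descending.
#' @export
screen_pairs <- function(mat, focus = NULL, alpha = 0.05,
                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- ncol(mat)
  if (n < 3L) stop("need at least 3 samples")
  if (!is.null(focus) && !focus %in% rownames(mat))
    stop("focus organism '", focus, "' not in the abundance matrix")
  variable <- apply(mat, 1L, stats::sd) > 0
  m <- mat[variable, , drop = FALSE]
  cm <- stats::cor(t(m), method = method)

  if (is.null(focus)) {
    idx <- which(upper.tri(cm), arr.ind = TRUE)
  } else {
    if (!focus %in% rownames(m))
      stop("focus organism '", focus, "' has zero variance")
    fi <- match(focus, rownames(m))
    idx <- cbind(fi, setdiff(seq_len(nrow(m)), fi))
  }
  r <- cm[idx]
  p <- r_to_p(r, n)
  out <- data.frame(
    organism_a = rownames(m)[idx[, 1L]],
    organism_b = rownames(m)[idx[, 2L]],
    r = r, p = p, fdr_q = bh_fdr(p), n_samples = n,
    stringsAsFactors = FALSE)
  out$significant <- out$fdr_q < alpha
  out <- out[order(out$fdr_q, -abs(out$r)), ]
  rownames(out) <- NULL
  out
}
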