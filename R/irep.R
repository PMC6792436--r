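#' Sliding-window mean coverage
#'
#' Reduces a per-base depth series to mean depths over sliding windows, the
#' input to replication-rate estimation. The last partial window is
#' dropped.
#'
#' @param depth_per_base Numeric vector of per-base depths along the genome.
#' @param window_size Window length in bases (default 5000).
#' @param step Window step in bases (default 100).
#' @return A \code{coverage_profile} data frame (\code{window_start}
#'   0-based, \code{depth}).
#' @export
window_coverage <- function(depth_per_base, window_size = 5000L, step = 100L) {
  n <- length(depth_per_base)
  if (n < window_size)
    stop("genome shorter than one window (", n, " < ", window_size, ")")
  starts <- seq(0L, n - window_size, by = step)
  cs <- c(0, cumsum(depth_per_base))
  means <- (cs[starts + window_size + 1L] - cs[starts + 1L]) / window_size
  coverage_profile(window_start = starts, depth = means,
                   window_size = window_size, step = step)
}

#' Estimate the index of replication (iRep) from a coverage profile
#'
#' A population in which many cells are replicating shows higher sequencing
#' coverage near the replication origin than the terminus. Because contig
#' order does not reflect replication position, window depths are sorted
#' ascending; after discarding the lowest and highest \code{trim_fraction}
#' of windows, \code{log2(depth)} is regressed on relative rank position in
#' [0, 1] and iRep is the coverage ratio implied by the fitted line:
#' \code{2^(fit(1) - fit(0))}. A value of 1 means no replication; 2 means
#' the whole population is replicating once.
#'
#' @param profile A \code{coverage_profile} (or anything with a
#'   \code{depth} component).
#' @param trim_fraction Fraction of windows trimmed from each tail of the
#'   sorted depths (default 0.05).
#' @param min_depth Minimum mean depth for the estimate to pass QC
#'   (default 5).
#' @param min_r2 Minimum regression r-squared to pass QC (default 0.90).
#' @return A \code{replication_estimate}: list with \code{irep},
#'   \code{r_squared}, \code{mean_depth}, \code{passed_qc},
#'   \code{n_windows}. A perfectly flat profile is a perfect fit to a
#'   zero-slope line: \code{irep = 1}, \code{r_squared = 1}.
#' @export
estimate_irep <- function(profile, trim_fraction = 0.05, min_depth = 5,
                          min_r2 = 0.90) {
  depths <- profile$depth
  if (all(depths == 0)) stop("estimate_irep: no coverage (all depths zero)")
  mean_depth <- mean(depths)
  d <- sort(depths)
  n <- length(d)
  # rank positions span [0, 1] over ALL sorted windows; trimming removes the
  # tails of the line, and the origin/terminus ratio is read off the fit
  # extrapolated back to positions 0 and 1
  x <- seq(0, 1, length.out = n)
  k <- floor(trim_fraction * n)
  keep <- seq.int(k + 1L, n - k)
  keep <- keep[d[keep] > 0]  # log2 undefined at zero depth
  if (length(keep) < 10L) stop("estimate_irep: fewer than 10 windows after trimming")
  x <- x[keep]
  y <- log2(d[keep])
  if (stats::var(y) == 0) {
    est <- list(irep = 1, r_squared = 1, mean_depth = mean_depth,
                n_windows = length(keep))
  } else {
    slope <- stats::cov(x, y) / stats::var(x)
    est <- list(irep = 2^slope,
                r_squared = stats::cor(x, y)^2,
                mean_depth = mean_depth,
                n_windows = length(keep))
  }
  est$passed_qc <- est$mean_depth >= min_depth && est$r_squared >= min_r2
  structure(est, class = "replication_estimate")
}

#' @export
print.replication_estimate <- function(x, ...) {
  cat(sprintf("<replication_estimate> iRep %.3f (r2 %.3f, depth %.1fx, QC %s)\n",
              x$irep, x$r_squared, x$mean_depth,
              if (x$passed_qc) "pass" else "fail"))
  invisible(x)
}

#' iRep estimates for many genome/sample depth series
#'
#' @param depth_list Named list of per-base depth vectors (one per genome),
#'   e.g. the \code{depth} component of \code{\link{ingest_depth}}.
#' @param window_size,step Passed to \code{\link{window_coverage}}.
#' @param trim_fraction,min_depth,min_r2 Passed to
#'   \code{\link{estimate_irep}}.
#' @return Data frame with one row per genome: iRep, r-squared, mean depth,
#'   QC flag.
#' @export
irep_table <- function(depth_list, window_size = 5000L, step = 100L,
                       trim_fraction = 0.05, min_depth = 5, min_r2 = 0.90) {
  do.call(rbind, lapply(names(depth_list), function(gn) {
    est <- tryCatch({
      prof <- window_coverage(depth_list[[gn]], window_size, step)
      estimate_irep(prof, trim_fraction, min_depth, min_r2)
    }, error = function(e) NULL)
    if (is.null(est))
      return(data.frame(genome = gn, irep = NA_real_, r_squared = NA_real_,
                        mean_depth = NA_real_, passed_qc = FALSE,
                        stringsAsFactors = FALSE))
    data.frame(genome = gn, irep = est$irep, r_squared = est$r_squared,
               mean_depth = est$mean_depth, passed_qc = est$passed_qc,
               stringsAsFactors = FALSE)
  }))
}
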