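#' Simulate community abundances across the eruption cycle
#'
#' Forward model for the organisms x samples abundance structure. Each
#' organism has a lognormal baseline abundance; organisms planted as
#' enriched have their mean multiplied by the spec's effect size within
#' their phase; every cell receives lognormal multiplicative noise
#' (mean-preserving). Symbiont trajectories are mixtures of the host
#' trajectory and independent noise at the specified correlation strength,
#' rescaled to the symbiont's own baseline. Per-sample read totals are drawn
#' uniformly from the spec's range and mapped-read counts are derived from
#' the true abundances, so the normalization stage is exercised with
#' unequal sequencing depths.
#'
#' @param spec A \code{\link{community_spec}}.
#' @return A list with components:
#'   \describe{
#'     \item{abundance}{normalized abundance matrix (organisms x samples)
#'       built from the simulated counts via \code{\link{build_matrix}}}
#'     \item{counts}{mapping-counts data frame (\code{sample}, \code{genome},
#'       \code{r}, \code{N_s}, \code{l}, \code{g})}
#'     \item{metadata}{sample metadata with phase labels, collection
#'       windows, and environmental variables (see Details)}
#'     \item{truth}{planted structure: true abundance matrix, baselines,
#'       enriched sets, symbiont pairs, genome lengths}
#'   }
#' @details Environmental variables attached to the metadata are a
#' deterministic time surrogate (\code{time_h}, the collection-window
#' midpoint) plus measurement-noise-dominated variables (temperature,
#' electrical conductivity, calcium, iron, sodium) that carry no planted
#' relation to community structure, emulating the finding that time alone,
#' not geochemistry, tracked the compositional trajectory.
#' @export
simulate_abundance <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  ids <- spec$organism_ids
  n_org <- spec$n_organisms
  n_smp <- spec$n_samples
  phases <- spec$phase_assignment
  sdlog <- spec$abundance_noise

  baseline <- stats::rlnorm(n_org, meanlog = log(0.1), sdlog = 1.5)
  names(baseline) <- ids

  mu <- matrix(baseline, n_org, n_smp, dimnames = list(ids, NULL))
  for (ph in names(spec$enriched_sets)) {
    orgs <- spec$enriched_sets[[ph]]
    mu[orgs, phases == ph] <- mu[orgs, phases == ph] * spec$effect_size
  }
  noise <- matrix(stats::rlnorm(n_org * n_smp, meanlog = -sdlog^2 / 2, sdlog = sdlog),
                  n_org, n_smp)
  a_true <- mu * noise

  if (!is.null(spec$symbiont_pairs)) {
    for (r in seq_len(nrow(spec$symbiont_pairs))) {
      host <- spec$symbiont_pairs$host[r]
      sym <- spec$symbiont_pairs$symbiont[r]
      s <- spec$symbiont_pairs$strength[r]
      host_tr <- a_true[host, ]
      indep <- a_true[sym, ]
      mix <- s * host_tr / mean(host_tr) + (1 - s) * indep / mean(indep)
      a_true[sym, ] <- mix / mean(mix) * baseline[sym]
    }
  }

  sample_ids <- sprintf("s%02d", seq_len(n_smp))
  colnames(a_true) <- sample_ids

  n_s <- round(stats::runif(n_smp, spec$read_total_range[1], spec$read_total_range[2]))
  n_m <- max(n_s)
  g_len <- round(stats::runif(n_org, 1e6, 5e6))
  names(g_len) <- ids
  read_len <- 150

  # invert the A_r normalization to get integer mapped-read counts
  r_counts <- round(sweep(a_true * g_len / read_len, 2, n_s / n_m, `*`))
  counts <- data.frame(
    sample = rep(sample_ids, each = n_org),
    genome = rep(ids, times = n_smp),
    r = as.vector(r_counts),
    N_s = rep(n_s, each = n_org),
    l = read_len,
    g = rep(g_len, times = n_smp),
    stringsAsFactors = FALSE)

  window_h <- 114 / n_smp
  start_h <- (seq_len(n_smp) - 1L) * window_h
  metadata <- data.frame(
    sample = sample_ids,
    phase = phases,
    window_start = start_h,
    window_end = start_h + window_h,
    time_h = start_h + window_h / 2,
    temperature = 16.9 + stats::rnorm(n_smp, 0, 0.3),
    electrical_conductivity = 30 + stats::rnorm(n_smp, 0, 3),
    calcium = 450 + stats::rnorm(n_smp, 0, 40),
    iron = 2 + stats::rnorm(n_smp, 0, 0.5),
    sodium = 2500 + stats::rnorm(n_smp, 0, 200),
    stringsAsFactors = FALSE)

  list(abundance = build_matrix(counts),
       counts = counts,
       metadata = metadata,
       truth = list(abundance = a_true, baseline = baseline,
                    enriched_sets = spec$enriched_sets,
                    symbiont_pairs = spec$symbiont_pairs,
                    genome_lengths = g_len, read_totals = n_s))
}

#' Simulate a coverage profile with a planted replication signal
#'
#' Generates per-window sequencing depths whose expectation declines
#' log2-linearly from replication origin to terminus with a total span of
#' \code{log2(irep_true)} — the signature of bidirectional genome
#' replication in a growing population. Window order is randomly permuted,
#' since assembled contig order carries no information about replication
#' position; the estimator must sort.
#'
#' @param genome_length Genome length in bases; must hold at least one
#'   window.
#' @param irep_true Planted origin-to-terminus coverage ratio (>= 1); 1
#'   means no replication.
#' @param mean_depth Mean fold-coverage over the genome.
#' @param noise_sd Standard deviation of the sub-window depth noise
#'   (fold-coverage units), injected per step-sized block of the genome and
#'   smoothed by window averaging — overlapping sliding windows share most
#'   of their reads, so window-level noise is strongly autocorrelated, as in
#'   real mapped-read depth. Negative depths are truncated at 0.
#' @param seed Random seed.
#' @param window_size,step Window geometry in bases.
#' @return A \code{coverage_profile} data frame (\code{window_start},
#'   \code{depth}) with attributes recording the geometry and the planted
#'   \code{irep_true}.
#' @export
simulate_coverage <- function(genome_length, irep_true, mean_depth,
                              noise_sd = 0, seed = 1L,
                              window_size = 5000L, step = 100L) {
  stopifnot(irep_true >= 1, mean_depth > 0)
  if (genome_length < window_size)
    stop("genome shorter than one window (", genome_length, " < ", window_size, ")")
  set.seed(seed)
  starts <- seq(0L, genome_length - window_size, by = step)
  n_win <- length(starts)
  x <- seq(0, 1, length.out = n_win)  # relative window position, origin = 0
  expected <- 2^(log2(irep_true) * (1 - x))
  expected <- expected / mean(expected) * mean_depth
  # per-block noise averaged over the blocks each window spans
  bpw <- max(1L, window_size %/% step)
  blocks <- stats::rnorm(n_win + bpw - 1L, 0, noise_sd)
  cs <- c(0, cumsum(blocks))
  win_noise <- (cs[seq_len(n_win) + bpw] - cs[seq_len(n_win)]) / bpw
  depth <- pmax(0, expected + win_noise)
  perm <- sample(n_win)
  coverage_profile(window_start = starts, depth = depth[perm],
                   window_size = window_size, step = step,
                   irep_true = irep_true)
}

coverage_profile <- function(window_start, depth, window_size, step, ...) {
  stopifnot(all(depth >= 0), length(window_start) == length(depth))
  structure(data.frame(window_start = window_start, depth = depth),
            window_size = window_size, step = step, ...,
            class = c("coverage_profile", "data.frame"))
}
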