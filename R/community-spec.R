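#' Specify a synthetic geyser community
#'
#' A community specification fixes everything the abundance simulator needs:
#' community and sample sizes, the ordered phase design, which organisms are
#' planted as enriched in which source-depth phase, host-symbiont pairs with
#' their trajectory correlation strength, and the noise model dispersion.
#'
#' Samples form three contiguous ordered blocks mirroring the eruption
#' cycle: the recovery phase (intermediate-depth source water), minor
#' eruptions (deep source) and major eruptions (shallow source). Phases are
#' labelled by source depth: \code{"intermediate"}, \code{"deep"},
#' \code{"shallow"}.
#'
#' @param n_organisms Number of organisms in the community.
#' @param phase_lengths Integer vector of block lengths for the
#'   intermediate, deep and shallow phases, in cycle order (default
#'   \code{c(7, 11, 7)}, 25 samples in total).
#' @param enriched_sets Named list mapping phase label to the organism ids
#'   planted as enriched in that phase.
#' @param symbiont_pairs Data frame with columns \code{host},
#'   \code{symbiont}, \code{strength} (correlation strength in [0, 1]).
#' @param effect_size Fold elevation of an enriched organism's mean
#'   abundance in its phase relative to the other phases.
#' @param abundance_noise Dispersion (sdlog) of the lognormal multiplicative
#'   noise applied to every organism-sample abundance.
#' @param read_total_range Range the per-sample read totals are drawn from
#'   uniformly, so normalization is exercised with unequal depths.
#' @param seed Random seed.
#' @return An object of class \code{community_spec}.
#' @export
community_spec <- function(n_organisms = 500L,
                           phase_lengths = c(intermediate = 7L, deep = 11L, shallow = 7L),
                           enriched_sets = list(),
                           symbiont_pairs = NULL,
                           effect_size = 8,
                           abundance_noise = 0.5,
                           read_total_range = c(1e6, 1e8),
                           seed = 1L) {
  stopifnot(n_organisms >= 1, length(phase_lengths) == 3L, all(phase_lengths >= 2))
  ids <- organism_ids(n_organisms)
  phases <- c("intermediate", "deep", "shallow")
  names(phase_lengths) <- phases
  if (length(enriched_sets)) {
    if (!all(names(enriched_sets) %in% phases))
      stop("enriched_sets names must be phase labels: ", paste(phases, collapse = ", "))
    unknown <- setdiff(unlist(enriched_sets), ids)
    if (length(unknown))
      stop("enriched organism ids not in the community: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (!is.null(symbiont_pairs)) {
    stopifnot(is.data.frame(symbiont_pairs),
              all(c("host", "symbiont", "strength") %in% names(symbiont_pairs)))
    if (any(symbiont_pairs$strength < 0 | symbiont_pairs$strength > 1))
      stop("symbiont correlation strength must be in [0, 1]")
    unknown <- setdiff(c(symbiont_pairs$host, symbiont_pairs$symbiont), ids)
    if (length(unknown))
      stop("symbiont pair ids not in the community: ", paste(unknown, collapse = ", "))
  }
  structure(list(
    n_organisms = as.integer(n_organisms),
    organism_ids = ids,
    n_samples = sum(phase_lengths),
    phase_lengths = phase_lengths,
    phase_assignment = rep(phases, times = phase_lengths),
    enriched_sets = enriched_sets,
    symbiont_pairs = symbiont_pairs,
    effect_size = effect_size,
    abundance_noise = abundance_noise,
    read_total_range = read_total_range,
    seed = as.integer(seed)
  ), class = "community_spec")
}

organism_ids <- function(n) sprintf("org%04d", seq_len(n))

#' Default synthetic community mirroring the geyser study design
#'
#' 500 organisms over 25 samples in three ordered phase blocks (7
#' intermediate, 11 deep, 7 shallow). About 57% of organisms are planted as
#' enriched in one phase, split across the phases, matching the fraction of
#' organisms that could be sourced to a depth in the real community. One
#' host-symbiont pair is planted at correlation strength 0.95, with the host
#' among the deep-enriched organisms.
#'
#' @param seed Random seed controlling which organisms are enriched where.
#' @param n_organisms Community size (default 500).
#' @param symbiont_strength Trajectory correlation strength of the planted
#'   pair (default 0.95).
#' @param effect_size,abundance_noise Passed to \code{\link{community_spec}}.
#' @return A \code{community_spec}.
#' @export
default_community_spec <- function(seed = 1L, n_organisms = 500L,
                                   symbiont_strength = 0.95,
                                   effect_size = 8, abundance_noise = 0.5) {
  set.seed(seed)
  ids <- organism_ids(n_organisms)
  n_enriched <- round(0.57 * n_organisms)
  enriched <- sample(ids, n_enriched)
  # larger share to the intermediate phase, as in the observed community
  split_sizes <- round(n_enriched * c(intermediate = 0.42, deep = 0.35))
  phase_of <- rep(c("intermediate", "deep", "shallow"),
                  c(split_sizes, n_enriched - sum(split_sizes)))
  sets <- split(enriched, phase_of)
  host <- sets$deep[1L]
  symbiont <- sets$deep[2L]
  community_spec(
    n_organisms = n_organisms,
    enriched_sets = sets,
    symbiont_pairs = data.frame(host = host, symbiont = symbiont,
                                strength = symbiont_strength,
                                stringsAsFactors = FALSE),
    effect_size = effect_size,
    abundance_noise = abundance_noise,
    seed = seed)
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf(
    "<community_spec> %d organisms x %d samples (phases %s); %d enriched; %d symbiont pair(s)\n",
    x$n_organisms, x$n_samples,
    paste(x$phase_lengths, collapse = "/"),
    length(unlist(x$enriched_sets)),
    if (is.null(x$symbiont_pairs)) 0L else nrow(x$symbiont_pairs)))
  invisible(x)
}
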