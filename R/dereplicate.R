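#' Dereplicate genome bins into species-level clusters
#'
#' Single-linkage clustering of bins over alignment edges at or above the
#' nucleotide-identity threshold (default 98%) and aligned-fraction
#' requirement. Within each cluster, the representative is the member with
#' the highest quality score (\code{scg - 2 * mscg}); ties are broken by
#' highest N50, then lexicographic id for determinism. Clusters partition
#' the input: every bin lands in exactly one cluster, unaligned bins as
#' singletons.
#'
#' @param bins List of \code{genome_bin} objects.
#' @param summaries Data frame of pairwise alignment summaries (columns
#'   \code{query}, \code{target}, \code{aligned_fraction_of_query},
#'   \code{mean_identity}); missing pairs are treated as non-matching.
#' @param identity_threshold Minimum mean nucleotide identity for an edge
#'   (default 0.98).
#' @param linkage_fraction Minimum aligned fraction of the query for an edge
#'   (default 0.30).
#' @return List of clusters, each a list with \code{members} (bin ids),
#'   \code{representative} (bin id) and \code{identity_threshold}.
#' @export
dereplicate <- function(bins, summaries, identity_threshold = 0.98,
                        linkage_fraction = 0.30) {
  ids <- vapply(bins, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate bin ids")
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }

  if (!is.null(summaries) && nrow(summaries) > 0) {
    edges <- summaries[
      summaries$mean_identity >= identity_threshold &
      summaries$aligned_fraction_of_query >= linkage_fraction &
      summaries$query %in% ids & summaries$target %in% ids, , drop = FALSE]
    for (r in seq_len(nrow(edges))) {
      i <- find(match(edges$query[r], ids))
      j <- find(match(edges$target[r], ids))
      if (i != j) parent[max(i, j)] <- min(i, j)
    }
  }

  roots <- vapply(seq_along(ids), find, integer(1))
  lapply(unname(split(seq_along(ids), roots)), function(members) {
    list(members = ids[members],
         representative = choose_representative(bins[members]),
         identity_threshold = identity_threshold)
  })
}

# Highest score, then highest N50, then lexicographic id.
choose_representative <- function(members) {
  scores <- vapply(members, bin_score, numeric(1))
  n50s <- vapply(members, `[[`, numeric(1), "n50")
  ids <- vapply(members, `[[`, character(1), "id")
  ord <- order(-scores, -n50s, ids)
  ids[ord[1L]]
}

#' Cluster membership table
#'
#' @param clusters Output of \code{\link{dereplicate}}.
#' @return Data frame with columns \code{cluster}, \code{member},
#'   \code{representative}, \code{is_representative}.
#' @export
cluster_table <- function(clusters) {
  do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster = i, member = cl$members,
               representative = cl$representative,
               is_representative = cl$members == cl$representative,
               stringsAsFactors = FALSE)
  }))
}

#' Match single amplified genomes to metagenome-derived genomes
#'
#' A SAG is considered represented by a MAG when it shares more than 30% of
#' its genomic content (aligned fraction of the SAG) with a MAG that is at
#' least 70% complete, at the dereplication identity level (98%). Among
#' qualifying MAGs the one with the highest aligned fraction wins. Unmatched
#' SAGs of draft quality are flagged for addition to the genome database.
#'
#' @param sags List of \code{genome_bin} objects (queries).
#' @param mags List of \code{genome_bin} objects (targets).
#' @param summaries Pairwise alignment summaries with SAG ids as
#'   \code{query} and MAG ids as \code{target}.
#' @param min_aligned_fraction Strict lower bound on the SAG's aligned
#'   fraction (default 0.30).
#' @param min_identity Minimum mean identity (default 0.98).
#' @param min_mag_completeness Minimum completeness of the matched MAG
#'   (default 0.70, inclusive).
#' @return Data frame with one row per SAG: \code{sag}, \code{mag} (NA when
#'   unmatched), \code{aligned_fraction}, \code{identity},
#'   \code{add_to_database} (TRUE for unmatched draft-quality SAGs).
#' @export
match_sags <- function(sags, mags, summaries, min_aligned_fraction = 0.30,
                       min_identity = 0.98, min_mag_completeness = 0.70) {
  mag_ids <- vapply(mags, `[[`, character(1), "id")
  mag_ok <- mag_ids[vapply(mags, completeness, numeric(1)) >= min_mag_completeness]
  do.call(rbind, lapply(sags, function(sag) {
    cand <- summaries[
      summaries$query == sag$id & summaries$target %in% mag_ok &
      summaries$mean_identity >= min_identity &
      summaries$aligned_fraction_of_query > min_aligned_fraction, , drop = FALSE]
    if (nrow(cand) > 0) {
      best <- cand[order(-cand$aligned_fraction_of_query, cand$target), ][1L, ]
      data.frame(sag = sag$id, mag = best$target,
                 aligned_fraction = best$aligned_fraction_of_query,
                 identity = best$mean_identity, add_to_database = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sag = sag$id, mag = NA_character_,
                 aligned_fraction = NA_real_, identity = NA_real_,
                 add_to_database = completeness(sag) > 0.70 && sag$mscg_count <= 2L,
                 stringsAsFactors = FALSE)
    }
  }))
}
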