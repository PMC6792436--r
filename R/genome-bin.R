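#' Single-copy marker gene sets
#'
#' Identifiers for the domain-specific single-copy gene (SCG) marker sets used
#' to estimate genome bin completeness and contamination: 51 markers for
#' Bacteria and 38 for Archaea. The first sixteen bacterial entries are the
#' ribosomal proteins also used for concatenated marker alignments; the
#' remainder are generic placeholder identifiers standing in for the rest of
#' the published marker panels, which downstream code treats as opaque labels.
#'
#' @format Character vectors of marker identifiers.
#' @name marker_sets
NULL

#' @rdname marker_sets
#' @export
bacterial_scg_set <- function() {
  c("rpL2", "rpL3", "rpL4", "rpL5", "rpL6", "rpL14", "rpL15", "rpL16",
    "rpL18", "rpL22", "rpL24", "rpS3", "rpS8", "rpS10", "rpS17", "rpS19",
    paste0("bscg", sprintf("%02d", 17:51)))
}

#' @rdname marker_sets
#' @export
archaeal_scg_set <- function() {
  c("rpL2", "rpL3", "rpL4", "rpL5", "rpL6", "rpL14", "rpL15", "rpL16",
    "rpL18", "rpL22", "rpL24", "rpS3", "rpS8", "rpS10", "rpS17", "rpS19",
    paste0("ascg", sprintf("%02d", 17:38)))
}

scg_set_for <- function(domain) {
  switch(domain,
    bacterial = bacterial_scg_set(),
    archaeal  = archaeal_scg_set(),
    stop("unknown domain: ", domain, " (must be 'bacterial' or 'archaeal')")
  )
}

#' Construct a genome bin
#'
#' A genome bin is a set of contigs together with single-copy marker gene
#' counts. Length statistics (total length, N50) are derived from the contig
#' table at construction time.
#'
#' @param id Bin identifier.
#' @param contigs Data frame with columns \code{contig} and \code{length}
#'   (bases).
#' @param scg_count Number of distinct single-copy genes present.
#' @param mscg_count Number of single-copy genes present in multiple copies
#'   (must not exceed \code{scg_count}).
#' @param domain \code{"bacterial"} or \code{"archaeal"}; selects the marker
#'   set size (51 or 38) used for completeness.
#' @param seqs Optional \code{DNAStringSet} of contig sequences, named by
#'   contig identifier.
#' @return An object of class \code{genome_bin}.
#' @export
genome_bin <- function(id, contigs, scg_count, mscg_count,
                       domain = c("bacterial", "archaeal"), seqs = NULL) {
  domain <- match.arg(domain)
  stopifnot(is.data.frame(contigs), all(c("contig", "length") %in% names(contigs)))
  if (mscg_count > scg_count)
    stop("mscg_count (", mscg_count, ") exceeds scg_count (", scg_count, ")")
  if (scg_count > length(scg_set_for(domain)))
    stop("scg_count exceeds the ", domain, " marker-set size")
  structure(list(
    id = as.character(id),
    contigs = contigs[, c("contig", "length")],
    scg_count = as.integer(scg_count),
    mscg_count = as.integer(mscg_count),
    domain = domain,
    n50 = n50(contigs$length),
    total_length = sum(as.numeric(contigs$length)),
    seqs = seqs
  ), class = "genome_bin")
}

#' @export
print.genome_bin <- function(x, ...) {
  cat(sprintf(
    "<genome_bin> %s: %d contigs, %.0f bp (N50 %.0f), %s, SCG %d (multi %d), score %d\n",
    x$id, nrow(x$contigs), x$total_length, x$n50, x$domain,
    x$scg_count, x$mscg_count, bin_score(x)))
  invisible(x)
}

#' N50 of a set of contig lengths
#'
#' Length of the shortest contig in the smallest set of longest contigs
#' covering at least half the total assembly length.
#'
#' @param lengths Numeric vector of contig lengths.
#' @return The N50 in bases.
#' @export
n50 <- function(lengths) {
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  if (length(lengths) == 0L) return(0)
  lengths[which(cumsum(lengths) >= sum(lengths) / 2)[1L]]
}

#' Bin quality score
#'
#' Score used to rank bins within a dereplication cluster:
#' \code{scg_count - 2 * mscg_count}. Higher is better; the score rewards
#' completeness (distinct single-copy genes) and penalizes contamination
#' (single-copy genes present in multiple copies) twice as strongly. May be
#' negative.
#'
#' @param bin A \code{genome_bin}.
#' @return Integer score.
#' @export
bin_score <- function(bin) {
  bin$scg_count - 2L * bin$mscg_count
}

#' Bin completeness from single-copy genes
#'
#' Fraction of the domain marker set (51 bacterial or 38 archaeal single-copy
#' genes) detected in the bin.
#'
#' @param bin A \code{genome_bin} with its \code{domain} set.
#' @return Completeness fraction in [0, 1].
#' @export
completeness <- function(bin) {
  bin$scg_count / length(scg_set_for(bin$domain))
}

#' Filter bins to draft quality
#'
#' Retains bins with completeness strictly greater than
#' \code{min_completeness} and at most \code{max_mscg} multiply-present
#' single-copy genes. The defaults encode the medium-quality draft rule:
#' more than 70% complete with fewer than three multiple single-copy genes.
#' Input order is preserved.
#'
#' @param bins List of \code{genome_bin} objects.
#' @param min_completeness Completeness threshold (strict \code{>}).
#' @param max_mscg Maximum allowed multiple single-copy genes (inclusive).
#' @return The retained sub-list of \code{bins}.
#' @export
quality_filter <- function(bins, min_completeness = 0.70, max_mscg = 2L) {
  keep <- vapply(bins, function(b) {
    completeness(b) > min_completeness && b$mscg_count <= max_mscg
  }, logical(1))
  bins[keep]
}

#' Per-bin quality table
#'
#' @param bins List of \code{genome_bin} objects.
#' @return Data frame with one row per bin: id, domain, contig count, total
#'   length, N50, SCG counts, completeness, score, and draft-quality flag.
#' @export
bin_quality_table <- function(bins) {
  df <- do.call(rbind, lapply(bins, function(b) {
    data.frame(
      id = b$id, domain = b$domain, n_contigs = nrow(b$contigs),
      total_length = b$total_length, n50 = b$n50,
      scg_count = b$scg_count, mscg_count = b$mscg_count,
      completeness = completeness(b), score = bin_score(b),
      draft_quality = completeness(b) > 0.70 && b$mscg_count <= 2L,
      stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df
}
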