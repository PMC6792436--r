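#' Pairwise nucleotide identity by fragment mapping
#'
#' Estimates average nucleotide identity (ANI) and aligned fraction between
#' two genomes. The query is cut into fragments; each fragment is placed on
#' the target by shared k-mer anchors (both strands), then globally aligned
#' to the anchored target window with \code{Biostrings::pairwiseAlignment}.
#' The summary reports the fragment-length-weighted mean identity over mapped
#' fragments and the fraction of the query covered by mapped fragments. This
#' is the fragment-mapping ANI scheme common in genome dereplication tools;
#' the contract is the (identity, aligned fraction) summary, not a particular
#' aligner.
#'
#' @param a Query genome: a \code{DNAStringSet}, \code{DNAString}, or
#'   character vector of contig sequences.
#' @param b Target genome, same accepted types.
#' @param k Anchor word size (default 15).
#' @param fragment_size Query fragment length in bases (default 1000).
#' @param query_id,target_id Identifiers recorded in the summary.
#' @return A one-row data frame (class \code{pairwise_alignment_summary})
#'   with columns \code{query}, \code{target},
#'   \code{aligned_fraction_of_query} and \code{mean_identity}, both
#'   fractions in [0, 1].
#' @export
pairwise_identity <- function(a, b, k = 15L, fragment_size = 1000L,
                              query_id = "query", target_id = "target") {
  a <- as_dna_set(a)
  b <- as_dna_set(b)
  if (sum(Biostrings::width(a)) == 0L || sum(Biostrings::width(b)) == 0L)
    stop("pairwise_identity: empty sequence")

  index <- kmer_index(b, k)
  total_q <- sum(Biostrings::width(a))
  mapped_len <- 0
  id_weighted <- 0

  for (ci in seq_along(a)) {
    contig <- as.character(a[[ci]])
    n <- nchar(contig)
    starts <- seq(1L, n, by = fragment_size)
    for (s in starts) {
      e <- min(s + fragment_size - 1L, n)
      frag <- substr(contig, s, e)
      hit <- place_fragment(frag, index, k)
      if (is.null(hit)) next
      pid <- align_fragment(frag, hit)
      if (is.na(pid)) next
      w <- e - s + 1L
      mapped_len <- mapped_len + w
      id_weighted <- id_weighted + pid * w
    }
  }

  structure(data.frame(
    query = query_id, target = target_id,
    aligned_fraction_of_query = mapped_len / total_q,
    mean_identity = if (mapped_len > 0) id_weighted / mapped_len else 0,
    stringsAsFactors = FALSE
  ), class = c("pairwise_alignment_summary", "data.frame"))
}

as_dna_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (methods::is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  Biostrings::DNAStringSet(as.character(x))
}

# Hash of target k-mer -> positions in a single concatenated coordinate
# system; contigs are padded apart so anchors never chain across a junction.
kmer_index <- function(seqs, k) {
  seq1 <- paste(as.character(seqs), collapse = strrep("N", k))
  n <- nchar(seq1)
  if (n < k) return(list(map = list(), seq = seq1))
  words <- substring(seq1, 1:(n - k + 1L), k:n)
  ok <- !grepl("N", words, fixed = TRUE)
  list(map = split(which(ok), words[ok]), seq = seq1)
}

# Anchor a fragment on the indexed target: sample k-mers along the fragment
# on both strands, vote on the (target - query) offset, and return the target
# window under the winning offset. NULL when too few anchors agree.
place_fragment <- function(frag, index, k, stride = 50L, min_anchors = 3L,
                           pad = 100L) {
  # fragments shorter than the word size: fall back to exact search
  if (nchar(frag) < k) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
    for (fr in c(frag, rc)) {
      hit <- regexpr(fr, index$seq, fixed = TRUE)
      if (hit > 0)
        return(list(strand = "fwd", offset = hit - 1L, support = 1L,
                    window = fr, frag_oriented = fr))
    }
    return(NULL)
  }
  best <- NULL
  for (strand in c("fwd", "rev")) {
    fr <- if (strand == "fwd") frag else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
    n <- nchar(fr)
    qpos <- unique(c(seq(1L, n - k + 1L, by = stride), n - k + 1L))
    min_anchors <- min(min_anchors, length(qpos))
    words <- substring(fr, qpos, qpos + k - 1L)
    offs <- unlist(lapply(seq_along(qpos), function(i) {
      tp <- index$map[[words[i]]]
      if (is.null(tp)) return(integer(0))
      tp - qpos[i]
    }))
    if (length(offs) == 0L) next
    # allow small indel wobble by binning offsets
    tab <- table(round(offs / 20))
    support <- max(tab)
    if (support < min_anchors) next
    if (is.null(best) || support > best$support) {
      off <- as.integer(names(tab)[which.max(tab)]) * 20L
      best <- list(strand = strand, offset = off, support = support,
                   window = substr(index$seq,
                                   max(1L, off + 1L - pad),
                                   min(nchar(index$seq), off + n + pad)))
    }
  }
  if (is.null(best)) return(NULL)
  best$frag_oriented <- if (best$strand == "fwd") frag else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(frag)))
  best
}

# Global-local alignment of the oriented fragment against its target window;
# identity = matches / alignment length (gaps count against identity).
align_fragment <- function(frag, hit) {
  win <- gsub("N", "", hit$window, fixed = TRUE)
  if (nchar(win) < 0.5 * nchar(frag)) return(NA_real_)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(hit$frag_oriented), Biostrings::DNAString(win),
    type = "global-local")
  Biostrings::pid(aln, type = "PID1") / 100
}

#' All-vs-all pairwise identity summaries
#'
#' Computes \code{\link{pairwise_identity}} for every ordered pair of bins
#' that carry sequences, as input to \code{\link{dereplicate}} and
#' \code{\link{match_sags}}.
#'
#' @param bins List of \code{genome_bin} objects with non-NULL \code{seqs}.
#' @param ... Passed to \code{\link{pairwise_identity}}.
#' @return Data frame of pairwise summaries, both directions per pair.
#' @export
all_vs_all_identity <- function(bins, ...) {
  ids <- vapply(bins, `[[`, character(1), "id")
  out <- list()
  for (i in seq_along(bins)) for (j in seq_along(bins)) {
    if (i == j) next
    out[[length(out) + 1L]] <- pairwise_identity(
      bins[[i]]$seqs, bins[[j]]$seqs,
      query_id = ids[i], target_id = ids[j], ...)
  }
  do.call(rbind, out)
}
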