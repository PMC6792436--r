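#' Simulate source genomes
#'
#' Generates random genomes as contig sets with single-copy marker genes
#' placed on random contigs. These are the ground truth from which
#' \code{\link{simulate_bins}} derives bins of varying completeness and
#' contamination.
#'
#' @param n Number of genomes.
#' @param genome_length Total genome length in bases (recycled).
#' @param n_contigs Contigs per genome (recycled); genomes are split at
#'   uniform-random breakpoints.
#' @param domain \code{"bacterial"} or \code{"archaeal"} (recycled); selects
#'   the 51- or 38-marker single-copy gene set, all of which are placed
#'   (complete genomes).
#' @param seed Random seed; identical seeds reproduce identical genomes.
#' @return List of \code{synthetic_genome} objects: \code{id}, \code{seqs}
#'   (\code{DNAStringSet} of contigs), \code{contigs} (data frame),
#'   \code{markers} (data frame marker -> contig), \code{domain}.
#' @export
simulate_genomes <- function(n, genome_length = 20000L, n_contigs = 20L,
                             domain = "bacterial", seed = 1L) {
  stopifnot(n >= 1)
  set.seed(seed)
  genome_length <- rep_len(as.integer(genome_length), n)
  n_contigs <- rep_len(as.integer(n_contigs), n)
  domain <- rep_len(domain, n)
  lapply(seq_len(n), function(i) {
    len <- genome_length[i]
    nc <- min(n_contigs[i], len)
    seq_chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    # uniform-random internal breakpoints
    breaks <- sort(sample(seq_len(len - 1L), nc - 1L))
    starts <- c(1L, breaks + 1L)
    ends <- c(breaks, len)
    contig_ids <- sprintf("g%03d_c%03d", i, seq_len(nc))
    seqs <- Biostrings::DNAStringSet(vapply(seq_len(nc), function(j)
      paste(seq_chars[starts[j]:ends[j]], collapse = ""), character(1)))
    names(seqs) <- contig_ids
    markers <- scg_set_for(domain[i])
    structure(list(
      id = sprintf("genome%03d", i),
      seqs = seqs,
      contigs = data.frame(contig = contig_ids, length = ends - starts + 1L,
                           stringsAsFactors = FALSE),
      markers = data.frame(marker = markers,
                           contig = sample(contig_ids, length(markers), replace = TRUE),
                           stringsAsFactors = FALSE),
      domain = domain[i]
    ), class = "synthetic_genome")
  })
}

#' Mutate a genome by uniform random substitutions
#'
#' Each base is substituted, independently with probability \code{rate}, by
#' one of the three other bases. Used to plant known divergence between
#' genome copies for identity and dereplication tests.
#'
#' @param genome A \code{synthetic_genome}.
#' @param rate Per-base substitution probability.
#' @param seed Random seed.
#' @param id Identifier of the mutated copy.
#' @return A \code{synthetic_genome} with mutated sequences and an attribute
#'   \code{n_substitutions} recording the planted count.
#' @export
mutate_genome <- function(genome, rate, seed = 1L, id = paste0(genome$id, "_mut")) {
  set.seed(seed)
  total_subs <- 0L
  seqs <- genome$seqs
  out <- vapply(seq_along(seqs), function(j) {
    s <- strsplit(as.character(seqs[[j]]), "")[[1]]
    hit <- which(stats::runif(length(s)) < rate)
    total_subs <<- total_subs + length(hit)
    for (p in hit) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
    paste(s, collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(out)
  names(out) <- names(seqs)
  mutated <- genome
  mutated$id <- id
  mutated$seqs <- out
  attr(mutated, "n_substitutions") <- total_subs
  mutated
}

#' Derive genome bins from source genomes
#'
#' Each bin retains a random contig subset of one source genome reaching a
#' target completeness (fraction of genome length, drawn uniformly from
#' \code{completeness_range}), optionally plus contaminant contigs from a
#' different genome: every contig of one randomly chosen donor genome is
#' included independently with probability \code{contamination_rate}.
#' Single-copy gene presence and duplication are recomputed from the
#' retained contigs, so contamination by a donor sharing markers produces
#' multiple single-copy genes.
#'
#' @param source_genomes Non-empty list of \code{synthetic_genome}s.
#' @param completeness_range Interval in (0, 1] for the target length
#'   fraction retained.
#' @param contamination_rate Per-donor-contig inclusion probability in
#'   [0, 1).
#' @param replicates_per_genome Bins derived per source genome.
#' @param seed Random seed; identical seeds give bit-identical bins.
#' @return List of \code{genome_bin} objects carrying sequences; each has
#'   attributes \code{source} (truth) and \code{target_completeness}.
#' @export
simulate_bins <- function(source_genomes, completeness_range = c(0.7, 1),
                          contamination_rate = 0, replicates_per_genome = 1L,
                          seed = 1L) {
  if (length(source_genomes) == 0L) stop("simulate_bins: empty source genome list")
  stopifnot(completeness_range[1] > 0, completeness_range[2] <= 1,
            replicates_per_genome >= 1)
  set.seed(seed)
  bins <- list()
  for (gi in seq_along(source_genomes)) {
    g <- source_genomes[[gi]]
    for (rep_i in seq_len(replicates_per_genome)) {
      target <- stats::runif(1, completeness_range[1], completeness_range[2])
      total <- sum(g$contigs$length)
      ord <- sample(nrow(g$contigs))
      if (target >= 1) {
        keep <- ord
      } else {
        # include whole contigs up to the target length; the contig that
        # crosses the target is included with probability equal to the
        # remaining length fraction, so E[retained length] = target * total
        cum <- cumsum(g$contigs$length[ord])
        k <- sum(cum < target * total)
        keep <- ord[seq_len(k)]
        if (k < length(ord)) {
          before <- if (k == 0L) 0 else cum[k]
          p_cross <- (target * total - before) / g$contigs$length[ord[k + 1L]]
          if (stats::runif(1) < p_cross) keep <- c(keep, ord[k + 1L])
        }
        if (length(keep) == 0L) keep <- ord[1L]
      }
      keep <- sort(keep)
      kept_contigs <- g$contigs[keep, , drop = FALSE]
      kept_seqs <- g$seqs[kept_contigs$contig]
      marker_copies <- g$markers$marker[g$markers$contig %in% kept_contigs$contig]

      if (contamination_rate > 0 && length(source_genomes) > 1L) {
        donor <- source_genomes[[resample(setdiff(seq_along(source_genomes), gi), 1L)]]
        inc <- stats::runif(nrow(donor$contigs)) < contamination_rate
        if (any(inc)) {
          dc <- donor$contigs[inc, , drop = FALSE]
          dseqs <- donor$seqs[dc$contig]
          names(dseqs) <- dc$contig
          kept_contigs <- rbind(kept_contigs, dc)
          kept_seqs <- c(kept_seqs, dseqs)
          marker_copies <- c(marker_copies,
                             donor$markers$marker[donor$markers$contig %in% dc$contig])
        }
      }

      tab <- table(marker_copies)
      bin <- genome_bin(
        id = sprintf("%s_bin%02d", g$id, rep_i),
        contigs = kept_contigs,
        scg_count = length(tab),
        mscg_count = sum(tab > 1L),
        domain = g$domain,
        seqs = kept_seqs)
      attr(bin, "source") <- g$id
      attr(bin, "target_completeness") <- target
      bins[[length(bins) + 1L]] <- bin
    }
  }
  bins
}

# sample() treats a length-1 numeric x as 1:x; this does not.
resample <- function(x, size) x[sample.int(length(x), size)]
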