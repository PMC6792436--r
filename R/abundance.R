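#' Normalized relative abundance of a genome in a sample
#'
#' The study's abundance measure: fold-coverage of the genome rescaled to
#' the deepest sample,
#' \deqn{A_r = \frac{N_m}{N_s} \cdot \frac{r \, l}{g}}
#' where \eqn{r} is the number of reads from the sample mapped to the
#' genome, \eqn{l} the mean read length, \eqn{g} the genome length,
#' \eqn{N_s} the sample's total read count and \eqn{N_m} the maximum total
#' read count over all samples. For the deepest sample (\eqn{N_s = N_m})
#' this is plain fold-coverage \eqn{r l / g}.
#'
#' @param r Mapped-read count(s).
#' @param N_s Total reads in the sample.
#' @param l Mean read length in bases.
#' @param g Genome length in bases.
#' @param N_m Maximum total reads over all samples (must be >= \code{N_s}).
#' @return Normalized relative abundance, vectorized over the inputs.
#' @export
normalize_abundance <- function(r, N_s, l, g, N_m) {
  if (any(N_s == 0)) stop("N_s = 0: sample has no reads")
  if (any(g == 0)) stop("g = 0: genome length must be positive")
  if (any(N_m < N_s)) stop("N_m must be >= N_s for every sample")
  (N_m / N_s) * (r * l) / g
}

#' Assemble the organisms x samples abundance matrix
#'
#' Applies the \eqn{A_r} normalization cell-wise to a table of per-sample
#' mapped-read counts. \eqn{N_m} is computed internally as the maximum
#' per-sample read total. Missing (sample, genome) pairs are treated as
#' zero counts; rows and columns are ordered lexicographically for
#' determinism.
#'
#' @param counts Data frame with columns \code{sample}, \code{genome},
#'   \code{r} (mapped reads), \code{N_s} (sample read total), \code{l}
#'   (mean read length) and \code{g} (genome length). \code{N_s} and
#'   \code{l} must be consistent within a sample, \code{g} within a genome.
#' @return An \code{abundance_matrix}: numeric matrix (genomes x samples)
#'   with attribute \code{N_m}.
#' @export
build_matrix <- function(counts) {
  req <- c("sample", "genome", "r", "N_s", "l", "g")
  stopifnot(all(req %in% names(counts)))
  if (anyDuplicated(counts[, c("sample", "genome")]))
    stop("duplicate (sample, genome) rows in counts")
  samples <- sort(unique(as.character(counts$sample)))
  genomes <- sort(unique(as.character(counts$genome)))

  n_s <- tapply(counts$N_s, counts$sample, function(x) {
    if (length(unique(x)) > 1L) stop("inconsistent N_s within a sample")
    x[1L]
  })[samples]
  l_s <- tapply(counts$l, counts$sample, function(x) mean(x))[samples]
  g_g <- tapply(counts$g, counts$genome, function(x) {
    if (length(unique(x)) > 1L) stop("inconsistent genome length g")
    x[1L]
  })[genomes]
  n_m <- max(n_s)

  r_mat <- matrix(0, length(genomes), length(samples),
                  dimnames = list(genomes, samples))
  r_mat[cbind(as.character(counts$genome), as.character(counts$sample))] <- counts$r

  a <- r_mat
  for (s in seq_along(samples))
    a[, s] <- normalize_abundance(r_mat[, s], n_s[s], l_s[s], g_g, n_m)
  structure(a, N_m = n_m, class = c("abundance_matrix", "matrix", "array"))
}

#' Read mapped alignments or a depth table into counts and coverage
#'
#' Ingests either a SAM file of read alignments or a 3-column per-base depth
#' table (\code{genome <tab> pos <tab> depth}, as produced by
#' \code{samtools depth}). For SAM input, alignments whose \code{NM} edit
#' distance exceeds \code{max_mismatches} are discarded before counting —
#' the abundance stage uses 3 mismatches per 150-bp read (98% identity)
#' while replication-rate estimation uses the stricter 1 mismatch per read.
#' Per-base depths are accumulated from the retained alignments and emitted
#' for the replication module.
#'
#' @param path Path to a SAM file (detected by \code{.sam} extension or a
#'   leading \code{@} header) or a depth TSV.
#' @param max_mismatches Maximum NM edit distance per retained read
#'   (SAM input only; default 3).
#' @return A list with \code{counts} (data frame \code{genome}, \code{r})
#'   and \code{depth} (named list of per-base depth vectors per genome).
#' @export
ingest_depth <- function(path, max_mismatches = 3L) {
  first <- readLines(path, n = 1L)
  if (grepl("\\.sam$", path) || (length(first) && startsWith(first, "@")))
    ingest_sam(path, max_mismatches)
  else
    ingest_depth_tsv(path)
}

ingest_sam <- function(path, max_mismatches) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("SAM ingestion requires the Rsamtools package")
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = TRUE)
  aln <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth"), tag = "NM"))[[1]]
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  nm <- aln$tag$NM
  keep <- !is.na(aln$pos) & !is.na(nm) & nm <= max_mismatches
  rname <- as.character(aln$rname[keep])
  pos <- aln$pos[keep]
  w <- aln$qwidth[keep]
  counts <- data.frame(genome = names(hdr), r = 0L, stringsAsFactors = FALSE)
  tab <- table(rname)
  counts$r[match(names(tab), counts$genome)] <- as.integer(tab)
  depth <- lapply(names(hdr), function(gn) {
    sel <- rname == gn
    if (!any(sel)) return(numeric(hdr[[gn]]))
    cov <- IRanges::coverage(
      IRanges::IRanges(start = pos[sel], width = w[sel]), width = hdr[[gn]])
    as.numeric(cov)
  })
  names(depth) <- names(hdr)
  list(counts = counts, depth = depth)
}

ingest_depth_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(list(counts = data.frame(genome = character(0), r = integer(0),
                                    stringsAsFactors = FALSE),
                depth = list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed depth record at line ", bad[1L], ": expected 3 tab-separated fields")
  genome <- vapply(parts, `[[`, character(1), 1L)
  pos <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
  dep <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  bad <- which(is.na(pos) | is.na(dep))
  if (length(bad))
    stop("malformed depth record at line ", bad[1L], ": non-numeric position or depth")
  depth <- lapply(split(seq_along(genome), genome), function(i) {
    v <- numeric(max(pos[i]))
    v[pos[i]] <- dep[i]
    v
  })
  counts <- data.frame(genome = names(depth),
                       r = NA_integer_,  # read counts are not recoverable from depth
                       stringsAsFactors = FALSE)
  list(counts = counts, depth = depth)
}
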