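#' Concatenated marker-protein alignment
#'
#' Builds a concatenated alignment from per-protein aligned blocks, the
#' input to ribosomal-protein phylogenetics. Taxa missing from a block are
#' filled with gaps; blocks are concatenated in the order given (the
#' package's documented fixed order for the 16 ribosomal proteins is
#' rpL2, rpL3, rpL4, rpL5, rpL6, rpL14, rpL15, rpL16, rpL18, rpL22, rpL24,
#' rpS3, rpS8, rpS10, rpS17, rpS19).
#'
#' @param blocks Named list of per-protein alignments, each an
#'   \code{AAStringSet} (or named character vector) of equal-width aligned
#'   sequences named by taxon.
#' @return A \code{concat_alignment}: list with \code{matrix} (taxa x
#'   columns character matrix, gaps as \code{"-"}) and \code{block_map}
#'   (data frame \code{block}, \code{start}, \code{end}, 1-based inclusive).
#' @export
concat_alignment <- function(blocks) {
  stopifnot(length(blocks) >= 1L, !is.null(names(blocks)))
  blocks <- lapply(blocks, function(b) {
    nms <- names(b)
    v <- as.character(b)
    names(v) <- nms
    if (is.null(nms) || anyNA(nms)) stop("block sequences must be named by taxon")
    if (length(unique(nchar(v))) != 1L) stop("unequal row widths within a block")
    v
  })
  taxa <- sort(unique(unlist(lapply(blocks, names))))
  widths <- vapply(blocks, function(b) nchar(b[[1L]]), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L

  m <- matrix("-", length(taxa), sum(widths), dimnames = list(taxa, NULL))
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    for (tx in names(b))
      m[tx, starts[bi]:ends[bi]] <- strsplit(b[[tx]], "")[[1]]
  }
  structure(list(matrix = m,
                 block_map = data.frame(block = names(blocks),
                                        start = starts, end = ends,
                                        stringsAsFactors = FALSE)),
            class = "concat_alignment")
}

is_gap <- function(m) m == "-" | m == "."

#' @export
print.concat_alignment <- function(x, ...) {
  cat(sprintf("<concat_alignment> %d taxa x %d columns in %d blocks\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$block_map)))
  invisible(x)
}

#' Remove low-occupancy alignment columns
#'
#' Drops columns whose non-gap occupancy (fraction of taxa with a residue)
#' is below \code{min_occupancy}; this both strips poorly covered internal
#' columns and trims the alignment ends to the first and last columns
#' meeting the threshold. Block boundaries are recomputed from the
#' retained columns. Idempotent.
#'
#' @param aln A \code{concat_alignment}.
#' @param min_occupancy Minimum non-gap column occupancy (default 0.05).
#' @return The trimmed \code{concat_alignment}.
#' @export
trim_columns <- function(aln, min_occupancy = 0.05) {
  occ <- colMeans(!is_gap(aln$matrix))
  keep <- occ >= min_occupancy
  if (!any(keep)) stop("all columns removed at occupancy ", min_occupancy)
  new_block <- rep(aln$block_map$block,
                   aln$block_map$end - aln$block_map$start + 1L)[keep]
  m <- aln$matrix[, keep, drop = FALSE]
  widths <- as.integer(table(factor(new_block, levels = aln$block_map$block)))
  nonzero <- widths > 0L
  ends <- cumsum(widths[nonzero])
  structure(list(matrix = m,
                 block_map = data.frame(block = aln$block_map$block[nonzero],
                                        start = ends - widths[nonzero] + 1L,
                                        end = ends, stringsAsFactors = FALSE)),
            class = "concat_alignment")
}

#' Per-taxon span fraction of an alignment
#'
#' @param aln A \code{concat_alignment}.
#' @return Named numeric vector: fraction of non-gap columns per taxon.
#' @export
taxon_span <- function(aln) rowMeans(!is_gap(aln$matrix))

#' Drop taxa spanning too little of the alignment
#'
#' Taxa whose sequences span less than \code{min_span} of the trimmed
#' alignment columns are removed from the alignment and emitted on a
#' fallback list (attribute \code{fallback}) for classification by other
#' means (e.g. ribosomal protein S3 or 16S rRNA).
#'
#' @param aln A \code{concat_alignment} (typically already trimmed).
#' @param min_span Minimum span fraction, inclusive (default 0.50).
#' @return The filtered \code{concat_alignment}; removed taxa and their
#'   span fractions are in \code{attr(, "fallback")}.
#' @export
filter_taxa_by_span <- function(aln, min_span = 0.50) {
  span <- taxon_span(aln)
  keep <- span >= min_span
  if (!any(keep)) stop("all taxa removed at span ", min_span)
  out <- structure(list(matrix = aln$matrix[keep, , drop = FALSE],
                        block_map = aln$block_map),
                   class = "concat_alignment")
  attr(out, "fallback") <- data.frame(taxon = names(span)[!keep],
                                      span = unname(span[!keep]),
                                      stringsAsFactors = FALSE)
  out
}

#' Read per-protein alignment blocks from FASTA files
#'
#' @param paths Named character vector of FASTA paths (names are block
#'   labels; basenames used when unnamed).
#' @return A \code{concat_alignment} via \code{\link{concat_alignment}}.
#' @export
read_alignment_blocks <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  concat_alignment(lapply(paths, Biostrings::readAAStringSet))
}

#' Write a concatenated alignment as FASTA
#'
#' @param aln A \code{concat_alignment}.
#' @param path Output FASTA path.
#' @export
write_alignment_fasta <- function(aln, path) {
  seqs <- apply(aln$matrix, 1L, paste, collapse = "")
  writeLines(paste0(">", names(seqs), "\n", seqs), path)
  invisible(path)
}
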