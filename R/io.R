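#' Write and read pipeline tables
#'
#' Plain-TSV persistence for the pipeline's main objects, plus a JSON
#' sidecar recording the normalization constant and filter settings so a
#' written abundance matrix is self-describing.
#'
#' @param mat An \code{abundance_matrix}.
#' @param path Output TSV path; the sidecar goes to \code{<path>.json}.
#' @param filters Optional named list of filter settings to record.
#' @return \code{path}, invisibly.
#' @export
write_abundance_tsv <- function(mat, path, filters = list()) {
  df <- data.frame(organism = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(list(N_m = attr(mat, "N_m"),
           n_organisms = nrow(mat), n_samples = ncol(mat)), filters),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$organism
  side <- paste0(path, ".json")
  n_m <- if (file.exists(side)) jsonlite::read_json(side)$N_m else NA_real_
  structure(m, N_m = n_m, class = c("abundance_matrix", "matrix", "array"))
}

#' Write genome or bin sequences as FASTA
#'
#' @param x A \code{synthetic_genome} or \code{genome_bin} carrying
#'   sequences, or a \code{DNAStringSet}.
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(x, path) {
  seqs <- if (methods::is(x, "DNAStringSet")) x else x$seqs
  if (is.null(seqs)) stop("no sequences to write")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a coverage profile as a two-column TSV
#'
#' @param profile A \code{coverage_profile}.
#' @param path Output path (columns \code{window_start}, \code{depth}).
#' @export
write_coverage_tsv <- function(profile, path) {
  utils::write.table(profile[, c("window_start", "depth")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generic data frame as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
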