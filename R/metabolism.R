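#' Read a metabolic module catalog
#'
#' A catalog defines each metabolic process as a set of enzyme identifiers
#' with a designated subset of key enzymes. The package ships a small
#' synthetic example catalog (\code{inst/extdata/example_module_catalog.tsv})
#' covering the processes profiled across source depths (Wood-Ljungdahl,
#' reverse TCA, Calvin-Benson-Bassham, oxygen respiration, sulfide
#' oxidation, nitrogen fixation, hydrogen oxidation); its enzyme sets are
#' illustrative fixtures, not curated KEGG modules — supply your own catalog
#' for real analyses.
#'
#' @param path Path to a TSV with columns \code{module}, \code{process},
#'   \code{enzymes} (comma-separated), \code{key_enzymes}
#'   (comma-separated, subset of \code{enzymes}).
#' @return A \code{module_catalog}: named list of entries with
#'   \code{module}, \code{process}, \code{enzymes}, \code{key_enzymes}.
#' @export
read_module_catalog <- function(path = system.file("extdata",
                                                   "example_module_catalog.tsv",
                                                   package = "geysertrack")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("module", "process", "enzymes", "key_enzymes") %in% names(df)))
  entries <- lapply(seq_len(nrow(df)), function(i) {
    enz <- strsplit(df$enzymes[i], ",", fixed = TRUE)[[1]]
    key <- strsplit(df$key_enzymes[i], ",", fixed = TRUE)[[1]]
    if (length(enz) == 0L) stop("module ", df$module[i], " has no enzymes")
    if (!all(key %in% enz))
      stop("key enzymes of module ", df$module[i], " not all in its enzyme set")
    list(module = df$module[i], process = df$process[i],
         enzymes = enz, key_enzymes = key)
  })
  names(entries) <- df$module
  structure(entries, class = "module_catalog")
}

#' Filter annotation hits by e-value
#'
#' Retains HMM annotation hits strictly below the e-value cutoff (default
#' 1e-10).
#'
#' @param table Data frame with columns \code{genome}, \code{enzyme},
#'   \code{evalue}.
#' @param max_evalue Strict upper bound on retained e-values.
#' @return The filtered table.
#' @export
filter_hits <- function(table, max_evalue = 1e-10) {
  stopifnot(all(c("genome", "enzyme", "evalue") %in% names(table)))
  if (any(table$evalue < 0)) stop("negative e-value in annotation table")
  table[table$evalue < max_evalue, , drop = FALSE]
}

#' Call a metabolic capacity for one genome
#'
#' A genome is credited with a metabolic process when all of the module's
#' key enzymes are present and pathway coverage — the fraction of the
#' module's enzymes detected — is at least \code{min_coverage} (default
#' 0.60).
#'
#' @param hits Character vector of enzyme identifiers detected in the
#'   genome (already e-value filtered).
#' @param module One entry of a \code{\link{read_module_catalog}} catalog.
#' @param min_coverage Minimum module coverage fraction (inclusive).
#' @return TRUE when the capacity is called.
#' @export
call_capacity <- function(hits, module, min_coverage = 0.60) {
  all(module$key_enzymes %in% hits) &&
    length(intersect(module$enzymes, hits)) / length(module$enzymes) >= min_coverage
}

#' Genome x process capacity matrix
#'
#' @param annotations Annotation table (\code{genome}, \code{enzyme},
#'   \code{evalue}), filtered through \code{\link{filter_hits}} first unless
#'   \code{max_evalue} is NULL.
#' @param catalog A \code{module_catalog}.
#' @param max_evalue E-value cutoff applied before calling (default 1e-10);
#'   NULL to skip filtering.
#' @param min_coverage Passed to \code{\link{call_capacity}}.
#' @return Logical matrix, genomes x processes.
#' @export
capacity_matrix <- function(annotations, catalog, max_evalue = 1e-10,
                            min_coverage = 0.60) {
  if (!is.null(max_evalue)) annotations <- filter_hits(annotations, max_evalue)
  genomes <- sort(unique(annotations$genome))
  hits_by_genome <- split(annotations$enzyme, annotations$genome)
  procs <- vapply(catalog, `[[`, character(1), "process")
  out <- matrix(FALSE, length(genomes), length(catalog),
                dimnames = list(genomes, unname(procs)))
  for (g in genomes) for (m in seq_along(catalog))
    out[g, m] <- call_capacity(hits_by_genome[[g]], catalog[[m]], min_coverage)
  out
}

#' Cumulative abundance of metabolic capacities across phases
#'
#' For each process, sums the normalized abundance of all genomes carrying
#' the capacity, per sample, and tests phase differences with ANOVA plus
#' Tukey HSD. A process is flagged as significantly increased (or
#' decreased) in a phase when that phase's mean is the highest (lowest) and
#' both Tukey comparisons against the other phases are significant at
#' \code{alpha}.
#'
#' @param capacities Logical genome x process matrix
#'   (\code{\link{capacity_matrix}}); genomes absent from the abundance
#'   matrix are ignored, genomes absent from \code{capacities} are treated
#'   as lacking every capacity.
#' @param mat Abundance matrix (organisms x samples).
#' @param meta Sample metadata (\code{sample}, \code{phase}).
#' @param alpha Significance level for the arrows (default 0.05).
#' @return List with \code{profile} (process x sample cumulative abundance)
#'   and \code{arrows} (long data frame: process, phase, mean, direction in
#'   {increase, decrease, none}).
#' @export
capacity_abundance <- function(capacities, mat, meta, alpha = 0.05) {
  genomes <- intersect(rownames(mat), rownames(capacities))
  profile <- t(capacities[genomes, , drop = FALSE]) %*% mat[genomes, , drop = FALSE]
  phase <- meta$phase[match(colnames(mat), meta$sample)]
  split_idx <- split(seq_len(ncol(mat)), phase)

  arrows <- do.call(rbind, lapply(rownames(profile), function(pr) {
    row <- profile[pr, ]
    gr <- lapply(split_idx, function(i) row[i])
    means <- vapply(gr, mean, numeric(1))
    tk <- if (stats::var(row) == 0) NULL else tukey_hsd(gr)
    do.call(rbind, lapply(names(gr), function(ph) {
      dir <- "none"
      if (!is.null(tk)) {
        others <- setdiff(names(gr), ph)
        p_pair <- vapply(others, function(o) {
          nm <- c(paste(ph, o, sep = "-"), paste(o, ph, sep = "-"))
          unname(tk[nm[nm %in% names(tk)][1L]])
        }, numeric(1))
        if (all(p_pair < alpha)) {
          if (means[ph] == max(means)) dir <- "increase"
          else if (means[ph] == min(means)) dir <- "decrease"
        }
      }
      data.frame(process = pr, phase = ph, mean = means[[ph]],
                 direction = dir, stringsAsFactors = FALSE)
    }))
  }))
  rownames(arrows) <- NULL
  list(profile = profile, arrows = arrows)
}
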