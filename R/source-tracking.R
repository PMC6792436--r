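#' Average an environmental time series over a collection window
#'
#' Continuously logged variables (temperature, electrical conductivity,
#' ion concentrations) are reduced to one value per metagenome sample: the
#' arithmetic mean of all observations falling in the sample's collection
#' window, taken half-open \code{[start, end)}.
#'
#' @param times Numeric timestamps of the observations.
#' @param values Observed values, same length as \code{times}.
#' @param window Length-2 numeric: window start and end.
#' @return Mean of the in-window observations.
#' @export
average_env_over_window <- function(times, values, window) {
  stopifnot(length(times) == length(values), length(window) == 2L)
  sel <- times >= window[1] & times < window[2]
  if (!any(sel)) stop("no observations in window [", window[1], ", ", window[2], ")")
  mean(values[sel])
}

#' One-way analysis of variance
#'
#' Classical one-way fixed-effects F test across groups, used to test
#' whether an organism's abundance differs between eruption phases.
#' Degenerate inputs are given explicit contracts: if every observation is
#' identical there is no evidence of a difference (F = 0, p = 1); if
#' within-group variance is zero but group means differ, the difference is
#' certain at this resolution (F = Inf, p = 0).
#'
#' @param groups List of two or more numeric vectors, each of length >= 2.
#' @return List with \code{statistic} (F), \code{p_value}, and degrees of
#'   freedom \code{df1}, \code{df2}.
#' @export
anova_oneway <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  df1 <- length(groups) - 1L
  df2 <- length(x) - length(groups)
  means <- vapply(groups, mean, numeric(1))
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ss_within == 0) {
    if (max(means) == min(means))
      return(list(statistic = 0, p_value = 1, df1 = df1, df2 = df2))
    return(list(statistic = Inf, p_value = 0, df1 = df1, df2 = df2))
  }
  ht <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df1 = df1, df2 = df2)
}

#' Tukey honest significant difference post hoc test
#'
#' Pairwise group comparisons with familywise adjustment via the
#' studentized range distribution, applied after a significant ANOVA to
#' identify which phase pairs differ. With zero residual variance the
#' adjusted p is 1 for pairs with equal means and 0 otherwise.
#'
#' @param groups List of two or more numeric vectors (names become group
#'   labels; unnamed groups are labelled g1, g2, ...).
#' @return Named numeric vector of adjusted p-values, one per unordered
#'   group pair, names like \code{"g2-g1"}.
#' @export
tukey_hsd <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("g", seq_along(groups))
  x <- unlist(groups)
  g <- factor(rep(labs, lengths(groups)), levels = labs)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  pairs <- utils::combn(labs, 2L)
  pair_names <- paste(pairs[2L, ], pairs[1L, ], sep = "-")
  if (ss_within == 0) {
    means <- vapply(groups, mean, numeric(1))
    p <- ifelse(means[pairs[2L, ]] == means[pairs[1L, ]], 1, 0)
    names(p) <- pair_names
    return(p)
  }
  tk <- stats::TukeyHSD(stats::aov(x ~ g))$g
  p <- tk[, "p adj"]
  names(p) <- rownames(tk)
  p[pair_names]
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment of a vector of p-values controlling the expected
#' false discovery rate, with enforced monotonicity and values capped at 1.
#'
#' @param pvalues Numeric vector of p-values in [0, 1] (NAs allowed and
#'   propagated).
#' @return Adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Assign organisms to groundwater source depths
#'
#' Per organism, a one-way ANOVA tests abundance differences across the
#' three phases; p-values are Benjamini-Hochberg corrected across
#' organisms. An organism is sourced to a phase only when (i) its FDR-
#' corrected p is below \code{alpha}, (ii) that phase has the highest mean
#' abundance, and (iii) both Tukey HSD comparisons of that phase against
#' the other two are individually significant at \code{alpha}. Otherwise it
#' remains unassigned — assignment is exclusive, at most one depth per
#' organism.
#'
#' @param mat Abundance matrix (organisms x samples).
#' @param meta Sample metadata with columns \code{sample} and \code{phase};
#'   every column of \code{mat} must have a phase, each phase >= 2 samples.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with one row per organism: \code{organism},
#'   \code{anova_p}, \code{fdr_q}, \code{assigned_phase} (NA when
#'   unassigned), per-phase mean abundances (\code{mean_<phase>}) and Tukey
#'   adjusted p-values for the winning phase's two comparisons
#'   (\code{tukey_p1}, \code{tukey_p2}; NA when the FDR gate fails).
#' @export
assign_source_depth <- function(mat, meta, alpha = 0.05) {
  phase <- meta$phase[match(colnames(mat), meta$sample)]
  if (anyNA(phase)) stop("missing phase labels for some samples")
  phases <- unique(phase)
  if (any(table(phase) < 2L)) stop("need >= 2 samples per phase")

  split_idx <- split(seq_len(ncol(mat)), phase)
  anova_p <- apply(mat, 1L, function(row) {
    groups <- lapply(split_idx, function(i) row[i])
    if (stats::var(row) == 0) return(NA_real_)  # constant organism: untestable
    anova_oneway(groups)$p_value
  })
  fdr_q <- bh_fdr(anova_p)

  means <- t(apply(mat, 1L, function(row)
    vapply(split_idx, function(i) mean(row[i]), numeric(1))))
  colnames(means) <- paste0("mean_", names(split_idx))

  assigned <- rep(NA_character_, nrow(mat))
  tukey_p1 <- tukey_p2 <- rep(NA_real_, nrow(mat))
  for (i in seq_len(nrow(mat))) {
    if (is.na(fdr_q[i]) || fdr_q[i] >= alpha) next
    top <- names(split_idx)[which.max(means[i, ])]
    groups <- lapply(split_idx, function(idx) mat[i, idx])
    tk <- tukey_hsd(groups)
    others <- setdiff(names(split_idx), top)
    p_pair <- vapply(others, function(o) {
      nm <- c(paste(top, o, sep = "-"), paste(o, top, sep = "-"))
      unname(tk[nm[nm %in% names(tk)][1L]])
    }, numeric(1))
    tukey_p1[i] <- p_pair[1L]
    tukey_p2[i] <- p_pair[2L]
    if (all(p_pair < alpha)) assigned[i] <- top
  }

  out <- data.frame(organism = rownames(mat), anova_p = anova_p, fdr_q = fdr_q,
                    assigned_phase = assigned, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(means))
  out$tukey_p1 <- tukey_p1
  out$tukey_p2 <- tukey_p2
  rownames(out) <- NULL
  out
}

#' Cumulative abundance of lineage groups per phase
#'
#' Sums normalized abundances within lineage groups (e.g. CPR, DPANN, other
#' bacteria, other archaea) per sample, then tests phase differences of each
#' group's cumulative abundance with ANOVA and Tukey HSD.
#'
#' @param mat Abundance matrix (organisms x samples).
#' @param meta Sample metadata with \code{sample} and \code{phase}.
#' @param groups Named character vector mapping every organism (names) to a
#'   lineage group.
#' @return List with \code{totals} (groups x samples matrix of cumulative
#'   abundance) and \code{tests} (per group: ANOVA p, phase of maximal mean,
#'   Tukey adjusted p-values).
#' @export
cumulative_group_abundance <- function(mat, meta, groups) {
  if (!all(rownames(mat) %in% names(groups)))
    stop("every organism needs a lineage group")
  grp <- factor(groups[rownames(mat)])
  totals <- rowsum(mat, grp)
  phase <- meta$phase[match(colnames(mat), meta$sample)]
  split_idx <- split(seq_len(ncol(mat)), phase)

  tests <- do.call(rbind, lapply(rownames(totals), function(g) {
    row <- totals[g, ]
    gr <- lapply(split_idx, function(i) row[i])
    a <- anova_oneway(gr)
    tk <- tukey_hsd(gr)
    means <- vapply(gr, mean, numeric(1))
    df <- data.frame(group = g, anova_p = a$p_value,
                     max_phase = names(which.max(means)),
                     stringsAsFactors = FALSE)
    for (nm in names(tk)) df[[paste0("tukey_", nm)]] <- tk[[nm]]
    df
  }))
  tests$fdr_q <- bh_fdr(tests$anova_p)
  list(totals = totals, tests = tests)
}
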