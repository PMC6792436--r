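# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles rather than calling the package.

# Step-up FDR adjustment straight from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  adj[ord] <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  pmin(adj, 1)
}

# Classical one-way ANOVA from sums of squares.
anova_oracle <- function(groups) {
  x <- unlist(groups)
  grand <- mean(x)
  ss_between <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - grand)^2)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- length(x) - length(groups)
  f <- (ss_between / df1) / (ss_within / df2)
  list(statistic = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Tukey HSD adjusted p for one pair, directly from the studentized range
# distribution given group summaries.
tukey_oracle <- function(groups, i, j) {
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df2 <- sum(lengths(groups)) - length(groups)
  mse <- ss_within / df2
  ni <- length(groups[[i]]); nj <- length(groups[[j]])
  se <- sqrt(mse / 2 * (1 / ni + 1 / nj))
  q <- abs(mean(groups[[i]]) - mean(groups[[j]])) / se
  stats::ptukey(q, nmeans = length(groups), df = df2, lower.tail = FALSE)
}

# Bray-Curtis from the definition, one pair at a time.
bray_oracle <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Kruskal stress-1 of a fixed configuration against dissimilarities, with
# monotone regression of configuration distances on dissimilarity ranks.
stress1_oracle <- function(points, d) {
  dc <- as.vector(stats::dist(points))
  dv <- as.vector(d)
  ord <- order(dv)
  fit <- stats::isoreg(seq_along(ord), dc[ord])$yf
  dhat <- numeric(length(dc))
  dhat[ord] <- fit
  sqrt(sum((dc - dhat)^2) / sum(dc^2))
}

# Connected components over an explicit edge list (union-find-free BFS).
components_oracle <- function(ids, edges) {
  comp <- stats::setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      a <- edges$from[r]; b <- edges$to[r]
      if (comp[a] != comp[b]) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(ids, comp[ids])
}

# Canonical form of a partition for comparison.
canon_partition <- function(parts) {
  parts <- lapply(parts, sort)
  unname(parts[order(vapply(parts, `[[`, character(1), 1L))])
}
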