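test_that("window averaging is a half-open filter-and-mean", {
  expect_equal(average_env_over_window(1:10, rep(4.2, 10), c(0, 11)), 4.2)
  expect_equal(average_env_over_window(c(1, 2, 3), c(1, 2, 3), c(1, 4)), 2)
  # half-open [start, end): the end point is excluded
  expect_equal(average_env_over_window(c(1, 2, 3), c(1, 2, 3), c(1, 3)), 1.5)
  expect_error(average_env_over_window(1:3, 1:3, c(10, 20)), "no observations")
  # irregular timestamps against a brute-force filter-and-mean
  set.seed(8)
  t <- sort(runif(200, 0, 100)); v <- rnorm(200)
  w <- c(17.3, 42.9)
  expect_equal(average_env_over_window(t, v, w),
               mean(v[t >= w[1] & t < w[2]]))
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  # means 2, 3, 4; SSB = 6 over 2 df, SSW = 6 over 6 df -> F = 3
  groups <- list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  res <- anova_oneway(groups)
  expect_equal(res$statistic, 3.0)
  oracle <- anova_oracle(groups)
  expect_equal(res$statistic, oracle$statistic)
  expect_equal(res$p_value, oracle$p_value)
  # random cases against the oracle
  set.seed(12)
  for (i in 1:10) {
    g <- lapply(1:3, function(k) rnorm(sample(3:9, 1), mean = rnorm(1)))
    r <- anova_oneway(g); o <- anova_oracle(g)
    expect_equal(r$statistic, o$statistic)
    expect_equal(r$p_value, o$p_value)
  }
  # degenerate contracts
  same <- list(c(1, 1, 1), c(1, 1, 1))
  expect_equal(anova_oneway(same)$p_value, 1)
  sep <- list(c(1, 1, 1), c(2, 2, 2))
  expect_equal(anova_oneway(sep)$p_value, 0)
})

test_that("Tukey HSD matches the studentized-range oracle", {
  set.seed(19)
  groups <- list(a = rnorm(6, 0), b = rnorm(6, 0.2), c = rnorm(6, 3))
  p <- tukey_hsd(groups)
  expect_equal(unname(p["b-a"]), tukey_oracle(groups, 1, 2), tolerance = 1e-8)
  expect_equal(unname(p["c-a"]), tukey_oracle(groups, 1, 3), tolerance = 1e-8)
  expect_equal(unname(p["c-b"]), tukey_oracle(groups, 2, 3), tolerance = 1e-8)
  # far-separated pairs significant, overlapping pair not
  expect_lt(p["c-a"], 0.01)
  expect_lt(p["c-b"], 0.01)
  expect_gt(p["b-a"], 0.1)
  # unbalanced groups still match the oracle (Tukey-Kramer)
  g2 <- list(a = rnorm(4), b = rnorm(9, 1), c = rnorm(6, 2))
  p2 <- tukey_hsd(g2)
  expect_equal(unname(p2["b-a"]), tukey_oracle(g2, 1, 2), tolerance = 1e-8)
  # identical groups: all adjusted p = 1
  expect_true(all(tukey_hsd(list(a = c(1, 1, 1), b = c(1, 1, 1))) == 1))
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(30)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_oracle(p))
    # monotone in sorted-p order and never below the raw p
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj >= p - 1e-12))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

sim_meta <- function(sim) sim$metadata[, c("sample", "phase")]

stack_sets <- function(sets) {
  out <- rep(names(sets), lengths(sets))
  names(out) <- unlist(sets)
  out
}

test_that("source-depth assignment recovers planted enrichment and is exclusive", {
  spec <- default_community_spec(seed = 3, n_organisms = 80)
  sim <- simulate_abundance(spec)
  res <- assign_source_depth(sim$abundance, sim_meta(sim))
  expect_true(all(table(res$organism) == 1))  # at most one phase per organism
  planted <- stack_sets(sim$truth$enriched_sets)
  hit <- res$assigned_phase[match(names(planted), res$organism)] == planted
  expect_gt(mean(!is.na(hit) & hit), 0.9)
})

test_that("constant organisms stay unassigned and missing labels error", {
  spec <- community_spec(n_organisms = 12, phase_lengths = c(3, 4, 3), seed = 2)
  sim <- simulate_abundance(spec)
  mat <- sim$abundance
  mat["org0001", ] <- 3.14
  res <- assign_source_depth(mat, sim_meta(sim))
  expect_true(is.na(res$assigned_phase[res$organism == "org0001"]))
  expect_true(is.na(res$anova_p[res$organism == "org0001"]))
  bad_meta <- sim_meta(sim)[-1, ]
  expect_error(assign_source_depth(mat, bad_meta), "missing phase")
})

test_that("permuting phase labels destroys assignments", {
  spec <- default_community_spec(seed = 9, n_organisms = 60)
  sim <- simulate_abundance(spec)
  meta <- sim_meta(sim)
  set.seed(101)
  rate <- vapply(1:5, function(i) {
    meta$phase <- sample(meta$phase)
    res <- assign_source_depth(sim$abundance, meta)
    mean(!is.na(res$assigned_phase))
  }, numeric(1))
  expect_lt(mean(rate), 0.05)
})

test_that("group cumulative abundance conserves totals and flags planted groups", {
  spec <- community_spec(
    n_organisms = 30, phase_lengths = c(4, 5, 4),
    enriched_sets = list(deep = sprintf("org%04d", 1:8)),
    effect_size = 10, seed = 13)
  sim <- simulate_abundance(spec)
  groups <- setNames(rep("other", 30), sprintf("org%04d", 1:30))
  groups[sprintf("org%04d", 1:8)] <- "DPANN"
  res <- cumulative_group_abundance(sim$abundance, sim_meta(sim), groups)
  # conservation: group sums add to community totals per sample
  expect_equal(colSums(res$totals), colSums(sim$abundance))
  # single all-organism group equals the column sums
  one <- cumulative_group_abundance(sim$abundance, sim_meta(sim),
                                    setNames(rep("all", 30), names(groups)))
  expect_equal(unname(one$totals["all", ]), unname(colSums(sim$abundance)))
  # the planted deep-enriched group is significantly highest in the deep phase
  row <- res$tests[res$tests$group == "DPANN", ]
  expect_identical(row$max_phase, "deep")
  expect_lt(row$anova_p, 0.05)
  expect_error(cumulative_group_abundance(sim$abundance, sim_meta(sim),
                                          groups[-1]), "lineage group")
})
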