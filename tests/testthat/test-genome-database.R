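test_that("bin score is completeness minus twice contamination", {
  mk <- function(scg, mscg, domain = "bacterial")
    genome_bin("b", data.frame(contig = "c1", length = 1000L), scg, mscg, domain)
  expect_identical(bin_score(mk(51, 0)), 51L)
  expect_identical(bin_score(mk(45, 4)), 37L)
  expect_identical(bin_score(mk(10, 10)), -10L)
})

test_that("completeness is the detected fraction of the domain marker set", {
  mk <- function(scg, mscg, domain)
    genome_bin("b", data.frame(contig = "c1", length = 1000L), scg, mscg, domain)
  expect_equal(completeness(mk(51, 0, "bacterial")), 1.0)
  expect_equal(completeness(mk(19, 0, "archaeal")), 0.5)
  expect_equal(completeness(mk(36, 0, "bacterial")), 36 / 51)
  expect_error(genome_bin("b", data.frame(contig = "c1", length = 10L),
                          5, 6, "bacterial"), "exceeds")
})

test_that("draft-quality filter uses strict >70% completeness and mscg <= 2", {
  mk <- function(id, scg, mscg)
    genome_bin(id, data.frame(contig = "c1", length = 1000L), scg, mscg, "bacterial")
  bins <- list(mk("keep", 37, 2),      # 37/51 = 0.725, mscg 2 -> retained
               mk("contaminated", 37, 3), # mscg 3 -> removed
               mk("boundary", 36, 0))  # 36/51 = 0.7059 > 0.70 -> retained
  kept <- quality_filter(bins)
  expect_identical(vapply(kept, `[[`, character(1), "id"), c("keep", "boundary"))
  # completeness exactly at the threshold is removed (strict inequality);
  # 51 * 0.70 is not integral, so exercise the boundary at 0.50
  exactly <- genome_bin("exact", data.frame(contig = "c1", length = 1000L),
                        19, 0, "archaeal")  # completeness 19/38 = 0.50
  expect_length(quality_filter(list(exactly), min_completeness = 0.50), 0L)
  # order preserved
  expect_identical(vapply(quality_filter(rev(bins)), `[[`, character(1), "id"),
                   c("boundary", "keep"))
})

test_that("N50 matches the cumulative-length definition", {
  expect_equal(n50(c(10, 10, 10, 10)), 10)
  expect_equal(n50(c(100, 10, 10)), 100)
  # brute-force oracle on random length sets
  set.seed(42)
  for (i in 1:20) {
    lens <- sample(100:5000, sample(3:30, 1))
    srt <- sort(lens, decreasing = TRUE)
    expect_equal(n50(lens), srt[which(cumsum(srt) >= sum(srt) / 2)[1]])
  }
})

test_that("pairwise identity is exact on identical and reverse-complement input", {
  g <- simulate_genomes(1, genome_length = 6000, n_contigs = 8, seed = 7)[[1]]
  self <- pairwise_identity(g$seqs, g$seqs)
  expect_equal(self$mean_identity, 1.0)
  expect_equal(self$aligned_fraction_of_query, 1.0)
  rc <- Biostrings::reverseComplement(g$seqs[[1]])
  flip <- pairwise_identity(rc, g$seqs[[1]])
  expect_equal(flip$mean_identity, 1.0)
  expect_equal(flip$aligned_fraction_of_query, 1.0)
  expect_error(pairwise_identity(Biostrings::DNAStringSet(), g$seqs), "empty")
})

test_that("pairwise identity recovers a planted substitution rate", {
  g <- simulate_genomes(1, genome_length = 10000, n_contigs = 1, seed = 13)[[1]]
  m <- mutate_genome(g, 0.01, seed = 17)
  planted <- 1 - attr(m, "n_substitutions") / 10000
  s <- pairwise_identity(m$seqs, g$seqs)
  expect_equal(s$mean_identity, planted, tolerance = 0.003)
  expect_gt(s$aligned_fraction_of_query, 0.99)
  # near-symmetry when query and target are swapped on equal-length input
  s2 <- pairwise_identity(g$seqs, m$seqs)
  expect_equal(s$mean_identity, s2$mean_identity, tolerance = 0.003)
})

test_that("dereplication clusters by single linkage and picks scored representatives", {
  mk <- function(id, scg, mscg, n50_len)
    genome_bin(id, data.frame(contig = "c1", length = n50_len), scg, mscg, "bacterial")
  bins <- list(mk("A", 50, 0, 1000), mk("B", 40, 2, 2000), mk("C", 45, 0, 500))
  summ <- data.frame(query = "A", target = "B",
                     aligned_fraction_of_query = 0.9, mean_identity = 0.99,
                     stringsAsFactors = FALSE)
  cl <- dereplicate(bins, summ)
  parts <- canon_partition(lapply(cl, `[[`, "members"))
  expect_identical(parts, list(c("A", "B"), "C"))
  ab <- cl[[which(vapply(cl, function(x) "A" %in% x$members, logical(1)))]]
  expect_identical(ab$representative, "A")  # score 50 beats 36

  # transitive chain joins under single linkage even when A-C is weak
  summ3 <- data.frame(query = c("A", "B"), target = c("B", "C"),
                      aligned_fraction_of_query = 0.9, mean_identity = 0.99,
                      stringsAsFactors = FALSE)
  cl3 <- dereplicate(bins, summ3)
  expect_length(cl3, 1L)
  expect_setequal(cl3[[1]]$members, c("A", "B", "C"))
})

test_that("representative ties break by N50 then id, invariant to input order", {
  mk <- function(id, n50_len)
    genome_bin(id, data.frame(contig = "c1", length = n50_len), 40, 0, "bacterial")
  bins <- list(mk("x", 1000), mk("y", 2000), mk("z", 2000))
  summ <- data.frame(query = c("x", "y"), target = c("y", "z"),
                     aligned_fraction_of_query = 0.9, mean_identity = 0.99,
                     stringsAsFactors = FALSE)
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    cl <- dereplicate(bins[perm], summ)
    expect_identical(cl[[1]]$representative, "y")  # N50 tie y vs z -> lexicographic
  }
})

test_that("dereplication partition equals a connected-components oracle", {
  set.seed(99)
  n <- 20
  ids <- sprintf("bin%02d", 1:n)
  bins <- lapply(ids, function(id)
    genome_bin(id, data.frame(contig = "c1", length = sample(1000:9000, 1)),
               sample(30:51, 1), sample(0:2, 1), "bacterial"))
  # random summaries with planted duplicate structure
  pairs <- t(combn(n, 2))
  dup <- runif(nrow(pairs)) < 0.08
  summ <- data.frame(
    query = ids[pairs[, 1]], target = ids[pairs[, 2]],
    aligned_fraction_of_query = ifelse(dup, runif(nrow(pairs), 0.4, 1), runif(nrow(pairs), 0, 0.25)),
    mean_identity = ifelse(dup, runif(nrow(pairs), 0.985, 1), runif(nrow(pairs), 0.7, 0.97)),
    stringsAsFactors = FALSE)
  cl <- dereplicate(bins, summ)

  qual <- summ[summ$mean_identity >= 0.98 & summ$aligned_fraction_of_query >= 0.30, ]
  oracle <- components_oracle(ids, data.frame(from = qual$query, to = qual$target))
  expect_identical(canon_partition(lapply(cl, `[[`, "members")),
                   canon_partition(oracle))
  # partition property: every bin in exactly one cluster
  all_members <- unlist(lapply(cl, `[[`, "members"))
  expect_setequal(all_members, ids)
  expect_identical(anyDuplicated(all_members), 0L)
})

test_that("dereplication recovers the true source count on sequence bins", {
  sources <- simulate_genomes(4, genome_length = 6000, n_contigs = 6, seed = 21)
  bins <- list()
  for (i in seq_along(sources)) {
    for (rep_i in 1:2) {
      m <- mutate_genome(sources[[i]], 0.005, seed = i * 10 + rep_i,
                         id = sprintf("src%d_copy%d", i, rep_i))
      b <- simulate_bins(list(m), completeness_range = c(1, 1), seed = rep_i)[[1]]
      b$id <- m$id
      bins[[length(bins) + 1]] <- b
    }
  }
  summ <- all_vs_all_identity(bins)
  cl <- dereplicate(bins, summ)
  expect_length(cl, 4L)
  src_of <- function(id) sub("_copy\\d+", "", id)
  for (c1 in cl) expect_length(unique(src_of(c1$members)), 1L)
})

test_that("SAG matching applies the 30% content / 98% identity / 70% complete rule", {
  mk <- function(id, scg) genome_bin(id, data.frame(contig = "c1", length = 1000L),
                                     scg, 0, "bacterial")
  sags <- list(mk("sag1", 40), mk("sag2", 40), mk("sag3", 40), mk("sag4", 20))
  mags <- list(mk("magA", 45), mk("magB", 30))  # magB 59% complete: fails gate
  summ <- data.frame(
    query = c("sag1", "sag2", "sag3", "sag4"),
    target = c("magA", "magA", "magB", "magA"),
    aligned_fraction_of_query = c(0.35, 0.25, 0.31, 0.20),
    mean_identity = c(0.985, 0.999, 0.99, 0.99),
    stringsAsFactors = FALSE)
  res <- match_sags(sags, mags, summ)
  expect_identical(res$mag[res$sag == "sag1"], "magA")
  expect_true(is.na(res$mag[res$sag == "sag2"]))  # fraction below 0.30
  expect_true(is.na(res$mag[res$sag == "sag3"]))  # MAG fails completeness gate
  # unmatched draft-quality SAGs are flagged for database addition
  expect_true(res$add_to_database[res$sag == "sag2"])
  expect_false(res$add_to_database[res$sag == "sag4"])  # not draft quality
})
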