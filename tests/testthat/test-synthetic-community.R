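test_that("community spec validates planted structure", {
  expect_error(community_spec(n_organisms = 10,
                              enriched_sets = list(deep = "org9999")),
               "not in the community")
  expect_error(community_spec(n_organisms = 10,
                              symbiont_pairs = data.frame(host = "org0001",
                                                          symbiont = "org0002",
                                                          strength = 1.2)),
               "strength")
  spec <- community_spec(n_organisms = 10, phase_lengths = c(3, 4, 3))
  expect_identical(spec$phase_assignment,
                   rep(c("intermediate", "deep", "shallow"), c(3, 4, 3)))
})

test_that("simulators are bit-reproducible under a fixed seed", {
  gs1 <- simulate_genomes(2, genome_length = 3000, n_contigs = 5, seed = 5)
  gs2 <- simulate_genomes(2, genome_length = 3000, n_contigs = 5, seed = 5)
  expect_identical(lapply(gs1, function(g) as.character(g$seqs)),
                   lapply(gs2, function(g) as.character(g$seqs)))
  b1 <- simulate_bins(gs1, completeness_range = c(0.5, 0.9), seed = 3)
  b2 <- simulate_bins(gs1, completeness_range = c(0.5, 0.9), seed = 3)
  expect_identical(b1, b2)
  spec <- default_community_spec(seed = 4, n_organisms = 40)
  expect_identical(simulate_abundance(spec)$abundance,
                   simulate_abundance(spec)$abundance)
  expect_identical(simulate_coverage(1e5, 1.5, 20, 2, seed = 8),
                   simulate_coverage(1e5, 1.5, 20, 2, seed = 8))
})

test_that("a full-completeness uncontaminated bin reproduces its source", {
  g <- simulate_genomes(1, genome_length = 5000, n_contigs = 6, seed = 2)[[1]]
  bin <- simulate_bins(list(g), completeness_range = c(1, 1),
                       contamination_rate = 0, seed = 1)[[1]]
  expect_setequal(bin$contigs$contig, g$contigs$contig)
  expect_equal(bin$total_length, sum(g$contigs$length))
  expect_equal(completeness(bin), 1.0)
  expect_identical(bin$mscg_count, 0L)
  expect_error(simulate_bins(list(), seed = 1), "empty")
})

test_that("marker retention at half completeness matches the binomial oracle", {
  # markers land on contigs uniformly; retaining half the genome length keeps
  # each marker with probability ~0.5, so the mean count over 100 replicate
  # bins must sit in the binomial 99% interval around 51 * 0.5 = 25.5
  g <- simulate_genomes(1, genome_length = 20000, n_contigs = 100, seed = 31)[[1]]
  counts <- vapply(1:100, function(s)
    simulate_bins(list(g), completeness_range = c(0.5, 0.5), seed = s)[[1]]$scg_count,
    integer(1))
  half_width <- qnorm(0.995) * sqrt(51 * 0.25 / 100)
  expect_gt(mean(counts), 25.5 - half_width)
  expect_lt(mean(counts), 25.5 + half_width)
})

test_that("contamination produces duplicated markers at the enumerated rate", {
  gs <- simulate_genomes(2, genome_length = 8000, n_contigs = 12, seed = 41)
  # donor for genome 1 is genome 2; with full completeness the bin holds every
  # marker name, so any included donor contig carrying markers duplicates one.
  # Each donor contig enters independently with probability 0.2:
  donor_marker_contigs <- length(unique(gs[[2]]$markers$contig))
  p_true <- 1 - (1 - 0.2)^donor_marker_contigs
  hits <- vapply(1:400, function(s) {
    bins <- simulate_bins(gs, completeness_range = c(1, 1),
                          contamination_rate = 0.2, seed = s)
    bins[[1]]$mscg_count >= 1L
  }, logical(1))
  half_width <- qnorm(0.995) * sqrt(p_true * (1 - p_true) / 400)
  expect_lt(abs(mean(hits) - p_true), half_width + 1e-9)
})

test_that("noise-free symbiont trajectory at strength 1 is proportional to the host", {
  spec <- community_spec(
    n_organisms = 20, phase_lengths = c(3, 4, 3),
    enriched_sets = list(deep = c("org0001", "org0002")),
    symbiont_pairs = data.frame(host = "org0001", symbiont = "org0002",
                                strength = 1),
    abundance_noise = 0, seed = 6)
  sim <- simulate_abundance(spec)
  a <- sim$truth$abundance
  expect_equal(cor(a["org0001", ], a["org0002", ]), 1.0)
  ratio <- a["org0002", ] / a["org0001", ]
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
})

test_that("abundance matrices are finite, non-negative, with positive column sums", {
  for (seed in 1:5) {
    sim <- simulate_abundance(default_community_spec(seed = seed, n_organisms = 60))
    expect_true(all(is.finite(sim$abundance)))
    expect_true(all(sim$abundance >= 0))
    expect_true(all(colSums(sim$abundance) > 0))
    expect_equal(attr(sim$abundance, "N_m"), max(sim$counts$N_s))
  }
})

test_that("normalized abundance from counts recovers the planted abundance", {
  sim <- simulate_abundance(default_community_spec(seed = 11, n_organisms = 50))
  a_hat <- sim$abundance[rownames(sim$truth$abundance), colnames(sim$truth$abundance)]
  # counts are rounded, so recovery is near-exact, not bitwise
  rel_err <- abs(a_hat - sim$truth$abundance) / pmax(sim$truth$abundance, 1e-6)
  expect_lt(stats::median(rel_err), 1e-3)
})

test_that("simulated coverage has the planted origin-terminus span and permuted order", {
  prof <- simulate_coverage(2e5, irep_true = 2, mean_depth = 10, noise_sd = 0,
                            seed = 3)
  expect_equal(max(prof$depth) / min(prof$depth), 2, tolerance = 1e-9)
  flat <- simulate_coverage(2e5, irep_true = 1, mean_depth = 10, noise_sd = 0,
                            seed = 3)
  expect_equal(sd(flat$depth), 0)
  expect_equal(mean(flat$depth), 10)
  # window starts are sorted but the depth ramp is shuffled along the genome
  expect_true(!is.unsorted(prof$window_start))
  expect_gt(sd(diff(prof$depth)), 0)
  expect_error(simulate_coverage(1000, 1.5, 10, 0, seed = 1, window_size = 5000),
               "shorter than one window")
})

test_that("zero planted enrichment yields near-nominal per-organism ANOVA rejections", {
  # type-I error of the phase ANOVA under the generator's lognormal noise
  spec <- community_spec(n_organisms = 200, abundance_noise = 0.5, seed = 77)
  sim <- simulate_abundance(spec)
  phase <- sim$metadata$phase
  idx <- split(seq_len(ncol(sim$abundance)), phase)
  p <- apply(sim$abundance, 1, function(row)
    anova_oneway(lapply(idx, function(i) row[i]))$p_value)
  # 200 organisms, nominal 0.05: binomial 99% interval around 10 rejections
  expect_lt(abs(mean(p < 0.05) - 0.05), qnorm(0.995) * sqrt(0.05 * 0.95 / 200) + 0.02)
})
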