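# The synthetic-data generator: determinism, distributional shape, and
# file round-trips.

test_that("the whole generator is deterministic under a seed", {
  s1 <- simulate_study(tiny_config(seed = 61L), select_iterations = 300L)
  s2 <- simulate_study(tiny_config(seed = 61L), select_iterations = 300L)
  expect_identical(s1$protein$sequence, s2$protein$sequence)
  expect_identical(s1$freqs, s2$freqs)
  expect_identical(s1$tcell_genotypes, s2$tcell_genotypes)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$mapps, s2$mapps)
  expect_identical(s1$truth$epitopes, s2$truth$epitopes)
  s3 <- simulate_study(tiny_config(seed = 62L), select_iterations = 300L)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("population frequencies are a proper spectrum", {
  for (seed in 1:5) {
    pop <- simulate_population(sim_config(), seed = seed)
    expect_equal(sum(pop$freqs$freq), 1)
    expect_true(all(pop$freqs$freq > 0))
    expect_true(all(c(pop$pool_genotypes$allele1,
                      pop$pool_genotypes$allele2) %in% pop$freqs$allele))
  }
})

test_that("a single fixed allele makes every genotype homozygous", {
  # degenerate spectrum: concentration pushed onto one allele by using
  # two alleles where one has essentially all the mass
  config <- sim_config(n_alleles = 2L, n_pool_donors = 30L,
                       dirichlet_concentration = 1e4)
  pop <- simulate_population(config, seed = 3L)
  # force the degenerate case directly through the genotype sampler
  freqs <- tibble::tibble(allele = c("DRB1*01:01", "DRB1*02:01"),
                          freq = c(1, 0))
  withr::with_seed(4L, {
    g <- tibble::tibble(
      donor_id = sprintf("d%02d", 1:20),
      allele1 = sample(freqs$allele, 20L, replace = TRUE,
                       prob = freqs$freq),
      allele2 = sample(freqs$allele, 20L, replace = TRUE,
                       prob = freqs$freq))
  })
  expect_true(all(g$allele1 == "DRB1*01:01" & g$allele2 == "DRB1*01:01"))
})

test_that("planted truth ties expected responders to carried alleles", {
  config <- tiny_config(seed = 63L)
  withr::with_seed(config$seed, {
    pop <- simulate_population(config)
    truth <- simulate_truth(config, pop$freqs)
    lib <- peptide_library(simulate_protein(config$protein_length),
                           pool_size = config$pool_size)
    pools <- attr(lib, "pools")
    expected <- expected_responses(truth, pop$pool_genotypes, pools)
    carriers <- genotype_carriers(pop$pool_genotypes)
    for (i in seq_len(nrow(expected))) {
      own <- carriers$allele[carriers$donor_id == expected$donor_id[i]]
      span <- pools[pools$pool_id == expected$pool_id[i], ]
      ok <- any(vapply(seq_len(nrow(truth$epitopes)), function(e) {
        overlap <- truth$epitopes$start[e] <= span$span_end &&
          truth$epitopes$end[e] >= span$span_start
        overlap &&
          length(intersect(truth$epitopes$alleles[[e]], own)) > 0L
      }, logical(1)))
      expect_true(ok)
    }
  })
  # epitope spans stay inside the protein and are non-overlapping
  tr <- simulate_truth(tiny_config(), tibble::tibble(
    allele = sprintf("DRB1*%02d:01", 1:3), freq = rep(1 / 3, 3)),
    seed = 2L)$epitopes
  expect_true(all(tr$start >= 1L & tr$end <= 320L & tr$start <= tr$end))
  expect_true(all(tr$start[-1] > tr$end[-nrow(tr)]))
})

test_that("a unit effect multiplier yields an exchangeable null dataset", {
  config <- tiny_config(seed = 64L, effect_multiplier = 1)
  withr::with_seed(config$seed, {
    pop <- simulate_population(config)
    truth <- simulate_truth(config, pop$freqs)
    pools <- attr(peptide_library(simulate_protein(config$protein_length),
                                  pool_size = config$pool_size), "pools")
    counts <- simulate_counts(config, truth, pop$pool_genotypes, pools)
  })
  pool_rows <- counts[counts$stimulus_type == "pool", ]
  unstim_rows <- counts[counts$stimulus_type == "unstimulated", ]
  # empirical rates close between stimulated and unstimulated
  expect_equal(sum(pool_rows$positive_count) / sum(pool_rows$total_count),
               sum(unstim_rows$positive_count) /
                 sum(unstim_rows$total_count),
               tolerance = 0.3)
  # SEB control is always strongly positive
  seb <- counts[counts$stimulus_type == "control", ]
  expect_gt(sum(seb$positive_count) / sum(seb$total_count),
            10 * config$background_rate)
})

test_that("MAPPs ladders hug planted epitopes and lengths mimic MHC-II", {
  config <- sim_config(seed = 65L, mapps_noise = 0)
  s <- withr::with_seed(config$seed, {
    pop <- simulate_population(config)
    truth <- simulate_truth(config, pop$freqs)
    protein <- simulate_protein(config$protein_length)
    list(mapps = simulate_mapps(config, truth, pop$mapps_genotypes,
                                protein),
         truth = truth, protein = protein)
  })
  mapped <- suppressWarnings(map_mapps_peptides(s$mapps, s$protein))
  # with no decoys, every identification overlaps a planted epitope
  ep <- s$truth$epitopes
  overlaps <- vapply(seq_len(nrow(mapped)), function(i) {
    any(mapped$start[i] <= ep$end & mapped$end[i] >= ep$start)
  }, logical(1))
  expect_true(all(overlaps))
  lens <- nchar(s$mapps$sequence)
  expect_gte(min(lens), 7L)
  expect_lte(max(lens), 24L)
  expect_lt(abs(stats::median(lens) - 15), 2.1)
  expect_true(all(s$mapps$expect_value <= 0.05))
})

test_that("generated tables round-trip through the readers and writers", {
  s <- simulate_study(tiny_config(seed = 66L), select_iterations = 300L)
  dir <- withr::local_tempdir()
  paths <- write_simulated_study(s, dir)
  expect_identical(read_protein_fasta(paths["fasta"])$sequence,
                   s$protein$sequence)
  expect_equal(as.data.frame(read_allele_frequencies(
    paths["allele_freqs"])), as.data.frame(s$freqs))
  expect_equal(as.data.frame(read_genotype_table(
    paths["genotypes_tcell"])), as.data.frame(s$tcell_genotypes))
  expect_equal(as.data.frame(read_stimulation_counts(paths["counts"])),
               as.data.frame(s$counts))
  expect_equal(as.data.frame(read_mapps_table(paths["mapps"])),
               as.data.frame(s$mapps[, c("donor_id", "sequence",
                                         "expect_value")]))
})

test_that("recovery metrics follow the span-overlap definition", {
  truth <- list(epitopes = tibble::tibble(
    epitope_id = 1:2, start = c(10L, 60L), end = c(25L, 80L),
    alleles = list("DRB1*01:01", "DRB1*02:01"),
    markers = list("IFNg", "IL2")))
  class(truth) <- "synthetic_truth"
  perfect <- tibble::tibble(start = c(10L, 60L), end = c(25L, 80L))
  m <- recovery_metrics(perfect, truth)
  expect_equal(c(m$precision, m$recall), c(1, 1))
  none <- recovery_metrics(perfect[0, ], truth)
  expect_equal(c(none$precision, none$recall), c(1, 0))
  # shifted-by-one span still recovered under the >= 9 overlap rule
  shifted <- tibble::tibble(start = 11L, end = 26L)
  expect_equal(recovery_metrics(shifted, truth)$recall, 0.5)
  far <- tibble::tibble(start = 90L, end = 110L)
  m_far <- recovery_metrics(far, truth)
  expect_equal(c(m_far$precision, m_far$recall), c(0, 0))
})
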