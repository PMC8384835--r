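# Donor matching, residue-level merge/filter, and the full four-step
# integration against a brute-force oracle.

A <- "DRB1*01:01"; B <- "DRB1*02:01"; C <- "DRB1*03:01"; D <- "DRB1*04:01"

test_that("donors match iff they share a DRB1 allele", {
  mapps_g <- tibble::tibble(donor_id = c("m1", "m2", "m3"),
                            allele1 = c(A, C, B),
                            allele2 = c("DRB1*15:01", D, B))
  tcell_g <- tibble::tibble(donor_id = c("t1", "t2"),
                            allele1 = c(A, B), allele2 = c(D, B))
  m <- match_donors(mapps_g, tcell_g)
  key <- paste(m$mapps_donor_id, m$tcell_donor_id)
  expect_setequal(key, c("m1 t1", "m2 t1", "m3 t2"))
  expect_equal(m$shared_alleles[[which(key == "m1 t1")]], A)
  expect_equal(m$shared_alleles[[which(key == "m2 t1")]], D)
  # identical homozygotes: one match, one shared allele
  expect_equal(m$shared_alleles[[which(key == "m3 t2")]], B)
  # disjoint genotypes never match
  expect_false(any(m$mapps_donor_id == "m3" & m$tcell_donor_id == "t1"))
})

test_that("matched residues are span intersections", {
  pool <- tibble::tibble(span_start = 1L, span_end = 60L)
  expect_equal(matched_residues(tibble::tibble(start = 12L, end = 25L),
                                pool), 12:25)
  expect_equal(matched_residues(tibble::tibble(start = 55L, end = 70L),
                                pool), 55:60)
  expect_equal(matched_residues(tibble::tibble(start = 12L, end = 25L),
                                pool[0, ]), integer(0))
  # containment mode keeps whole contained peptides, drops partial ones
  expect_equal(
    matched_residues(tibble::tibble(start = c(12L, 55L), end = c(25L, 70L)),
                     pool, mode = "contained"), 12:25)
})

test_that("combine_and_filter splits runs and applies the length floor", {
  runs <- combine_and_filter(list(12:25, 20:30))
  expect_equal(nrow(runs), 1L)
  expect_equal(c(runs$start, runs$end, runs$length), c(12L, 30L, 19L))
  # boundary: 8 dropped, 9 kept
  expect_equal(nrow(combine_and_filter(1:8)), 0L)
  kept <- combine_and_filter(1:9)
  expect_equal(c(kept$start, kept$end), c(1L, 9L))
  # disjoint runs split
  two <- combine_and_filter(c(1:12, 50:70), min_length = 9L)
  expect_equal(two$start, c(1L, 50L))
  expect_equal(two$end, c(12L, 70L))
  expect_equal(nrow(combine_and_filter(integer(0))), 0L)
})

test_that("a single planted epitope is recovered exactly on a toy fixture", {
  prot <- random_protein(100L, seed = 51L)
  pools <- tibble::tibble(pool_id = 1:2, span_start = c(1L, 46L),
                          span_end = c(60L, 100L))
  tcell_g <- tibble::tibble(donor_id = "t1", allele1 = A, allele2 = B)
  mapps_g <- tibble::tibble(donor_id = "m1", allele1 = A, allele2 = C)
  calls <- fake_calls("t1", list(t1 = 1L), n_pools = 2L)
  mapped <- tibble::tibble(donor_id = "m1",
                           sequence = substr(prot$sequence, 20L, 39L),
                           expect_value = 0.01, start = 20L, end = 39L)
  res <- integrate_epitopes(calls, mapped, tcell_g, mapps_g, pools, prot)
  expect_equal(nrow(res$candidates), 1L)
  expect_equal(c(res$candidates$start, res$candidates$end), c(20L, 39L))
  expect_equal(res$candidates$sequence,
               substr(prot$sequence, 20L, 39L))
  expect_equal(res$candidates$associated_alleles[[1]], A)
  expect_equal(res$intervals$start, 20L)
  expect_equal(res$intervals$end, 39L)
  # no matches -> empty candidate list
  res0 <- integrate_epitopes(calls, mapped, tcell_g,
                             tibble::tibble(donor_id = "m1", allele1 = C,
                                            allele2 = D),
                             pools, prot)
  expect_equal(nrow(res0$candidates), 0L)
})

test_that("integration equals the brute-force oracle on random instances", {
  prot <- random_protein(120L, seed = 52L)
  pools <- tibble::tibble(pool_id = 1:3, span_start = c(1L, 41L, 81L),
                          span_end = c(50L, 90L, 120L))
  alleles <- c(A, B, C, D)
  for (seed in 1:25) {
    withr::with_seed(100L + seed, {
      n_t <- sample(2:5, 1L); n_m <- sample(2:5, 1L)
      tcell_g <- tibble::tibble(
        donor_id = sprintf("t%d", seq_len(n_t)),
        allele1 = sample(alleles, n_t, replace = TRUE),
        allele2 = sample(alleles, n_t, replace = TRUE))
      mapps_g <- tibble::tibble(
        donor_id = sprintf("m%d", seq_len(n_m)),
        allele1 = sample(alleles, n_m, replace = TRUE),
        allele2 = sample(alleles, n_m, replace = TRUE))
      pos <- stats::setNames(lapply(seq_len(n_t), function(i) {
        which(stats::runif(3) < 0.5)
      }), tcell_g$donor_id)
      calls <- fake_calls(tcell_g$donor_id, pos, n_pools = 3L)
      n_pep <- sample(1:8, 1L)
      starts <- sample(1:105, n_pep, replace = TRUE)
      mapped <- tibble::tibble(
        donor_id = sample(mapps_g$donor_id, n_pep, replace = TRUE),
        start = as.integer(starts),
        end = pmin(as.integer(starts + sample(8:20, n_pep,
                                              replace = TRUE)), 120L),
        expect_value = 0.01)
      mapped$sequence <- substring(prot$sequence, mapped$start,
                                   mapped$end)
      res <- integrate_epitopes(calls, mapped, tcell_g, mapps_g, pools,
                                prot)
      oracle <- oracle_integration(calls, mapped, tcell_g, mapps_g,
                                   pools, 120L)
      expect_equal(res$candidates$start, oracle$start,
                   ignore_attr = TRUE)
      expect_equal(res$candidates$end, oracle$end, ignore_attr = TRUE)
    })
  }
})

test_that("adding evidence never removes a candidate", {
  prot <- random_protein(120L, seed = 53L)
  pools <- tibble::tibble(pool_id = 1:2, span_start = c(1L, 56L),
                          span_end = c(65L, 120L))
  tcell_g <- tibble::tibble(donor_id = "t1", allele1 = A, allele2 = B)
  mapps_g <- tibble::tibble(donor_id = "m1", allele1 = A, allele2 = A)
  calls1 <- fake_calls("t1", list(t1 = 1L), n_pools = 2L)
  calls2 <- fake_calls("t1", list(t1 = 1:2), n_pools = 2L)
  mapped1 <- tibble::tibble(donor_id = "m1",
                            sequence = substr(prot$sequence, 10L, 29L),
                            expect_value = 0.01, start = 10L, end = 29L)
  mapped2 <- dplyr::bind_rows(
    mapped1,
    tibble::tibble(donor_id = "m1",
                   sequence = substr(prot$sequence, 70L, 89L),
                   expect_value = 0.01, start = 70L, end = 89L))
  base <- integrate_epitopes(calls1, mapped1, tcell_g, mapps_g, pools,
                             prot)$candidates
  more_pools <- integrate_epitopes(calls2, mapped1, tcell_g, mapps_g,
                                   pools, prot)$candidates
  more_peps <- integrate_epitopes(calls2, mapped2, tcell_g, mapps_g,
                                  pools, prot)$candidates
  covers <- function(cand, ref) {
    all(vapply(seq_len(nrow(ref)), function(i) {
      any(cand$start <= ref$start[i] & cand$end >= ref$end[i])
    }, logical(1)))
  }
  expect_true(covers(more_pools, base))
  expect_true(covers(more_peps, more_pools))
  expect_gte(nrow(more_peps), nrow(more_pools))
})

test_that("candidate provenance links both assays", {
  s <- simulate_study(tiny_config(seed = 54L), select_iterations = 500L)
  calls <- call_responders(s$counts)
  mapped <- suppressWarnings(
    map_mapps_peptides(filter_by_expect_value(s$mapps), s$protein))
  res <- integrate_epitopes(calls, mapped, s$tcell_genotypes,
                            s$mapps_genotypes, s$pools, s$protein)
  pos <- donor_positive(calls)
  # every candidate's sequence is the protein substring at its own span
  expect_equal(res$candidates$sequence,
               substring(s$protein$sequence, res$candidates$start,
                         res$candidates$end))
  for (i in seq_len(nrow(res$candidates))) {
    pairs <- res$candidates$supporting_matches[[i]]
    expect_gte(nrow(pairs), 1L)
    span <- seq.int(res$candidates$start[i], res$candidates$end[i])
    for (j in seq_len(nrow(pairs))) {
      pep <- mapped[mapped$donor_id == pairs$mapps_donor_id[j], ]
      expect_true(any(pep$start <= max(span) & pep$end >= min(span)))
      expect_true(any(pos$positive[pos$donor_id == pairs$tcell_donor_id[j] &
                                     pos$stimulus_type == "pool"]))
    }
  }
})

test_that("population coverage of candidates uses the allele union", {
  freqs <- tibble::tibble(allele = c(A, B), freq = c(0.2, 0.1))
  cands <- tibble::tibble(start = c(1L, 50L), end = c(20L, 70L),
                          associated_alleles = list(c(A, B), A))
  expect_equal(epitope_population_coverage(cands, freqs), 30)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          associated_alleles = list())
  expect_equal(epitope_population_coverage(empty, freqs), 0)
})
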