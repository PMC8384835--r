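# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately avoid the code paths they check: the Fisher
# oracle sums binomial coefficients directly, and the integration oracle
# enumerates the four-step procedure with plain loops over residue
# vectors (no IRanges, no dplyr grouping).

# exact upper-tail hypergeometric sum for the one-sided 2x2 test,
# via log binomial coefficients
fisher_tail_oracle <- function(stim_pos, stim_total, unstim_pos,
                               unstim_total) {
  K <- stim_pos + unstim_pos
  N <- stim_total + unstim_total
  n <- stim_total
  ks <- seq.int(stim_pos, min(K, n))
  if (length(ks) == 0L) {
    return(0)
  }
  sum(exp(lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)))
}

# exhaustive best size-n subset by cohort objective
exhaustive_best_cohort <- function(pool, n, target) {
  subsets <- utils::combn(nrow(pool), n)
  objs <- apply(subsets, 2, function(idx) {
    cohort_objective(cohort_allele_frequencies(pool[idx, ]), target)
  })
  list(objective = min(objs),
       sets = lapply(which(objs <= min(objs) + 1e-12),
                     function(j) sort(pool$donor_id[subsets[, j]])))
}

# brute-force enumeration of the four-step integration procedure
oracle_integration <- function(calls, mapped, tcell_g, mapps_g, pools,
                               protein_len, min_length = 9L) {
  # step 0: donor x pool positivity (any marker)
  pos_pools <- list()
  for (d in unique(calls$donor_id)) {
    rows <- calls[calls$donor_id == d & calls$stimulus_type == "pool", ]
    ids <- integer(0)
    for (s in unique(rows$stimulus)) {
      if (any(rows$positive[rows$stimulus == s])) {
        ids <- c(ids, as.integer(sub("^pool_", "", s)))
      }
    }
    pos_pools[[d]] <- ids
  }
  geno_set <- function(g, d) {
    unique(c(g$allele1[g$donor_id == d], g$allele2[g$donor_id == d]))
  }
  # steps 1 + 2: matches and matched residues
  covered <- rep(FALSE, protein_len)
  for (md in mapps_g$donor_id) {
    for (td in tcell_g$donor_id) {
      if (length(intersect(geno_set(mapps_g, md),
                           geno_set(tcell_g, td))) == 0L) next
      peps <- mapped[mapped$donor_id == md, ]
      for (pid in pos_pools[[td]] %||% integer(0)) {
        q <- pools[pools$pool_id == pid, ]
        if (nrow(q) == 0L || nrow(peps) == 0L) next
        for (i in seq_len(nrow(peps))) {
          lo <- max(peps$start[i], q$span_start)
          hi <- min(peps$end[i], q$span_end)
          if (lo <= hi) covered[lo:hi] <- TRUE
        }
      }
    }
  }
  # step 3: maximal runs >= min_length
  runs <- data.frame(start = integer(), end = integer())
  i <- 1L
  while (i <= protein_len) {
    if (covered[i]) {
      j <- i
      while (j < protein_len && covered[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_length) {
        runs <- rbind(runs, data.frame(start = i, end = j))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  # cohort regions by sort-and-scan merge (overlap >= 1)
  regions <- data.frame(start = integer(), end = integer())
  if (nrow(mapped) > 0L) {
    sp <- mapped[order(mapped$start, mapped$end), c("start", "end")]
    cur_s <- sp$start[1L]
    cur_e <- sp$end[1L]
    if (nrow(sp) > 1L) {
      for (i in 2:nrow(sp)) {
        if (sp$start[i] <= cur_e) {
          cur_e <- max(cur_e, sp$end[i])
        } else {
          regions <- rbind(regions, data.frame(start = cur_s, end = cur_e))
          cur_s <- sp$start[i]
          cur_e <- sp$end[i]
        }
      }
    }
    regions <- rbind(regions, data.frame(start = cur_s, end = cur_e))
  }
  # step 4: regions sharing >= min_length residues with a surviving run
  keep <- logical(nrow(regions))
  for (r in seq_len(nrow(regions))) {
    for (v in seq_len(nrow(runs))) {
      shared <- min(regions$end[r], runs$end[v]) -
        max(regions$start[r], runs$start[v]) + 1L
      if (shared >= min_length) keep[r] <- TRUE
    }
  }
  regions[keep, , drop = FALSE]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# deterministic random protein for fixtures
random_protein <- function(len, seed = 1L) {
  withr::with_seed(seed, simulate_protein(len))
}

# hand-built calls tibble: one marker, explicit positives
fake_calls <- function(donor_ids, positive_pools_by_donor, n_pools) {
  rows <- list()
  for (d in donor_ids) {
    for (p in seq_len(n_pools)) {
      pos <- p %in% (positive_pools_by_donor[[d]] %||% integer(0))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        donor_id = d, stimulus = sprintf("pool_%02d", p),
        stimulus_type = "pool", marker = "IFNg",
        raw_p = if (pos) 1e-6 else 0.9,
        adjusted_p = if (pos) 1e-5 else 1, positive = pos)
    }
  }
  dplyr::bind_rows(rows)
}

# downsized simulation config for fast end-to-end fixtures
tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, protein_length = 320L, n_epitopes = 2L,
             n_pool_donors = 14L, n_tcell_donors = 7L,
             n_mapps_donors = 6L, n_alleles = 6L,
             total_cells = c(2e4, 4e4), ...)
}
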