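# Seeded synthetic-data generator. Emulates every input the pipeline
# consumes -- reference allele frequencies, donor genotypes, gated cell
# counts per cytokine marker, and per-donor MAPPs identification sets
# nested around planted epitope regions -- together with the ground truth
# needed for recovery metrics.

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. Defaults describe a
#' study-sized instance: a 1053-residue antigen tiled into 15-mers
#' staggered by 5 and pooled by 10, a 50-donor HLA-typed pool from which a
#' 21-donor T-cell cohort is annealed, an 18-donor immunopeptidomics
#' cohort, binomially gated cell counts with a 1e-4 background positive
#' rate over 5e4-1e5 total CD4+ cells, a 20-fold positive-rate increase
#' for true responder combinations, and 8 planted epitope regions each
#' presented by 1-3 population-frequency-weighted alleles.
#'
#' @param seed Integer seed driving every random draw.
#' @param protein_length Antigen length in residues.
#' @param window,stagger,pool_size Peptide-library design parameters.
#' @param n_pool_donors Size of the HLA-typed donor pool.
#' @param n_tcell_donors T-cell cohort size selected from the pool.
#' @param n_mapps_donors Immunopeptidomics cohort size.
#' @param n_alleles Number of DRB1 alleles in the reference population.
#' @param dirichlet_concentration Symmetric Dirichlet concentration for the
#'   reference allele frequencies (smaller = more skewed).
#' @param markers Cytokine marker names.
#' @param background_rate Per-marker background positive-cell rate.
#' @param total_cells Two-element range for per-sample total CD4+ counts.
#' @param effect_multiplier Fold increase of the positive rate for true
#'   responder (donor, pool, marker) combinations; 1 gives a null dataset.
#' @param seb_multiplier Fold increase for the SEB positive control.
#' @param n_epitopes Number of planted epitope regions.
#' @param epitope_length Two-element range of planted epitope lengths.
#' @param ladder_size Two-element range of MAPPs peptides per presented
#'   epitope per donor.
#' @param mapps_noise Mean decoy identifications per MAPPs donor (Poisson).
#' @param decoy_ev_log10 log10 Expect-Value range for decoys (uniform);
#'   spans the 0.05 threshold so a small, realistic fraction survives the
#'   filter.
#' @param epitope_ev_log10 log10 Expect-Value range for true ladder
#'   peptides (all at or below the threshold).
#' @param decoy_unmappable_frac Fraction of decoys emitted as shuffled,
#'   unmappable sequences.
#' @param alpha Responder-calling significance level.
#' @param min_epitope_length Minimum epitope length for integration.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       protein_length = 1053L,
                       window = 15L, stagger = 5L, pool_size = 10L,
                       n_pool_donors = 50L,
                       n_tcell_donors = 21L,
                       n_mapps_donors = 18L,
                       n_alleles = 15L,
                       dirichlet_concentration = 1.5,
                       markers = c("IFNg", "TNFa", "IL2"),
                       background_rate = 1e-4,
                       total_cells = c(5e4, 1e5),
                       effect_multiplier = 20,
                       seb_multiplier = 50,
                       n_epitopes = 8L,
                       epitope_length = c(15L, 25L),
                       ladder_size = c(5L, 12L),
                       mapps_noise = 2,
                       decoy_ev_log10 = c(-1.4, 2),
                       epitope_ev_log10 = c(-4, log10(0.05)),
                       decoy_unmappable_frac = 0.3,
                       alpha = 0.05,
                       min_epitope_length = 9L) {
  config <- list(
    seed = as.integer(seed), protein_length = as.integer(protein_length),
    window = as.integer(window), stagger = as.integer(stagger),
    pool_size = as.integer(pool_size),
    n_pool_donors = as.integer(n_pool_donors),
    n_tcell_donors = as.integer(n_tcell_donors),
    n_mapps_donors = as.integer(n_mapps_donors),
    n_alleles = as.integer(n_alleles),
    dirichlet_concentration = dirichlet_concentration,
    markers = markers, background_rate = background_rate,
    total_cells = total_cells, effect_multiplier = effect_multiplier,
    seb_multiplier = seb_multiplier, n_epitopes = as.integer(n_epitopes),
    epitope_length = as.integer(epitope_length),
    ladder_size = as.integer(ladder_size), mapps_noise = mapps_noise,
    decoy_ev_log10 = decoy_ev_log10,
    epitope_ev_log10 = epitope_ev_log10,
    decoy_unmappable_frac = decoy_unmappable_frac,
    alpha = alpha, min_epitope_length = as.integer(min_epitope_length)
  )
  with(config, stopifnot(
    protein_length >= window, window >= stagger, stagger >= 1L,
    n_pool_donors >= n_tcell_donors, n_tcell_donors >= 1L,
    n_mapps_donors >= 1L, n_alleles >= 2L,
    background_rate > 0, background_rate < 1,
    length(total_cells) == 2L, total_cells[1] <= total_cells[2],
    effect_multiplier >= 1, n_epitopes >= 1L,
    epitope_length[1] <= epitope_length[2],
    mapps_noise >= 0, decoy_unmappable_frac >= 0,
    decoy_unmappable_frac <= 1, alpha > 0, alpha < 1
  ))
  structure(config, class = "sim_config")
}

#' Simulate a random protein sequence
#'
#' Uniform draws from the 20 canonical residues; at study scale this makes
#' 15-mer windows effectively unique, so exact-substring mapping is
#' unambiguous.
#'
#' @param length Number of residues.
#' @param id Sequence identifier.
#' @param seed Optional seed (`NULL` uses the current RNG stream).
#' @return A `protein_record`.
#' @export
simulate_protein <- function(length, id = "synthetic_antigen",
                             seed = NULL) {
  with_optional_seed(seed, {
    protein_record(id, paste(sample(AA_ALPHABET, length, replace = TRUE),
                             collapse = ""))
  })
}

#' Simulate a reference population and HLA-typed donor cohorts
#'
#' Allele frequencies are a symmetric Dirichlet draw; genotypes are two
#' independent allele draws per donor (Hardy-Weinberg, no linkage).
#'
#' @param config A [sim_config()].
#' @param seed Optional seed (`NULL` uses the current RNG stream).
#' @return List with `freqs` (allele, freq), `pool_genotypes` (the
#'   `n_pool_donors` HLA-typed pool), and `mapps_genotypes`.
#' @export
simulate_population <- function(config, seed = NULL) {
  with_optional_seed(seed, {
    g <- stats::rgamma(config$n_alleles,
                       shape = config$dirichlet_concentration)
    freqs <- tibble::tibble(
      allele = sprintf("DRB1*%02d:01", seq_len(config$n_alleles)),
      freq = g / sum(g)
    ) %>% dplyr::arrange(dplyr::desc(.data$freq))
    draw_genotypes <- function(n, prefix) {
      tibble::tibble(
        donor_id = sprintf("%s%03d", prefix, seq_len(n)),
        allele1 = sample(freqs$allele, n, replace = TRUE,
                         prob = freqs$freq),
        allele2 = sample(freqs$allele, n, replace = TRUE,
                         prob = freqs$freq)
      )
    }
    list(freqs = freqs,
         pool_genotypes = draw_genotypes(config$n_pool_donors, "T"),
         mapps_genotypes = draw_genotypes(config$n_mapps_donors, "M"))
  })
}

#' Simulate the planted ground truth
#'
#' Places `n_epitopes` non-overlapping epitope regions (one per equal-width
#' protein block, with margins so neighbouring epitopes stay well
#' separated), assigns each 1-3 presenting alleles drawn with probability
#' proportional to population frequency, and marks 1-3 responsive cytokine
#' markers per epitope.
#'
#' @param config A [sim_config()].
#' @param freqs Reference allele-frequency tibble.
#' @param seed Optional seed.
#' @return List of class `synthetic_truth`: `epitopes` tibble (`epitope_id`,
#'   `start`, `end`, list-columns `alleles` and `markers`).
#' @export
simulate_truth <- function(config, freqs, seed = NULL) {
  with_optional_seed(seed, {
    block <- config$protein_length %/% config$n_epitopes
    max_len <- config$epitope_length[2]
    if (block < max_len + 40L) {
      stop("protein too short for ", config$n_epitopes,
           " well-separated epitopes", call. = FALSE)
    }
    lens <- sample(seq(config$epitope_length[1], config$epitope_length[2]),
                   config$n_epitopes, replace = TRUE)
    offsets <- vapply(lens, function(l) {
      sample(seq(5L, block - l - 35L), 1L)
    }, integer(1))
    starts <- (seq_len(config$n_epitopes) - 1L) * block + offsets
    epitopes <- tibble::tibble(
      epitope_id = seq_len(config$n_epitopes),
      start = as.integer(starts),
      end = as.integer(starts + lens - 1L),
      alleles = purrr::map(seq_len(config$n_epitopes), function(i) {
        k <- sample(1:3, 1L)
        sort(sample(freqs$allele, k, prob = freqs$freq))
      }),
      markers = purrr::map(seq_len(config$n_epitopes), function(i) {
        k <- sample(seq_along(config$markers), 1L)
        sort(sample(config$markers, k))
      })
    )
    structure(list(epitopes = epitopes), class = "synthetic_truth")
  })
}

# pools a donor is expected to respond to: pools whose span overlaps an
# epitope presented by at least one of the donor's alleles, with the
# responsive markers of those epitopes
expected_responses <- function(truth, genotypes, pools) {
  carriers <- genotype_carriers(genotypes)
  purrr::map(seq_len(nrow(genotypes)), function(i) {
    donor <- genotypes$donor_id[i]
    own <- carriers$allele[carriers$donor_id == donor]
    ep <- truth$epitopes[
      vapply(truth$epitopes$alleles,
             function(a) length(intersect(a, own)) > 0L, logical(1)), ,
      drop = FALSE]
    if (nrow(ep) == 0L) {
      return(tibble::tibble(donor_id = character(), pool_id = integer(),
                            markers = list()))
    }
    hits <- purrr::map(seq_len(nrow(pools)), function(p) {
      keep <- ep$start <= pools$span_end[p] & ep$end >= pools$span_start[p]
      if (any(keep)) sort(unique(unlist(ep$markers[keep]))) else NULL
    })
    idx <- which(!vapply(hits, is.null, logical(1)))
    tibble::tibble(donor_id = donor, pool_id = pools$pool_id[idx],
                   markers = hits[idx])
  }) %>% dplyr::bind_rows()
}

#' Simulate gated stimulation cell counts
#'
#' Per (donor, stimulus, marker): total CD4+ count uniform in the
#' configured range, positive count binomial with the background rate,
#' multiplied by `effect_multiplier` when the donor is a planted responder
#' for that pool and the marker is responsive. One unstimulated row per
#' (donor, marker), an always-responding SEB control row, and one
#' whole-protein stimulus row (responding when the donor presents any
#' epitope) are included.
#'
#' @param config A [sim_config()].
#' @param truth Output of [simulate_truth()].
#' @param genotypes T-cell cohort genotypes.
#' @param pools Pool table from [assign_pools()].
#' @param seed Optional seed.
#' @return Long-format stimulation count tibble (see
#'   [call_responders()]).
#' @export
simulate_counts <- function(config, truth, genotypes, pools, seed = NULL) {
  with_optional_seed(seed, {
    expected <- expected_responses(truth, genotypes, pools)
    stimuli <- tibble::tibble(
      stimulus = c(pool_stimulus(pools$pool_id), "protein_full", "SEB",
                   "unstim"),
      stimulus_type = c(rep("pool", nrow(pools)), "protein", "control",
                        "unstimulated")
    )
    grid <- tidyr::expand_grid(donor_id = genotypes$donor_id,
                               stimulus = stimuli$stimulus,
                               marker = config$markers) %>%
      dplyr::left_join(stimuli, by = "stimulus")
    expected_key <- paste(expected$donor_id, expected$pool_id)
    protein_responders <- unique(expected$donor_id)
    multiplier <- purrr::pmap_dbl(
      list(grid$donor_id, grid$stimulus, grid$stimulus_type, grid$marker),
      function(donor, stim, type, marker) {
        if (type == "control") {
          return(config$seb_multiplier)
        }
        if (type == "pool") {
          j <- match(paste(donor, parse_pool_id(stim)), expected_key)
          if (!is.na(j) && marker %in% expected$markers[[j]]) {
            return(config$effect_multiplier)
          }
        }
        if (type == "protein" && donor %in% protein_responders) {
          return(config$effect_multiplier)
        }
        1
      })
    grid %>%
      dplyr::mutate(
        total_count = as.integer(round(stats::runif(
          dplyr::n(), config$total_cells[1], config$total_cells[2]))),
        positive_count = stats::rbinom(
          dplyr::n(), .data$total_count,
          pmin(config$background_rate * multiplier, 1))
      ) %>%
      dplyr::select("donor_id", "stimulus", "stimulus_type", "marker",
                    "positive_count", "total_count")
  })
}

#' Simulate MAPPs identifications
#'
#' For each immunopeptidomics donor and each planted epitope presented by
#' one of the donor's alleles, emits a ladder of nested/staggered peptides
#' (starts staggered by 1-3 residues, lengths a clipped normal(15, 3) in
#' 7-24, mimicking MHC-II length variants) whose spans overlap the epitope,
#' with Expect Values below the significance threshold. Decoy
#' identifications are added at rate `mapps_noise` per donor at random
#' positions with Expect Values spanning the threshold; a configurable
#' fraction of decoys are shuffled (unmappable) sequences.
#'
#' @param config A [sim_config()].
#' @param truth Output of [simulate_truth()].
#' @param genotypes MAPPs cohort genotypes.
#' @param protein Protein record.
#' @param seed Optional seed.
#' @return MAPPs tibble `donor_id`, `sequence`, `expect_value`, plus a
#'   logical `decoy` column retained for diagnostics (readers/writers drop
#'   nothing; the analysis never looks at it).
#' @export
simulate_mapps <- function(config, truth, genotypes, protein,
                           seed = NULL) {
  protein <- as_protein(protein)
  len <- protein_length(protein)
  with_optional_seed(seed, {
    carriers <- genotype_carriers(genotypes)
    rows <- list()
    draw_len <- function(n) {
      pmin(pmax(round(stats::rnorm(n, 15, 3)), 7L), 24L)
    }
    for (i in seq_len(nrow(genotypes))) {
      donor <- genotypes$donor_id[i]
      own <- carriers$allele[carriers$donor_id == donor]
      presented <- truth$epitopes[
        vapply(truth$epitopes$alleles,
               function(a) length(intersect(a, own)) > 0L, logical(1)), ,
        drop = FALSE]
      for (e in seq_len(nrow(presented))) {
        n_pep <- sample(seq(config$ladder_size[1], config$ladder_size[2]),
                        1L)
        s <- presented$start[e] - sample(0:3, 1L)
        for (p in seq_len(n_pep)) {
          l <- draw_len(1L)
          start <- max(1L, min(s, len - l + 1L))
          end <- min(len, start + l - 1L)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            donor_id = donor,
            sequence = protein_subseq(protein, start, end),
            expect_value = 10^stats::runif(1L, config$epitope_ev_log10[1],
                                           config$epitope_ev_log10[2]),
            decoy = FALSE)
          s <- s + sample(1:3, 1L)
          if (s > presented$end[e] - 6L) break
        }
      }
      n_decoy <- stats::rpois(1L, config$mapps_noise)
      for (d in seq_len(n_decoy)) {
        l <- draw_len(1L)
        start <- sample.int(len - l + 1L, 1L)
        seq_d <- protein_subseq(protein, start, start + l - 1L)
        if (stats::runif(1L) < config$decoy_unmappable_frac) {
          seq_d <- paste(sample(strsplit(seq_d, "")[[1L]]), collapse = "")
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          donor_id = donor, sequence = seq_d,
          expect_value = 10^stats::runif(1L, config$decoy_ev_log10[1],
                                         config$decoy_ev_log10[2]),
          decoy = TRUE)
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Simulate a complete study
#'
#' Runs the whole generator under one seed: protein, peptide library and
#' pools, reference population and genotypes, annealed T-cell cohort
#' selection from the donor pool, stimulation counts, and MAPPs
#' identifications, together with the planted truth.
#'
#' @param config A [sim_config()]; its `seed` drives everything.
#' @param select_iterations Annealing iterations for the embedded cohort
#'   selection (default 5000, plenty for a 50-donor pool).
#' @return List of class `synthetic_study` with elements `config`,
#'   `protein`, `library`, `pools`, `freqs`, `pool_genotypes`,
#'   `tcell_genotypes`, `mapps_genotypes`, `cohort`, `counts`, `mapps`,
#'   `truth`.
#' @export
simulate_study <- function(config = sim_config(),
                           select_iterations = 5000L) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    protein <- simulate_protein(config$protein_length)
    library <- peptide_library(protein, config$window, config$stagger,
                               config$pool_size)
    pools <- attr(library, "pools")
    pop <- simulate_population(config)
    cohort <- select_cohort(pop$pool_genotypes, config$n_tcell_donors,
                            pop$freqs, iterations = select_iterations)
    tcell_genotypes <- dplyr::filter(
      pop$pool_genotypes,
      .data$donor_id %in% cohort$selected_donor_ids)
    truth <- simulate_truth(config, pop$freqs)
    counts <- simulate_counts(config, truth, tcell_genotypes, pools)
    mapps <- simulate_mapps(config, truth, pop$mapps_genotypes, protein)
    structure(
      list(config = config, protein = protein, library = library,
           pools = pools, freqs = pop$freqs,
           pool_genotypes = pop$pool_genotypes,
           tcell_genotypes = tcell_genotypes,
           mapps_genotypes = pop$mapps_genotypes,
           cohort = cohort, counts = counts, mapps = mapps,
           truth = truth),
      class = "synthetic_study"
    )
  })
}

#' Span-overlap recovery metrics against the planted truth
#'
#' A planted epitope counts as recovered when some candidate overlaps it by
#' at least `min_overlap` residues; a candidate is a true positive when it
#' overlaps some planted epitope likewise. Precision over an empty
#' candidate list is 1 by convention.
#'
#' @param candidates Candidate tibble (`start`, `end`), e.g.
#'   `integrate_epitopes(...)$candidates`.
#' @param truth Output of [simulate_truth()].
#' @param min_overlap Minimum shared residues (default 9).
#' @return List with `precision`, `recall`, `n_candidates`, `n_epitopes`.
#' @export
recovery_metrics <- function(candidates, truth, min_overlap = 9L) {
  ep <- truth$epitopes
  overlap_len <- function(s1, e1, s2, e2) {
    pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
  }
  recovered <- vapply(seq_len(nrow(ep)), function(i) {
    nrow(candidates) > 0L &&
      any(overlap_len(ep$start[i], ep$end[i], candidates$start,
                      candidates$end) >= min_overlap)
  }, logical(1))
  true_pos <- vapply(seq_len(nrow(candidates)), function(j) {
    any(overlap_len(candidates$start[j], candidates$end[j], ep$start,
                    ep$end) >= min_overlap)
  }, logical(1))
  list(
    precision = if (nrow(candidates) == 0L) 1 else mean(true_pos),
    recall = mean(recovered),
    n_candidates = nrow(candidates),
    n_epitopes = nrow(ep)
  )
}

#' Write every table of a simulated study to a directory
#'
#' Emits the five input-table roles (allele frequencies, pool and MAPPs
#' genotypes, stimulation counts, MAPPs identifications), the protein
#' FASTA, the peptide library, and a plain-text truth table, using the same
#' formats the pipeline readers consume.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "protein.fasta"),
    library = file.path(dir, "library.tsv"),
    allele_freqs = file.path(dir, "allele_freqs.tsv"),
    genotypes_tcell = file.path(dir, "genotypes_tcell.tsv"),
    genotypes_mapps = file.path(dir, "genotypes_mapps.tsv"),
    counts = file.path(dir, "counts.tsv"),
    mapps = file.path(dir, "mapps.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_protein_fasta(study$protein, paths["fasta"])
  write_peptide_library(study$library, paths["library"])
  readr::write_tsv(study$freqs, paths["allele_freqs"])
  readr::write_tsv(study$tcell_genotypes, paths["genotypes_tcell"])
  readr::write_tsv(study$mapps_genotypes, paths["genotypes_mapps"])
  readr::write_tsv(study$counts, paths["counts"])
  readr::write_tsv(study$mapps[, c("donor_id", "sequence",
                                   "expect_value")], paths["mapps"])
  truth_flat <- study$truth$epitopes %>%
    dplyr::mutate(
      alleles = vapply(.data$alleles, paste, character(1),
                       collapse = ","),
      markers = vapply(.data$markers, paste, character(1),
                       collapse = ","))
  readr::write_tsv(truth_flat, paths["truth"])
  invisible(paths)
}
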