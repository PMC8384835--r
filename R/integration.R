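# Integration of the two assays: HLA-based donor matching, residue-level
# intersection of MAPPs identifications with positive peptide-pool spans,
# run decomposition and length filtering, and the final cross-reference
# against distinct MAPPs regions.

#' Match donors across the two assay cohorts by shared DRB1 alleles
#'
#' Two donors match when their DRB1 genotypes share at least one allele.
#' All cross-cohort pairs are returned; one immunopeptidomics donor may
#' match several T-cell donors and vice versa.
#'
#' @param mapps_genotypes,tcell_genotypes Genotype tibbles for the
#'   immunopeptidomics and T-cell assay cohorts.
#' @return Tibble `mapps_donor_id`, `tcell_donor_id`, `n_shared`,
#'   list-column `shared_alleles`.
#' @export
match_donors <- function(mapps_genotypes, tcell_genotypes) {
  validate_genotypes(mapps_genotypes, "MAPPs genotype table")
  validate_genotypes(tcell_genotypes, "T-cell genotype table")
  pairs <- tidyr::expand_grid(
    mapps_donor_id = mapps_genotypes$donor_id,
    tcell_donor_id = tcell_genotypes$donor_id
  )
  m_alleles <- purrr::map(
    seq_len(nrow(mapps_genotypes)),
    function(i) unique(c(mapps_genotypes$allele1[i],
                         mapps_genotypes$allele2[i])))
  names(m_alleles) <- mapps_genotypes$donor_id
  t_alleles <- purrr::map(
    seq_len(nrow(tcell_genotypes)),
    function(i) unique(c(tcell_genotypes$allele1[i],
                         tcell_genotypes$allele2[i])))
  names(t_alleles) <- tcell_genotypes$donor_id
  pairs$shared_alleles <- purrr::map2(
    pairs$mapps_donor_id, pairs$tcell_donor_id,
    function(m, t) sort(intersect(m_alleles[[m]], t_alleles[[t]])))
  pairs %>%
    dplyr::mutate(n_shared = lengths(.data$shared_alleles)) %>%
    dplyr::filter(.data$n_shared > 0L) %>%
    dplyr::select("mapps_donor_id", "tcell_donor_id", "n_shared",
                  "shared_alleles")
}

#' Residues supported by both assays for one matched donor pair
#'
#' For a matched pair, the supported residues are the union over all
#' (MAPPs peptide, positive pool) combinations of the residue-level
#' intersection of the peptide span with the pool span — equivalently, the
#' residues covered by at least one MAPPs peptide of the
#' immunopeptidomics donor and at least one positive pool of the T-cell
#' donor. With `mode = "contained"` only peptides fully inside a positive
#' pool span contribute, and they contribute their whole span.
#'
#' @param mapps_spans Tibble of the MAPPs donor's mapped peptide spans
#'   (`start`, `end`).
#' @param pool_spans Tibble of the T-cell donor's positive pool spans
#'   (`span_start`, `span_end`).
#' @param mode `"partial"` (default): residue intersection; `"contained"`:
#'   full containment required.
#' @return Sorted integer vector of residue positions (possibly empty).
#' @export
matched_residues <- function(mapps_spans, pool_spans,
                             mode = c("partial", "contained")) {
  mode <- match.arg(mode)
  check_columns(mapps_spans, c("start", "end"), "MAPPs spans")
  check_columns(pool_spans, c("span_start", "span_end"), "pool spans")
  if (nrow(mapps_spans) == 0L || nrow(pool_spans) == 0L) {
    return(integer(0))
  }
  pep <- IRanges::IRanges(mapps_spans$start, mapps_spans$end)
  pool <- IRanges::IRanges(pool_spans$span_start, pool_spans$span_end)
  if (mode == "contained") {
    hits <- IRanges::findOverlaps(pep, pool, type = "within")
    pep <- pep[unique(S4Vectors::queryHits(hits))]
    if (length(pep) == 0L) {
      return(integer(0))
    }
    covered <- IRanges::reduce(pep)
  } else {
    covered <- IRanges::intersect(IRanges::reduce(pep),
                                  IRanges::reduce(pool))
  }
  sort(unique(unlist(purrr::map2(IRanges::start(covered),
                                 IRanges::end(covered), seq.int))))
}

#' Decompose a residue set into maximal runs and filter short runs
#'
#' Takes the union of all supplied residue sets, splits it into maximal
#' runs of consecutive positions, and discards runs shorter than
#' `min_length` (boundary inclusive: a run of exactly `min_length` is
#' kept).
#'
#' @param residue_sets Integer vector of residue positions, or a list of
#'   such vectors (one per matched donor pair) whose union is taken.
#' @param min_length Minimum run length retained (default 9).
#' @return Tibble `start`, `end`, `length`, sorted by `start`.
#' @export
combine_and_filter <- function(residue_sets, min_length = 9L) {
  if (is.list(residue_sets)) {
    residue_sets <- unlist(residue_sets)
  }
  residues <- sort(unique(as.integer(residue_sets)))
  if (length(residues) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          length = integer()))
  }
  breaks <- c(0L, which(diff(residues) > 1L), length(residues))
  runs <- tibble::tibble(
    start = residues[breaks[-length(breaks)] + 1L],
    end = residues[breaks[-1L]]
  ) %>%
    dplyr::mutate(length = .data$end - .data$start + 1L) %>%
    dplyr::filter(.data$length >= min_length) %>%
    dplyr::arrange(.data$start)
  runs
}

#' Cross-reference surviving intervals with distinct MAPPs regions
#'
#' Reports every distinct MAPPs region (or distinct peptide sequence) whose
#' span overlaps a surviving interval by at least `min_overlap` residues.
#' The candidate's coordinates and sequence are those of the MAPPs region
#' on the protein.
#'
#' @param intervals Output of [combine_and_filter()].
#' @param regions Cohort-scope [merge_regions()] output (or any tibble with
#'   `start`, `end`).
#' @param protein Protein record, used to attach candidate sequences.
#' @param min_overlap Minimum shared residues between region and interval
#'   (default 9, so candidates honour the epitope length filter).
#' @return Tibble `start`, `end`, `sequence`, `overlap` (best shared
#'   residue count), plus any extra columns carried on `regions`.
#' @export
cross_reference <- function(intervals, regions, protein,
                            min_overlap = 9L) {
  check_columns(intervals, c("start", "end"), "intervals")
  check_columns(regions, c("start", "end"), "MAPPs regions")
  protein <- as_protein(protein)
  if (nrow(regions) == 0L || nrow(intervals) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          sequence = character(), overlap = integer()))
  }
  reg <- IRanges::IRanges(regions$start, regions$end)
  itv <- IRanges::IRanges(intervals$start, intervals$end)
  ov <- IRanges::findOverlaps(reg, itv,
                              minoverlap = as.integer(min_overlap))
  if (length(ov) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          sequence = character(), overlap = integer()))
  }
  width <- IRanges::width(IRanges::pintersect(
    reg[S4Vectors::queryHits(ov)], itv[S4Vectors::subjectHits(ov)]))
  hit <- tibble::tibble(idx = S4Vectors::queryHits(ov), overlap = width) %>%
    dplyr::group_by(.data$idx) %>%
    dplyr::summarise(overlap = max(.data$overlap), .groups = "drop")
  regions[hit$idx, , drop = FALSE] %>%
    dplyr::mutate(overlap = hit$overlap,
                  sequence = protein_subseq(protein, .data$start,
                                            .data$end)) %>%
    dplyr::relocate("start", "end", "sequence", "overlap") %>%
    dplyr::arrange(.data$start)
}

#' Run the full two-assay integration
#'
#' The four-step procedure producing the final epitope list:
#' \enumerate{
#'   \item match donors across cohorts by shared DRB1 alleles
#'     ([match_donors()]);
#'   \item per matched pair, intersect the MAPPs donor's peptide spans with
#'     the T-cell donor's positive pool spans at residue level
#'     ([matched_residues()]);
#'   \item take the union of matched residues over all pairs, split into
#'     maximal runs, and drop runs shorter than `min_length`
#'     ([combine_and_filter()]);
#'   \item cross-reference the surviving intervals with distinct
#'     cohort-scope MAPPs regions ([cross_reference()]).
#' }
#' Each candidate carries the matched donor pairs whose residues intersect
#' its span and the union of their shared alleles.
#'
#' @param calls Responder calls ([call_responders()]) for the T-cell cohort.
#' @param mapps Mapped, EV-filtered MAPPs tibble.
#' @param tcell_genotypes,mapps_genotypes Genotypes for the two cohorts.
#' @param pools Pool table ([assign_pools()]); pool `stimulus` labels in
#'   `calls` must follow `pool_01`, `pool_02`, ...
#' @param protein Protein record.
#' @param min_length Minimum epitope length in residues (default 9), used
#'   both for run filtering and the final overlap requirement.
#' @param mode Residue-matching mode, see [matched_residues()].
#' @param distinct `"region"` (default): cross-reference merged MAPPs
#'   regions; `"sequence"`: distinct peptide sequences.
#' @return Object of class `epitope_integration`: list with `candidates`
#'   (tibble `start`, `end`, `sequence`, `overlap`, `n_matches`,
#'   `supporting_matches`, `associated_alleles`), `intervals`, `matches`,
#'   `regions`, and `residues_by_match`.
#' @export
integrate_epitopes <- function(calls, mapps, tcell_genotypes,
                               mapps_genotypes, pools, protein,
                               min_length = 9L,
                               mode = c("partial", "contained"),
                               distinct = c("region", "sequence")) {
  mode <- match.arg(mode)
  distinct <- match.arg(distinct)
  validate_mapps(mapps, mapped = TRUE)
  check_columns(pools, c("pool_id", "span_start", "span_end"),
                "pool table")
  protein <- as_protein(protein)

  matches <- match_donors(mapps_genotypes, tcell_genotypes)

  pos_pools <- donor_positive(calls) %>%
    dplyr::filter(.data$stimulus_type == "pool", .data$positive) %>%
    dplyr::mutate(pool_id = parse_pool_id(.data$stimulus)) %>%
    dplyr::inner_join(pools, by = "pool_id")

  residues_by_match <- purrr::map(seq_len(nrow(matches)), function(i) {
    pep <- dplyr::filter(mapps,
                         .data$donor_id == matches$mapps_donor_id[i])
    pl <- dplyr::filter(pos_pools,
                        .data$donor_id == matches$tcell_donor_id[i])
    matched_residues(pep, pl, mode = mode)
  })

  intervals <- combine_and_filter(residues_by_match,
                                  min_length = min_length)

  regions <- if (distinct == "region") {
    merge_regions(mapps, scope = "cohort")
  } else {
    mapps %>%
      dplyr::distinct(.data$sequence, .data$start, .data$end) %>%
      dplyr::arrange(.data$start)
  }

  candidates <- cross_reference(intervals, regions, protein,
                                min_overlap = min_length)

  if (nrow(candidates) > 0L) {
    support <- purrr::map(seq_len(nrow(candidates)), function(i) {
      span <- seq.int(candidates$start[i], candidates$end[i])
      which(vapply(residues_by_match,
                   function(r) any(r %in% span), logical(1)))
    })
    candidates$n_matches <- lengths(support)
    candidates$supporting_matches <- purrr::map(support, function(i) {
      matches[i, c("mapps_donor_id", "tcell_donor_id")]
    })
    candidates$associated_alleles <- purrr::map(support, function(i) {
      sort(unique(unlist(matches$shared_alleles[i])))
    })
  } else {
    candidates$n_matches <- integer(0)
    candidates$supporting_matches <- list()
    candidates$associated_alleles <- list()
  }

  structure(
    list(candidates = candidates, intervals = intervals,
         matches = matches, regions = regions,
         residues_by_match = residues_by_match,
         min_length = min_length, mode = mode, distinct = distinct),
    class = "epitope_integration"
  )
}

#' @export
print.epitope_integration <- function(x, ...) {
  cat("<epitope_integration> ", nrow(x$candidates), " candidate(s) from ",
      nrow(x$matches), " matched donor pair(s), ",
      nrow(x$intervals), " surviving interval(s)\n", sep = "")
  invisible(x)
}

#' Cumulative population frequency covered by the final epitope list
#'
#' Sums reference frequencies over the union of alleles associated with any
#' candidate; `mode = "carrier"` instead reports the Hardy-Weinberg
#' probability of carrying at least one such allele.
#'
#' @param integration `epitope_integration` object or candidate tibble with
#'   an `associated_alleles` list-column.
#' @param freqs Reference allele-frequency tibble.
#' @param mode `"cumulative"` (default) or `"carrier"`.
#' @return Percentage in \[0, 100\].
#' @export
epitope_population_coverage <- function(integration, freqs,
                                        mode = c("cumulative", "carrier")) {
  mode <- match.arg(mode)
  candidates <- if (inherits(integration, "epitope_integration")) {
    integration$candidates
  } else {
    integration
  }
  alleles <- unique(unlist(candidates$associated_alleles))
  if (mode == "cumulative") {
    cumulative_allele_frequency(alleles, freqs)
  } else {
    carrier_coverage(alleles, freqs)
  }
}

#' Write the final candidate table to TSV
#'
#' List-columns are flattened to comma-separated strings.
#'
#' @param integration `epitope_integration` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epitope_candidates <- function(integration, path) {
  cand <- integration$candidates
  flat <- tibble::tibble(
    start = cand$start,
    end = cand$end,
    sequence = cand$sequence,
    length = cand$end - cand$start + 1L,
    overlap = cand$overlap,
    n_matches = cand$n_matches,
    supporting_pairs = vapply(
      cand$supporting_matches,
      function(m) paste(m$mapps_donor_id, m$tcell_donor_id, sep = ":",
                        collapse = ","),
      character(1)),
    associated_alleles = vapply(
      cand$associated_alleles, paste, character(1), collapse = ",")
  )
  readr::write_tsv(flat, path)
  invisible(path)
}
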