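# Allele-by-stimulus association maps under the "any" and "all" carrier
# rules, frequency-weighted promiscuity scores, and cumulative population
# allele frequency.

#' Build an allele-by-stimulus association map
#'
#' A donor "carries" an allele if it occupies either DRB1 slot (homozygotes
#' count once). Under the `any` rule an (allele, stimulus) cell is true when
#' at least one carrier responds to the stimulus; under the stricter `all`
#' rule every carrier in the cohort must respond. Only alleles carried by at
#' least one donor in the calls appear in the map.
#'
#' @param calls Output of [call_responders()].
#' @param genotypes Genotype tibble covering every donor in `calls`.
#' @param rule `"any"` (default) or `"all"`.
#' @param stimulus_types Which stimulus types to map (default `"pool"`).
#' @return Tibble `allele`, `stimulus`, `stimulus_type`, `n_carriers`,
#'   `n_positive_carriers`, `associated`, and list-column
#'   `supporting_donors` (positive carriers); the rule is recorded both as a
#'   `rule` column and attribute.
#' @export
build_association_map <- function(calls, genotypes, rule = c("any", "all"),
                                  stimulus_types = "pool") {
  rule <- match.arg(rule)
  validate_genotypes(genotypes)
  dp <- donor_positive(calls) %>%
    dplyr::filter(.data$stimulus_type %in% stimulus_types)
  missing <- setdiff(unique(dp$donor_id), genotypes$donor_id)
  if (length(missing) > 0L) {
    stop("no genotype for donor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  carriers <- genotype_carriers(genotypes) %>%
    dplyr::filter(.data$donor_id %in% dp$donor_id)

  map <- carriers %>%
    dplyr::inner_join(dp, by = "donor_id",
                      relationship = "many-to-many") %>%
    dplyr::group_by(.data$allele, .data$stimulus, .data$stimulus_type) %>%
    dplyr::summarise(
      n_carriers = dplyr::n(),
      n_positive_carriers = sum(.data$positive),
      supporting_donors = list(sort(.data$donor_id[.data$positive])),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      associated = if (rule == "any") .data$n_positive_carriers >= 1L
                   else .data$n_positive_carriers == .data$n_carriers,
      rule = rule
    ) %>%
    dplyr::arrange(.data$allele, .data$stimulus)
  attr(map, "rule") <- rule
  map
}

#' Frequency-weighted promiscuity score per stimulus
#'
#' For each stimulus, sums the reference-population frequencies of the
#' alleles associated with it, approximating the fraction of the population
#' whose MHC-II repertoire could engage the stimulus. Alleles missing from
#' the frequency table contribute zero with a warning. The unweighted
#' associated-allele count is reported alongside.
#'
#' @param map Output of [build_association_map()].
#' @param freqs Reference allele-frequency tibble (`allele`, `freq`).
#' @return Tibble `stimulus`, `stimulus_type`, `n_alleles`, `score`.
#' @export
promiscuity_scores <- function(map, freqs) {
  check_columns(map, c("allele", "stimulus", "stimulus_type", "associated"),
                "association map")
  check_columns(freqs, c("allele", "freq"), "allele-frequency table")
  assoc <- dplyr::filter(map, .data$associated)
  unknown <- setdiff(unique(assoc$allele), freqs$allele)
  if (length(unknown) > 0L) {
    warning("allele(s) absent from the frequency table contribute 0: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  scores <- assoc %>%
    dplyr::left_join(freqs, by = "allele") %>%
    dplyr::mutate(freq = dplyr::coalesce(.data$freq, 0)) %>%
    dplyr::group_by(.data$stimulus, .data$stimulus_type) %>%
    dplyr::summarise(n_alleles = dplyr::n(), score = sum(.data$freq),
                     .groups = "drop")
  # stimuli with no associated allele score 0, not NA
  dplyr::distinct(map, .data$stimulus, .data$stimulus_type) %>%
    dplyr::left_join(scores, by = c("stimulus", "stimulus_type")) %>%
    dplyr::mutate(n_alleles = dplyr::coalesce(.data$n_alleles, 0L),
                  score = dplyr::coalesce(.data$score, 0)) %>%
    dplyr::arrange(.data$stimulus)
}

#' Cumulative population frequency of a set of alleles
#'
#' Plain sum of reference frequencies over the distinct alleles, expressed
#' as a percentage (no diploidy or linkage correction). For the probability
#' that a random diploid individual carries at least one of the alleles, see
#' [carrier_coverage()].
#'
#' @param alleles Character vector of allele names (duplicates count once).
#' @param freqs Reference allele-frequency tibble.
#' @return Percentage in \[0, 100\].
#' @export
cumulative_allele_frequency <- function(alleles, freqs) {
  check_columns(freqs, c("allele", "freq"), "allele-frequency table")
  alleles <- unique(alleles)
  if (length(alleles) == 0L) {
    return(0)
  }
  f <- freqs$freq[match(alleles, freqs$allele)]
  if (anyNA(f)) {
    warning("allele(s) absent from the frequency table contribute 0: ",
            paste(alleles[is.na(f)], collapse = ", "), call. = FALSE)
    f[is.na(f)] <- 0
  }
  100 * sum(f)
}

#' Carrier coverage of a set of alleles under Hardy-Weinberg
#'
#' `100 * (1 - (1 - sum(f))^2)`: the percentage of diploid individuals
#' expected to carry at least one of the alleles.
#'
#' @inheritParams cumulative_allele_frequency
#' @return Percentage in \[0, 100\].
#' @export
carrier_coverage <- function(alleles, freqs) {
  total <- cumulative_allele_frequency(alleles, freqs) / 100
  100 * (1 - (1 - min(total, 1))^2)
}

#' Write an association map as a 0/1 allele-by-stimulus TSV matrix
#'
#' @param map Output of [build_association_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_matrix <- function(map, path) {
  wide <- map %>%
    dplyr::mutate(value = as.integer(.data$associated)) %>%
    dplyr::select("allele", "stimulus", "value") %>%
    tidyr::pivot_wider(names_from = "stimulus", values_from = "value",
                       values_fill = 0L) %>%
    dplyr::arrange(.data$allele)
  readr::write_tsv(wide, path)
  invisible(path)
}
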