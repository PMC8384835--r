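# MHC-II immunopeptidomics (MAPPs) processing: Expect-Value filtering,
# mapping identifications onto the protein, merging nested/staggered length
# variants into continuous regions, and the cohort summary table.

validate_mapps <- function(peptides, mapped = FALSE) {
  cols <- c("donor_id", "sequence", "expect_value")
  if (mapped) cols <- c(cols, "start", "end")
  check_columns(peptides, cols, "MAPPs identification table")
  if (any(peptides$expect_value <= 0)) {
    stop("expect_value must be positive", call. = FALSE)
  }
  invisible(peptides)
}

#' Filter MAPPs identifications by Expect Value
#'
#' Keeps identifications whose search-engine Expect Value is at or below the
#' threshold (boundary inclusive). EV <= 0.05 is the conventional cutoff for
#' confident identifications.
#'
#' @param peptides MAPPs tibble with `donor_id`, `sequence`, `expect_value`.
#' @param threshold Maximum Expect Value retained (default 0.05).
#' @return Filtered tibble.
#' @export
filter_by_expect_value <- function(peptides, threshold = 0.05) {
  validate_mapps(peptides)
  dplyr::filter(peptides, .data$expect_value <= threshold)
}

#' Map MAPPs peptides onto the protein sequence
#'
#' Assigns 1-based inclusive coordinates by exact substring search
#' ([locate_peptide()]). Identifications that do not occur in the protein
#' are dropped with a single warning reporting how many; the count is also
#' attached as the `"n_unmapped"` attribute. Peptides with several exact
#' occurrences take the first and are counted in the `"n_ambiguous"`
#' attribute.
#'
#' @param peptides MAPPs tibble (ideally already EV-filtered).
#' @param protein Protein to map against.
#' @return Tibble with added `start`, `end` columns.
#' @export
map_mapps_peptides <- function(peptides, protein) {
  validate_mapps(peptides)
  protein <- as_protein(protein)
  loc <- purrr::map(peptides$sequence, function(s) {
    tryCatch(locate_peptide(protein, s),
             error = function(e) tibble::tibble(start = NA_integer_,
                                                end = NA_integer_,
                                                n_matches = 0L))
  }) %>%
    dplyr::bind_rows()
  out <- dplyr::bind_cols(peptides,
                          loc[, c("start", "end", "n_matches")])
  n_unmapped <- sum(is.na(out$start))
  n_ambiguous <- sum(out$n_matches > 1L, na.rm = TRUE)
  if (n_unmapped > 0L) {
    warning("dropped ", n_unmapped,
            " MAPPs identification(s) not found in protein '",
            protein$id, "'", call. = FALSE)
    out <- dplyr::filter(out, !is.na(.data$start))
  }
  if (n_ambiguous > 0L) {
    warning(n_ambiguous, " identification(s) occur more than once in the ",
            "protein; first occurrence used", call. = FALSE)
  }
  out$n_matches <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_ambiguous") <- n_ambiguous
  out
}

#' Merge mapped peptides into maximal continuous regions
#'
#' Peptides whose residue spans overlap by at least `min_overlap` residues
#' (default 1; merely adjacent spans stay separate) are merged transitively
#' into maximal, sorted, non-overlapping regions. With `scope = "donor"`
#' merging is done within each donor, matching the per-donor unique-peptide
#' counts; `scope = "cohort"` pools all donors first.
#'
#' @param peptides Mapped MAPPs tibble (with `start`, `end`).
#' @param scope `"cohort"` (default) or `"donor"`.
#' @param min_overlap Minimum shared residues for two spans to merge.
#' @return Tibble `donor_id` (`NA` at cohort scope), `start`, `end`,
#'   `n_peptides`, `n_donors`, list-column `donors`.
#' @export
merge_regions <- function(peptides, scope = c("cohort", "donor"),
                          min_overlap = 1L) {
  scope <- match.arg(scope)
  validate_mapps(peptides, mapped = TRUE)
  stopifnot(min_overlap >= 1L)
  merge_one <- function(df, donor) {
    if (nrow(df) == 0L) {
      return(tibble::tibble(donor_id = character(), start = integer(),
                            end = integer(), n_peptides = integer(),
                            n_donors = integer(), donors = list()))
    }
    ir <- IRanges::IRanges(start = df$start, end = df$end)
    # reduce() merges ranges whose gap < min.gapwidth; an overlap of k
    # residues is a gap of -k, so requiring overlap >= min_overlap means
    # min.gapwidth = 1 - min_overlap
    red <- IRanges::reduce(ir, min.gapwidth = 1L - as.integer(min_overlap))
    # every input span lies within exactly one reduced region
    hits <- IRanges::findOverlaps(ir, red, type = "within")
    members <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
    tibble::tibble(
      donor_id = donor,
      start = IRanges::start(red),
      end = IRanges::end(red),
      n_peptides = unname(lengths(members)),
      n_donors = unname(vapply(members,
                               function(i) dplyr::n_distinct(df$donor_id[i]),
                               integer(1))),
      donors = unname(purrr::map(members,
                                 function(i) sort(unique(df$donor_id[i]))))
    )
  }
  if (scope == "cohort") {
    merge_one(peptides, NA_character_)
  } else {
    peptides %>%
      dplyr::group_by(.data$donor_id) %>%
      dplyr::group_split() %>%
      purrr::map(~ merge_one(.x, .x$donor_id[1L])) %>%
      dplyr::bind_rows() %>%
      dplyr::arrange(.data$donor_id, .data$start)
  }
}

#' Summary statistics of a MAPPs dataset
#'
#' One-row table in the style of a cohort immunopeptidomics summary: donor
#' count, total identifications, unique continuous regions (cohort scope),
#' distinct peptide sequences, per-identification length statistics, and
#' mean identifications per donor.
#'
#' @param peptides Mapped MAPPs tibble.
#' @param regions Optional precomputed cohort-scope [merge_regions()]
#'   output; computed if omitted.
#' @return One-row tibble.
#' @export
summarize_mapps <- function(peptides, regions = NULL) {
  validate_mapps(peptides, mapped = TRUE)
  if (is.null(regions)) {
    regions <- merge_regions(peptides, scope = "cohort")
  }
  lens <- nchar(peptides$sequence)
  n_donors <- dplyr::n_distinct(peptides$donor_id)
  tibble::tibble(
    n_donors = n_donors,
    n_identifications = nrow(peptides),
    n_unique_regions = nrow(regions),
    n_distinct_sequences = dplyr::n_distinct(peptides$sequence),
    length_min = min(lens),
    length_max = max(lens),
    length_median = stats::median(lens),
    mean_per_donor = nrow(peptides) / n_donors
  )
}

#' Unique continuous regions per donor
#'
#' @param peptides Mapped MAPPs tibble.
#' @param min_overlap See [merge_regions()].
#' @return Tibble `donor_id`, `n_regions`.
#' @export
per_donor_unique_counts <- function(peptides, min_overlap = 1L) {
  merge_regions(peptides, scope = "donor", min_overlap = min_overlap) %>%
    dplyr::count(.data$donor_id, name = "n_regions")
}

#' Read a MAPPs identification table from TSV
#'
#' @param path TSV with columns `donor_id`, `sequence`, `expect_value`.
#' @return Validated tibble (sequences uppercased).
#' @export
read_mapps_table <- function(path) {
  peptides <- readr::read_tsv(path, col_types = readr::cols(
    donor_id = readr::col_character(),
    sequence = readr::col_character(),
    expect_value = readr::col_double()))
  peptides$sequence <- toupper(peptides$sequence)
  validate_mapps(peptides)
  peptides
}
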