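# Responder calling from gated cell counts: one-sided Fisher exact tests
# against each donor's unstimulated sample, Holm step-down adjustment
# within a per-donor family, and the derived cohort summaries.

STIMULUS_TYPES <- c("pool", "protein", "control", "unstimulated")

validate_counts <- function(records) {
  check_columns(records,
                c("donor_id", "stimulus", "stimulus_type", "marker",
                  "positive_count", "total_count"),
                "stimulation count table")
  bad_type <- setdiff(unique(records$stimulus_type), STIMULUS_TYPES)
  if (length(bad_type) > 0L) {
    stop("unknown stimulus_type value(s): ",
         paste(bad_type, collapse = ", "), call. = FALSE)
  }
  if (any(records$total_count <= 0L)) {
    stop("total_count must be positive", call. = FALSE)
  }
  if (any(records$positive_count < 0L |
            records$positive_count > records$total_count)) {
    stop("positive_count must lie in [0, total_count]", call. = FALSE)
  }
  invisible(records)
}

#' One-sided Fisher exact p-value for stimulated vs unstimulated counts
#'
#' Exact p-value for the one-sided hypothesis that the stimulated
#' positive-cell proportion exceeds the unstimulated proportion, i.e. the
#' upper hypergeometric tail of the 2x2 table
#' `[[stim_pos, stim_total - stim_pos], [unstim_pos, unstim_total -
#' unstim_pos]]` conditioned on its margins. Vectorised over all four
#' arguments. When enrichment is impossible (e.g. `stim_pos = 0`) the
#' p-value is 1, never an error.
#'
#' @param stim_pos,stim_total Positive and total cell counts under
#'   stimulation.
#' @param unstim_pos,unstim_total Counts for the matched unstimulated
#'   sample.
#' @return Vector of exact p-values.
#' @export
#' @examples
#' fisher_one_sided(30, 10000, 10, 10000)
fisher_one_sided <- function(stim_pos, stim_total, unstim_pos,
                             unstim_total) {
  if (any(stim_total <= 0L) || any(unstim_total <= 0L)) {
    stop("total counts must be positive", call. = FALSE)
  }
  if (any(stim_pos < 0L) || any(unstim_pos < 0L) ||
        any(stim_pos > stim_total) || any(unstim_pos > unstim_total)) {
    stop("positive counts must lie in [0, total]", call. = FALSE)
  }
  stats::phyper(stim_pos - 1,
                m = stim_pos + unstim_pos,
                n = (stim_total - stim_pos) + (unstim_total - unstim_pos),
                k = stim_total,
                lower.tail = FALSE)
}

#' Holm step-down adjustment
#'
#' Family-wise error controlling step-down adjustment: sort ascending,
#' multiply the i-th smallest by (m - i + 1), enforce monotonicity with a
#' running maximum, cap at 1, and return in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Call positive responders per donor, stimulus, and marker
#'
#' Each stimulated row is tested against the same donor and marker's
#' unstimulated row with [fisher_one_sided()]. Raw p-values are Holm-adjusted
#' within a family, by default all stimulus-by-marker tests of one donor,
#' and a call is positive when the adjusted p falls below `alpha`.
#'
#' @param records Long stimulation count table with columns `donor_id`,
#'   `stimulus`, `stimulus_type` (one of pool/protein/control/unstimulated),
#'   `marker`, `positive_count`, `total_count`. Every (donor, marker) must
#'   have exactly one unstimulated row.
#' @param alpha Significance level on the adjusted scale (default 0.05).
#' @param family `"donor"` (default): adjust within each donor's tests;
#'   `"global"`: one family across all donors.
#' @return Tibble of calls: `donor_id`, `stimulus`, `stimulus_type`,
#'   `marker`, `raw_p`, `adjusted_p`, `positive`; `alpha` stored as an
#'   attribute.
#' @export
call_responders <- function(records, alpha = 0.05,
                            family = c("donor", "global")) {
  family <- match.arg(family)
  validate_counts(records)

  unstim <- records %>%
    dplyr::filter(.data$stimulus_type == "unstimulated") %>%
    dplyr::select("donor_id", "marker",
                  unstim_pos = "positive_count",
                  unstim_total = "total_count")
  dup <- unstim %>%
    dplyr::count(.data$donor_id, .data$marker) %>%
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("multiple unstimulated rows for donor/marker: ",
         paste(dup$donor_id, dup$marker, sep = "/", collapse = ", "),
         call. = FALSE)
  }

  stim <- dplyr::filter(records, .data$stimulus_type != "unstimulated")
  joined <- dplyr::left_join(stim, unstim, by = c("donor_id", "marker"))
  if (anyNA(joined$unstim_total)) {
    miss <- joined %>%
      dplyr::filter(is.na(.data$unstim_total)) %>%
      dplyr::distinct(.data$donor_id, .data$marker)
    stop("missing unstimulated row for donor/marker: ",
         paste(miss$donor_id, miss$marker, sep = "/", collapse = ", "),
         call. = FALSE)
  }

  calls <- joined %>%
    dplyr::mutate(raw_p = fisher_one_sided(.data$positive_count,
                                           .data$total_count,
                                           .data$unstim_pos,
                                           .data$unstim_total))
  calls <- if (family == "donor") {
    calls %>%
      dplyr::group_by(.data$donor_id) %>%
      dplyr::mutate(adjusted_p = holm_adjust(.data$raw_p)) %>%
      dplyr::ungroup()
  } else {
    dplyr::mutate(calls, adjusted_p = holm_adjust(.data$raw_p))
  }
  out <- calls %>%
    dplyr::mutate(positive = .data$adjusted_p < alpha) %>%
    dplyr::select("donor_id", "stimulus", "stimulus_type", "marker",
                  "raw_p", "adjusted_p", "positive")
  attr(out, "alpha") <- alpha
  out
}

#' Collapse marker-level calls to a donor-by-stimulus response
#'
#' The worst-case rule: a donor responds to a stimulus if any measured
#' cytokine marker gave a positive call.
#'
#' @param calls Output of [call_responders()].
#' @return Tibble `donor_id`, `stimulus`, `stimulus_type`, `positive`.
#' @export
donor_positive <- function(calls) {
  check_columns(calls, c("donor_id", "stimulus", "stimulus_type",
                         "positive"), "responder calls")
  calls %>%
    dplyr::group_by(.data$donor_id, .data$stimulus, .data$stimulus_type) %>%
    dplyr::summarise(positive = any(.data$positive), .groups = "drop")
}

#' Percent of donors responding to each stimulus
#'
#' @param calls Output of [call_responders()].
#' @return Tibble `stimulus`, `stimulus_type`, `n_positive`, `n_donors`,
#'   `percent`.
#' @export
percent_responders <- function(calls) {
  dp <- donor_positive(calls)
  n_donors <- dplyr::n_distinct(dp$donor_id)
  if (n_donors == 0L) {
    stop("no donors in calls", call. = FALSE)
  }
  dp %>%
    dplyr::group_by(.data$stimulus, .data$stimulus_type) %>%
    dplyr::summarise(n_positive = sum(.data$positive), .groups = "drop") %>%
    dplyr::mutate(n_donors = n_donors,
                  percent = 100 * .data$n_positive / n_donors)
}

#' Number of positive peptide pools per donor
#'
#' Counts pool stimuli only; protein and control stimuli are excluded.
#' Donors present in the calls but with no positive pool are reported with
#' zero.
#'
#' @param calls Output of [call_responders()].
#' @return Tibble `donor_id`, `n_positive_pools`.
#' @export
pools_per_donor <- function(calls) {
  dp <- donor_positive(calls)
  dp %>%
    dplyr::filter(.data$stimulus_type == "pool") %>%
    dplyr::group_by(.data$donor_id) %>%
    dplyr::summarise(n_positive_pools = sum(.data$positive),
                     .groups = "drop") %>%
    tidyr::complete(donor_id = unique(dp$donor_id),
                    fill = list(n_positive_pools = 0L)) %>%
    dplyr::arrange(.data$donor_id)
}

#' Log fold change of positive-cell rate versus unstimulated
#'
#' `log_base((stim_pos + pseudocount) / stim_total /
#' ((unstim_pos + pseudocount) / unstim_total))`; the pseudocount guards
#' zero counts. Vectorised.
#'
#' @inheritParams fisher_one_sided
#' @param pseudocount Added to both positive counts (default 0.5).
#' @param base Logarithm base (default 2).
#' @return Numeric vector of signed log fold changes.
#' @export
log_fold_change <- function(stim_pos, stim_total, unstim_pos, unstim_total,
                            pseudocount = 0.5, base = 2) {
  if (any(stim_total <= 0L) || any(unstim_total <= 0L)) {
    stop("total counts must be positive", call. = FALSE)
  }
  log(((stim_pos + pseudocount) / stim_total) /
        ((unstim_pos + pseudocount) / unstim_total), base = base)
}

#' Long-format log-fold-change table for all stimulated rows
#'
#' @param records Stimulation count table (see [call_responders()]).
#' @inheritParams log_fold_change
#' @return Tibble `donor_id`, `stimulus`, `stimulus_type`, `marker`, `lfc`.
#' @export
log_fold_change_table <- function(records, pseudocount = 0.5, base = 2) {
  validate_counts(records)
  unstim <- records %>%
    dplyr::filter(.data$stimulus_type == "unstimulated") %>%
    dplyr::select("donor_id", "marker",
                  unstim_pos = "positive_count",
                  unstim_total = "total_count")
  records %>%
    dplyr::filter(.data$stimulus_type != "unstimulated") %>%
    dplyr::inner_join(unstim, by = c("donor_id", "marker")) %>%
    dplyr::mutate(lfc = log_fold_change(.data$positive_count,
                                        .data$total_count,
                                        .data$unstim_pos,
                                        .data$unstim_total,
                                        pseudocount, base)) %>%
    dplyr::select("donor_id", "stimulus", "stimulus_type", "marker", "lfc")
}

#' Read a long-format stimulation count table from TSV
#'
#' @param path TSV with columns `donor_id`, `stimulus`, `stimulus_type`,
#'   `marker`, `positive_count`, `total_count`.
#' @return Validated tibble.
#' @export
read_stimulation_counts <- function(path) {
  records <- readr::read_tsv(path, col_types = readr::cols(
    donor_id = readr::col_character(),
    stimulus = readr::col_character(),
    stimulus_type = readr::col_character(),
    marker = readr::col_character(),
    positive_count = readr::col_integer(),
    total_count = readr::col_integer()))
  validate_counts(records)
  records
}
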