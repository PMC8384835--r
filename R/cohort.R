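# HLA-representative cohort selection: allele spectra and simulated
# annealing over fixed-size donor subsets.

allele_pattern <- "^[A-Z0-9]+\\*[0-9]{2,3}:[0-9]{2,3}$"

validate_genotypes <- function(genotypes, what = "genotype table") {
  check_columns(genotypes, c("donor_id", "allele1", "allele2"), what)
  alleles <- c(genotypes$allele1, genotypes$allele2)
  bad <- unique(alleles[!grepl(allele_pattern, alleles)])
  if (length(bad) > 0L) {
    stop(what, " contains malformed allele name(s): ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " (expected e.g. 'DRB1*07:01')", call. = FALSE)
  }
  if (anyDuplicated(genotypes$donor_id)) {
    stop(what, " has duplicated donor_id values", call. = FALSE)
  }
  invisible(genotypes)
}

# long view: one row per (donor, allele slot); homozygotes appear twice
genotypes_long <- function(genotypes) {
  tibble::tibble(
    donor_id = rep(genotypes$donor_id, 2L),
    allele = c(genotypes$allele1, genotypes$allele2)
  )
}

# carry relation: one row per (donor, distinct allele)
genotype_carriers <- function(genotypes) {
  dplyr::distinct(genotypes_long(genotypes))
}

#' Allele-frequency spectrum of a donor cohort
#'
#' Each donor contributes two DRB1 allele slots; the frequency of an allele
#' is its slot count divided by twice the number of donors, so frequencies
#' sum to one.
#'
#' @param genotypes Tibble with `donor_id`, `allele1`, `allele2`.
#' @return Tibble with `allele`, `freq`, sorted by decreasing frequency.
#' @export
cohort_allele_frequencies <- function(genotypes) {
  validate_genotypes(genotypes)
  if (nrow(genotypes) == 0L) {
    stop("empty donor list", call. = FALSE)
  }
  genotypes_long(genotypes) %>%
    dplyr::count(.data$allele, name = "n") %>%
    dplyr::mutate(freq = .data$n / (2L * nrow(genotypes))) %>%
    dplyr::select("allele", "freq") %>%
    dplyr::arrange(dplyr::desc(.data$freq), .data$allele)
}

#' Divergence between a cohort spectrum and a target population spectrum
#'
#' Default is the L1 distance over the union of alleles (missing entries read
#' as zero), which is zero iff the spectra are identical and robust to rare
#' alleles; an L2 variant is available. Alleles present in the cohort but
#' absent from the target contribute their full cohort frequency, penalising
#' unrepresentative alleles.
#'
#' @param cohort_freqs,target_freqs Tibbles with `allele`, `freq`.
#' @param metric `"l1"` (default) or `"l2"`.
#' @return Non-negative divergence score.
#' @export
cohort_objective <- function(cohort_freqs, target_freqs,
                             metric = c("l1", "l2")) {
  metric <- match.arg(metric)
  check_columns(cohort_freqs, c("allele", "freq"), "cohort frequency table")
  check_columns(target_freqs, c("allele", "freq"), "target frequency table")
  universe <- union(cohort_freqs$allele, target_freqs$allele)
  a <- cohort_freqs$freq[match(universe, cohort_freqs$allele)]
  b <- target_freqs$freq[match(universe, target_freqs$allele)]
  a[is.na(a)] <- 0
  b[is.na(b)] <- 0
  d <- abs(a - b)
  switch(metric, l1 = sum(d), l2 = sqrt(sum(d^2)))
}

#' Read an allele-frequency table from TSV
#'
#' @param path TSV with columns `allele`, `freq`.
#' @return Validated tibble.
#' @export
read_allele_frequencies <- function(path) {
  freqs <- readr::read_tsv(path, col_types = readr::cols(
    allele = readr::col_character(), freq = readr::col_double()))
  check_columns(freqs, c("allele", "freq"), "allele-frequency table")
  if (any(freqs$freq < 0 | freqs$freq > 1)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  if (sum(freqs$freq) > 1 + 1e-6) {
    stop("allele frequencies sum to more than 1", call. = FALSE)
  }
  freqs
}

#' Read a donor genotype table from TSV
#'
#' @param path TSV with columns `donor_id`, `allele1`, `allele2`. Additional
#'   columns (other loci) are dropped with a message: only the two DRB1
#'   alleles drive the analysis.
#' @return Validated tibble.
#' @export
read_genotype_table <- function(path) {
  genotypes <- readr::read_tsv(path, col_types = readr::cols())
  extra <- setdiff(names(genotypes), c("donor_id", "allele1", "allele2"))
  if (length(extra) > 0L) {
    message("ignoring non-DRB1 genotype column(s): ",
            paste(extra, collapse = ", "))
    genotypes <- genotypes[, c("donor_id", "allele1", "allele2")]
  }
  genotypes$donor_id <- as.character(genotypes$donor_id)
  validate_genotypes(genotypes)
  genotypes
}

#' Select a donor cohort matching a target allele spectrum
#'
#' Simulated annealing over size-`n` subsets of the donor pool. The move set
#' swaps one selected donor for one unselected donor; moves are accepted by
#' the Metropolis rule under a geometric cooling schedule `T_k = t0 *
#' cooling^k`. The objective is [cohort_objective()] against `target`. The
#' best subset ever visited is returned, so the search can never do worse
#' than its start.
#'
#' @param pool Genotype tibble (`donor_id`, `allele1`, `allele2`) to select
#'   from.
#' @param n Cohort size; must not exceed the pool size.
#' @param target Target allele-frequency tibble (`allele`, `freq`).
#' @param iterations Number of annealing moves (default 20000).
#' @param t0 Initial temperature (default 1).
#' @param cooling Geometric cooling factor per iteration (default 0.995).
#' @param metric Divergence metric, see [cohort_objective()].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return Object of class `cohort_selection`: list with
#'   `selected_donor_ids`, `objective_value`, `trace` (objective after each
#'   iteration), `seed`, `metric`.
#' @export
select_cohort <- function(pool, n, target, iterations = 20000L, t0 = 1,
                          cooling = 0.995, metric = c("l1", "l2"),
                          seed = NULL) {
  metric <- match.arg(metric)
  validate_genotypes(pool, "donor pool")
  check_columns(target, c("allele", "freq"), "target frequency table")
  n <- as.integer(n)
  n_pool <- nrow(pool)
  if (n < 1L || n > n_pool) {
    stop("requested cohort size n = ", n,
         " must be between 1 and the pool size (", n_pool, ")",
         call. = FALSE)
  }

  universe <- union(union(pool$allele1, pool$allele2), target$allele)
  target_vec <- target$freq[match(universe, target$allele)]
  target_vec[is.na(target_vec)] <- 0
  # each donor indexes its two allele slots in the shared universe
  slot1 <- match(pool$allele1, universe)
  slot2 <- match(pool$allele2, universe)

  obj_from_counts <- function(counts) {
    d <- abs(counts / (2 * n) - target_vec)
    if (metric == "l1") sum(d) else sqrt(sum(d^2))
  }

  result <- with_optional_seed(seed, {
    selected <- sample.int(n_pool, n)
    in_cohort <- logical(n_pool)
    in_cohort[selected] <- TRUE
    counts <- tabulate(c(slot1[selected], slot2[selected]),
                       nbins = length(universe))
    current <- obj_from_counts(counts)
    best <- current
    best_set <- selected
    trace <- numeric(0)
    if (n < n_pool && iterations > 0L) {
      trace <- numeric(iterations)
      temp <- t0
      out_pool <- which(!in_cohort)
      for (k in seq_len(iterations)) {
        i_sel <- selected[sample.int(n, 1L)]
        i_new <- out_pool[sample.int(length(out_pool), 1L)]
        counts[slot1[i_sel]] <- counts[slot1[i_sel]] - 1L
        counts[slot2[i_sel]] <- counts[slot2[i_sel]] - 1L
        counts[slot1[i_new]] <- counts[slot1[i_new]] + 1L
        counts[slot2[i_new]] <- counts[slot2[i_new]] + 1L
        proposal <- obj_from_counts(counts)
        accept <- proposal <= current ||
          stats::runif(1L) < exp((current - proposal) / temp)
        if (accept) {
          current <- proposal
          in_cohort[i_sel] <- FALSE
          in_cohort[i_new] <- TRUE
          selected[selected == i_sel] <- i_new
          out_pool[out_pool == i_new] <- i_sel
          if (current < best) {
            best <- current
            best_set <- selected
          }
        } else {
          counts[slot1[i_sel]] <- counts[slot1[i_sel]] + 1L
          counts[slot2[i_sel]] <- counts[slot2[i_sel]] + 1L
          counts[slot1[i_new]] <- counts[slot1[i_new]] - 1L
          counts[slot2[i_new]] <- counts[slot2[i_new]] - 1L
        }
        trace[k] <- current
        temp <- temp * cooling
      }
    }
    list(ids = sort(pool$donor_id[best_set]), objective = best,
         trace = trace)
  })

  structure(
    list(selected_donor_ids = result$ids,
         objective_value = result$objective,
         trace = result$trace,
         seed = seed,
         metric = metric),
    class = "cohort_selection"
  )
}

#' @export
print.cohort_selection <- function(x, ...) {
  cat("<cohort_selection> ", length(x$selected_donor_ids),
      " donors, objective = ", format(x$objective_value, digits = 4),
      " (", x$metric, ")\n", sep = "")
  invisible(x)
}
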