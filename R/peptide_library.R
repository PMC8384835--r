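# Overlapping-peptide library design: tiling, pooling, and coordinate lookup.
# Coordinates are 1-based and inclusive on both ends throughout the package.

#' Tile a protein into overlapping peptides
#'
#' Generates the overlapping-peptide library used to stimulate PBMCs: fixed
#' `window`-mer peptides whose start positions are staggered by `stagger`
#' residues. When the last full window does not reach the C-terminus, one
#' shorter terminal peptide ending at the final residue is appended (it starts
#' one stagger after the last full window), provided it is at least
#' `min_terminal` residues long.
#'
#' @param protein A `protein_record`, plain sequence string, or `AAStringSet`.
#' @param window Peptide length in residues (default 15).
#' @param stagger Offset between consecutive peptide starts (default 5).
#' @param min_terminal Minimum length for the terminal fragment (default 7);
#'   a shorter remainder is not emitted.
#' @return A tibble with columns `index` (1-based ordinal), `sequence`,
#'   `start`, `end` (1-based inclusive positions on the protein).
#' @export
#' @examples
#' tile_protein(protein_record("toy", strrep("ACDEF", 6)), window = 15,
#'              stagger = 5)
tile_protein <- function(protein, window = 15L, stagger = 5L,
                         min_terminal = 7L) {
  protein <- as_protein(protein)
  window <- as.integer(window)
  stagger <- as.integer(stagger)
  stopifnot(window >= 1L, stagger >= 1L, window >= stagger,
            min_terminal >= 1L)
  len <- protein_length(protein)
  if (len < window) {
    stop("protein '", protein$id, "' (", len,
         " aa) is shorter than the tiling window (", window, " aa)",
         call. = FALSE)
  }
  starts <- seq.int(1L, len - window + 1L, by = stagger)
  ends <- starts + window - 1L
  last_end <- ends[length(ends)]
  if (last_end < len) {
    term_start <- starts[length(starts)] + stagger
    if (len - term_start + 1L >= min_terminal) {
      starts <- c(starts, term_start)
      ends <- c(ends, len)
    } else {
      message("terminal remainder (", len - term_start + 1L,
              " aa) shorter than min_terminal = ", min_terminal,
              "; not emitted")
    }
  }
  tibble::tibble(
    index = seq_along(starts),
    sequence = substring(protein$sequence, starts, ends),
    start = as.integer(starts),
    end = as.integer(ends)
  )
}

#' Group tiled peptides into consecutive pools
#'
#' Peptides are assigned to pools of `pool_size` consecutive library members;
#' the final pool holds the remainder. Each pool's residue span is the
#' minimum start / maximum end over its members, so consecutive pool spans
#' overlap the way the underlying peptides do.
#'
#' @param peptides Tibble from [tile_protein()], ordered by `index`.
#' @param pool_size Number of peptides per pool (default 10).
#' @return A tibble with columns `pool_id`, `n_peptides`, `span_start`,
#'   `span_end`, and a list-column `peptide_indices`.
#' @export
assign_pools <- function(peptides, pool_size = 10L) {
  check_columns(peptides, c("index", "start", "end"), "peptide library")
  pool_size <- as.integer(pool_size)
  stopifnot(pool_size >= 1L)
  if (nrow(peptides) == 0L) {
    stop("cannot pool an empty peptide library", call. = FALSE)
  }
  if (is.unsorted(peptides$index)) {
    peptides <- dplyr::arrange(peptides, .data$index)
  }
  peptides %>%
    dplyr::mutate(pool_id = ((.data$index - 1L) %/% pool_size) + 1L) %>%
    dplyr::group_by(.data$pool_id) %>%
    dplyr::summarise(
      n_peptides = dplyr::n(),
      span_start = min(.data$start),
      span_end = max(.data$end),
      peptide_indices = list(.data$index),
      .groups = "drop"
    )
}

#' Build a complete peptide library with pool assignments
#'
#' Convenience wrapper: tiles the protein, assigns pools, and returns the
#' per-peptide table with a `pool_id` column plus the pool table as the
#' `"pools"` attribute.
#'
#' @inheritParams tile_protein
#' @inheritParams assign_pools
#' @return Tibble of peptides with `pool_id`; `attr(, "pools")` holds the
#'   pool spans.
#' @export
peptide_library <- function(protein, window = 15L, stagger = 5L,
                            pool_size = 10L, min_terminal = 7L) {
  peptides <- tile_protein(protein, window, stagger, min_terminal)
  pools <- assign_pools(peptides, pool_size)
  peptides$pool_id <- ((peptides$index - 1L) %/% as.integer(pool_size)) + 1L
  attr(peptides, "pools") <- pools
  peptides
}

#' Locate a peptide on a protein
#'
#' Exact substring search, case-insensitive. Returns the first occurrence
#' together with the total number of occurrences so downstream code can flag
#' ambiguous placements instead of silently guessing.
#'
#' @param protein Protein to search in.
#' @param peptide_sequence Non-empty amino-acid string.
#' @return One-row tibble with `start`, `end`, `n_matches`.
#' @export
#' @examples
#' locate_peptide(protein_record("toy", "MKEILV"), "EILV")
locate_peptide <- function(protein, peptide_sequence) {
  protein <- as_protein(protein)
  stopifnot(is.character(peptide_sequence), length(peptide_sequence) == 1L)
  peptide_sequence <- toupper(peptide_sequence)
  if (!nzchar(peptide_sequence)) {
    stop("peptide sequence is empty", call. = FALSE)
  }
  hits <- gregexpr(peptide_sequence, protein$sequence, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) {
    stop("peptide '", peptide_sequence, "' does not occur in protein '",
         protein$id, "'", call. = FALSE)
  }
  start <- as.integer(hits[1L])
  tibble::tibble(
    start = start,
    end = start + nchar(peptide_sequence) - 1L,
    n_matches = length(hits)
  )
}

# canonical stimulus label for a peptide pool, shared by the simulator,
# the responder caller and the integration step
pool_stimulus <- function(pool_id) sprintf("pool_%02d", as.integer(pool_id))

parse_pool_id <- function(stimulus) {
  out <- suppressWarnings(as.integer(sub("^pool_", "", stimulus)))
  if (anyNA(out)) {
    stop("not a pool stimulus label: ",
         paste(stimulus[is.na(out)], collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a peptide library to TSV
#'
#' Columns: index, sequence, start, end, pool_id.
#'
#' @param library Tibble from [peptide_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_library <- function(library, path) {
  check_columns(library, c("index", "sequence", "start", "end", "pool_id"),
                "peptide library")
  readr::write_tsv(library[, c("index", "sequence", "start", "end",
                               "pool_id")], path)
  invisible(path)
}
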