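# Protein sequence container and FASTA input.

# canonical one-letter amino-acid alphabet; anything else is rejected on input
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Create a protein record
#'
#' A minimal container for a protein sequence. Sequences are normalised to
#' uppercase and must use only the 20 canonical one-letter residue codes;
#' whitespace is stripped.
#'
#' @param id Single character identifier.
#' @param sequence Amino-acid sequence (one-letter codes, case-insensitive).
#' @return An object of class `protein_record` with elements `id` and
#'   `sequence`.
#' @export
#' @examples
#' protein_record("toy", "MKEILV")
protein_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(sequence)) {
    stop("protein sequence is empty", call. = FALSE)
  }
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(residues), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("non-canonical residue(s) in protein '", id, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(id = id, sequence = sequence), class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record> ", x$id, ": ", nchar(x$sequence), " aa\n", sep = "")
  invisible(x)
}

#' Coerce to a protein record
#'
#' Accepts a `protein_record`, a single (optionally named) character string,
#' or a `Biostrings::AAStringSet` with one sequence.
#'
#' @param x Object to coerce.
#' @return A `protein_record`.
#' @export
as_protein <- function(x) {
  if (inherits(x, "protein_record")) {
    return(x)
  }
  if (inherits(x, "AAStringSet")) {
    if (length(x) != 1L) {
      stop("expected exactly one sequence, got ", length(x), call. = FALSE)
    }
    return(protein_record(names(x) %||% "protein", as.character(x[[1L]])))
  }
  if (is.character(x) && length(x) == 1L) {
    return(protein_record(names(x) %||% "protein", unname(x)))
  }
  stop("cannot interpret object of class '", class(x)[1L],
       "' as a protein", call. = FALSE)
}

#' Read a protein from a FASTA file
#'
#' @param path Path to a FASTA file. The file must contain a single record;
#'   if several are present the first is used with a warning.
#' @return A `protein_record`.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    stop("no sequences in FASTA file: ", path, call. = FALSE)
  }
  if (length(aa) > 1L) {
    warning("FASTA file contains ", length(aa),
            " records; using the first", call. = FALSE)
  }
  id <- sub("\\s.*$", "", names(aa)[1L])
  protein_record(id, as.character(aa[[1L]]))
}

#' Write a protein to a FASTA file
#'
#' @param protein A `protein_record` (or anything `as_protein()` accepts).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(protein, path) {
  protein <- as_protein(protein)
  aa <- Biostrings::AAStringSet(stats::setNames(protein$sequence, protein$id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

protein_length <- function(protein) nchar(as_protein(protein)$sequence)

protein_subseq <- function(protein, start, end) {
  substring(as_protein(protein)$sequence, start, end)
}
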