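#' The 20 canonical amino acid single-letter codes
#'
#' Alphabetical order of the single-letter codes
#' (A, C, D, E, F, G, H, I, K, L, M, N, P, Q, R, S, T, V, W, Y).
#' All property tables and feature encodings index residues in this order.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Construct a set of protein records
#'
#' A protein set is a data frame with columns `id`, `sequence` and `length`.
#' Sequences are upper-cased; surrounding whitespace is stripped. No alphabet
#' validation is performed here — see [validate_records()].
#'
#' @param id Character vector of record identifiers.
#' @param sequence Character vector of amino acid sequences.
#' @return A data frame of class `protein_set`.
#' @export
protein_set <- function(id = character(), sequence = character()) {
  stopifnot(length(id) == length(sequence))
  sequence <- toupper(gsub("[[:space:]]", "", as.character(sequence)))
  out <- data.frame(id = as.character(id), sequence = sequence,
                    length = nchar(sequence), stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Read protein sequences from a FASTA file
#'
#' One record per FASTA entry, in file order. The record id is the first
#' whitespace-delimited token of the header; sequences are upper-cased.
#'
#' @param path Path to a FASTA file.
#' @return A [protein_set()] data frame (possibly with zero rows).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  meaningful <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), ";"))
  if (length(meaningful) > 0 &&
      !startsWith(trimws(lines[meaningful[1]]), ">")) {
    stop("malformed FASTA in ", path, ": sequence line before any header ",
         "at line ", meaningful[1])
  }
  if (length(meaningful) == 0) {
    return(protein_set())
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1)
  protein_set(id = ids, sequence = as.character(set))
}

#' Write protein records to a FASTA file
#'
#' Standard FASTA output, wrapped at 60 columns. `read_fasta()` applied to
#' the output reproduces the input id/sequence pairs exactly.
#'
#' @param records A [protein_set()] data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Validate a single protein sequence
#'
#' A sequence is rejected if it contains any character outside the 20
#' canonical residue codes — this covers ambiguity codes (X, B, Z),
#' non-standard residues (U, O), stop marks (*) and alignment gaps — or if
#' it is shorter than `min_length`. Rejection is a verdict, not an error;
#' the verdict names the first offending character and its position.
#'
#' @param sequence A single amino acid sequence (character scalar).
#' @param min_length Minimum accepted length; dipeptide encoding requires at
#'   least 2.
#' @return A list with elements `ok` (logical) and `reason` (`NA` when
#'   accepted).
#' @export
#' @examples
#' validate_record("ACDEX")$reason
validate_record <- function(sequence, min_length = 2L) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!(chars %in% amino_acids()))
  if (length(bad) > 0) {
    return(list(ok = FALSE, reason = sprintf(
      "ambiguous residue %s at position %d", chars[bad[1]], bad[1])))
  }
  if (nchar(sequence) < min_length) {
    return(list(ok = FALSE, reason = sprintf(
      "length %d below minimum %d", nchar(sequence), as.integer(min_length))))
  }
  list(ok = TRUE, reason = NA_character_)
}

#' Validate every record of a protein set
#'
#' @param records A [protein_set()] data frame.
#' @param min_length Minimum accepted sequence length (default 2).
#' @return A data frame with columns `id`, `ok`, `reason` (one row per
#'   record, in input order).
#' @export
validate_records <- function(records, min_length = 2L) {
  verdicts <- lapply(records$sequence, validate_record, min_length = min_length)
  data.frame(
    id = records$id,
    ok = vapply(verdicts, `[[`, logical(1), "ok"),
    reason = vapply(verdicts, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
}
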