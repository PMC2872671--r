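# AlignedLocus: one locus's aligned sequence matrix over A/C/G/T, two-base
# IUPAC ambiguity codes and the gap character '-'.

new_aligned_locus <- function(locus_name, strain_ids, matrix) {
  structure(
    list(
      locus_name = locus_name,
      strain_ids = strain_ids,
      matrix = matrix,
      n_sites = ncol(matrix)
    ),
    class = "aligned_locus"
  )
}

#' Construct an aligned locus from sequences
#'
#' Builds the validated alignment container used throughout the package: a
#' strains-by-sites character matrix over `A`/`C`/`G`/`T`, the two-base
#' IUPAC ambiguity codes (`R`, `Y`, `M`, `K`, `W`, `S`) and the gap
#' character `-`.  Input is case-insensitive; storage is upper-case.  The
#' gap dialect is `-` only; `.` is rejected so alignments from other
#' conventions fail loudly rather than silently misclassify.
#'
#' @param sequences Named character vector of aligned sequences (equal
#'   lengths), names are strain identifiers.
#' @param locus_name Name of the locus (e.g. `"ITS"`).
#' @return An object of class `aligned_locus` with fields `locus_name`,
#'   `strain_ids`, `matrix` and `n_sites`.
#' @examples
#' aligned_locus(c(s1 = "ACGT", s2 = "ACYT"), "toy")
#' @export
aligned_locus <- function(sequences, locus_name = "locus") {
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    abort("`sequences` must be a named character vector (names = strain ids).")
  }
  if (anyDuplicated(names(sequences))) {
    abort(sprintf("Duplicated strain ids: %s.",
                  paste(unique(names(sequences)[duplicated(names(sequences))]),
                        collapse = ", ")))
  }
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1) {
    bad <- names(sequences)[lens != lens[1]][1]
    abort(sprintf(
      "Ragged alignment: record '%s' has length %d, expected %d.",
      bad, nchar(sequences[[bad]]), lens[1]
    ), class = "mycopop_alignment_error")
  }
  mat <- do.call(rbind, strsplit(sequences, ""))
  rownames(mat) <- names(sequences)
  illegal <- matrix(!(mat %in% LEGAL_CHARS), nrow = nrow(mat))
  if (any(illegal)) {
    idx <- which(illegal, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Illegal character '%s' in record '%s' at position %d.",
      mat[idx[1], idx[2]], rownames(mat)[idx[1]], idx[2]
    ), class = "mycopop_parse_error")
  }
  new_aligned_locus(locus_name, names(sequences), mat)
}

#' Read an aligned FASTA file as an aligned locus
#'
#' Reads a pre-aligned FASTA file (gaps allowed, IUPAC two-base ambiguity
#' codes allowed) and validates it into an [aligned_locus()].  Record order
#' is preserved and characters are upper-cased.
#'
#' @param path Path to an aligned FASTA file with at least two records.
#' @param locus_name Locus name to attach; defaults to the file name
#'   without extension.
#' @return An `aligned_locus`.
#' @seealso [write_fasta_alignment()]
#' @export
read_fasta_alignment <- function(path, locus_name = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path))
  }
  locus_name <- locus_name %||% sub("\\.[^.]*$", "", basename(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2) {
    abort(sprintf("Alignment '%s' must contain at least 2 records.", path))
  }
  seqs <- setNames(as.character(set), names(set))
  aligned_locus(seqs, locus_name)
}

#' Write an aligned locus to FASTA
#'
#' @param locus An `aligned_locus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(locus, path) {
  stopifnot(inherits(locus, "aligned_locus"))
  seqs <- locus_sequences(locus)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

# sequences as a named character vector
locus_sequences <- function(locus) {
  setNames(apply(locus$matrix, 1, paste0, collapse = ""), locus$strain_ids)
}

# restrict an aligned locus to a subset of strains (order preserved)
subset_locus <- function(locus, strains) {
  missing <- setdiff(strains, locus$strain_ids)
  if (length(missing) > 0) {
    abort(sprintf("Strains not in alignment '%s': %s.", locus$locus_name,
                  paste(missing, collapse = ", ")))
  }
  keep <- locus$strain_ids[locus$strain_ids %in% strains]
  new_aligned_locus(locus$locus_name, keep, locus$matrix[keep, , drop = FALSE])
}

#' @export
print.aligned_locus <- function(x, ...) {
  cat(sprintf("<aligned_locus> %s: %d strains x %d sites\n",
              x$locus_name, length(x$strain_ids), x$n_sites))
  invisible(x)
}

#' @export
as_tibble.aligned_locus <- function(x, ...) {
  tibble(
    strain_id = x$strain_ids,
    sequence = unname(locus_sequences(x))
  )
}
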