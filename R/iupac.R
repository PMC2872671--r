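# IUPAC two-base ambiguity handling for dikaryon sequences.
#
# Direct sequencing of a dikaryotic (effectively diploid) strain yields one
# composite sequence per locus in which heterozygous positions carry the
# two-base IUPAC code for the pair of underlying alleles (T/C = Y, A/G = R,
# A/C = M, G/T = K, A/T = W, G/C = S).  Three- and four-fold codes
# (B, D, H, V, N) cannot arise from a biallelic dikaryon and are rejected.

IUPAC2 <- c(R = "AG", Y = "CT", M = "AC", K = "GT", W = "AT", S = "CG")

#' Decode a base or two-base IUPAC ambiguity code
#'
#' Maps a single character to the unordered pair of bases it represents in a
#' dikaryotic composite sequence: a plain base maps to a homozygous pair
#' (`"A"` to `c("A", "A")`), a two-base code to its constituent bases
#' (`"Y"` to `c("C", "T")`).  Three- and four-fold codes (`B`, `D`, `H`,
#' `V`, `N`) are rejected because a single dikaryon cannot carry more than
#' two alleles.
#'
#' @param code A single character: `A`, `C`, `G`, `T` or one of
#'   `R`, `Y`, `M`, `K`, `W`, `S` (case-insensitive).
#' @return A character vector of length two, sorted, giving the unordered
#'   base pair.
#' @seealso [encode_ambiguity()] for the inverse.
#' @examples
#' decode_ambiguity("Y")
#' decode_ambiguity("a")
#' @export
decode_ambiguity <- function(code) {
  if (!is.character(code) || length(code) != 1 || nchar(code) != 1) {
    abort("`code` must be a single character.")
  }
  code <- toupper(code)
  if (code %in% c("A", "C", "G", "T")) {
    return(c(code, code))
  }
  if (code %in% names(IUPAC2)) {
    return(strsplit(IUPAC2[[code]], "")[[1]])
  }
  if (code %in% c("B", "D", "H", "V", "N")) {
    abort(sprintf(
      "Ambiguity code '%s' covers more than two bases and cannot represent a dikaryon genotype.",
      code
    ), class = "mycopop_unsupported_code")
  }
  abort(sprintf("'%s' is not a base or supported IUPAC ambiguity code.", code),
        class = "mycopop_unsupported_code")
}

#' Encode an unordered base pair as a base or IUPAC ambiguity code
#'
#' Inverse of [decode_ambiguity()]: a homozygous pair returns the base
#' itself, a heterozygous pair returns the two-base IUPAC code.
#'
#' @param base1,base2 Single bases (`A`, `C`, `G` or `T`).
#' @return A single character.
#' @examples
#' encode_ambiguity("T", "C")
#' @export
encode_ambiguity <- function(base1, base2) {
  b <- sort(toupper(c(base1, base2)))
  if (!all(b %in% c("A", "C", "G", "T"))) {
    abort("`base1` and `base2` must each be one of A, C, G, T.")
  }
  if (b[1] == b[2]) {
    return(b[1])
  }
  names(IUPAC2)[match(paste0(b[1], b[2]), IUPAC2)]
}

# vectorised encode for simulation: two equal-length base vectors -> codes
encode_pair_vec <- function(b1, b2) {
  out <- b1
  het <- b1 != b2
  if (any(het)) {
    key <- paste0(pmin(b1[het], b2[het]), pmax(b1[het], b2[het]))
    out[het] <- names(IUPAC2)[match(key, IUPAC2)]
  }
  out
}

LEGAL_CHARS <- c("A", "C", "G", "T", names(IUPAC2), "-")

# expand a character vector of alignment symbols into a list of state sets
# (bases, with '-' kept as its own state); used by site classification and
# divergence.  Unsupported codes raise an error.
expand_states <- function(chars) {
  lapply(chars, function(ch) {
    if (ch == "-") return("-")
    decode_ambiguity(ch)
  })
}

# per-column set of states observed across strains, heterozygotes expanded
column_state_set <- function(column) {
  sort(unique(unlist(expand_states(column))))
}
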