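# Column classification: invariant / substitution / indel, with indel-track
# grouping.  A column containing any gap character is classed indel (gap
# takes precedence); a gap-free column with two or more distinct allele
# states -- after expanding heterozygous IUPAC codes into both bases -- is a
# substitution column.  Maximal runs of consecutive indel columns form
# indel tracks, each treated as one insertion/deletion event region.

#' Classify alignment columns as invariant, substitution or indel sites
#'
#' Scans every column of an aligned locus and classifies it.  Heterozygous
#' IUPAC codes are expanded to their two bases before judging variability,
#' so a column that is `A` in every strain except one `R` (= A/G) strain is
#' a substitution site.  Any column containing a gap is an indel site;
#' consecutive indel columns are grouped into maximal disjoint tracks.
#' Substitution variation inside a gapped column does not change its class
#' but is flagged in the per-site detail table.
#'
#' @param locus An [aligned_locus()].
#' @return An object of class `site_classification` with elements
#'   `sites` (tibble: `position` 1-based, `class`, `states`,
#'   `substitution_within_indel`), `indel_tracks` (tibble: `start`, `end`,
#'   `length`), and counts `n_sites`, `n_variable`, `n_substitution`,
#'   `n_indel_sites`, `n_indel_tracks`.  `n_variable` is always
#'   `n_substitution + n_indel_sites`.
#' @examples
#' loc <- aligned_locus(c(a = "ACG--T", b = "ACGTTT", c = "AYGTTA"), "toy")
#' classify_sites(loc)
#' @export
classify_sites <- function(locus) {
  stopifnot(inherits(locus, "aligned_locus"))
  m <- locus$matrix
  state_sets <- lapply(seq_len(ncol(m)), function(j) column_state_set(m[, j]))
  has_gap <- vapply(state_sets, function(s) "-" %in% s, logical(1))
  base_states <- lapply(state_sets, setdiff, "-")
  n_base_states <- vapply(base_states, length, integer(1))
  cls <- ifelse(has_gap, "indel",
                ifelse(n_base_states >= 2, "substitution", "invariant"))
  sites <- tibble(
    position = seq_len(ncol(m)),
    class = cls,
    states = vapply(state_sets, paste, character(1), collapse = "/"),
    substitution_within_indel = has_gap & n_base_states >= 2
  )
  idx <- which(cls == "indel")
  if (length(idx) == 0) {
    tracks <- tibble(start = integer(), end = integer(), length = integer())
  } else {
    brk <- cumsum(c(1L, diff(idx) != 1L))
    tracks <- tibble(
      start = as.integer(tapply(idx, brk, min)),
      end = as.integer(tapply(idx, brk, max))
    )
    tracks$length <- tracks$end - tracks$start + 1L
  }
  structure(
    list(
      locus_name = locus$locus_name,
      sites = sites,
      indel_tracks = tracks,
      n_sites = ncol(m),
      n_variable = sum(cls != "invariant"),
      n_substitution = sum(cls == "substitution"),
      n_indel_sites = sum(cls == "indel"),
      n_indel_tracks = nrow(tracks)
    ),
    class = "site_classification"
  )
}

#' @export
print.site_classification <- function(x, ...) {
  cat(sprintf(
    "<site_classification> %s: %d sites; %d variable (%d substitution, %d indel in %d tracks)\n",
    x$locus_name, x$n_sites, x$n_variable, x$n_substitution,
    x$n_indel_sites, x$n_indel_tracks
  ))
  invisible(x)
}

#' Tidy a site classification into a per-site tibble
#'
#' @param x A `site_classification`.
#' @param ... Unused.
#' @return A tibble with one row per alignment column.
#' @export
tidy.site_classification <- function(x, ...) {
  x$sites
}

#' One-row summary of a site classification
#'
#' @param x A `site_classification`.
#' @param ... Unused.
#' @return A one-row tibble of site counts.
#' @export
glance.site_classification <- function(x, ...) {
  tibble(
    locus = x$locus_name,
    n_sites = x$n_sites,
    n_variable = x$n_variable,
    n_substitution = x$n_substitution,
    n_indel_sites = x$n_indel_sites,
    n_indel_tracks = x$n_indel_tracks
  )
}

#' Write a per-site classification report as TSV
#'
#' Site indices are 1-based.  Columns: `position`, `class`, `states`.
#'
#' @param x A `site_classification`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(x, path) {
  stopifnot(inherits(x, "site_classification"))
  readr::write_tsv(x$sites[, c("position", "class", "states")], path)
  invisible(path)
}

#' Plot site classes along an alignment
#'
#' @param object A `site_classification`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.site_classification <- function(object, ...) {
  d <- dplyr::filter(object$sites, .data$class != "invariant")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$class,
                                  colour = .data$class)) +
    ggplot2::geom_point(shape = 124, size = 4, show.legend = FALSE) +
    ggplot2::labs(
      title = sprintf("Variable sites along %s", object$locus_name),
      x = "alignment position", y = NULL
    ) +
    ggplot2::theme_minimal()
}
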