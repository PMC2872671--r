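# Genotype identification and genotypic diversity.
#
# Each dikaryon's composite aligned sequence -- gaps and IUPAC ambiguity
# codes included -- is the genotyping unit: two strains share a genotype
# iff their full aligned strings are identical (so an indel difference or
# Y vs T distinguishes genotypes).  Diversity is the unbiased probability
# that two individuals drawn at random (without replacement) have
# different genotypes: D = (1 - sum(p_i^2)) * n/(n-1).

#' Validate a strain-to-population/lineage partition table
#'
#' @param df A data frame with columns `strain_id`, `population` and
#'   optionally `lineage` (copied from `population` when absent).
#' @return A validated tibble with all three columns.
#' @export
lineage_partition <- function(df) {
  df <- as_tibble(df)
  if (!all(c("strain_id", "population") %in% names(df))) {
    abort("Partition must have columns `strain_id` and `population`.")
  }
  if (!"lineage" %in% names(df)) df$lineage <- df$population
  if (anyDuplicated(df$strain_id)) {
    abort(sprintf("Strains assigned more than once: %s.",
                  paste(unique(df$strain_id[duplicated(df$strain_id)]),
                        collapse = ", ")))
  }
  if (anyNA(df$population) || anyNA(df$lineage)) {
    abort("Partition contains missing population or lineage labels.")
  }
  df[, c("strain_id", "population", "lineage")]
}

#' Collapse aligned sequences into unique genotypes per population
#'
#' Groups strains by exact string identity of their full aligned sequence
#' (all sites, indels and ambiguity codes included) and tabulates genotype
#' counts per population.  Genotype indices are assigned in order of first
#' appearance, so they are stable given identical input order.
#'
#' @param locus An [aligned_locus()].
#' @param partition A partition table accepted by [lineage_partition()]
#'   covering every strain in the alignment.
#' @return An object of class `genotype_table` with elements
#'   `locus_name`, `genotype_seqs` (character vector, index = genotype id),
#'   `assignments` (tibble: `strain_id`, `population`, `genotype`), and
#'   `counts` (tibble: `population`, `genotype`, `count`).
#' @examples
#' loc <- aligned_locus(c(s1 = "ACGT", s2 = "ACGT", s3 = "ACGA"), "toy")
#' part <- tibble::tibble(strain_id = c("s1", "s2", "s3"), population = "P")
#' collapse_genotypes(loc, part)
#' @export
collapse_genotypes <- function(locus, partition) {
  stopifnot(inherits(locus, "aligned_locus"))
  partition <- lineage_partition(partition)
  missing <- setdiff(locus$strain_ids, partition$strain_id)
  if (length(missing) > 0) {
    abort(sprintf("Strains missing from partition: %s.",
                  paste(missing, collapse = ", ")),
          class = "mycopop_assignment_error")
  }
  seqs <- locus_sequences(locus)
  geno <- match(seqs, unique(seqs))
  assignments <- tibble(strain_id = locus$strain_ids, genotype = geno) |>
    left_join(partition[, c("strain_id", "population")], by = "strain_id") |>
    select("strain_id", "population", "genotype")
  counts <- assignments |>
    dplyr::count(.data$population, .data$genotype, name = "count") |>
    arrange(.data$population, .data$genotype)
  structure(
    list(
      locus_name = locus$locus_name,
      genotype_seqs = unique(unname(seqs)),
      assignments = assignments,
      counts = counts
    ),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %s: %d genotypes among %d strains, %d population(s)\n",
              x$locus_name, length(x$genotype_seqs), nrow(x$assignments),
              length(unique(x$assignments$population))))
  invisible(x)
}

#' @export
tidy.genotype_table <- function(x, ...) x$counts

#' @export
glance.genotype_table <- function(x, ...) {
  tibble(
    locus = x$locus_name,
    n_strains = nrow(x$assignments),
    n_genotypes = length(x$genotype_seqs),
    n_populations = length(unique(x$assignments$population))
  )
}

#' Unbiased genotypic diversity from genotype counts
#'
#' The probability that two individuals taken at random have different
#' genotypes, computed as `D = (1 - sum(p_i^2)) * n/(n-1)` with
#' `p_i = c_i/n`.  The `n/(n-1)` factor makes this the exact probability
#' for a draw *without* replacement: algebraically,
#' `D = 1 - sum(c_i*(c_i-1)) / (n*(n-1))`.
#'
#' @param counts Integer vector of per-genotype counts, all >= 1, with
#'   `sum(counts) >= 2`.
#' @return A single value in `[0, 1]`; full precision (round only when
#'   reporting).
#' @examples
#' genotypic_diversity(c(2, 2, 1, 2, 1, 1, 1, 1))
#' @export
genotypic_diversity <- function(counts) {
  if (length(counts) == 0 || any(is.na(counts)) || any(counts < 1) ||
      any(counts != round(counts))) {
    abort("`counts` must be a nonempty vector of positive integers.")
  }
  n <- sum(counts)
  if (n < 2) {
    abort("Diversity is undefined for n < 2.",
          class = "mycopop_undefined_diversity")
  }
  p <- counts / n
  (1 - sum(p^2)) * n / (n - 1)
}

#' Per-population genotypic diversity report
#'
#' One row per population plus a pooled `TOTAL` row, ordered by population
#' name.  Populations with a single individual get `diversity = NA`
#' (undefined, not zero).  `diversity_3dp` is the value rounded to three
#' decimals for table display; `diversity` keeps full precision.
#'
#' @param table A [collapse_genotypes()] result.
#' @return A tibble with columns `population`, `n`, `n_genotypes`,
#'   `genotype_counts` (label string), `diversity`, `diversity_3dp`.
#' @export
diversity_report <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  one_row <- function(counts, label) {
    n <- sum(counts$count)
    d <- if (n >= 2) genotypic_diversity(counts$count) else NA_real_
    tibble(
      population = label,
      n = n,
      n_genotypes = nrow(counts),
      genotype_counts = paste(sprintf("%d(%d)", counts$genotype, counts$count),
                              collapse = "; "),
      diversity = d,
      diversity_3dp = round(d, 3)
    )
  }
  pops <- sort(unique(table$counts$population))
  per_pop <- purrr::map(pops, function(p) {
    one_row(dplyr::filter(table$counts, .data$population == p), p)
  })
  pooled <- table$assignments |>
    dplyr::count(.data$genotype, name = "count") |>
    arrange(.data$genotype)
  bind_rows(per_pop, one_row(pooled, "TOTAL"))
}

#' Write a Table-1-style diversity report as TSV
#'
#' @param table A `genotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diversity_report <- function(table, path) {
  readr::write_tsv(diversity_report(table), path)
  invisible(path)
}

#' Plot genotype count spectra per population
#'
#' @param object A `genotype_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genotype_table <- function(object, ...) {
  ggplot2::ggplot(object$counts,
                  ggplot2::aes(x = factor(.data$genotype), y = .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~population, scales = "free_x") +
    ggplot2::labs(
      title = sprintf("Genotype counts per population (%s)", object$locus_name),
      x = "genotype", y = "isolates"
    ) +
    ggplot2::theme_minimal()
}
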