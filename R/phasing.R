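# Haplotype phasing of dikaryons.
#
# A dikaryotic strain's composite sequence is a diploid genotype: at each
# biallelic SNP site the strain carries an unordered base pair (a plain
# base = homozygous, a two-base IUPAC code = heterozygous).  Phasing
# resolves each strain into an unordered pair of haplotypes and estimates
# population haplotype frequencies by maximum likelihood via EM
# (Excoffier-Slatkin style): the E-step weights each compatible
# resolution of a strain by the product of current haplotype frequencies,
# the M-step re-estimates frequencies from the expected haplotype counts.

#' Extract biallelic SNP genotypes from an aligned locus
#'
#' Restricts the alignment to substitution-variable sites (indel columns
#' are excluded; the indel signal is handled by the genotyping and
#' divergence stages), expands heterozygote codes into unordered base
#' pairs, and records 1-based alignment positions.  Every retained site
#' must be biallelic across the selected strains after ambiguity
#' expansion.
#'
#' @param locus An [aligned_locus()].
#' @param strains Optional character vector of strain ids to keep
#'   (default: all).
#' @return An object of class `diploid_genotypes`: `strain_ids`,
#'   `positions`, `allele1`/`allele2` (strains-by-sites base matrices with
#'   `allele1 <= allele2` per cell), `site_alleles` (per-site sorted base
#'   pair), `locus_name`.
#' @export
snpify <- function(locus, strains = NULL) {
  stopifnot(inherits(locus, "aligned_locus"))
  if (!is.null(strains)) locus <- subset_locus(locus, strains)
  cls <- classify_sites(locus)
  keep <- cls$sites$position[cls$sites$class == "substitution"]
  # restrict to sites variable within the selected strains
  state_sets <- lapply(keep, function(j) column_state_set(locus$matrix[, j]))
  sizes <- vapply(state_sets, length, integer(1))
  tri <- keep[sizes > 2]
  if (length(tri) > 0) {
    abort(sprintf(
      "Site(s) with more than two alleles: %s.",
      paste(sprintf("%d (%s)", tri,
                    vapply(state_sets[sizes > 2], paste, character(1),
                           collapse = "/")),
            collapse = ", ")
    ), class = "mycopop_triallelic_error")
  }
  keep <- keep[sizes == 2]
  state_sets <- state_sets[sizes == 2]
  n <- length(locus$strain_ids)
  a1 <- matrix("", n, length(keep), dimnames = list(locus$strain_ids, NULL))
  a2 <- a1
  for (k in seq_along(keep)) {
    pairs <- expand_states(locus$matrix[, keep[k]])
    a1[, k] <- vapply(pairs, function(p) sort(p)[1], character(1))
    a2[, k] <- vapply(pairs, function(p) sort(p)[2], character(1))
  }
  structure(
    list(
      locus_name = locus$locus_name,
      strain_ids = locus$strain_ids,
      positions = keep,
      allele1 = a1,
      allele2 = a2,
      site_alleles = state_sets
    ),
    class = "diploid_genotypes"
  )
}

#' @export
print.diploid_genotypes <- function(x, ...) {
  cat(sprintf("<diploid_genotypes> %s: %d strains x %d biallelic sites\n",
              x$locus_name, length(x$strain_ids), length(x$positions)))
  invisible(x)
}

#' @export
as_tibble.diploid_genotypes <- function(x, ...) {
  tibble(
    strain_id = rep(x$strain_ids, each = length(x$positions)),
    position = rep(x$positions, times = length(x$strain_ids)),
    allele_1 = as.vector(t(x$allele1)),
    allele_2 = as.vector(t(x$allele2))
  )
}

# unordered haplotype-pair resolutions compatible with one strain's
# genotype: 2^(k-1) for k heterozygous sites (first het site pinned to
# haplotype A to avoid double counting)
enumerate_resolutions <- function(a1, a2) {
  het <- which(a1 != a2)
  k <- length(het)
  if (k == 0) {
    h <- paste(a1, collapse = "")
    return(list(c(h, h)))
  }
  if (k > 14) {
    abort(sprintf("Strain has %d heterozygous sites; resolution enumeration capped at 14.", k))
  }
  n_res <- 2^(k - 1)
  out <- vector("list", n_res)
  for (r in seq_len(n_res) - 1L) {
    flip <- c(FALSE, as.logical(bitwAnd(r, 2^(seq_len(k - 1) - 1L)) > 0))
    hA <- a1
    hB <- a2
    hA[het[flip]] <- a2[het[flip]]
    hB[het[flip]] <- a1[het[flip]]
    out[[r + 1L]] <- c(paste(hA, collapse = ""), paste(hB, collapse = ""))
  }
  out
}

#' EM haplotype phasing of diploid SNP genotypes
#'
#' Maximum-likelihood estimation of population haplotype frequencies by
#' expectation-maximization over all haplotype pairs compatible with each
#' strain, followed by maximum-posterior phase assignment per strain.
#' The observed-data log-likelihood is non-decreasing across iterations;
#' iteration stops when the largest frequency change drops below `tol` or
#' at `max_iter`.  Initialization is exactly uniform over all compatible
#' haplotypes, so symmetric (truly ambiguous) configurations remain
#' symmetric: strains whose best resolutions are equally likely are
#' reported with posterior 0.5 and flagged, never silently broken.
#' `seed` is accepted for determinism of the interface; the algorithm
#' consumes no randomness from a uniform start.
#'
#' For ITS-like multi-copy loci the heterozygous sites may reflect
#' variation among paralogs rather than the two nuclear haplotypes; a
#' note to that effect is attached to the output metadata when the locus
#' name contains "ITS".
#'
#' @param genotypes A [snpify()] result with at least one strain.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the maximum absolute frequency
#'   change.
#' @param seed Integer seed (tie perturbation only).
#' @return An object of class `phased_haplotypes`: `haplotypes` (tibble:
#'   `haplotype`, `frequency`), `phases` (tibble: `strain_id`, `hap_a`,
#'   `hap_b`, `posterior`, `tied`), `loglik` (per-iteration trace),
#'   `n_iter`, `positions`, `metadata`.
#' @export
em_phase <- function(genotypes, max_iter = 10000, tol = 1e-8, seed = 1) {
  stopifnot(inherits(genotypes, "diploid_genotypes"))
  n <- length(genotypes$strain_ids)
  if (n == 0) abort("Empty genotype matrix.")
  res_list <- lapply(seq_len(n), function(i) {
    enumerate_resolutions(genotypes$allele1[i, ], genotypes$allele2[i, ])
  })
  universe <- sort(unique(unlist(res_list)))
  H <- length(universe)
  # index resolutions into the haplotype universe
  res_idx <- lapply(res_list, function(rs) {
    t(vapply(rs, function(p) match(p, universe), integer(2)))
  })
  # exactly uniform initialization: symmetric (truly ambiguous)
  # configurations then stay symmetric through EM and are reported as
  # flagged ties rather than being silently broken by a random nudge.
  # `seed` is accepted for interface stability; with a uniform start the
  # algorithm consumes no randomness.
  f <- rep(1 / H, H)
  loglik <- numeric(0)
  post <- vector("list", n)
  for (it in seq_len(max_iter)) {
    counts <- numeric(H)
    ll <- 0
    for (i in seq_len(n)) {
      ridx <- res_idx[[i]]
      homo <- ridx[, 1] == ridx[, 2]
      w <- ifelse(homo, f[ridx[, 1]]^2, 2 * f[ridx[, 1]] * f[ridx[, 2]])
      tot <- sum(w)
      ll <- ll + log(tot)
      pw <- w / tot
      post[[i]] <- pw
      for (r in seq_len(nrow(ridx))) {
        counts[ridx[r, 1]] <- counts[ridx[r, 1]] + pw[r]
        counts[ridx[r, 2]] <- counts[ridx[r, 2]] + pw[r]
      }
    }
    loglik <- c(loglik, ll)
    f_new <- counts / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  phases <- purrr::map(seq_len(n), function(i) {
    pw <- post[[i]]
    ridx <- res_idx[[i]]
    best <- which.max(pw)
    tied_set <- which(abs(pw - pw[best]) < 1e-9)
    tied <- length(tied_set) > 1
    if (tied) {
      # lexicographically first tied resolution, posterior reported as 0.5
      keys <- apply(ridx[tied_set, , drop = FALSE], 1, function(r) {
        paste(sort(universe[r]), collapse = "|")
      })
      best <- tied_set[order(keys)[1]]
    }
    pair <- sort(universe[ridx[best, ]])
    tibble(
      strain_id = genotypes$strain_ids[i],
      hap_a = pair[1],
      hap_b = pair[2],
      posterior = if (tied) 0.5 else pw[best],
      tied = tied
    )
  }) |> bind_rows()
  # hard consistency assertion: each reported pair reproduces the genotype
  for (i in seq_len(n)) {
    g1 <- strsplit(phases$hap_a[i], "")[[1]]
    g2 <- strsplit(phases$hap_b[i], "")[[1]]
    ok <- all(pmin(g1, g2) == genotypes$allele1[i, ] &
                pmax(g1, g2) == genotypes$allele2[i, ])
    if (!ok) abort("Internal error: phased pair inconsistent with genotype.")
  }
  # drop numerically-dead haplotypes (dying EM mass) and renormalise
  keep <- f > 1e-6
  f[keep] <- f[keep] / sum(f[keep])
  metadata <- list(
    method = "EM (haplotype-frequency maximum likelihood)",
    locus = genotypes$locus_name,
    tol = tol,
    seed = seed,
    notes = character(0)
  )
  if (grepl("ITS", genotypes$locus_name, ignore.case = TRUE)) {
    metadata$notes <- c(metadata$notes, paste(
      "ITS is a multi-copy locus: heterozygous sites may reflect variation",
      "among paralogs rather than the two nuclear haplotypes."
    ))
  }
  structure(
    list(
      haplotypes = tibble(haplotype = universe[keep],
                          frequency = f[keep]) |>
        arrange(desc(.data$frequency), .data$haplotype),
      phases = phases,
      loglik = loglik,
      n_iter = length(loglik),
      positions = genotypes$positions,
      metadata = metadata
    ),
    class = "phased_haplotypes"
  )
}

#' @export
print.phased_haplotypes <- function(x, ...) {
  cat(sprintf("<phased_haplotypes> %s: %d haplotypes among %d strains (%d EM iterations)\n",
              x$metadata$locus, nrow(x$haplotypes), nrow(x$phases), x$n_iter))
  for (note in x$metadata$notes) cat("note:", note, "\n")
  invisible(x)
}

#' @export
tidy.phased_haplotypes <- function(x, ...) x$phases

#' @export
glance.phased_haplotypes <- function(x, ...) {
  tibble(
    locus = x$metadata$locus,
    n_strains = nrow(x$phases),
    n_haplotypes = nrow(x$haplotypes),
    n_tied = sum(x$phases$tied),
    loglik = x$loglik[x$n_iter],
    n_iter = x$n_iter
  )
}

#' Haplotype catalogue with frequencies and carrier strains
#'
#' Catalogue sorted by descending frequency (ties by haplotype string),
#' listing carriers with the `a`/`b` allele labels of each strain.
#'
#' @param ph A [em_phase()] result.
#' @return A tibble: `haplotype`, `frequency`, `carriers` (comma-separated
#'   `<strain>a`/`<strain>b` labels), `n_carriers`.
#' @export
haplotype_catalogue <- function(ph) {
  stopifnot(inherits(ph, "phased_haplotypes"))
  carriers <- ph$phases |>
    tidyr::pivot_longer(c("hap_a", "hap_b"), names_to = "which",
                        values_to = "haplotype") |>
    mutate(label = paste0(.data$strain_id,
                          ifelse(.data$which == "hap_a", "a", "b"))) |>
    group_by(.data$haplotype) |>
    summarise(carriers = paste(.data$label, collapse = ","),
              n_carriers = n(), .groups = "drop")
  ph$haplotypes |>
    left_join(carriers, by = "haplotype") |>
    arrange(desc(.data$frequency), .data$haplotype)
}

#' Write phased haplotypes as TSV
#'
#' Columns: strain, allele `a` string, allele `b` string, posterior, tie
#' flag.
#'
#' @param ph A `phased_haplotypes` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phased_tsv <- function(ph, path) {
  stopifnot(inherits(ph, "phased_haplotypes"))
  readr::write_tsv(ph$phases, path)
  invisible(path)
}

#' Write per-strain haplotype sequences as FASTA
#'
#' Labels follow the `<strain>a` / `<strain>b` convention for the two
#' alleles of a dikaryon.
#'
#' @param ph A `phased_haplotypes` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_fasta <- function(ph, path) {
  stopifnot(inherits(ph, "phased_haplotypes"))
  seqs <- c(
    setNames(ph$phases$hap_a, paste0(ph$phases$strain_id, "a")),
    setNames(ph$phases$hap_b, paste0(ph$phases$strain_id, "b"))
  )
  # interleave a/b per strain in input order
  ord <- as.vector(rbind(paste0(ph$phases$strain_id, "a"),
                         paste0(ph$phases$strain_id, "b")))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs[ord]), path,
                              width = 80L)
  invisible(path)
}

#' Plot the phased haplotype frequency spectrum
#'
#' @param object A `phased_haplotypes` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phased_haplotypes <- function(object, ...) {
  d <- mutate(object$haplotypes,
              haplotype = factor(.data$haplotype,
                                 levels = rev(object$haplotypes$haplotype)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, y = .data$haplotype)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      title = sprintf("Haplotype frequencies (%s)", object$metadata$locus),
      x = "estimated frequency", y = "haplotype"
    ) +
    ggplot2::theme_minimal()
}
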