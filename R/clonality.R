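# Mode-of-reproduction tests on multilocus genotypes.
#
# The canonical input is a tidy tibble with one row per strain and locus:
# columns `strain_id`, `locus`, `allele_a`, `allele_b` (unordered allele
# pair; allele identifiers are locus-scoped, e.g. haplotype labels from
# phasing).  Under free recombination alleles at different loci associate
# at random (index of association near 0); clonal reproduction preserves
# allele combinations across loci (positive index, and pairwise loci stay
# phylogenetically compatible).

validate_mlg <- function(df) {
  df <- as_tibble(df)
  need <- c("strain_id", "locus", "allele_a", "allele_b")
  if (!all(need %in% names(df))) {
    abort(sprintf("Multilocus genotype table needs columns: %s.",
                  paste(need, collapse = ", ")))
  }
  if (anyDuplicated(df[, c("strain_id", "locus")])) {
    abort("Each strain/locus combination must appear exactly once.")
  }
  complete <- df |>
    dplyr::count(.data$strain_id) |>
    dplyr::pull(n)
  if (length(unique(complete)) > 1) {
    abort("Every strain must have an entry for every locus.")
  }
  df
}

# wide allele matrices: list(a1, a2) strains x loci, pairs sorted per cell
mlg_matrices <- function(df) {
  df <- validate_mlg(df)
  strains <- unique(df$strain_id)
  loci <- unique(df$locus)
  a1 <- matrix("", length(strains), length(loci),
               dimnames = list(strains, loci))
  a2 <- a1
  lo <- pmin(df$allele_a, df$allele_b)
  hi <- pmax(df$allele_a, df$allele_b)
  idx <- cbind(match(df$strain_id, strains), match(df$locus, loci))
  a1[idx] <- lo
  a2[idx] <- hi
  list(a1 = a1, a2 = a2, strains = strains, loci = loci)
}

#' Allele-sharing distance between two multilocus genotypes
#'
#' Per locus the distance is 0 when the unordered allele pairs are
#' identical, 0.5 when exactly one allele is shared (counting
#' multiplicity), and 1 when no allele is shared; the total is the sum
#' over loci.
#'
#' @param g1,g2 Named lists (or data frames with columns `locus`,
#'   `allele_a`, `allele_b`) giving one allele pair per locus; both must
#'   cover the same loci.
#' @return A list with `per_locus` (named numeric vector) and `total`.
#' @examples
#' pairwise_distance(
#'   list(ITS = c("A", "a"), RPB2 = c("B", "B")),
#'   list(ITS = c("A", "A"), RPB2 = c("B", "B"))
#' )
#' @export
pairwise_distance <- function(g1, g2) {
  as_pairs <- function(g) {
    if (is.data.frame(g)) {
      setNames(lapply(seq_len(nrow(g)),
                      function(i) c(g$allele_a[i], g$allele_b[i])),
               g$locus)
    } else {
      g
    }
  }
  g1 <- as_pairs(g1)
  g2 <- as_pairs(g2)
  if (!setequal(names(g1), names(g2))) {
    abort("Genotypes cover different locus sets.",
          class = "mycopop_locus_mismatch")
  }
  per_locus <- vapply(names(g1), function(l) {
    p1 <- sort(g1[[l]])
    p2 <- sort(g2[[l]])
    if (identical(p1, p2)) return(0)
    # shared alleles counted with multiplicity (multiset intersection)
    tab1 <- table(p1)
    tab2 <- table(p2)
    common <- intersect(names(tab1), names(tab2))
    shared <- if (length(common) > 0) {
      sum(pmin(as.integer(tab1[common]), as.integer(tab2[common])))
    } else 0
    1 - shared / 2
  }, numeric(1))
  list(per_locus = per_locus, total = sum(per_locus))
}

# vectorised per-locus distance matrix over all strain pairs
locus_distance_matrix <- function(a1, a2) {
  n <- length(a1)
  d <- matrix(0, n, n)
  same <- outer(a1, a1, "==") & outer(a2, a2, "==")
  share1 <- outer(a1, a1, "==") | outer(a1, a2, "==") |
    outer(a2, a1, "==") | outer(a2, a2, "==")
  d[!same & share1] <- 0.5
  d[!share1] <- 1
  d
}

pair_variance <- function(dmat) {
  v <- dmat[upper.tri(dmat)]
  mean(v^2) - mean(v)^2   # denominator = number of pairs
}

#' Index of association test for clonality
#'
#' Computes the index of association `I_A = V_O/V_E - 1` and its
#' standardized form `rbarD`, where `V_O` is the variance over all strain
#' pairs of the total allele-sharing distance and `V_E` the sum of
#' per-locus distance variances (variances use the number of pairs as
#' denominator).  The null distribution is built by permuting
#' single-locus genotypes among strains independently at each locus,
#' which preserves single-locus allele frequencies while destroying
#' between-locus associations.  The tail probability counts the observed
#' arrangement in numerator and denominator:
#' `p = (1 + #\{I_A.null >= I_A.obs\}) / (1 + n_permutations)`.
#'
#' Loci monomorphic across all strains are excluded with a warning; with
#' a single informative locus `I_A` is identically 0.  Strains with
#' identical multilocus genotypes are kept by default (set
#' `clone_correct = TRUE` to collapse them first).
#'
#' @param df Tidy multilocus genotype tibble (`strain_id`, `locus`,
#'   `allele_a`, `allele_b`); at least 4 strains.
#' @param n_permutations Number of permutation replicates.
#' @param seed Integer seed.
#' @param exhaustive If `TRUE` (2+ loci, small n), enumerate the exact
#'   null over all relative per-locus permutations instead of sampling;
#'   `p` is then the exact tail proportion.
#' @param clone_correct Collapse duplicate multilocus genotypes before
#'   testing.
#' @return An object of class `ia_result`: `ia`, `rbard`, `null`
#'   (permuted `I_A` values), `p`, `n_permutations`, `seed`,
#'   `loci_used`, `loci_excluded`, `convention`.
#' @export
index_of_association <- function(df, n_permutations = 999, seed = 1,
                                 exhaustive = FALSE, clone_correct = FALSE) {
  mm <- mlg_matrices(df)
  if (clone_correct) {
    key <- apply(cbind(mm$a1, mm$a2), 1, paste, collapse = "|")
    keep <- !duplicated(key)
    mm$a1 <- mm$a1[keep, , drop = FALSE]
    mm$a2 <- mm$a2[keep, , drop = FALSE]
    mm$strains <- mm$strains[keep]
  }
  n <- length(mm$strains)
  if (n < 4) abort("Index of association requires at least 4 strains.")
  mono <- vapply(seq_along(mm$loci), function(l) {
    length(unique(c(mm$a1[, l], mm$a2[, l]))) < 2
  }, logical(1))
  if (all(mono)) {
    abort("All loci are monomorphic; the index of association is undefined.")
  }
  if (any(mono)) {
    warn(sprintf("Excluding monomorphic locus/loci: %s.",
                 paste(mm$loci[mono], collapse = ", ")))
  }
  loci <- mm$loci[!mono]
  dmats <- lapply(which(!mono), function(l) {
    locus_distance_matrix(mm$a1[, l], mm$a2[, l])
  })
  ia_from <- function(dmats) {
    total <- Reduce(`+`, dmats)
    v_o <- pair_variance(total)
    v_l <- vapply(dmats, pair_variance, numeric(1))
    v_e <- sum(v_l)
    ia <- v_o / v_e - 1
    denom <- 0
    if (length(v_l) >= 2) {
      for (l in seq_along(v_l)) {
        for (m in seq_along(v_l)) {
          if (l < m) denom <- denom + sqrt(v_l[l] * v_l[m])
        }
      }
    }
    rbard <- if (denom > 0) (v_o - v_e) / (2 * denom) else NA_real_
    c(ia = ia, rbard = rbard)
  }
  obs <- ia_from(dmats)
  permute_dmats <- function(perms) {
    lapply(seq_along(dmats), function(l) {
      s <- perms[[l]]
      dmats[[l]][s, s, drop = FALSE]
    })
  }
  if (exhaustive) {
    if (length(dmats) < 2) {
      abort("Exhaustive enumeration needs at least two informative loci.")
    }
    if (factorial(n)^(length(dmats) - 1) > 50000) {
      abort("Exhaustive enumeration is limited to small problems (n! per extra locus).")
    }
    # relative permutations: fixing locus 1 loses no generality because
    # I_A is invariant under simultaneous relabelling of strains
    perm_list <- all_permutations(n)
    grids <- rep(list(seq_along(perm_list)), length(dmats) - 1)
    combos <- expand.grid(grids)
    null <- vapply(seq_len(nrow(combos)), function(i) {
      perms <- c(list(seq_len(n)),
                 lapply(seq_len(ncol(combos)),
                        function(k) perm_list[[combos[i, k]]]))
      ia_from(permute_dmats(perms))[["ia"]]
    }, numeric(1))
    p <- sum(null >= obs[["ia"]] - 1e-12) / length(null)
    n_permutations <- length(null)
  } else {
    assert_scalar_count(n_permutations, "n_permutations")
    null <- withr::with_seed(derive_seed(seed, "ia_perm"), {
      vapply(seq_len(n_permutations), function(b) {
        perms <- lapply(dmats, function(...) sample.int(n))
        ia_from(permute_dmats(perms))[["ia"]]
      }, numeric(1))
    })
    p <- (1 + sum(null >= obs[["ia"]] - 1e-12)) / (1 + n_permutations)
  }
  structure(
    list(
      ia = unname(obs[["ia"]]),
      rbard = unname(obs[["rbard"]]),
      null = null,
      p = p,
      n_permutations = n_permutations,
      seed = seed,
      n_strains = n,
      loci_used = loci,
      loci_excluded = mm$loci[mono],
      clone_corrected = clone_correct,
      convention = paste(
        "distance per locus: 0 identical pair / 0.5 one shared allele /",
        "1 none; variances over strain pairs (denominator = number of",
        "pairs); null: independent per-locus permutation of single-locus",
        "genotypes; observed arrangement counted in p"
      )
    ),
    class = "ia_result"
  )
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}

#' @export
print.ia_result <- function(x, ...) {
  cat(sprintf(
    "<ia_result> I_A = %.5f, rbarD = %s; p = %.4g (%d permutations, null %.5f..%.5f)\n",
    x$ia, ifelse(is.na(x$rbard), "NA", sprintf("%.5f", x$rbard)), x$p,
    x$n_permutations, min(x$null), max(x$null)
  ))
  invisible(x)
}

#' @export
tidy.ia_result <- function(x, ...) {
  tibble(permutation = seq_along(x$null), ia = x$null)
}

#' @export
glance.ia_result <- function(x, ...) {
  tibble(
    ia = x$ia, rbard = x$rbard, p = x$p,
    null_min = min(x$null), null_max = max(x$null),
    n_permutations = x$n_permutations, n_strains = x$n_strains,
    n_loci = length(x$loci_used)
  )
}

#' Plot the index-of-association permutation null
#'
#' @param object An `ia_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ia_result <- function(object, ...) {
  ggplot2::ggplot(tibble(ia = object$null), ggplot2::aes(x = .data$ia)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey35") +
    ggplot2::geom_vline(xintercept = object$ia, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      title = sprintf("Index of association: observed %.4f, p = %.3g",
                      object$ia, object$p),
      x = expression(I[A]), y = "permutations"
    ) +
    ggplot2::theme_minimal()
}

#' Write an index-of-association report as JSON
#'
#' @param x An `ia_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ia_report <- function(x, path) {
  stopifnot(inherits(x, "ia_result"))
  jsonlite::write_json(
    list(
      ia = x$ia, rbard = x$rbard, p = x$p,
      null_range = range(x$null),
      n_permutations = x$n_permutations, seed = x$seed,
      n_strains = x$n_strains,
      loci_used = x$loci_used, loci_excluded = x$loci_excluded,
      convention = x$convention
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Pairwise-locus phylogenetic compatibility test
#'
#' Two loci are phylogenetically incompatible -- evidence of recombination
#' under an infinite-alleles view -- when for some pair of alleles at each
#' locus all four combinations are observed.  A combination `(a, b)` is
#' *evidenced* by a strain carrying `a` at locus 1 and `b` at locus 2
#' with at least one of the two loci homozygous (cross-locus phase then
#' unambiguous), or by a doubly heterozygous strain in which the
#' combination is present under both possible cross-locus pairings.
#'
#' @param df Tidy multilocus genotype tibble.
#' @param locus1,locus2 Names of the two loci to compare.
#' @return An object of class `compatibility_report`: `quartets` (tibble
#'   of incompatible allele quartets with witness strains per
#'   combination), `n_quartets_tested`, `evidence` (tibble of evidenced
#'   combinations).
#' @export
phylogenetic_compatibility <- function(df, locus1, locus2) {
  mm <- mlg_matrices(df)
  for (l in c(locus1, locus2)) {
    if (!l %in% mm$loci) abort(sprintf("Locus '%s' not in matrix.", l))
  }
  x1 <- mm$a1[, locus1]; y1 <- mm$a2[, locus1]
  x2 <- mm$a1[, locus2]; y2 <- mm$a2[, locus2]
  ev <- list()   # key "a||b" -> witness strains
  add <- function(ev, a, b, strain) {
    key <- paste0(a, "\r", b)
    ev[[key]] <- c(ev[[key]], strain)
    ev
  }
  for (i in seq_along(mm$strains)) {
    s <- mm$strains[i]
    hom1 <- x1[i] == y1[i]
    hom2 <- x2[i] == y2[i]
    if (hom1 || hom2) {
      for (a in unique(c(x1[i], y1[i]))) {
        for (b in unique(c(x2[i], y2[i]))) {
          ev <- add(ev, a, b, s)
        }
      }
    } else {
      pairing1 <- list(c(x1[i], x2[i]), c(y1[i], y2[i]))
      pairing2 <- list(c(x1[i], y2[i]), c(y1[i], x2[i]))
      keys1 <- vapply(pairing1, paste, character(1), collapse = "\r")
      keys2 <- vapply(pairing2, paste, character(1), collapse = "\r")
      for (key in intersect(keys1, keys2)) {
        ab <- strsplit(key, "\r")[[1]]
        ev <- add(ev, ab[1], ab[2], s)
      }
    }
  }
  ev_keys <- names(ev) %||% character(0)
  evidence <- tibble(
    allele1 = vapply(strsplit(ev_keys, "\r"), `[`, character(1), 1),
    allele2 = vapply(strsplit(ev_keys, "\r"), `[`, character(1), 2),
    witnesses = vapply(ev, function(w) paste(sort(unique(w)), collapse = ","),
                       character(1))
  )
  alleles1 <- sort(unique(c(x1, y1)))
  alleles2 <- sort(unique(c(x2, y2)))
  quartets <- list()
  n_tested <- 0L
  if (length(alleles1) >= 2 && length(alleles2) >= 2) {
    has <- function(a, b) any(evidence$allele1 == a & evidence$allele2 == b)
    wit <- function(a, b) {
      evidence$witnesses[evidence$allele1 == a & evidence$allele2 == b][1]
    }
    for (pa in utils::combn(alleles1, 2, simplify = FALSE)) {
      for (pb in utils::combn(alleles2, 2, simplify = FALSE)) {
        n_tested <- n_tested + 1L
        if (has(pa[1], pb[1]) && has(pa[1], pb[2]) &&
            has(pa[2], pb[1]) && has(pa[2], pb[2])) {
          quartets[[length(quartets) + 1L]] <- tibble(
            locus1_allele_1 = pa[1], locus1_allele_2 = pa[2],
            locus2_allele_1 = pb[1], locus2_allele_2 = pb[2],
            witnesses = paste(
              sprintf("%s x %s: %s",
                      c(pa[1], pa[1], pa[2], pa[2]),
                      c(pb[1], pb[2], pb[1], pb[2]),
                      c(wit(pa[1], pb[1]), wit(pa[1], pb[2]),
                        wit(pa[2], pb[1]), wit(pa[2], pb[2]))),
              collapse = "; "
            )
          )
        }
      }
    }
  }
  structure(
    list(
      locus1 = locus1,
      locus2 = locus2,
      quartets = if (length(quartets) > 0) bind_rows(quartets) else
        tibble(locus1_allele_1 = character(), locus1_allele_2 = character(),
               locus2_allele_1 = character(), locus2_allele_2 = character(),
               witnesses = character()),
      n_quartets_tested = n_tested,
      evidence = evidence
    ),
    class = "compatibility_report"
  )
}

#' @export
print.compatibility_report <- function(x, ...) {
  cat(sprintf(
    "<compatibility_report> %s vs %s: %d of %d allele quartets incompatible (recombination-evidencing)\n",
    x$locus1, x$locus2, nrow(x$quartets), x$n_quartets_tested
  ))
  invisible(x)
}

#' @export
tidy.compatibility_report <- function(x, ...) x$quartets

#' @export
glance.compatibility_report <- function(x, ...) {
  tibble(
    locus1 = x$locus1, locus2 = x$locus2,
    n_incompatible_quartets = nrow(x$quartets),
    n_quartets_tested = x$n_quartets_tested
  )
}

#' Write a compatibility report as TSV
#'
#' @param x A `compatibility_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compatibility_report <- function(x, path) {
  stopifnot(inherits(x, "compatibility_report"))
  readr::write_tsv(x$quartets, path)
  invisible(path)
}
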