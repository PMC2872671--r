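# Genealogical concordance: the incongruence-length-difference (partition
# homogeneity) test and the monophyly-constrained search used to ask
# whether independent loci support the same lineages.

#' Partition homogeneity (incongruence length difference) test
#'
#' Tests whether separate loci support congruent genealogies.  The
#' statistic is the sum over partitions of the best parsimony length of
#' that partition's variable characters.  The null distribution is built
#' by pooling all variable characters and randomly repartitioning them
#' into blocks of the original sizes.  Congruent data give partition sums
#' at the low, typical end of the null, so the tail probability is the
#' proportion of repartitions with a summed length less than or equal to
#' the observed sum (observed arrangement included in numerator and
#' denominator); *small* p indicates incongruence.
#'
#' @param loci List of two or more [aligned_locus()] objects over an
#'   identical strain set.
#' @param n_reps Number of random repartitions.
#' @param seed Integer seed.
#' @param n_random_addition Random-addition replicates per parsimony
#'   search.
#' @return An object of class `ild_result`: `observed` (summed length),
#'   `null` (numeric vector of length `n_reps`), `p`, `block_sizes`.
#' @export
ild_test <- function(loci, n_reps = 99, seed = 1, n_random_addition = 2) {
  if (!is.list(loci) || length(loci) < 2) {
    abort("`loci` must be a list of at least two aligned loci.")
  }
  purrr::walk(loci, function(l) stopifnot(inherits(l, "aligned_locus")))
  strains <- loci[[1]]$strain_ids
  for (l in loci[-1]) {
    if (!setequal(l$strain_ids, strains)) {
      abort(sprintf("Locus '%s' has a different strain set.", l$locus_name))
    }
  }
  if (length(strains) < 4) abort("ILD test requires at least 4 strains.")
  # pool variable characters, rows aligned to the first locus's strain order
  char_mats <- lapply(loci, function(l) {
    l <- subset_locus(l, strains)
    l$strain_ids <- strains
    l$matrix <- l$matrix[strains, , drop = FALSE]
    enc <- encode_characters(l)
    enc$masks[, enc$variable, drop = FALSE]
  })
  sizes <- vapply(char_mats, ncol, integer(1))
  if (sum(sizes) == 0) abort("No variable characters in any locus.")
  pooled <- do.call(cbind, char_mats)
  block <- rep(seq_along(sizes), sizes)
  score_partition <- function(cols) {
    if (length(cols) == 0) return(0)
    pat <- compress_patterns(pooled, cols)
    search_core(strains, pat$masks, pat$weights, n_random_addition)$length
  }
  sum_lengths <- function(assignment) {
    sum(vapply(seq_along(sizes), function(k) {
      score_partition(which(assignment == k))
    }, numeric(1)))
  }
  res <- withr::with_seed(derive_seed(seed, "ild"), {
    observed <- sum_lengths(block)
    null <- vapply(seq_len(n_reps), function(b) {
      sum_lengths(sample(block))
    }, numeric(1))
    list(observed = observed, null = null)
  })
  structure(
    list(
      observed = res$observed,
      null = res$null,
      p = (1 + sum(res$null <= res$observed)) / (1 + n_reps),
      block_sizes = sizes,
      n_reps = n_reps,
      seed = seed
    ),
    class = "ild_result"
  )
}

#' @export
print.ild_result <- function(x, ...) {
  cat(sprintf("<ild_result> observed summed length %s; p = %.4g (%d repartitions)\n",
              format(x$observed), x$p, x$n_reps))
  invisible(x)
}

#' @export
glance.ild_result <- function(x, ...) {
  tibble(observed = x$observed, p = x$p, n_reps = x$n_reps,
         null_min = min(x$null), null_max = max(x$null))
}

#' Monophyly-constrained parsimony search and permutation test
#'
#' Searches for the best tree subject to each given group being
#' monophyletic (stepwise placements and NNI moves that would break a
#' constraint are rejected), and compares its length with the
#' unconstrained optimum: `delta = constrained - unconstrained >= 0` by
#' construction, with `delta = 0` meaning the constraint costs nothing
#' (the data are compatible with the grouping).  A permutation null for
#' `delta` is built by independently permuting each character's states
#' among the strains, which destroys any grouping signal; the tail
#' probability is the proportion of permuted deltas at least as large as
#' the observed one (observed included).  A p near 1 means the constraint
#' fits far better than it would on structureless data.
#'
#' @param locus An [aligned_locus()].
#' @param constraint Named list of disjoint character vectors of strain
#'   ids, each to be held monophyletic.
#' @param seed Integer seed.
#' @param n_random_addition Random-addition replicates per search.
#' @param n_permutations Permutation replicates for the null; 0 skips the
#'   permutation test (`p` is then `NA`).
#' @return An object of class `constraint_test`: `constrained_length`,
#'   `unconstrained_length`, `delta`, `p`, `null` (permuted deltas),
#'   `trees` (constrained minimal topologies as `phylo`).
#' @export
constrained_search <- function(locus, constraint, seed = 1,
                               n_random_addition = 10,
                               n_permutations = 99) {
  stopifnot(inherits(locus, "aligned_locus"))
  if (!is.list(constraint) || length(constraint) == 0) {
    abort("`constraint` must be a nonempty list of strain-id groups.")
  }
  all_members <- unlist(constraint)
  if (anyDuplicated(all_members)) {
    abort("Constraint groups must be disjoint.",
          class = "mycopop_constraint_error")
  }
  missing <- setdiff(all_members, locus$strain_ids)
  if (length(missing) > 0) {
    abort(sprintf("Constraint strains not in alignment: %s.",
                  paste(missing, collapse = ", ")))
  }
  prep <- prepare_search(locus)
  groups <- lapply(constraint, function(g) match(g, locus$strain_ids))
  delta_of <- function(masks, weights, n_add) {
    un <- search_core(prep$labels, masks, weights, n_add)
    co <- search_core(prep$labels, masks, weights, n_add,
                      constraint_ids = groups)
    list(delta = co$length - un$length, un = un, co = co)
  }
  res <- withr::with_seed(derive_seed(seed, "constrained"), {
    obs <- delta_of(prep$masks, prep$weights, n_random_addition)
    n <- length(prep$labels)
    null <- vapply(seq_len(n_permutations), function(b) {
      perm <- prep$masks
      for (j in seq_len(ncol(perm))) perm[, j] <- perm[sample.int(n), j]
      delta_of(perm, prep$weights, max(2L, ceiling(n_random_addition / 5)))$delta
    }, numeric(1))
    list(obs = obs, null = null)
  })
  structure(
    list(
      locus_name = locus$locus_name,
      constrained_length = res$obs$co$length,
      unconstrained_length = res$obs$un$length,
      delta = res$obs$delta,
      null = res$null,
      p = if (n_permutations > 0) {
        (1 + sum(res$null >= res$obs$delta)) / (1 + n_permutations)
      } else NA_real_,
      trees = lapply(res$obs$co$trees, ut_to_phylo,
                     labels = locus$strain_ids),
      n_permutations = n_permutations,
      seed = seed
    ),
    class = "constraint_test"
  )
}

#' @export
print.constraint_test <- function(x, ...) {
  cat(sprintf(
    "<constraint_test> %s: constrained %s vs unconstrained %s (delta = %s); p = %.4g\n",
    x$locus_name, format(x$constrained_length),
    format(x$unconstrained_length), format(x$delta), x$p
  ))
  invisible(x)
}

#' @export
glance.constraint_test <- function(x, ...) {
  tibble(
    locus = x$locus_name,
    constrained_length = x$constrained_length,
    unconstrained_length = x$unconstrained_length,
    delta = x$delta,
    p = x$p,
    n_permutations = x$n_permutations
  )
}
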