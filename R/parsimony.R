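# Maximum parsimony: Fitch scoring with consistency and retention indices,
# heuristic search (random stepwise addition + NNI branch swapping), and
# nonparametric bootstrap.
#
# Conventions: gaps are treated as missing data in parsimony scoring (the
# indel signal enters the genotyping and divergence modules instead);
# two-base IUPAC codes are treated as partial uncertainty between their
# constituent bases.

BASE_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, M = 3L, K = 12L, W = 9L, S = 6L,
  "-" = 15L
)

popcount4 <- function(x) {
  (bitwAnd(x, 1L) > 0) + (bitwAnd(x, 2L) > 0) +
    (bitwAnd(x, 4L) > 0) + (bitwAnd(x, 8L) > 0)
}

# encode an aligned locus into bitmask characters; returns the mask matrix
# (strains x sites), plus per-site bookkeeping
encode_characters <- function(locus) {
  m <- locus$matrix
  masks <- matrix(BASE_MASK[m], nrow = nrow(m))
  rownames(masks) <- locus$strain_ids
  nonmissing <- masks != 15L
  # per column: union of non-missing masks, and per-base containment counts
  n_char <- ncol(masks)
  union_mask <- integer(n_char)
  max_contain <- integer(n_char)
  for (j in seq_len(n_char)) {
    col <- masks[nonmissing[, j], j]
    if (length(col) == 0) {
      union_mask[j] <- 0L
      max_contain[j] <- 0L
    } else {
      union_mask[j] <- Reduce(bitwOr, col)
      contain <- vapply(c(1L, 2L, 4L, 8L),
                        function(b) sum(bitwAnd(col, b) > 0), numeric(1))
      max_contain[j] <- max(contain)
    }
  }
  n_states <- popcount4(union_mask)
  n_eff <- colSums(nonmissing)
  min_steps <- pmax(n_states - 1L, 0L)
  max_steps <- pmax(n_eff - max_contain, 0L)
  variable <- n_states >= 2
  # informative: at least two states each carried by at least two strains
  informative <- logical(n_char)
  for (j in which(variable)) {
    col <- masks[nonmissing[, j], j]
    contain <- vapply(c(1L, 2L, 4L, 8L),
                      function(b) sum(bitwAnd(col, b) > 0), numeric(1))
    informative[j] <- sum(contain >= 2) >= 2
  }
  list(
    masks = masks,
    variable = variable,
    informative = informative,
    min_steps = min_steps,
    max_steps = max_steps
  )
}

# collapse identical variable columns into weighted patterns
compress_patterns <- function(masks, columns, weights = NULL) {
  if (length(columns) == 0) {
    return(list(masks = masks[, 0, drop = FALSE], weights = numeric(0)))
  }
  sub <- masks[, columns, drop = FALSE]
  w <- weights %||% rep(1, length(columns))
  key <- apply(sub, 2, paste, collapse = ",")
  first <- !duplicated(key)
  agg <- tapply(w, key, sum)
  list(
    masks = sub[, first, drop = FALSE],
    weights = as.numeric(agg[key[first]])
  )
}

#' Fitch parsimony score of a tree on an alignment
#'
#' Computes the minimum number of state changes needed on the given
#' unrooted topology under Fitch parsimony (post-order state-set pass:
#' intersection where nonempty, else union with one added step), together
#' with the ensemble consistency index `CI = sum(m_i)/sum(s_i)` and
#' retention index `RI = (sum(g_i) - sum(s_i))/(sum(g_i) - sum(m_i))`,
#' where for each character `m_i` is the number of distinct observed
#' states minus one and `g_i` is the number of scored strains minus the
#' count of the most frequent state.  Gaps are missing data; two-base
#' ambiguity codes are partial uncertainty.  Indices are reported both
#' over all variable characters and over parsimony-informative characters
#' only, since conventions differ.
#'
#' @param tree An ape `phylo` whose tips are exactly the alignment strains.
#' @param locus An [aligned_locus()].
#' @return An object of class `parsimony_score`: `length` (total steps),
#'   `ci`, `ri`, `ci_informative`, `ri_informative`, and `per_character`
#'   (tibble: `position`, `steps`, `min_steps`, `max_steps`,
#'   `informative`).
#' @export
fitch_length <- function(tree, locus) {
  stopifnot(inherits(locus, "aligned_locus"))
  tr <- ut_from_phylo(tree, locus$strain_ids)
  if (length(tr$tips_in) != length(locus$strain_ids)) {
    abort("Tree tips and alignment strains must match exactly.",
          class = "mycopop_label_error")
  }
  enc <- encode_characters(locus)
  cols <- which(enc$variable)
  if (length(cols) == 0) {
    steps <- integer(0)
  } else {
    steps <- ut_fitch_steps(tr, enc$masks[, cols, drop = FALSE])
  }
  per_character <- tibble(
    position = cols,
    steps = as.integer(steps),
    min_steps = enc$min_steps[cols],
    max_steps = enc$max_steps[cols],
    informative = enc$informative[cols]
  )
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  s <- sum(per_character$steps)
  m <- sum(per_character$min_steps)
  g <- sum(per_character$max_steps)
  inf <- per_character[per_character$informative, ]
  si <- sum(inf$steps); mi <- sum(inf$min_steps); gi <- sum(inf$max_steps)
  structure(
    list(
      locus_name = locus$locus_name,
      length = s,
      ci = ratio(m, s),
      ri = ratio(g - s, g - m),
      ci_informative = ratio(mi, si),
      ri_informative = ratio(gi - si, gi - mi),
      per_character = per_character
    ),
    class = "parsimony_score"
  )
}

#' @export
print.parsimony_score <- function(x, ...) {
  cat(sprintf("<parsimony_score> %s: length %d, CI %.3f, RI %.3f (%d variable characters)\n",
              x$locus_name, x$length, x$ci, x$ri, nrow(x$per_character)))
  invisible(x)
}

#' @export
tidy.parsimony_score <- function(x, ...) x$per_character

#' @export
glance.parsimony_score <- function(x, ...) {
  tibble(
    locus = x$locus_name, length = x$length,
    ci = x$ci, ri = x$ri,
    ci_informative = x$ci_informative, ri_informative = x$ri_informative,
    n_variable = nrow(x$per_character),
    n_informative = sum(x$per_character$informative)
  )
}

# core heuristic search over a prepared pattern set; deterministic given
# the RNG state at entry.  Returns the set of minimal-length local optima.
search_core <- function(labels, masks, weights, n_random_addition,
                        constraint_ids = NULL) {
  n <- length(labels)
  best_len <- Inf
  best <- list()   # signature -> utree
  score <- function(tr) ut_length(tr, masks, weights)
  ok <- function(tr) {
    is.null(constraint_ids) || ut_constraints_ok(tr, constraint_ids)
  }
  for (rep in seq_len(n_random_addition)) {
    ord <- sample.int(n)
    tr <- ut_init(n, ord[1:3])
    for (tip in ord[-(1:3)]) {
      cand_best <- NULL
      cand_len <- Inf
      for (e in seq_len(nrow(tr$edges))) {
        cand <- ut_insert(tr, e, tip)
        if (!ok(cand)) next
        len <- score(cand)
        if (len < cand_len) {
          cand_len <- len
          cand_best <- cand
        }
      }
      if (is.null(cand_best)) {
        abort("No constraint-compatible placement found during stepwise addition.")
      }
      tr <- cand_best
    }
    # NNI steepest descent
    cur_len <- score(tr)
    repeat {
      nb <- ut_nni_neighbours(tr)
      improved <- FALSE
      for (cand in nb) {
        if (!ok(cand)) next
        len <- score(cand)
        if (len < cur_len) {
          tr <- cand
          cur_len <- len
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    if (cur_len < best_len) {
      best_len <- cur_len
      best <- list()
    }
    if (cur_len == best_len) {
      sig <- ut_signature(tr)
      if (!sig %in% names(best)) best[[sig]] <- tr
    }
  }
  best <- best[order(names(best))]   # lexicographic tie-break
  list(trees = best, length = best_len)
}

prepare_search <- function(locus) {
  enc <- encode_characters(locus)
  pat <- compress_patterns(enc$masks, which(enc$variable))
  list(enc = enc, masks = pat$masks, weights = pat$weights,
       labels = locus$strain_ids)
}

#' Heuristic maximum-parsimony tree search
#'
#' Random-addition-sequence stepwise insertion followed by
#' nearest-neighbour-interchange (NNI) branch swapping to a local optimum,
#' repeated `n_random_addition` times.  All distinct minimal-length
#' topologies found are returned, ordered by a lexicographic bipartition
#' encoding so results are reproducible; the search is deterministic given
#' `seed`.
#'
#' @param locus An [aligned_locus()] with at least 4 strains.
#' @param n_random_addition Number of random-addition replicates.
#' @param seed Integer seed.
#' @return An object of class `mp_result`: `trees` (list of ape `phylo`),
#'   `length` (parsimony steps over variable characters), `n_trees`.
#' @export
mp_search <- function(locus, n_random_addition = 10, seed = 1) {
  stopifnot(inherits(locus, "aligned_locus"))
  if (length(locus$strain_ids) < 4) {
    abort("Parsimony search requires at least 4 strains.")
  }
  assert_scalar_count(n_random_addition, "n_random_addition")
  prep <- prepare_search(locus)
  res <- withr::with_seed(derive_seed(seed, "mp_search"), {
    search_core(prep$labels, prep$masks, prep$weights, n_random_addition)
  })
  structure(
    list(
      locus_name = locus$locus_name,
      trees = lapply(res$trees, ut_to_phylo, labels = locus$strain_ids),
      trees_internal = res$trees,
      length = res$length,
      n_trees = length(res$trees),
      seed = seed
    ),
    class = "mp_result"
  )
}

#' @export
print.mp_result <- function(x, ...) {
  cat(sprintf("<mp_result> %s: %d minimal tree(s) of length %s\n",
              x$locus_name, x$n_trees, format(x$length)))
  invisible(x)
}

#' @export
glance.mp_result <- function(x, ...) {
  tibble(locus = x$locus_name, length = x$length, n_trees = x$n_trees)
}

#' Nonparametric bootstrap support for the best parsimony tree
#'
#' Resamples alignment columns with replacement, repeats the parsimony
#' search on each pseudo-alignment, and reports for every internal edge of
#' the best tree the percentage of replicates whose best tree contains the
#' same bipartition.  Resampling is indexed by column, so supports do not
#' depend on strain input order.  Deterministic given `seed`.
#'
#' @inheritParams mp_search
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param n_random_addition_rep Random-addition replicates per bootstrap
#'   replicate (the full search for the reported tree uses
#'   `n_random_addition`).
#' @return An ape `phylo` (first minimal tree, lexicographic tie-break)
#'   with internal-node labels giving bootstrap percentages, and
#'   attributes `supports` (tibble: `bipartition`, `support`) and
#'   `mp_length`.  With no variable sites all supports are `NA`.
#' @export
bootstrap_support <- function(locus, n_reps = 100, seed = 1,
                              n_random_addition = 10,
                              n_random_addition_rep = 2) {
  stopifnot(inherits(locus, "aligned_locus"))
  assert_scalar_count(n_reps, "n_reps")
  full <- mp_search(locus, n_random_addition = n_random_addition, seed = seed)
  best_ut <- full$trees_internal[[1]]
  target_bips <- ut_bipartitions(best_ut)
  enc <- encode_characters(locus)
  n_sites <- ncol(enc$masks)
  no_signal <- sum(enc$variable) == 0
  hits <- setNames(numeric(length(target_bips)), target_bips)
  if (!no_signal && length(target_bips) > 0) {
    withr::with_seed(derive_seed(seed, "bootstrap"), {
      for (b in seq_len(n_reps)) {
        idx <- sample.int(n_sites, n_sites, replace = TRUE)
        w <- tabulate(idx, nbins = n_sites)
        cols <- which(enc$variable & w > 0)
        pat <- compress_patterns(enc$masks, cols, weights = w[cols])
        res <- search_core(locus$strain_ids, pat$masks, pat$weights,
                           n_random_addition_rep)
        rep_bips <- ut_bipartitions(res$trees[[1]])
        hit <- target_bips %in% rep_bips
        hits[hit] <- hits[hit] + 1
      }
    })
    support <- round(100 * hits / n_reps, 1)
  } else {
    support <- setNames(rep(NA_real_, length(target_bips)), target_bips)
  }
  phy <- ut_to_phylo(best_ut, locus$strain_ids, support = support)
  attr(phy, "supports") <- tibble(
    bipartition = names(support),
    support = unname(support)
  )
  attr(phy, "mp_length") <- full$length
  phy
}
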