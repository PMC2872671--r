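# Independent oracles used to freeze expected values.  These deliberately
# use brute-force enumeration (pair counting, exhaustive ancestral-state
# assignment, exhaustive topology scan, exhaustive permutation scan) and
# share no code with the implementation paths they check.

# probability that two individuals drawn without replacement differ,
# by literal pair enumeration
oracle_diversity <- function(counts) {
  ids <- rep(seq_along(counts), counts)
  pairs <- utils::combn(length(ids), 2)
  mean(ids[pairs[1, ]] != ids[pairs[2, ]])
}

# all integer partitions of n (count vectors up to reordering)
integer_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (k in seq_len(min(n, max_part))) {
    for (rest in integer_partitions(n - k, k)) {
      out[[length(out) + 1L]] <- c(k, rest)
    }
  }
  out
}

# bitmask encoding mirroring the four-bit base convention (gap = missing)
oracle_masks <- function(seqs) {
  map <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, M = 3L,
           K = 12L, W = 9L, S = 6L, "-" = 15L)
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  out <- matrix(map[m], nrow = nrow(m))
  rownames(out) <- names(seqs)
  out
}

# minimum parsimony steps of one tree by exhaustive enumeration of
# ancestral state assignments at the internal nodes (rooting is
# irrelevant to the minimum, so the tree is used as given)
oracle_tree_length <- function(phy, masks) {
  n <- length(phy$tip.label)
  masks <- masks[phy$tip.label, , drop = FALSE]
  n_int <- phy$Nnode
  n_char <- ncol(masks)
  states <- c(1L, 2L, 4L, 8L)
  grid <- as.matrix(expand.grid(rep(list(states), n_int)))
  cost <- matrix(0L, nrow(grid), n_char)
  for (e in seq_len(nrow(phy$edge))) {
    a <- phy$edge[e, 1]
    b <- phy$edge[e, 2]
    if (b <= n) {
      # tip edge: cost 1 unless the internal state is within the tip set
      tipmask <- matrix(masks[b, ], nrow(grid), n_char, byrow = TRUE)
      intstate <- grid[, a - n]
      cost <- cost + (bitwAnd(matrix(intstate, nrow(grid), n_char), tipmask) == 0L)
    } else {
      mism <- grid[, a - n] != grid[, b - n]
      cost <- cost + matrix(mism, nrow(grid), n_char)
    }
  }
  apply(cost, 2, min)
}

# global minimum length over all unrooted topologies (phangorn enumerates
# the topologies; scoring is the assignment-enumeration oracle above)
oracle_mp_length <- function(masks, weights = rep(1, ncol(masks))) {
  labels <- rownames(masks)
  trees <- phangorn::allTrees(length(labels), rooted = FALSE,
                              tip.label = labels)
  best <- Inf
  best_trees <- list()
  for (k in seq_along(trees)) {
    tr <- trees[[k]]   # [[ restores tip.label from compressed multiPhylo
    len <- sum(weights * oracle_tree_length(tr, masks))
    if (len < best - 1e-9) {
      best <- len
      best_trees <- list(tr)
    } else if (abs(len - best) < 1e-9) {
      best_trees[[length(best_trees) + 1L]] <- tr
    }
  }
  list(length = best, trees = best_trees)
}

# random IUPAC alignment for fuzzing (may include ambiguity codes and a
# gappy region)
random_alignment <- function(n_strains, n_sites, p_gap = 0.1, p_amb = 0.1) {
  alphabet <- c("A", "C", "G", "T")
  amb <- c("R", "Y", "M", "K", "W", "S")
  seqs <- vapply(seq_len(n_strains), function(i) {
    chars <- sample(alphabet, n_sites, replace = TRUE)
    k <- rbinom(1, n_sites, p_amb)
    if (k > 0) {
      pos <- sample(n_sites, k)
      chars[pos] <- sample(amb, k, replace = TRUE)
    }
    paste(chars, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("t%d", seq_len(n_strains))
  if (runif(1) < p_gap * n_strains) {
    # gap track in one strain
    who <- sample(n_strains, 1)
    start <- sample(n_sites, 1)
    len <- sample(min(3, n_sites - start + 1), 1)
    s <- strsplit(seqs[[who]], "")[[1]]
    s[start:(start + len - 1)] <- "-"
    seqs[[who]] <- paste(s, collapse = "")
  }
  seqs
}

# straightforward loop implementation of the index of association from
# two allele matrices (rows = strains), plus exhaustive permutation p
naive_ia <- function(a1, a2) {
  n <- nrow(a1)
  L <- ncol(a1)
  pairs <- utils::combn(n, 2)
  d <- matrix(0, ncol(pairs), L)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    for (l in seq_len(L)) {
      p1 <- sort(c(a1[i, l], a2[i, l]))
      p2 <- sort(c(a1[j, l], a2[j, l]))
      if (identical(p1, p2)) {
        d[k, l] <- 0
      } else if (any(p1 %in% p2)) {
        d[k, l] <- 0.5
      } else {
        d[k, l] <- 1
      }
    }
  }
  popvar <- function(x) mean(x^2) - mean(x)^2
  v_o <- popvar(rowSums(d))
  v_l <- apply(d, 2, popvar)
  v_o / sum(v_l) - 1
}

perms_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (s in perms_of(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}
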