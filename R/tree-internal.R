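# Internal unrooted-binary-tree toolkit used by the parsimony engine.
#
# Trees are kept as plain edge lists over integer node ids: tips use the
# ids 1..n of the full strain universe (so subsets of tips are valid
# during stepwise addition), internal nodes use ids above n in order of
# creation.  Conversion to/from ape's `phylo` happens only at the API
# boundary.

ut_init <- function(n_universe, first3) {
  list(
    n_universe = as.integer(n_universe),
    tips_in = as.integer(first3),
    edges = cbind(rep(n_universe + 1L, 3L), as.integer(first3)),
    next_id = n_universe + 2L
  )
}

ut_insert <- function(tr, edge_row, tip) {
  w <- tr$next_id
  uv <- tr$edges[edge_row, ]
  tr$edges[edge_row, ] <- c(uv[1], w)
  tr$edges <- rbind(tr$edges, c(w, uv[2]), c(w, tip))
  tr$next_id <- w + 1L
  tr$tips_in <- c(tr$tips_in, as.integer(tip))
  tr
}

ut_adj <- function(tr) {
  max_id <- tr$next_id - 1L
  adj <- vector("list", max_id)
  e <- tr$edges
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
    adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
  }
  adj
}

# preorder node list and parent vector, rooted at tip `r`
ut_orient <- function(tr, adj = ut_adj(tr), r = tr$tips_in[1]) {
  max_id <- tr$next_id - 1L
  parent <- integer(max_id)
  pre <- integer(0)
  stack <- adj[[r]]
  parent[stack] <- r
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    for (w in adj[[v]]) {
      if (w != parent[v]) {
        parent[w] <- v
        stack <- c(stack, w)
      }
    }
  }
  list(pre = pre, parent = parent, root_tip = r)
}

# Fitch scoring: masks is an n_universe x n_char integer bitmask matrix
# (A=1, C=2, G=4, T=8; ambiguity codes = union; gap/missing = 15).
# Returns per-character step counts; total length = sum(weights * steps).
ut_fitch_steps <- function(tr, masks, adj = ut_adj(tr)) {
  ori <- ut_orient(tr, adj)
  n_char <- ncol(masks)
  max_id <- tr$next_id - 1L
  S <- matrix(0L, nrow = max_id, ncol = n_char)
  S[tr$tips_in, ] <- masks[tr$tips_in, , drop = FALSE]
  steps <- integer(n_char)
  for (v in rev(ori$pre)) {
    if (v > tr$n_universe) {
      ch <- adj[[v]][adj[[v]] != ori$parent[v]]
      A <- S[ch[1], ]
      B <- S[ch[2], ]
      I <- bitwAnd(A, B)
      z <- I == 0L
      steps <- steps + z
      S[v, ] <- ifelse(z, bitwOr(A, B), I)
    }
  }
  top <- adj[[ori$root_tip]][1]
  steps + (bitwAnd(S[top, ], masks[ori$root_tip, ]) == 0L)
}

ut_length <- function(tr, masks, weights) {
  sum(weights * ut_fitch_steps(tr, masks))
}

# all NNI neighbours (two per internal edge)
ut_nni_neighbours <- function(tr) {
  adj <- ut_adj(tr)
  internal <- tr$edges[, 1] > tr$n_universe & tr$edges[, 2] > tr$n_universe
  out <- list()
  swap_edge <- function(tr, u, old, new) {
    hit <- which((tr$edges[, 1] == u & tr$edges[, 2] == old) |
                   (tr$edges[, 2] == u & tr$edges[, 1] == old))[1]
    tr$edges[hit, ] <- c(u, new)
    tr
  }
  for (i in which(internal)) {
    u <- tr$edges[i, 1]
    v <- tr$edges[i, 2]
    nb_u <- setdiff(adj[[u]], v)
    nb_v <- setdiff(adj[[v]], u)
    for (k in 1:2) {
      cand <- tr
      cand <- swap_edge(cand, u, nb_u[2], nb_v[k])
      cand <- swap_edge(cand, v, nb_v[k], nb_u[2])
      out[[length(out) + 1L]] <- cand
    }
  }
  out
}

# descendant tip sets per node, rooted at the smallest tip in the tree
ut_desc_sets <- function(tr, adj = ut_adj(tr)) {
  ori <- ut_orient(tr, adj, r = min(tr$tips_in))
  desc <- vector("list", tr$next_id - 1L)
  for (v in rev(ori$pre)) {
    if (v <= tr$n_universe) {
      desc[[v]] <- v
    } else {
      ch <- adj[[v]][adj[[v]] != ori$parent[v]]
      desc[[v]] <- sort(c(desc[[ch[1]]], desc[[ch[2]]]))
    }
  }
  list(desc = desc, ori = ori)
}

# canonical nontrivial bipartition keys ("id,id,..." for the side not
# containing the smallest tip)
ut_bipartitions <- function(tr) {
  adj <- ut_adj(tr)
  d <- ut_desc_sets(tr, adj)
  tips <- sort(tr$tips_in)
  n_in <- length(tips)
  keys <- character(0)
  for (v in d$ori$pre) {
    if (v > tr$n_universe) {
      side <- d$desc[[v]]
      if (length(side) >= 2 && length(side) <= n_in - 2) {
        if (tips[1] %in% side) side <- setdiff(tips, side)
        keys <- c(keys, paste(side, collapse = ","))
      }
    }
  }
  sort(unique(keys))
}

ut_signature <- function(tr) {
  paste(ut_bipartitions(tr), collapse = ";")
}

# does the current tree keep every constraint group (intersected with the
# tips present) monophyletic?
ut_constraints_ok <- function(tr, groups) {
  bips <- NULL
  tips <- sort(tr$tips_in)
  for (g in groups) {
    gin <- sort(intersect(g, tips))
    if (length(gin) < 2 || length(gin) >= length(tips) - 1) next
    if (is.null(bips)) bips <- ut_bipartitions(tr)
    key1 <- paste(gin, collapse = ",")
    key2 <- paste(setdiff(tips, gin), collapse = ",")
    if (!(key1 %in% bips || key2 %in% bips)) return(FALSE)
  }
  TRUE
}

# convert to an ape phylo (tips numbered by universe order of the tips
# present; internal nodes renumbered in preorder from a basal trichotomy)
ut_to_phylo <- function(tr, labels, support = NULL) {
  adj <- ut_adj(tr)
  tips <- sort(tr$tips_in)
  n_in <- length(tips)
  tip_new <- integer(tr$n_universe)
  tip_new[tips] <- seq_len(n_in)
  root <- adj[[tips[1]]][1]
  ori <- ut_orient(tr, adj, r = tips[1])
  internal_pre <- ori$pre[ori$pre > tr$n_universe]
  internal_pre <- c(root, setdiff(internal_pre, root))
  int_new <- integer(tr$next_id - 1L)
  int_new[internal_pre] <- n_in + seq_along(internal_pre)
  renum <- function(v) if (v <= tr$n_universe) tip_new[v] else int_new[v]
  # emit edges parent->child for every non-root node in preorder; the
  # rooting tip is re-attached under the basal node at the end
  edge <- matrix(0L, nrow = nrow(tr$edges), ncol = 2)
  k <- 0L
  for (v in ori$pre) {
    p <- ori$parent[v]
    if (v == root) next
    k <- k + 1L
    edge[k, ] <- c(renum(p), renum(v))
  }
  k <- k + 1L
  edge[k, ] <- c(int_new[root], tip_new[tips[1]])
  phy <- list(
    edge = edge,
    tip.label = labels[tips],
    Nnode = n_in - 2L
  )
  class(phy) <- "phylo"
  if (!is.null(support)) {
    # node labels indexed by internal node number - n_in; root label empty
    d <- ut_desc_sets(tr, adj)
    lab <- rep(NA_character_, n_in - 2L)
    for (v in internal_pre) {
      side <- d$desc[[v]]
      if (length(side) >= 2 && length(side) <= n_in - 2) {
        if (tips[1] %in% side) side <- setdiff(tips, side)
        key <- paste(side, collapse = ",")
        if (key %in% names(support)) {
          lab[int_new[v] - n_in] <- as.character(support[[key]])
        }
      }
    }
    phy$node.label <- lab
  }
  phy
}

# convert an ape phylo into the internal representation over a label
# universe (tree tips must all be universe members)
ut_from_phylo <- function(phy, labels) {
  if (!inherits(phy, "phylo")) abort("`tree` must be an ape 'phylo' object.")
  phy <- ape::unroot(phy)
  n <- length(phy$tip.label)
  ids <- match(phy$tip.label, labels)
  if (anyNA(ids)) {
    abort(sprintf("Tree tips not in strain set: %s.",
                  paste(phy$tip.label[is.na(ids)], collapse = ", ")),
          class = "mycopop_label_error")
  }
  n_universe <- length(labels)
  renum <- function(v) ifelse(v <= n, ids[v], n_universe + (v - n))
  edges <- cbind(renum(phy$edge[, 1]), renum(phy$edge[, 2]))
  list(
    n_universe = as.integer(n_universe),
    tips_in = sort(as.integer(ids)),
    edges = edges,
    next_id = as.integer(n_universe + phy$Nnode + 1L)
  )
}
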