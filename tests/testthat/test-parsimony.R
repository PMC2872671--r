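test_that("Fitch scoring matches hand-derived four-taxon cases", {
  loc <- aligned_locus(c(t1 = "A", t2 = "A", t3 = "T", t4 = "T"), "x")
  good <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  bad <- ape::read.tree(text = "((t1,t3),(t2,t4));")
  sg <- fitch_length(good, loc)
  sb <- fitch_length(bad, loc)
  expect_equal(sg$length, 1)
  expect_equal(sg$per_character$min_steps, 1)
  expect_equal(sg$per_character$max_steps, 2)
  expect_equal(sg$ci, 1)
  expect_equal(sg$ri, 1)
  expect_equal(sb$length, 2)
  expect_equal(sb$ci, 0.5)
  expect_equal(sb$ri, 0)
})

test_that("invariant characters cost zero on any topology", {
  loc <- aligned_locus(c(t1 = "AAAA", t2 = "AAAA", t3 = "AAAA", t4 = "AAAA"),
                       "x")
  tr <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  expect_equal(fitch_length(tr, loc)$length, 0)
})

test_that("tip/strain mismatches are rejected", {
  loc <- aligned_locus(c(t1 = "AC", t2 = "AC", t3 = "AC", t4 = "AC"), "x")
  tr <- ape::read.tree(text = "((t1,t2),(t3,t9));")
  expect_error(fitch_length(tr, loc), class = "mycopop_label_error")
})

test_that("Fitch lengths equal exhaustive assignment enumeration on fuzzed data", {
  withr::local_seed(71)
  for (i in 1:40) {
    n <- sample(4:6, 1)
    seqs <- random_alignment(n, sample(3:8, 1), p_gap = 0.3, p_amb = 0.15)
    loc <- aligned_locus(seqs, "fuzz")
    masks <- oracle_masks(seqs)
    tr <- ape::rtree(n, tip.label = sample(names(seqs)), br = NULL)
    got <- fitch_length(tr, loc)
    want <- oracle_tree_length(tr, masks)
    variable <- got$per_character$position
    expect_equal(got$length, sum(want[variable]))
    expect_equal(got$per_character$steps, unname(want[variable]))
    # cross-check against an independent library implementation
    if (requireNamespace("phangorn", quietly = TRUE)) {
      pd <- phangorn::phyDat(t(sapply(seqs, function(s) strsplit(s, "")[[1]])),
                             type = "DNA")
      expect_equal(got$length, phangorn::fitch(tr, pd))
    }
  }
})

test_that("heuristic search equals exhaustive topology enumeration on small cases", {
  withr::local_seed(72)
  for (i in 1:30) {
    n <- sample(4:6, 1)
    seqs <- random_alignment(n, sample(4:8, 1), p_gap = 0.2, p_amb = 0.1)
    loc <- aligned_locus(seqs, "fuzz")
    masks <- oracle_masks(seqs)
    res <- mp_search(loc, n_random_addition = 10, seed = i)
    oracle <- oracle_mp_length(masks)
    expect_equal(res$length, oracle$length)
  }
})

test_that("search recovers a planted bipartition and its clean length", {
  # 6 strains, two clades, 5 clean fixed differences
  seqs <- c(a1 = "AAAAA", a2 = "AAAAA", a3 = "AAAAA",
            b1 = "CCCCC", b2 = "CCCCC", b3 = "CCCCC")
  loc <- aligned_locus(seqs, "x")
  res <- mp_search(loc, n_random_addition = 3, seed = 1)
  expect_equal(res$length, 5)
  oracle <- oracle_mp_length(oracle_masks(seqs))
  expect_equal(res$length, oracle$length)
  # the a-clade forms a bipartition of the best tree
  bip <- ape::prop.part(res$trees[[1]])
  sides <- lapply(bip, function(s) sort(res$trees[[1]]$tip.label[s]))
  has_side <- function(x) any(vapply(sides, identical, logical(1), x))
  expect_true(has_side(c("a1", "a2", "a3")) || has_side(c("b1", "b2", "b3")))
})

test_that("search on an invariant alignment returns length zero", {
  loc <- aligned_locus(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT"), "x")
  expect_equal(mp_search(loc, n_random_addition = 2, seed = 1)$length, 0)
  expect_error(mp_search(aligned_locus(c(a = "AC", b = "AC"), "x")))
})

test_that("four-taxon single-character search groups the matching pair", {
  loc <- aligned_locus(c(t1 = "A", t2 = "A", t3 = "T", t4 = "T"), "x")
  res <- mp_search(loc, n_random_addition = 3, seed = 2)
  expect_equal(res$length, 1)
  bip <- ape::prop.part(res$trees[[1]])
  sides <- lapply(bip, function(s) sort(res$trees[[1]]$tip.label[s]))
  has_side <- function(x) any(vapply(sides, identical, logical(1), x))
  expect_true(has_side(c("t1", "t2")) || has_side(c("t3", "t4")))
})

test_that("CI is 1 exactly when no character is homoplastic", {
  withr::local_seed(73)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    seqs <- random_alignment(n, 6, p_gap = 0, p_amb = 0)
    loc <- aligned_locus(seqs, "fuzz")
    res <- mp_search(loc, n_random_addition = 3, seed = i)
    sc <- fitch_length(res$trees[[1]], loc)
    if (nrow(sc$per_character) == 0) next
    expect_equal(sc$ci == 1,
                 all(sc$per_character$steps == sc$per_character$min_steps))
  }
})

test_that("bootstrap gives high support for a clean clade and is order-invariant", {
  seqs <- c(a1 = "AAAAAAAAAAGT", a2 = "AAAAAAAAAATG", a3 = "AAAAAAAAAAGG",
            b1 = "CCCCCCCCCCGT", b2 = "CCCCCCCCCCTG", b3 = "CCCCCCCCCCGG")
  loc <- aligned_locus(seqs, "x")
  bt <- bootstrap_support(loc, n_reps = 50, seed = 4,
                          n_random_addition = 3)
  sup <- attr(bt, "supports")
  expect_gte(max(sup$support), 90)
  # same seed, reordered strains: identical support for the clean split
  loc2 <- aligned_locus(seqs[c(4, 2, 6, 1, 3, 5)], "x")
  bt2 <- bootstrap_support(loc2, n_reps = 50, seed = 4,
                           n_random_addition = 3)
  expect_equal(max(attr(bt2, "supports")$support), max(sup$support))
})

test_that("bootstrap on an invariant alignment reports no support values", {
  loc <- aligned_locus(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT",
                         e = "ACGT"), "x")
  bt <- bootstrap_support(loc, n_reps = 5, seed = 1, n_random_addition = 2)
  expect_true(all(is.na(attr(bt, "supports")$support)))
})

test_that("search and bootstrap are deterministic given the seed", {
  withr::local_seed(99)
  seqs <- random_alignment(6, 15)
  loc <- aligned_locus(seqs, "x")
  r1 <- mp_search(loc, n_random_addition = 4, seed = 7)
  r2 <- mp_search(loc, n_random_addition = 4, seed = 7)
  expect_identical(lapply(r1$trees, ape::write.tree),
                   lapply(r2$trees, ape::write.tree))
  b1 <- bootstrap_support(loc, n_reps = 10, seed = 7, n_random_addition = 2)
  b2 <- bootstrap_support(loc, n_reps = 10, seed = 7, n_random_addition = 2)
  expect_identical(attr(b1, "supports"), attr(b2, "supports"))
})
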