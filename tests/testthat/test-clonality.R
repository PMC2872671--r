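mlg_tbl <- function(...) {
  # build a tidy genotype table from per-strain strings "A/a,B/b"
  rows <- list(...)
  purrr::imap(rows, function(genos, strain) {
    loci <- strsplit(genos, ",")[[1]]
    purrr::imap(loci, function(pair, i) {
      al <- strsplit(pair, "/")[[1]]
      tibble::tibble(strain_id = strain, locus = sprintf("locus%d", i),
                     allele_a = min(al), allele_b = max(al))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

test_that("allele-sharing distances follow the 0 / 0.5 / 1 convention", {
  d0 <- pairwise_distance(list(L1 = c("A", "A"), L2 = c("B", "B")),
                          list(L1 = c("A", "A"), L2 = c("B", "B")))
  expect_equal(d0$total, 0)
  d1 <- pairwise_distance(list(L1 = c("A", "a")), list(L1 = c("A", "A")))
  expect_equal(unname(d1$per_locus), 0.5)
  d2 <- pairwise_distance(list(L1 = c("A", "a"), L2 = c("B", "b")),
                          list(L1 = c("c", "d"), L2 = c("e", "f")))
  expect_equal(d2$total, 2)
  expect_error(pairwise_distance(list(L1 = c("A", "A")),
                                 list(L2 = c("A", "A"))),
               class = "mycopop_locus_mismatch")
})

test_that("a single informative locus gives I_A = 0 exactly", {
  df <- mlg_tbl(s1 = "A/A,z/z", s2 = "A/a,z/z", s3 = "a/a,z/z",
                s4 = "A/a,z/z", s5 = "A/A,z/z")
  expect_warning(res <- index_of_association(df, n_permutations = 19,
                                             seed = 1),
                 "monomorphic")
  expect_identical(res$ia, 0)
  expect_equal(res$loci_excluded, "locus2")
})

test_that("a duplicated locus gives I_A = 1 exactly", {
  withr::local_seed(17)
  df1 <- simulate_mlg(n_strains = 10, n_loci = 1, n_alleles = 4,
                      mode = "sexual", seed = 8)
  df2 <- dplyr::mutate(df1, locus = "locus2")
  res <- index_of_association(dplyr::bind_rows(df1, df2),
                              n_permutations = 19, seed = 1)
  expect_equal(res$ia, 1, tolerance = 1e-12)
})

test_that("all-monomorphic input errors and I_A needs four strains", {
  df <- mlg_tbl(s1 = "A/A,B/B", s2 = "A/A,B/B", s3 = "A/A,B/B",
                s4 = "A/A,B/B")
  expect_error(suppressWarnings(index_of_association(df)), "monomorphic")
  small <- mlg_tbl(s1 = "A/a,B/b", s2 = "a/a,B/B", s3 = "A/A,b/b")
  expect_error(index_of_association(small), "at least 4")
})

test_that("exhaustive permutation p at n = 5 matches brute-force enumeration", {
  df <- mlg_tbl(s1 = "A/A,B/B", s2 = "A/a,B/b", s3 = "a/a,b/b",
                s4 = "A/a,B/B", s5 = "a/a,B/b")
  res <- index_of_association(df, exhaustive = TRUE)
  mm <- list(
    a1 = cbind(c("A", "A", "a", "A", "a"), c("B", "B", "b", "B", "B")),
    a2 = cbind(c("A", "a", "a", "a", "a"), c("B", "b", "b", "B", "b"))
  )
  a1 <- mm$a1; a2 <- mm$a2
  obs <- naive_ia(a1, a2)
  expect_equal(res$ia, obs, tolerance = 1e-12)
  # enumerate every relabelling of locus-2 genotypes among the strains
  null <- vapply(perms_of(5), function(s) {
    naive_ia(cbind(a1[, 1], a1[s, 2]), cbind(a2[, 1], a2[s, 2]))
  }, numeric(1))
  expect_equal(res$p, mean(null >= obs - 1e-12), tolerance = 1e-12)
  expect_equal(sort(res$null), sort(null), tolerance = 1e-12)
})

test_that("I_A is invariant under allele relabelling and strain reordering", {
  df <- simulate_mlg(n_strains = 12, n_loci = 3, n_alleles = 4,
                     mode = "sexual", seed = 5)
  base <- index_of_association(df, n_permutations = 19, seed = 2)
  relab <- dplyr::mutate(
    df,
    allele_a = ifelse(.data$locus == "locus1",
                      paste0("x", .data$allele_a), .data$allele_a),
    allele_b = ifelse(.data$locus == "locus1",
                      paste0("x", .data$allele_b), .data$allele_b)
  )
  expect_equal(index_of_association(relab, n_permutations = 19,
                                    seed = 2)$ia, base$ia)
  shuf <- df[order(rev(seq_len(nrow(df)))), ]
  expect_equal(index_of_association(shuf, n_permutations = 19,
                                    seed = 2)$ia, base$ia)
})

test_that("the permutation null is centred near zero", {
  df <- simulate_mlg(n_strains = 20, n_loci = 2, n_alleles = 5,
                     mode = "sexual", seed = 9)
  res <- index_of_association(df, n_permutations = 499, seed = 3)
  se <- stats::sd(res$null) / sqrt(length(res$null))
  expect_lt(abs(mean(res$null)), 3 * se + 1e-3)
})

test_that("phylogenetic compatibility flags a fully crossed homozygous quartet", {
  df <- mlg_tbl(s1 = "A/A,B/B", s2 = "A/A,b/b", s3 = "a/a,B/B",
                s4 = "a/a,b/b")
  rep <- phylogenetic_compatibility(df, "locus1", "locus2")
  expect_equal(nrow(rep$quartets), 1)
  expect_match(rep$quartets$witnesses, "s1")
  # only two combinations observed: no flag
  df2 <- mlg_tbl(s1 = "A/A,B/B", s2 = "a/a,b/b")
  expect_equal(nrow(phylogenetic_compatibility(df2, "locus1",
                                               "locus2")$quartets), 0)
})

test_that("double heterozygotes only evidence combinations fixed under both pairings", {
  # a single A/a x B/b strain evidences nothing
  df <- mlg_tbl(s1 = "A/a,B/b")
  rep <- phylogenetic_compatibility(df, "locus1", "locus2")
  expect_equal(nrow(rep$evidence), 0)
})

test_that("recombining panels get flagged and clonal panels do not", {
  sexual <- simulate_mlg(n_strains = 50, n_loci = 2, n_alleles = 3,
                         mode = "sexual", seed = 11)
  rep_s <- phylogenetic_compatibility(sexual, "locus1", "locus2")
  expect_gt(nrow(rep_s$quartets), 0)
  clonal <- simulate_mlg(n_strains = 50, n_loci = 2, n_alleles = 5,
                         mode = "clonal", n_founders = 4,
                         mutation_rate = 0, seed = 11)
  rep_c <- phylogenetic_compatibility(clonal, "locus1", "locus2")
  expect_equal(nrow(rep_c$quartets), 0)
})
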