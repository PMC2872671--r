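test_that("identical configs reproduce identical datasets byte for byte", {
  cfg <- sim_config(seed = 42)
  s1 <- simulate_population(simulate_lineage_pool(cfg), cfg)
  s2 <- simulate_population(simulate_lineage_pool(cfg), cfg)
  expect_identical(lapply(s1$loci, function(l) l$matrix),
                   lapply(s2$loci, function(l) l$matrix))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_population(simulate_lineage_pool(sim_config(seed = 43)),
                            sim_config(seed = 43))
  expect_false(identical(s1$loci$ITS$matrix, s3$loci$ITS$matrix))
})

test_that("the default configuration plants the study-scale divergence", {
  pools <- simulate_lineage_pool(sim_config(seed = 1))
  its <- dplyr::filter(pools$expected_fixed, locus == "ITS")
  expect_equal(its$n_fixed, c(21L, 47L, 37L))
  # indel tracks appear as planted: 3 bp and 18 bp
  cfg <- sim_config(seed = 1)
  sim <- simulate_population(pools, cfg)
  cls <- classify_sites(sim$loci$ITS)
  expect_true(all(c(3L, 18L) %in% cls$indel_tracks$length))
})

test_that("invalid configurations fail loudly", {
  expect_error(sim_config(), "mandatory")
  # single lineage cannot carry fixed differences
  cfg1 <- sim_config(
    seed = 1,
    lineages = tibble::tibble(lineage = "L1", population = "A",
                              n_strains = 4L),
    loci = list(sim_locus("x", 50, fixed_diff = 3))
  )
  expect_error(simulate_lineage_pool(cfg1), class = "mycopop_config_error")
  # site budget overflow
  cfg2 <- sim_config(
    seed = 1,
    lineages = tibble::tibble(lineage = c("L1", "L2"),
                              population = c("A", "B"),
                              n_strains = c(3L, 3L)),
    loci = list(sim_locus("x", 10, fixed_diff = 40))
  )
  expect_error(simulate_lineage_pool(cfg2), class = "mycopop_config_error")
  # pairwise targets with no star decomposition
  cfg3 <- sim_config(
    seed = 1,
    loci = list(sim_locus("x", 100, fixed_diff = c(0, 0, 7)))
  )
  expect_error(simulate_lineage_pool(cfg3), class = "mycopop_config_error")
})

test_that("sexual mode heterozygosity follows random union of gametes", {
  # one lineage, one locus, one polymorphic site with a half-frequency
  # derived allele would give expected heterozygote fraction 2pq; with a
  # pool split between two haplotypes p depends on the planted subset, so
  # measure p from the pool and compare the binomial count
  cfg <- sim_config(
    seed = 19,
    lineages = tibble::tibble(lineage = "L1", population = "A",
                              n_strains = 200L),
    loci = list(sim_locus("x", 30, fixed_diff = 0, n_within = 1)),
    pool_size = 2
  )
  pools <- simulate_lineage_pool(cfg)
  sim <- simulate_population(pools, cfg)
  site <- pools$loci[[1]]$within_sites$L1
  # pool of 2 haplotypes differing at `site`: p = 1/2, expected het 1/2
  col <- sim$loci$x$matrix[, site]
  het <- mean(col %in% c("R", "Y", "M", "K", "W", "S"))
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 200))
})

test_that("clonal mode with zero mutation copies founders exactly", {
  cfg <- sim_config(
    seed = 23,
    lineages = tibble::tibble(lineage = "L1", population = "A",
                              n_strains = 12L),
    loci = list(sim_locus("x", 40, fixed_diff = 0, n_within = 3)),
    mode = "clonal", mutation_rate = 0, n_founders = 2
  )
  sim <- simulate_population(simulate_lineage_pool(cfg), cfg)
  seqs <- apply(sim$loci$x$matrix, 1, paste, collapse = "")
  by_founder <- split(seqs, sim$truth$strains$founder)
  for (grp in by_founder) expect_equal(length(unique(grp)), 1)
  expect_lte(length(unique(seqs)), 2)
})

test_that("genotyping on mutation-free data recovers the planted pairs", {
  cfg <- sim_config(
    seed = 29,
    lineages = tibble::tibble(lineage = "L1", population = "A",
                              n_strains = 15L),
    loci = list(sim_locus("x", 60, fixed_diff = 0, n_within = 2)),
    pool_size = 3
  )
  sim <- simulate_population(simulate_lineage_pool(cfg), cfg)
  # each strain's emitted IUPAC sequence must re-encode its true pair
  truth <- sim$truth$haplotypes
  composites <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    h1 <- strsplit(truth$hap_a[i], "")[[1]]
    h2 <- strsplit(truth$hap_b[i], "")[[1]]
    want <- mycopop:::encode_pair_vec(pmin(h1, h2), pmax(h1, h2))
    expect_equal(unname(sim$loci$x$matrix[truth$strain_id[i], ]), want)
    composites[i] <- paste(want, collapse = "")
  }
  # and the genotype table has exactly the truth-derived composite types
  gt <- collapse_genotypes(sim$loci$x, sim$partition)
  expect_setequal(gt$genotype_seqs, unique(composites))
})

test_that("written datasets are complete and reloadable", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(
    seed = 31,
    lineages = tibble::tibble(lineage = c("L1", "L2"),
                              population = c("A", "B"),
                              n_strains = c(4L, 4L)),
    loci = list(sim_locus("x", 50, fixed_diff = 5, n_within = 1))
  )
  sim <- simulate_population(simulate_lineage_pool(cfg), cfg)
  write_sim_dataset(sim, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_fasta_alignment(file.path(dir, "x.fasta"), "x")
  expect_identical(back$matrix, sim$loci$x$matrix)
  part <- readr::read_tsv(file.path(dir, "partition.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(part), 8)
})
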