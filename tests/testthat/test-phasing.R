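test_that("snpify keeps biallelic substitution sites and expands heterozygotes", {
  loc <- aligned_locus(c(
    s1 = "AC-GYA",
    s2 = "AC-GTA",
    s3 = "ACTGTA"
  ), "toy")
  g <- snpify(loc)
  # column 3 is an indel column, column 5 the only substitution site
  expect_equal(g$positions, 5L)
  expect_equal(unname(g$allele1["s1", 1]), "C")
  expect_equal(unname(g$allele2["s1", 1]), "T")
  expect_equal(unname(g$allele1["s2", 1]), "T")
  expect_equal(unname(g$allele2["s2", 1]), "T")
})

test_that("triallelic sites are rejected with position and states", {
  loc <- aligned_locus(c(s1 = "AA", s2 = "GA", s3 = "TA"), "toy")
  expect_error(snpify(loc), class = "mycopop_triallelic_error")
  expect_error(snpify(loc), "A/G/T")
})

test_that("homozygous and single-heterozygote strains phase with certainty", {
  loc <- aligned_locus(c(
    s1 = "AATT",
    s2 = "AATT",
    s3 = "ARTT"
  ), "toy")
  ph <- em_phase(snpify(loc), seed = 1)
  hom <- dplyr::filter(ph$phases, strain_id == "s1")
  expect_equal(hom$hap_a, hom$hap_b)
  expect_equal(hom$posterior, 1)
  het <- dplyr::filter(ph$phases, strain_id == "s3")
  expect_equal(sort(c(het$hap_a, het$hap_b)), c("A", "G"))
  expect_equal(het$posterior, 1)
})

test_that("a double heterozygote is resolved towards the common haplotypes", {
  # four homozygous strains anchor AB and ab; the fifth is A/a x B/b
  loc <- aligned_locus(c(
    s1 = "AA", s2 = "AA",   # haplotype AB/AB (alleles A and A at the 2 sites)
    s3 = "GG", s4 = "GG",   # haplotype ab/ab
    s5 = "RR"
  ), "toy")
  ph <- em_phase(snpify(loc), seed = 1)
  s5 <- dplyr::filter(ph$phases, strain_id == "s5")
  expect_equal(sort(c(s5$hap_a, s5$hap_b)), c("AA", "GG"))
  expect_gt(s5$posterior, 0.5)
  expect_false(s5$tied)
  # independent oracle: maximise the 2-resolution likelihood numerically
  # over haplotype frequencies (softmax parametrisation) and compare the
  # implied posterior for the AB/ab resolution
  loglik <- function(theta) {
    f <- exp(c(theta, 0)) / sum(exp(c(theta, 0)))  # AB, ab, Ab, aB
    ll <- 4 * log(f[1]^2) / 2 + 4 * log(f[2]^2) / 2  # two strains each
    ll + log(2 * f[1] * f[2] + 2 * f[3] * f[4])
  }
  opt <- stats::optim(c(0, 0, 0), function(th) -loglik(th),
                      method = "BFGS")
  f <- exp(c(opt$par, 0)) / sum(exp(c(opt$par, 0)))
  post_ABab <- 2 * f[1] * f[2] / (2 * f[1] * f[2] + 2 * f[3] * f[4])
  expect_equal(s5$posterior, post_ABab, tolerance = 1e-3)
})

test_that("exactly tied resolutions are flagged with posterior one half", {
  # a single double-heterozygous strain: both resolutions symmetric
  loc <- aligned_locus(c(s1 = "RR", s2 = "RR", s3 = "RR"), "toy")
  ph <- em_phase(snpify(loc), seed = 1)
  expect_true(all(ph$phases$tied))
  expect_true(all(ph$phases$posterior == 0.5))
})

test_that("EM invariants hold: consistency, frequency sum, monotone likelihood", {
  withr::local_seed(31)
  for (i in 1:5) {
    pan <- simulate_dikaryon_panel(n_strains = 20, n_haplotypes = 4,
                                   n_sites = 5, seed = i)
    ph <- em_phase(pan$genotypes, seed = i)
    expect_equal(sum(ph$haplotypes$frequency), 1, tolerance = 1e-9)
    expect_true(all(diff(ph$loglik) >= -1e-9))
    # every reported pair reproduces the diploid genotype site by site
    for (j in seq_len(nrow(ph$phases))) {
      g1 <- strsplit(ph$phases$hap_a[j], "")[[1]]
      g2 <- strsplit(ph$phases$hap_b[j], "")[[1]]
      expect_equal(pmin(g1, g2),
                   unname(pan$genotypes$allele1[ph$phases$strain_id[j], ]))
      expect_equal(pmax(g1, g2),
                   unname(pan$genotypes$allele2[ph$phases$strain_id[j], ]))
    }
  }
})

test_that("the haplotype catalogue lists carriers with a/b labels", {
  loc <- aligned_locus(c(s1 = "AA", s2 = "AA", s3 = "AA"), "toy")
  ph <- em_phase(snpify(loc, strains = c("s1", "s2")), seed = 1)
  # degenerate: no variable site among the subset -> zero-length haplotypes
  expect_equal(nrow(ph$phases), 2)

  loc2 <- aligned_locus(c(s1 = "AT", s2 = "GC"), "toy")
  ph2 <- em_phase(snpify(loc2), seed = 1)
  cat2 <- haplotype_catalogue(ph2)
  expect_equal(nrow(cat2), 2)
  expect_equal(cat2$frequency, c(0.5, 0.5))
  expect_true(all(grepl("a|b", cat2$carriers)))
})

test_that("a simulated panel from four known haplotypes is fully recovered", {
  pan <- simulate_dikaryon_panel(n_strains = 30, n_haplotypes = 4,
                                 n_sites = 6, seed = 3)
  ph <- em_phase(pan$genotypes, seed = 3)
  cat4 <- haplotype_catalogue(ph)
  seen <- cat4$haplotype[!is.na(cat4$n_carriers)]
  expect_setequal(seen, pan$truth |>
                    tidyr::pivot_longer(c(hap_a, hap_b)) |>
                    dplyr::pull(value) |> unique())
})

test_that("an ITS-like locus name attaches the paralogy caveat", {
  loc <- aligned_locus(c(s1 = "AY", s2 = "AT", s3 = "AC"), "ITS")
  ph <- em_phase(snpify(loc), seed = 1)
  expect_match(ph$metadata$notes, "paralog", all = FALSE)
})
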