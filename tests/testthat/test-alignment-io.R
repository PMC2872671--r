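test_that("FASTA round-trip preserves the alignment exactly", {
  seqs <- c(s1 = "ACGTACGTAY", s2 = "ACG-ACGTAT", s3 = "ACGTACGWAT")
  loc <- aligned_locus(seqs, "toy")
  expect_equal(loc$n_sites, 10)
  expect_equal(loc$strain_ids, c("s1", "s2", "s3"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(loc, path)
  back <- read_fasta_alignment(path, "toy")
  expect_identical(back$matrix, loc$matrix)
  expect_identical(back$strain_ids, loc$strain_ids)
})

test_that("validation rejects ragged, illegal and dotted-gap input", {
  expect_error(aligned_locus(c(a = "ACGTACGTAC", b = "ACGTACGTA"), "x"),
               class = "mycopop_alignment_error")
  expect_error(aligned_locus(c(a = "ACGN", b = "ACGT"), "x"),
               class = "mycopop_parse_error")
  expect_error(aligned_locus(c(a = "AC.T", b = "ACGT"), "x"),
               class = "mycopop_parse_error")
  expect_error(aligned_locus(c(a = "ACGT", a = "ACGT"), "x"))
})

test_that("ambiguity codes are accepted, stored upper-case, and decoded", {
  loc <- aligned_locus(c(a = "acyt", b = "ACTT"), "x")
  expect_identical(unname(loc$matrix["a", 3]), "Y")
  expect_equal(decode_ambiguity("Y"), c("C", "T"))
  expect_equal(decode_ambiguity("R"), c("A", "G"))
  expect_equal(decode_ambiguity("M"), c("A", "C"))
  expect_equal(decode_ambiguity("K"), c("G", "T"))
  expect_equal(decode_ambiguity("A"), c("A", "A"))
  expect_error(decode_ambiguity("N"), class = "mycopop_unsupported_code")
  expect_error(decode_ambiguity("B"), class = "mycopop_unsupported_code")
})

test_that("encode and decode are mutually inverse on the six two-base codes", {
  for (code in c("R", "Y", "M", "K", "W", "S")) {
    pair <- decode_ambiguity(code)
    expect_identical(encode_ambiguity(pair[1], pair[2]), code)
    expect_identical(encode_ambiguity(pair[2], pair[1]), code)
  }
})

test_that("site classification matches the hand-scanned toy alignment", {
  # col 1 identical; col 2 A-vs-T substitution; cols 3-4 gapped in one
  # strain (one two-column track); cols 5-6 invariant
  loc <- aligned_locus(c(
    a = "AAGGCC",
    b = "AT--CC",
    c = "AAGGCC"
  ), "toy")
  cls <- classify_sites(loc)
  expect_equal(cls$n_variable, 3)
  expect_equal(cls$n_substitution, 1)
  expect_equal(cls$n_indel_sites, 2)
  expect_equal(cls$n_indel_tracks, 1)
  expect_equal(cls$indel_tracks$start, 3L)
  expect_equal(cls$indel_tracks$end, 4L)
})

test_that("heterozygous codes are expanded before judging variability", {
  loc <- aligned_locus(c(a = "AA", b = "RA", c = "AA"), "x")
  cls <- classify_sites(loc)
  expect_equal(cls$sites$class, c("substitution", "invariant"))
})

test_that("identical rows give zero variable sites", {
  loc <- aligned_locus(c(a = "ACGT", b = "ACGT"), "x")
  expect_equal(classify_sites(loc)$n_variable, 0)
})

test_that("classification counts and track structure hold on fuzzed alignments", {
  withr::local_seed(42)
  for (i in 1:30) {
    seqs <- random_alignment(sample(3:8, 1), sample(10:40, 1))
    cls <- classify_sites(aligned_locus(seqs, "fuzz"))
    expect_equal(cls$n_variable, cls$n_substitution + cls$n_indel_sites)
    # tracks are disjoint, maximal and cover exactly the indel columns
    covered <- as.integer(unlist(purrr::map2(cls$indel_tracks$start,
                                             cls$indel_tracks$end, seq)))
    expect_equal(sort(covered),
                 cls$sites$position[cls$sites$class == "indel"])
    expect_false(any(duplicated(covered)))
    if (nrow(cls$indel_tracks) > 1) {
      gaps <- cls$indel_tracks$start[-1] -
        cls$indel_tracks$end[-nrow(cls$indel_tracks)]
      expect_true(all(gaps > 1))  # maximality: adjacent tracks would merge
    }
  }
})
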