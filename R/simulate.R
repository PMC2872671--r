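# Seeded synthetic-data generator.
#
# Emulates the statistical structure the pipeline assumes: a few deeply
# divergent lineages separated by planted fixed differences and indel
# tracks, within-lineage polymorphism carried by small haplotype pools,
# invariant loci, and dikaryotic strains formed either by random union of
# two haplotypes (sexual mode, free recombination between loci) or by
# copying a small founder set with rare mutation (clonal mode).
# Everything is deterministic given the configuration seed.

#' Locus specification for the simulator
#'
#' @param name Locus name.
#' @param length Aligned length in sites; must exceed the total number of
#'   planted sites.
#' @param fixed_diff Pairwise fixed *substitution* differences between
#'   lineages: a single count for two lineages, or a length-3 vector
#'   `c(d12, d13, d23)` for three.  Indel tracks add their length on top
#'   of these counts for every lineage pair whose gap status differs.
#' @param n_within Named (or recycled) vector of within-lineage
#'   segregating substitution sites per lineage.
#' @param indel_tracks `NULL` or a data frame with columns `start`,
#'   `length` and `gapped` (list column: lineage labels carrying the
#'   deletion).
#' @return A locus spec list.
#' @export
sim_locus <- function(name, length, fixed_diff = 0, n_within = 0,
                      indel_tracks = NULL) {
  list(name = name, length = as.integer(length), fixed_diff = fixed_diff,
       n_within = n_within, indel_tracks = indel_tracks)
}

#' Simulation configuration
#'
#' Defaults mirror the scale of a multilocus study of a dikaryotic
#' mushroom species complex: 3 divergent lineages with 11 strains each,
#' an ITS-like locus (683 sites) whose planted pairwise divergence --
#' substitutions plus a 3 bp poly-T indel absent from lineages L1/L3 and
#' an 18 bp deletion private to L3 -- totals 21/47/37 fixed differences
#' for the three lineage pairs, an RPB2-like locus (422 sites) with
#' within-lineage polymorphism confined to L1, and two conserved rRNA
#' loci that never vary within lineages.
#'
#' @param seed Integer seed (mandatory; every downstream draw derives
#'   from it).
#' @param lineages Tibble with columns `lineage`, `population`,
#'   `n_strains`.
#' @param loci List of [sim_locus()] specs.
#' @param mode `"sexual"` (random union of two pool haplotypes per locus,
#'   independent across loci) or `"clonal"` (strains copied from a small
#'   founder set with per-site mutation).
#' @param mutation_rate Per-site, per-allele substitution probability in
#'   clonal mode (indels are planted, never mutated).
#' @param n_founders Founder dikaryons per lineage in clonal mode.
#' @param pool_size Haplotypes per lineage pool.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       lineages = tibble(
                         lineage = c("L1", "L2", "L3"),
                         population = c("AL", "ML", "DDG"),
                         n_strains = c(11L, 11L, 11L)
                       ),
                       loci = list(
                         sim_locus("ITS", 683, fixed_diff = c(18, 29, 16),
                                   n_within = c(L1 = 6, L2 = 2, L3 = 1),
                                   indel_tracks = tibble(
                                     start = c(520L, 600L),
                                     length = c(3L, 18L),
                                     gapped = list(c("L1", "L3"), "L3")
                                   )),
                         sim_locus("RPB2", 422, fixed_diff = c(5, 8, 7),
                                   n_within = c(L1 = 6, L2 = 0, L3 = 0)),
                         sim_locus("nucLSU", 902, fixed_diff = c(2, 3, 3)),
                         sim_locus("mtSSU", 429, fixed_diff = c(1, 2, 1))
                       ),
                       mode = c("sexual", "clonal"),
                       mutation_rate = 0,
                       n_founders = 3,
                       pool_size = 6) {
  if (missing(seed)) abort("`seed` is mandatory in a simulation config.")
  assert_scalar_count(seed, "seed", min = 0)
  mode <- match.arg(mode)
  lineages <- as_tibble(lineages)
  stopifnot(all(c("lineage", "population", "n_strains") %in% names(lineages)))
  k <- length(unique(lineages$lineage))
  if (k > 3) abort("At most 3 lineages are supported for pairwise planting.")
  structure(
    list(seed = as.integer(seed), lineages = lineages, loci = loci,
         mode = mode, mutation_rate = mutation_rate,
         n_founders = as.integer(n_founders),
         pool_size = as.integer(pool_size)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d lineage(s), %d strains, %d loci, mode %s, seed %d\n",
              length(unique(x$lineages$lineage)), sum(x$lineages$n_strains),
              length(x$loci), x$mode, x$seed))
  invisible(x)
}

# decompose pairwise fixed-substitution targets into per-lineage derived
# site counts plus (for 3 lineages) tri-state sites; star decomposition
# d_ij = x_i + x_j + x0
solve_fixed_plan <- function(fixed_diff, lineage_names) {
  k <- length(lineage_names)
  if (k == 1) {
    if (any(fixed_diff > 0)) {
      abort("Fixed differences are impossible with a single lineage.",
            class = "mycopop_config_error")
    }
    return(list(per_lineage = setNames(0L, lineage_names), n_tristate = 0L))
  }
  if (k == 2) {
    d <- fixed_diff[1]
    return(list(per_lineage = setNames(c(0L, as.integer(d)), lineage_names),
                n_tristate = 0L))
  }
  d <- fixed_diff
  if (length(d) != 3) {
    abort("For 3 lineages `fixed_diff` must be c(d12, d13, d23).",
          class = "mycopop_config_error")
  }
  for (x0 in 0:min(d)) {
    x1 <- (d[1] + d[2] - d[3] - x0) / 2
    x2 <- (d[1] + d[3] - d[2] - x0) / 2
    x3 <- (d[2] + d[3] - d[1] - x0) / 2
    x <- c(x1, x2, x3)
    if (all(x == round(x)) && all(x >= 0)) {
      return(list(per_lineage = setNames(as.integer(x), lineage_names),
                  n_tristate = as.integer(x0)))
    }
  }
  abort(sprintf(
    "Pairwise fixed differences c(%s) have no non-negative star decomposition.",
    paste(d, collapse = ", ")
  ), class = "mycopop_config_error")
}

other_base <- function(base) {
  vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
         character(1))
}

#' Build per-lineage, per-locus haplotype pools
#'
#' Draws an ancestral sequence per locus, plants the configured fixed
#' differences at disjoint random sites (lineage-private derived states,
#' plus three-state sites when the pairwise targets require them), adds
#' within-lineage polymorphism as derived alleles carried by a random
#' proper subset of each lineage's haplotype pool, and applies the indel
#' tracks.  Raises a config error when the planted sites do not fit in
#' the locus.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `lineage_pools` with per-locus pools and a
#'   construction-derived `expected_fixed` tibble (`locus`, `lineage1`,
#'   `lineage2`, `n_fixed`) giving the fixed-difference count each
#'   lineage pair must show, substitutions plus differing indel columns.
#' @export
simulate_lineage_pool <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lineage_names <- unique(cfg$lineages$lineage)
  k <- length(lineage_names)
  withr::with_seed(derive_seed(cfg$seed, "pools"), {
    loci <- lapply(cfg$loci, function(spec) {
      plan <- solve_fixed_plan(spec$fixed_diff, lineage_names)
      n_within <- rep(spec$n_within, length.out = k)
      if (!is.null(names(spec$n_within))) {
        n_within <- spec$n_within[lineage_names]
        n_within[is.na(n_within)] <- 0
      }
      n_within <- setNames(as.integer(n_within), lineage_names)
      tracks <- spec$indel_tracks
      gap_sites <- integer(0)
      if (!is.null(tracks)) {
        tracks <- as_tibble(tracks)
        for (i in seq_len(nrow(tracks))) {
          rng <- tracks$start[i]:(tracks$start[i] + tracks$length[i] - 1L)
          if (max(rng) > spec$length) {
            abort(sprintf("Indel track exceeds locus '%s' length.", spec$name),
                  class = "mycopop_config_error")
          }
          if (any(rng %in% gap_sites)) {
            abort(sprintf("Overlapping indel tracks in locus '%s'.", spec$name),
                  class = "mycopop_config_error")
          }
          bad <- setdiff(unlist(tracks$gapped[i]), lineage_names)
          if (length(bad) > 0) {
            abort(sprintf("Unknown lineage(s) in indel track: %s.",
                          paste(bad, collapse = ", ")),
                  class = "mycopop_config_error")
          }
          gap_sites <- c(gap_sites, rng)
        }
      }
      n_needed <- sum(plan$per_lineage) + plan$n_tristate + sum(n_within)
      avail <- setdiff(seq_len(spec$length), gap_sites)
      if (n_needed > length(avail)) {
        abort(sprintf(
          "Locus '%s' site budget overflow: %d planted sites, %d available.",
          spec$name, n_needed, length(avail)
        ), class = "mycopop_config_error")
      }
      anc <- sample(c("A", "C", "G", "T"), spec$length, replace = TRUE)
      sites <- sample(avail, n_needed)
      cursor <- 0L
      take <- function(n) {
        out <- sites[cursor + seq_len(n)]
        cursor <<- cursor + n
        out
      }
      base_seqs <- setNames(rep(list(anc), k), lineage_names)
      fixed_sites <- list()
      for (ln in lineage_names) {
        s <- take(plan$per_lineage[[ln]])
        fixed_sites[[ln]] <- s
        if (length(s) > 0) base_seqs[[ln]][s] <- other_base(anc[s])
      }
      tri_sites <- take(plan$n_tristate)
      for (s in tri_sites) {
        states <- sample(c("A", "C", "G", "T"), k)
        for (i in seq_len(k)) base_seqs[[lineage_names[i]]][s] <- states[i]
      }
      if (!is.null(tracks)) {
        for (i in seq_len(nrow(tracks))) {
          rng <- tracks$start[i]:(tracks$start[i] + tracks$length[i] - 1L)
          for (ln in unlist(tracks$gapped[i])) {
            base_seqs[[ln]][rng] <- "-"
          }
        }
      }
      pools <- list()
      within_sites <- list()
      for (ln in lineage_names) {
        pool <- matrix(rep(base_seqs[[ln]], cfg$pool_size),
                       nrow = cfg$pool_size, byrow = TRUE)
        s <- take(n_within[[ln]])
        within_sites[[ln]] <- s
        for (site in s) {
          derived <- other_base(base_seqs[[ln]][site])
          members <- sample(cfg$pool_size,
                            sample(max(1, cfg$pool_size - 1), 1))
          pool[members, site] <- derived
        }
        pools[[ln]] <- apply(pool, 1, paste0, collapse = "")
      }
      list(spec = spec, plan = plan, tracks = tracks, anc = anc,
           base_seqs = base_seqs, pools = pools,
           fixed_sites = fixed_sites, tri_sites = tri_sites,
           within_sites = within_sites)
    })
  })
  # construction-derived expected pairwise fixed differences
  expected <- list()
  if (k >= 2) {
    pairs <- utils::combn(sort(lineage_names), 2, simplify = FALSE)
    for (loc in loci) {
      for (p in pairs) {
        n_sub <- length(loc$fixed_sites[[p[1]]]) +
          length(loc$fixed_sites[[p[2]]]) + length(loc$tri_sites)
        n_indel <- 0L
        if (!is.null(loc$tracks)) {
          for (i in seq_len(nrow(loc$tracks))) {
            g <- unlist(loc$tracks$gapped[i])
            if (xor(p[1] %in% g, p[2] %in% g)) {
              n_indel <- n_indel + loc$tracks$length[i]
            }
          }
        }
        expected[[length(expected) + 1L]] <- tibble(
          locus = loc$spec$name, lineage1 = p[1], lineage2 = p[2],
          n_fixed = n_sub + n_indel
        )
      }
    }
  }
  structure(
    list(loci = loci, lineage_names = lineage_names, cfg = cfg,
         expected_fixed = if (length(expected)) bind_rows(expected) else
           tibble(locus = character(), lineage1 = character(),
                  lineage2 = character(), n_fixed = integer())),
    class = "lineage_pools"
  )
}

#' @export
print.lineage_pools <- function(x, ...) {
  cat(sprintf("<lineage_pools> %d lineage(s) x %d loci (pool size %d)\n",
              length(x$lineage_names), length(x$loci), x$cfg$pool_size))
  invisible(x)
}

#' Simulate a population of IUPAC-coded dikaryons from lineage pools
#'
#' Sexual mode: each strain unites two haplotypes drawn independently
#' (uniform over the pool) per locus, independently across loci -- free
#' recombination between unlinked loci.  Clonal mode: strains are copied
#' from a small founder set of dikaryons with per-site substitution
#' mutation on each allele (gap sites never mutate).  Heterozygous sites
#' are emitted as IUPAC codes; the generating truth (lineage, haplotype
#' pair per locus, founder pedigree) is recorded.
#'
#' @param pools A [simulate_lineage_pool()] result.
#' @param cfg The same [sim_config()].
#' @return An object of class `sim_dataset`: `loci` (named list of
#'   [aligned_locus()]), `partition` (tibble `strain_id`, `population`,
#'   `lineage`), `truth` (`strains` tibble with pedigree, `haplotypes`
#'   tibble with the true pair per strain and locus),
#'   `expected_fixed` (carried from the pools), `manifest`.
#' @export
simulate_population <- function(pools, cfg) {
  stopifnot(inherits(pools, "lineage_pools"), inherits(cfg, "sim_config"))
  rows <- cfg$lineages
  strain_tbl <- purrr::pmap(rows, function(lineage, population, n_strains) {
    tibble(
      strain_id = sprintf("%s_%s_%02d", lineage, population,
                          seq_len(n_strains)),
      population = population,
      lineage = lineage
    )
  }) |> bind_rows()
  n <- nrow(strain_tbl)
  truth_haps <- list()
  seq_mats <- lapply(pools$loci, function(loc) {
    matrix("", n, loc$spec$length,
           dimnames = list(strain_tbl$strain_id, NULL))
  })
  founders_of <- rep(NA_character_, n)
  withr::with_seed(derive_seed(cfg$seed, "population"), {
    if (cfg$mode == "clonal") {
      # founder dikaryons per lineage: pairs of pool haplotype indices
      founder_pairs <- list()
      for (ln in pools$lineage_names) {
        founder_pairs[[ln]] <- lapply(seq_len(cfg$n_founders), function(f) {
          lapply(pools$loci, function(loc) {
            sample(cfg$pool_size, 2, replace = TRUE)
          })
        })
      }
    }
    for (i in seq_len(n)) {
      ln <- strain_tbl$lineage[i]
      if (cfg$mode == "sexual") {
        hap_idx <- lapply(pools$loci, function(loc) {
          sample(cfg$pool_size, 2, replace = TRUE)
        })
      } else {
        f <- sample(cfg$n_founders, 1)
        founders_of[i] <- sprintf("%s_founder%d", ln, f)
        hap_idx <- founder_pairs[[ln]][[f]]
      }
      for (j in seq_along(pools$loci)) {
        loc <- pools$loci[[j]]
        h1 <- strsplit(loc$pools[[ln]][hap_idx[[j]][1]], "")[[1]]
        h2 <- strsplit(loc$pools[[ln]][hap_idx[[j]][2]], "")[[1]]
        if (cfg$mode == "clonal" && cfg$mutation_rate > 0) {
          for (h in c("h1", "h2")) {
            v <- get(h)
            hit <- runif(length(v)) < cfg$mutation_rate & v != "-"
            if (any(hit)) v[hit] <- other_base(v[hit])
            assign(h, v)
          }
        }
        seq_mats[[j]][i, ] <- encode_pair_vec(pmin(h1, h2), pmax(h1, h2))
        truth_haps[[length(truth_haps) + 1L]] <- tibble(
          strain_id = strain_tbl$strain_id[i],
          locus = loc$spec$name,
          hap_a = min(paste(h1, collapse = ""), paste(h2, collapse = "")),
          hap_b = max(paste(h1, collapse = ""), paste(h2, collapse = ""))
        )
      }
    }
  })
  loci <- lapply(seq_along(pools$loci), function(j) {
    new_aligned_locus(pools$loci[[j]]$spec$name, strain_tbl$strain_id,
                      seq_mats[[j]])
  })
  names(loci) <- vapply(pools$loci, function(l) l$spec$name, character(1))
  structure(
    list(
      loci = loci,
      partition = strain_tbl,
      truth = list(
        strains = mutate(strain_tbl, founder = founders_of),
        haplotypes = bind_rows(truth_haps)
      ),
      expected_fixed = pools$expected_fixed,
      manifest = list(seed = cfg$seed, mode = cfg$mode,
                      mutation_rate = cfg$mutation_rate,
                      n_strains = n,
                      loci = names(loci))
    ),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d strains, %d loci (%s mode, seed %d)\n",
              nrow(x$partition), length(x$loci), x$manifest$mode,
              x$manifest$seed))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits per-locus aligned FASTA, the partition TSV, the truth JSON and a
#' manifest JSON echoing all paths and the seed.
#'
#' @param sim A [simulate_population()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta_paths <- vapply(names(sim$loci), function(nm) {
    p <- file.path(dir, paste0(nm, ".fasta"))
    write_fasta_alignment(sim$loci[[nm]], p)
    p
  }, character(1))
  partition_path <- file.path(dir, "partition.tsv")
  readr::write_tsv(sim$partition, partition_path)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(strains = sim$truth$strains, haplotypes = sim$truth$haplotypes,
         expected_fixed = sim$expected_fixed),
    truth_path, dataframe = "rows", digits = NA
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    c(sim$manifest, list(fasta = unname(fasta_paths),
                         partition = partition_path, truth = truth_path)),
    manifest_path, auto_unbox = TRUE, digits = NA
  )
  invisible(manifest_path)
}

#' Simulate multilocus allele-pair genotypes directly
#'
#' Allele-level counterpart of [simulate_population()] for studying the
#' clonality tests: sexual mode draws each strain's two alleles per locus
#' independently (random union of gametes, free recombination); clonal
#' mode copies strains from a founder set that itself descends clonally
#' from a single ancestral dikaryon, with every mutation creating a
#' brand-new allele (infinite-alleles model), so strictly clonal panels
#' can never show a fully crossed allele quartet.
#'
#' @param n_strains,n_loci,n_alleles Panel dimensions.
#' @param mode `"sexual"` or `"clonal"`.
#' @param n_founders Founder genotypes in clonal mode.
#' @param mutation_rate Per-allele, per-locus mutation probability in
#'   clonal mode.
#' @param seed Integer seed.
#' @return A tidy tibble (`strain_id`, `locus`, `allele_a`, `allele_b`)
#'   with a `truth` attribute giving the founder of each strain (clonal
#'   mode).
#' @export
simulate_mlg <- function(n_strains = 30, n_loci = 2, n_alleles = 5,
                         mode = c("sexual", "clonal"), n_founders = 5,
                         mutation_rate = 0.01, seed = 1) {
  mode <- match.arg(mode)
  strains <- sprintf("S%02d", seq_len(n_strains))
  loci <- sprintf("locus%d", seq_len(n_loci))
  alleles <- sprintf("a%d", seq_len(n_alleles))
  withr::with_seed(derive_seed(seed, paste0("mlg_", mode)), {
    if (mode == "sexual") {
      rows <- tidyr::expand_grid(strain_id = strains, locus = loci)
      rows$allele_a <- sample(alleles, nrow(rows), replace = TRUE)
      rows$allele_b <- sample(alleles, nrow(rows), replace = TRUE)
      founder <- rep(NA_character_, n_strains)
    } else {
      # clonal genealogy of founders under infinite alleles: founder 1 is
      # a random dikaryon; each later founder copies an earlier one and
      # mutates one allele per locus to a brand-new allele, so loci are
      # polymorphic by construction and -- absent recombination -- no
      # allele quartet can ever be fully crossed
      mut_counter <- 0L
      new_allele <- function() {
        mut_counter <<- mut_counter + 1L
        sprintf("m%d", mut_counter)
      }
      fa <- matrix("", n_founders, n_loci)
      fb <- matrix("", n_founders, n_loci)
      fa[1, ] <- sample(alleles, n_loci, replace = TRUE)
      fb[1, ] <- sample(alleles, n_loci, replace = TRUE)
      for (f in seq_len(n_founders)[-1]) {
        parent <- sample(f - 1L, 1)
        fa[f, ] <- fa[parent, ]
        fb[f, ] <- fb[parent, ]
        for (l in seq_len(n_loci)) {
          if (runif(1) < 0.5) fa[f, l] <- new_allele() else
            fb[f, l] <- new_allele()
        }
      }
      pick <- sample(n_founders, n_strains, replace = TRUE)
      founder <- sprintf("founder%d", pick)
      a <- fa[pick, , drop = FALSE]
      b <- fb[pick, , drop = FALSE]
      mut <- function(x) {
        hit <- runif(length(x)) < mutation_rate
        x[hit] <- vapply(x[hit], function(al) new_allele(), character(1))
        x
      }
      a <- matrix(mut(as.vector(a)), n_strains, n_loci)
      b <- matrix(mut(as.vector(b)), n_strains, n_loci)
      rows <- tidyr::expand_grid(strain_id = strains, locus = loci)
      idx <- cbind(match(rows$strain_id, strains), match(rows$locus, loci))
      rows$allele_a <- a[idx]
      rows$allele_b <- b[idx]
    }
    lo <- pmin(rows$allele_a, rows$allele_b)
    hi <- pmax(rows$allele_a, rows$allele_b)
    rows$allele_a <- lo
    rows$allele_b <- hi
    attr(rows, "truth") <- tibble(strain_id = strains, founder = founder)
    rows
  })
}

#' Simulate a dikaryon SNP panel from a known haplotype pool
#'
#' Builds a pool of distinct haplotypes over biallelic sites (every site
#' polymorphic within the pool), draws pool frequencies from a symmetric
#' Dirichlet, and forms each strain by random union of two gametes.  Used
#' to measure phasing accuracy against known truth.
#'
#' @param n_strains,n_haplotypes,n_sites Panel dimensions
#'   (`n_haplotypes <= 2^n_sites`).
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration for pool frequencies.
#' @return A list: `genotypes` (a `diploid_genotypes` object), `truth`
#'   (tibble `strain_id`, `hap_a`, `hap_b`), `pool` (tibble `haplotype`,
#'   `frequency`).
#' @export
simulate_dikaryon_panel <- function(n_strains = 30, n_haplotypes = 4,
                                    n_sites = 6, seed = 1,
                                    concentration = 1.5) {
  if (n_haplotypes > 2^n_sites) {
    abort("More haplotypes requested than distinct site patterns exist.")
  }
  withr::with_seed(derive_seed(seed, "panel"), {
    site_alleles <- lapply(seq_len(n_sites), function(j) {
      sort(sample(c("A", "C", "G", "T"), 2))
    })
    for (try in 1:200) {
      pattern <- matrix(sample(1:2, n_haplotypes * n_sites, replace = TRUE),
                        n_haplotypes, n_sites)
      haps <- apply(pattern, 1, function(row) {
        paste(vapply(seq_len(n_sites),
                     function(j) site_alleles[[j]][row[j]], character(1)),
              collapse = "")
      })
      if (anyDuplicated(haps) == 0 &&
          all(apply(pattern, 2, function(col) length(unique(col)) == 2))) {
        break
      }
      haps <- NULL
    }
    if (is.null(haps)) {
      abort("Could not draw a pool with every site polymorphic.")
    }
    freq <- stats::rgamma(n_haplotypes, shape = concentration)
    freq <- freq / sum(freq)
    strains <- sprintf("D%02d", seq_len(n_strains))
    draw1 <- sample(haps, n_strains, replace = TRUE, prob = freq)
    draw2 <- sample(haps, n_strains, replace = TRUE, prob = freq)
    truth <- tibble(
      strain_id = strains,
      hap_a = pmin(draw1, draw2),
      hap_b = pmax(draw1, draw2)
    )
    split1 <- do.call(rbind, strsplit(truth$hap_a, ""))
    split2 <- do.call(rbind, strsplit(truth$hap_b, ""))
    geno <- structure(
      list(
        locus_name = "panel",
        strain_ids = strains,
        positions = seq_len(n_sites),
        allele1 = structure(pmin(split1, split2),
                            dimnames = list(strains, NULL)),
        allele2 = structure(pmax(split1, split2),
                            dimnames = list(strains, NULL)),
        site_alleles = site_alleles
      ),
      class = "diploid_genotypes"
    )
    list(genotypes = geno,
         truth = truth,
         pool = tibble(haplotype = haps, frequency = freq))
  })
}
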