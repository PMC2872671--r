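# End-to-end orchestration: genotype -> diversity -> divergence ->
# trees/concordance -> phasing -> clonality, with per-stage TSV/Newick/
# JSON outputs and a machine-readable manifest.  All randomness is
# funnelled through per-stage seeds recorded in the manifest, so
# rerunning with the same configuration reproduces byte-identical
# outputs.

#' Read a pipeline run configuration from YAML
#'
#' The file is a key-value document with the fields accepted by
#' [run_pipeline()]: `loci` (named map of locus name to FASTA path),
#' `partition` (TSV path with columns `strain_id`, `population`,
#' `lineage`), `out_dir`, `stages` (list of stage names to run), `seed`,
#' and optional per-stage parameters (`bootstrap_reps`,
#' `ild_reps`, `ia_permutations`, `n_random_addition`,
#' `constraint_permutations`, `phase_loci`, `lineage_constraint`).
#' Referenced files are checked for existence at validation time, before
#' any computation.
#'
#' @param path Path to a YAML config file.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file '%s' not found.", path))
  validate_run_config(yaml::read_yaml(path))
}

ALL_STAGES <- c("genotype", "diversity", "divergence", "tree",
                "concordance", "phase", "ia", "compat")

validate_run_config <- function(cfg) {
  if (is.null(cfg$loci) || length(cfg$loci) == 0 ||
      is.null(names(cfg$loci))) {
    abort("Config must name at least one locus FASTA under `loci`.")
  }
  for (nm in names(cfg$loci)) {
    if (!file.exists(cfg$loci[[nm]])) {
      abort(sprintf("Locus file for '%s' not found: %s.", nm, cfg$loci[[nm]]),
            class = "mycopop_config_error")
    }
  }
  if (is.null(cfg$partition) || !file.exists(cfg$partition)) {
    abort(sprintf("Partition file not found: %s.",
                  cfg$partition %||% "<missing>"),
          class = "mycopop_config_error")
  }
  if (is.null(cfg$seed)) abort("Config must set `seed`.")
  assert_scalar_count(cfg$seed, "seed", min = 0)
  cfg$stages <- cfg$stages %||% ALL_STAGES
  bad <- setdiff(cfg$stages, ALL_STAGES)
  if (length(bad) > 0) {
    abort(sprintf("Unknown stage(s): %s.", paste(bad, collapse = ", ")))
  }
  cfg$out_dir <- cfg$out_dir %||% "mycopop_out"
  cfg$bootstrap_reps <- cfg$bootstrap_reps %||% 100L
  cfg$ild_reps <- cfg$ild_reps %||% 99L
  cfg$ia_permutations <- cfg$ia_permutations %||% 999L
  cfg$n_random_addition <- cfg$n_random_addition %||% 10L
  cfg$constraint_permutations <- cfg$constraint_permutations %||% 99L
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on the configured loci and writes
#' each stage's outputs (TSV, Newick, JSON) under `out_dir`, plus a
#' `manifest.json` recording inputs, parameters, per-stage seeds, the
#' package version and any stage warnings.  Outputs are pure functions
#' of (inputs, parameters, seed).  A stage failure aborts with the stage
#' name and leaves a `FAILED` marker naming it; outputs of completed
#' stages are retained.
#'
#' @param cfg A `run_config` from [read_run_config()], or a list with the
#'   same fields.
#' @return The manifest (a list), invisibly; written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  loci <- purrr::imap(cfg$loci, function(path, nm) {
    read_fasta_alignment(path, locus_name = nm)
  })
  partition <- lineage_partition(readr::read_tsv(cfg$partition,
                                                 show_col_types = FALSE))
  notes <- character(0)
  outputs <- list()
  stage_seed <- function(stage) derive_seed(cfg$seed, paste0("stage_", stage))
  run_stage <- function(stage, fn) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    tryCatch(
      withCallingHandlers(fn(), warning = function(w) {
        notes <<- c(notes, sprintf("[%s] %s", stage, conditionMessage(w)))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
                   file.path(cfg$out_dir, "FAILED"))
        abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)),
              parent = e)
      }
    )
  }
  out_path <- function(...) file.path(cfg$out_dir, ...)
  genotype_tables <- NULL
  run_stage("genotype", function() {
    genotype_tables <<- purrr::imap(loci, function(l, nm) {
      gt <- collapse_genotypes(l, partition)
      readr::write_tsv(gt$assignments, out_path(paste0(nm, "_genotypes.tsv")))
      outputs[[paste0("genotypes_", nm)]] <<-
        out_path(paste0(nm, "_genotypes.tsv"))
      gt
    })
  })
  run_stage("diversity", function() {
    if (is.null(genotype_tables)) {
      genotype_tables <<- purrr::map(loci, collapse_genotypes,
                                     partition = partition)
    }
    div <- purrr::imap(genotype_tables, function(gt, nm) {
      mutate(diversity_report(gt), locus = nm, .before = 1)
    }) |> bind_rows()
    readr::write_tsv(div, out_path("diversity.tsv"))
    outputs$diversity <<- out_path("diversity.tsv")
  })
  run_stage("divergence", function() {
    if (length(unique(partition$lineage)) >= 2) {
      div <- purrr::map(loci, divergence_report, partition = partition) |>
        bind_rows()
      write_divergence_report(div, out_path("divergence.tsv"))
      outputs$divergence <<- out_path("divergence.tsv")
    } else {
      notes <<- c(notes, "[divergence] single lineage; stage skipped")
    }
  })
  run_stage("tree", function() {
    purrr::iwalk(loci, function(l, nm) {
      if (length(l$strain_ids) < 4) {
        notes <<- c(notes, sprintf("[tree] %s: <4 strains, skipped", nm))
        return(invisible(NULL))
      }
      bt <- bootstrap_support(l, n_reps = cfg$bootstrap_reps,
                              seed = stage_seed(paste0("tree_", nm)),
                              n_random_addition = cfg$n_random_addition)
      p <- out_path(paste0(nm, "_mp_bootstrap.nwk"))
      ape::write.tree(bt, p)
      outputs[[paste0("tree_", nm)]] <<- p
      sc <- fitch_length(bt, l)
      readr::write_tsv(tidy(sc), out_path(paste0(nm, "_char_steps.tsv")))
      outputs[[paste0("char_steps_", nm)]] <<-
        out_path(paste0(nm, "_char_steps.tsv"))
    })
  })
  run_stage("concordance", function() {
    usable <- purrr::keep(loci, function(l) {
      cls <- classify_sites(l)
      cls$n_substitution > 0
    })
    if (length(usable) >= 2) {
      ild <- ild_test(unname(usable), n_reps = cfg$ild_reps,
                      seed = stage_seed("ild"))
      jsonlite::write_json(as.list(glance(ild)), out_path("ild.json"),
                           auto_unbox = TRUE, digits = NA)
      outputs$ild <<- out_path("ild.json")
    } else {
      notes <<- c(notes, "[concordance] fewer than 2 variable loci; ILD skipped")
    }
    constraint <- cfg$lineage_constraint %||%
      split(partition$strain_id, partition$lineage)
    constraint <- purrr::keep(constraint, function(g) length(g) >= 2)
    if (length(constraint) >= 2) {
      cres <- purrr::imap(loci, function(l, nm) {
        if (length(l$strain_ids) < 4) return(NULL)
        ct <- constrained_search(l, constraint,
                                 seed = stage_seed(paste0("constraint_", nm)),
                                 n_random_addition = cfg$n_random_addition,
                                 n_permutations = cfg$constraint_permutations)
        glance(ct)
      }) |> purrr::compact() |> bind_rows()
      readr::write_tsv(cres, out_path("constraint_tests.tsv"))
      outputs$constraint_tests <<- out_path("constraint_tests.tsv")
    }
  })
  phased <- NULL
  run_stage("phase", function() {
    phase_loci <- cfg$phase_loci %||% names(loci)
    phased <<- purrr::compact(purrr::imap(loci[phase_loci], function(l, nm) {
      geno <- snpify(l)
      if (length(geno$positions) == 0) {
        notes <<- c(notes, sprintf("[phase] %s: no biallelic SNP sites", nm))
        return(NULL)
      }
      ph <- em_phase(geno, seed = stage_seed(paste0("phase_", nm)))
      notes <<- c(notes, sprintf("[phase] %s: %s", nm, ph$metadata$notes))
      write_phased_tsv(ph, out_path(paste0(nm, "_phased.tsv")))
      write_haplotype_fasta(ph, out_path(paste0(nm, "_haplotypes.fasta")))
      outputs[[paste0("phased_", nm)]] <<- out_path(paste0(nm, "_phased.tsv"))
      ph
    }))
  })
  mlg <- NULL
  if (!is.null(phased) && length(phased) >= 2) {
    mlg <- purrr::imap(phased, function(ph, nm) {
      mutate(ph$phases[, c("strain_id", "hap_a", "hap_b")], locus = nm)
    }) |>
      bind_rows() |>
      dplyr::rename(allele_a = "hap_a", allele_b = "hap_b")
  }
  run_stage("ia", function() {
    if (is.null(mlg)) {
      notes <<- c(notes, "[ia] needs phased haplotypes at >= 2 loci; skipped")
      return(invisible(NULL))
    }
    ia <- index_of_association(mlg, n_permutations = cfg$ia_permutations,
                               seed = stage_seed("ia"))
    write_ia_report(ia, out_path("index_of_association.json"))
    outputs$ia <<- out_path("index_of_association.json")
  })
  run_stage("compat", function() {
    if (is.null(mlg)) {
      notes <<- c(notes, "[compat] needs phased haplotypes at >= 2 loci; skipped")
      return(invisible(NULL))
    }
    locus_names <- unique(mlg$locus)
    reports <- purrr::map(utils::combn(locus_names, 2, simplify = FALSE),
                          function(p) {
      cp <- phylogenetic_compatibility(mlg, p[1], p[2])
      mutate(cp$quartets, locus1 = p[1], locus2 = p[2], .before = 1)
    }) |> bind_rows()
    readr::write_tsv(reports, out_path("compatibility.tsv"))
    outputs$compat <<- out_path("compatibility.tsv")
  })
  manifest <- list(
    package = "mycopop",
    version = as.character(utils::packageVersion("mycopop")),
    inputs = list(loci = cfg$loci, partition = cfg$partition),
    parameters = cfg[c("bootstrap_reps", "ild_reps", "ia_permutations",
                       "n_random_addition", "constraint_permutations")],
    seed = cfg$seed,
    stage_seeds = setNames(lapply(ALL_STAGES, stage_seed), ALL_STAGES),
    stages_run = cfg$stages,
    outputs = outputs,
    warnings = notes
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
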