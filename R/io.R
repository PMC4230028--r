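#' Read and write genotype matrices as tab-separated text
#'
#' Format: header row `id` followed by locus ids; one row per individual
#' with codes in `{0, 1, 2}` or `NA` for missing.  The round-trip is
#' lossless for integer codes and missingness.
#'
#' @param path file path.
#' @return [read_genotypes()] returns a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (names(tab)[1] != "id") stop("genotype file must start with an 'id' column")
  ids <- tab$id
  codes <- as.matrix(tab[-1])
  suppressWarnings(num <- matrix(as.numeric(codes), nrow = nrow(codes)))
  missing_tok <- is.na(codes) | codes %in% c("NA", "")
  invalid <- (is.na(num) & !missing_tok) |
             (!is.na(num) & !(num %in% c(0, 1, 2)))
  if (any(invalid)) {
    b <- which(invalid, arr.ind = TRUE)
    b <- b[order(b[, 1], b[, 2]), , drop = FALSE]  # earliest line first
    stop("non-{0,1,2,NA} token '", codes[b[1, , drop = FALSE]],
         "' at line ", b[1, 1] + 1, ", column ", b[1, 2] + 1)
  }
  dimnames(num) <- list(ids, colnames(codes))
  genotype_matrix(num)
}

#' @rdname read_genotypes
#' @param genotypes a [genotype_matrix()].
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  tab <- data.frame(id = rownames(genotypes$codes), genotypes$codes,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write pedigree and phenotype tables as CSV
#'
#' Pedigrees have named columns `id`, `sire`, `dam` (empty/NA for unknown
#' parents); phenotypes have `id`, `yd`, `eop`.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!all(c("id", "sire", "dam") %in% names(ped)))
    stop("pedigree CSV needs columns id, sire, dam")
  ped$sire[ped$sire == ""] <- NA_character_
  ped$dam[ped$dam == ""] <- NA_character_
  ped
}

#' @rdname read_pedigree
#' @param pedigree pedigree data.frame.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.csv(pedigree, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname read_pedigree
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "yd", "eop") %in% names(ph)))
    stop("phenotype CSV needs columns id, yd, eop")
  ph$id <- as.character(ph$id)
  ph
}

#' @rdname read_pedigree
#' @param phenotypes phenotype data.frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check that phenotyped individuals are genotyped
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes phenotype data.frame with an `id` column.
#' @return invisibly `TRUE`; errors listing offending ids otherwise.
#' @export
check_ids <- function(genotypes, phenotypes) {
  miss <- setdiff(phenotypes$id, rownames(genotypes$codes))
  if (length(miss) > 0)
    stop("phenotyped ids missing from genotypes: ",
         paste(head(miss, 10), collapse = ", "),
         if (length(miss) > 10) paste0(" (+", length(miss) - 10, " more)"))
  invisible(TRUE)
}

#' Run the full analysis pipeline on simulated or supplied data
#'
#' Executes, as selected, the stages `simulate` (cohort, effects,
#' phenotypes), `qc`, `matrices` (A, G, D), `reml` (models MA/MG/MGD plus the
#' dominance likelihood-ratio test), `gibbs` (animal-level MGD chain), `cv`
#' (10-fold cross-validation of MA/MG/MGD) and `mate` (BLUP-SNP effects,
#' expected offspring values of all bull x cow matings, allocation under the
#' capacity cap on both criteria).  Artifacts are written as plain text under
#' `out_dir` together with a JSON manifest carrying the configuration
#' snapshot, per-stage seeds and an md5 checksum per artifact.
#'
#' Stage seeds derive from the global seed by a fixed rule: the simulator
#' uses `seed`, fold assignment `seed + 1`, the Gibbs chain `seed + 2`.
#'
#' @param config a [sim_config()] (or a YAML file path whose fields are
#'   passed to [sim_config()]), defining the synthetic cohort.
#' @param out_dir output directory, created if needed; `NULL` runs in memory
#'   only.
#' @param stages character vector of stages to run (in the fixed order
#'   above).
#' @param n_bulls number of top sires (by true breeding value of their
#'   simulated genotypes) used as mating candidates.
#' @param cap per-bull mating capacity.
#' @param folds_k number of cross-validation folds.
#' @param gibbs_iter,gibbs_burn_in,gibbs_thin Gibbs chain controls for the
#'   `gibbs` stage.
#' @return list with the stage results and, when `out_dir` is given, the
#'   manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         stages = c("simulate", "qc", "matrices", "reml",
                                    "cv", "mate"),
                         n_bulls = 10, cap = 200, folds_k = 10,
                         gibbs_iter = 20000, gibbs_burn_in = 2000,
                         gibbs_thin = 10) {
  if (is.character(config)) {
    config <- do.call(sim_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "sim_config"))
  all_stages <- c("simulate", "qc", "matrices", "reml", "gibbs", "cv", "mate")
  stages <- intersect(all_stages, stages)
  res <- list(config = config)
  artifacts <- character(0)
  save_artifact <- function(obj, name, writer) {
    if (is.null(out_dir)) return()
    path <- file.path(out_dir, name)
    writer(obj, path)
    artifacts[[name]] <<- path
  }
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      pop <- simulate_population(config)
      cohort_ids <- pop$pedigree$id[pop$pedigree$generation == 1L]
      cohort <- geno_subset(pop$genotypes, cohort_ids, recompute_p = TRUE)
      effects <- assign_effects(cohort, config)
      phen <- simulate_phenotypes(cohort, effects, config)
      res$population <<- pop
      res$cohort_ids <<- cohort_ids
      res$effects <<- effects
      res$phenotypes <<- phen
      save_artifact(pop$genotypes, "genotypes.tsv", write_genotypes)
      save_artifact(pop$pedigree, "pedigree.csv", write_pedigree)
      save_artifact(phen, "phenotypes.csv", write_phenotypes)
      save_artifact(effects, "true_effects.csv",
                    function(o, p) utils::write.csv(o, p, row.names = FALSE))
    })
  }
  if ("qc" %in% stages) {
    run_stage("qc", function() {
      qc <- apply_qc(res$population$genotypes)
      res$qc <<- qc
      save_artifact(qc$genotypes, "genotypes_qc.tsv", write_genotypes)
    })
  }
  if ("matrices" %in% stages) {
    run_stage("matrices", function() {
      g_all <- if (!is.null(res$qc)) res$qc$genotypes else res$population$genotypes
      cohort <- geno_subset(g_all, res$cohort_ids, recompute_p = TRUE)
      A_full <- pedigree_A(res$population$pedigree)
      A <- new_rel_matrix(A_full[res$cohort_ids, res$cohort_ids], "A")
      G <- blend(scale_to_A(build_G_star(cohort), A), A, 0.95)
      D <- blend(build_D_star(cohort), diag(nrow(A)), 0.95, kind = "D")
      dimnames(D) <- dimnames(G)
      res$matrices <<- list(A = A, G = G, D = D)
      res$cohort <<- cohort
    })
  }
  if ("reml" %in% stages) {
    run_stage("reml", function() {
      fits <- list(
        MA = reml_fit(model_spec(res$phenotypes, model = "MA"), res$matrices),
        MG = reml_fit(model_spec(res$phenotypes, model = "MG"), res$matrices),
        MGD = reml_fit(model_spec(res$phenotypes, model = "MGD"), res$matrices))
      res$reml <<- fits
      res$lrt <<- mixture_lrt(fits$MG$neg2logL, fits$MGD$neg2logL)
    })
  }
  if ("gibbs" %in% stages) {
    run_stage("gibbs", function() {
      chain <- gibbs_animal(model_spec(res$phenotypes, model = "MGD"),
                            res$matrices, n_iter = gibbs_iter,
                            burn_in = gibbs_burn_in, thin = gibbs_thin,
                            seed = config$seed + 2L)
      res$gibbs <<- chain
      save_artifact(as.data.frame(chain$samples), "gibbs_chain.tsv",
                    function(o, p) write.table(o, p, sep = "\t",
                                               quote = FALSE, row.names = FALSE))
    })
  }
  if ("cv" %in% stages) {
    run_stage("cv", function() {
      folds <- make_folds(res$cohort_ids, K = folds_k, seed = config$seed + 1L)
      comp <- if (!is.null(res$reml)) res$reml$MGD$components else
        c(sigmaA2 = config$target_sigmaA2, sigmaD2 = config$target_sigmaD2,
          sigmaE2 = config$sigmaE2)
      cvs <- list(
        MA = cross_validate(model_spec(res$phenotypes, model = "MA"),
                            comp[c("sigmaA2", "sigmaE2")], res$matrices, folds),
        MG = cross_validate(model_spec(res$phenotypes, model = "MG"),
                            comp[c("sigmaA2", "sigmaE2")], res$matrices, folds),
        MGD = cross_validate(model_spec(res$phenotypes, model = "MGD"),
                             comp, res$matrices, folds))
      res$folds <<- folds
      res$cv <<- cvs
      tab <- do.call(rbind, lapply(names(cvs), function(mm) {
        s <- cvs[[mm]]$summary; s$model <- mm; s
      }))
      save_artifact(tab, "cv_summary.tsv",
                    function(o, p) write.table(o, p, sep = "\t",
                                               quote = FALSE, row.names = FALSE))
    })
  }
  if ("mate" %in% stages) {
    run_stage("mate", function() {
      comp <- if (!is.null(res$reml)) res$reml$MGD$components else
        c(sigmaA2 = config$target_sigmaA2, sigmaD2 = config$target_sigmaD2,
          sigmaE2 = config$sigmaE2)
      p <- res$cohort$p
      mk <- animal_to_marker_variance(comp[["sigmaA2"]], comp[["sigmaD2"]], p)
      eff <- snp_blup_effects(res$phenotypes,
                              genotype_matrix(res$cohort$codes, p = p),
                              sigma_a2 = mk[["sigma_a2"]],
                              sigma_d2 = mk[["sigma_d2"]],
                              sigmaE2 = comp[["sigmaE2"]])
      # bulls: top sires by true breeding value of their genotypes
      sires <- res$population$pedigree$id[res$population$pedigree$generation == 0L &
                                            grepl("^S", res$population$pedigree$id)]
      # true effects restricted to the post-QC loci of the cohort
      eff_true <- res$effects[match(colnames(res$cohort$codes),
                                    res$effects$locus), ]
      alpha_true <- alpha_effects(eff_true, p)
      sire_codes <- res$population$genotypes$codes[sires, colnames(res$cohort$codes),
                                                   drop = FALSE]
      tbv <- drop(sweep(sire_codes, 2, 2 * p) %*% alpha_true)
      bulls <- sires[order(-tbv)][seq_len(min(n_bulls, length(sires)))]
      parents <- genotype_matrix(rbind(sire_codes[bulls, , drop = FALSE],
                                       res$cohort$codes), p = p)
      scores <- mating_scores(parents, eff, bulls, res$cohort_ids)
      plan_g <- allocate_matings(scores, "g", cap = cap)
      plan_u <- allocate_matings(scores, "u", cap = cap)
      gain_g <- gain_summary(plan_g, scores)
      gain_u <- gain_summary(plan_u, scores)
      res$mate <<- list(effects = eff, scores = scores,
                        plan_g = plan_g, plan_u = plan_u,
                        gain_g = gain_g, gain_u = gain_u,
                        comparison = compare_mating_criteria(gain_g, gain_u))
      save_artifact(plan_g$assignment, "mating_plan_g.csv",
                    function(o, p) utils::write.csv(o, p, row.names = FALSE))
      save_artifact(plan_u$assignment, "mating_plan_u.csv",
                    function(o, p) utils::write.csv(o, p, row.names = FALSE))
    })
  }
  if (!is.null(out_dir)) {
    manifest <- list(
      seed = config$seed,
      stage_seeds = list(simulate = config$seed, folds = config$seed + 1L,
                         gibbs = config$seed + 2L),
      config = unclass(config),
      stages = stages,
      artifacts = lapply(artifacts, function(p)
        list(path = p, md5 = unname(tools::md5sum(p))))
    )
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    res$manifest <- manifest
  }
  res
}
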