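# Shared fixture builders.  Everything is generated in code; sizes are kept
# small so that the default test run stays fast.

# genotype matrix from explicit codes, optionally with fixed allele freqs
tiny_geno <- function(codes, p = NULL, ids = NULL) {
  codes <- as.matrix(codes)
  if (!is.null(ids)) rownames(codes) <- ids
  genotype_matrix(codes, p = p)
}

# a complete small simulated study: cohort genotypes, effects, phenotypes,
# and blended A/G/D matrices over the phenotyped cohort
sim_study <- function(seed = 1, n_sires = 8, n_dams = 150, n_offspring = 200,
                      m_loci = 600, n_qtl = 150, full_sib_fraction = 0.03,
                      target_sigmaA2 = 200, target_sigmaD2 = 100,
                      sigmaE2 = 150, eop_range = c(1, 3), with_A = TRUE) {
  cfg <- sim_config(n_sires = n_sires, n_dams = n_dams,
                    n_offspring = n_offspring,
                    full_sib_fraction = full_sib_fraction,
                    m_loci = m_loci, n_qtl = n_qtl,
                    target_sigmaA2 = target_sigmaA2,
                    target_sigmaD2 = target_sigmaD2,
                    sigmaE2 = sigmaE2, eop_range = eop_range, seed = seed)
  pop <- simulate_population(cfg)
  ids <- pop$pedigree$id[pop$pedigree$generation == 1L]
  cohort <- geno_subset(pop$genotypes, ids, recompute_p = TRUE)
  effects <- assign_effects(cohort, cfg)
  phen <- simulate_phenotypes(cohort, effects, cfg)
  matrices <- list()
  if (with_A) {
    A <- pedigree_A(pop$pedigree)[ids, ids]
    attr(A, "kind") <- "A"
    matrices$A <- A
    partner <- A
  } else {
    partner <- diag(length(ids))
    dimnames(partner) <- list(ids, ids)
    attr(partner, "kind") <- "A"
  }
  matrices$G <- blend(scale_to_A(build_G_star(cohort), partner), partner, 0.95)
  D <- blend(build_D_star(cohort), diag(length(ids)), 0.95, kind = "D")
  dimnames(D) <- list(ids, ids)
  matrices$D <- D
  list(cfg = cfg, pop = pop, ids = ids, cohort = cohort, effects = effects,
       phen = phen, matrices = matrices)
}

# independent -2 log restricted likelihood for a single-kernel model,
# computed from first principles (used as a grid-search oracle)
neg2_restricted_loglik <- function(y, K, w, sigma_k2, sigma_e2) {
  n <- length(y)
  V <- sigma_k2 * K + diag(sigma_e2 / w, n)
  X <- matrix(1, n, 1)
  Vinv <- solve(V)
  XtVX <- crossprod(X, Vinv %*% X)
  beta <- solve(XtVX, crossprod(X, Vinv %*% y))
  r <- y - X %*% beta
  as.numeric((n - 1) * log(2 * pi) +
             determinant(V, logarithm = TRUE)$modulus +
             log(XtVX) + crossprod(r, Vinv %*% r))
}
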