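#' Simulation configuration for a half-sib/full-sib cow cohort
#'
#' Defines the study conditions for the synthetic cohort generator: a single
#' phenotyped generation of cows descending from a modest number of sires
#' (large paternal half-sib families) with a small fraction of full sibs,
#' Hardy-Weinberg founder genotypes, additive-plus-dominance QTL effects and
#' residuals weighted by the effective number of own performances (EOP).
#'
#' Defaults emulate a dairy-cow genotyping cohort: 1996 phenotyped cows from
#' 20 sires with 3\\% of cows in full-sib pairs, MAF drawn uniform on
#' (0.05, 0.5) (a post-QC spectrum that avoids near-monomorphic QTL), and EOP
#' uniform on (1, 3) as for multi-lactation yield records.  For
#' conformation-like traits with a single record per cow set
#' `eop_range = c(1, 1)`.
#'
#' @param n_sires,n_dams,n_offspring sizes of the founder strata and of the
#'   phenotyped offspring generation.
#' @param full_sib_fraction fraction of offspring that are members of a
#'   full-sib pair (a repeated sire x dam mating).
#' @param m_loci number of biallelic SNP loci.
#' @param n_qtl number of loci carrying non-zero effects (`n_qtl <= m_loci`).
#' @param maf_range range of founder minor allele frequencies, within (0, 0.5].
#' @param target_sigmaA2,target_sigmaD2 additive and dominance genetic
#'   variances (trait units squared) that the rescaled QTL effects reproduce
#'   exactly at the cohort allele frequencies.
#' @param sigmaE2 residual variance of a record with EOP = 1.
#' @param mu overall mean of the simulated trait.
#' @param eop_range range of the per-cow EOP weight; residual variance of cow
#'   i is `sigmaE2 / EOP_i`.
#' @param seed integer seed; all generator functions are deterministic given
#'   the configuration.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_sires = 20, n_dams = 1000, n_offspring = 1996,
                       full_sib_fraction = 0.03,
                       m_loci = 2000, n_qtl = 300,
                       maf_range = c(0.05, 0.5),
                       target_sigmaA2 = 200, target_sigmaD2 = 100,
                       sigmaE2 = 150, mu = 0,
                       eop_range = c(1, 3), seed = 1L) {
  cfg <- list(n_sires = as.integer(n_sires), n_dams = as.integer(n_dams),
              n_offspring = as.integer(n_offspring),
              full_sib_fraction = full_sib_fraction,
              m_loci = as.integer(m_loci), n_qtl = as.integer(n_qtl),
              maf_range = maf_range,
              target_sigmaA2 = target_sigmaA2, target_sigmaD2 = target_sigmaD2,
              sigmaE2 = sigmaE2, mu = mu, eop_range = eop_range,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_sires >= 1, n_dams >= 1, n_offspring >= 0,
              full_sib_fraction >= 0, full_sib_fraction <= 1,
              m_loci >= 1, n_qtl >= 0, n_qtl <= m_loci,
              length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
              maf_range[1] <= maf_range[2],
              target_sigmaA2 >= 0, target_sigmaD2 >= 0, sigmaE2 >= 0,
              length(eop_range) == 2, eop_range[1] > 0,
              eop_range[1] <= eop_range[2])
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a pedigreed genotyped population by gene dropping
#'
#' Founder (sire and dam) genotypes are drawn per locus from Hardy-Weinberg
#' proportions at frequencies uniform on `maf_range`.  Offspring receive one
#' allele from each recorded parent per locus (gene dropping, loci unlinked).
#' Full sibs arise only from repeated sire x dam matings: the number of such
#' repeat matings is `round(full_sib_fraction * n_offspring) / 2`, every other
#' (sire, dam) pair is used once, and sires are used in (near-)equal numbers
#' so that the cohort consists of large paternal half-sib families.
#'
#' @param config a [sim_config()].
#' @return A list with elements `pedigree` (data.frame `id`, `sire`, `dam`,
#'   `generation`; founder parents are `NA`) and `genotypes` (a
#'   [genotype_matrix()] holding founders and offspring; allele frequencies
#'   are the observed frequencies over all individuals).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ns <- config$n_sires; nd <- config$n_dams; no <- config$n_offspring
  m <- config$m_loci
  sire_ids <- sprintf("S%03d", seq_len(ns))
  dam_ids  <- sprintf("D%04d", seq_len(nd))

  p <- runif(m, config$maf_range[1], config$maf_range[2])

  founder_codes <- matrix(
    rbinom((ns + nd) * m, size = 2, prob = rep(p, each = ns + nd)),
    nrow = ns + nd, ncol = m, dimnames = list(c(sire_ids, dam_ids), NULL)
  )

  ped <- data.frame(id = c(sire_ids, dam_ids),
                    sire = NA_character_, dam = NA_character_,
                    generation = 0L, stringsAsFactors = FALSE)

  if (no > 0) {
    n_fs <- 2L * as.integer(round(config$full_sib_fraction * no / 2))
    fs_pairs <- n_fs %/% 2L
    n_single <- no - n_fs
    n_matings <- fs_pairs + n_single
    if (n_matings > ns * nd)
      stop("infeasible mating design: ", n_matings,
           " distinct sire x dam pairs needed but only ", ns * nd, " exist")
    # cycle sires so family sizes differ by at most one mating
    mating_sire <- rep_len(seq_len(ns), n_matings)
    per_sire <- tabulate(mating_sire, ns)
    if (max(per_sire) > nd)
      stop("infeasible mating design: a sire needs ", max(per_sire),
           " distinct dams but only ", nd, " are available")
    mating_dam <- integer(n_matings)
    for (s in seq_len(ns)) {
      idx <- which(mating_sire == s)
      mating_dam[idx] <- sample.int(nd, length(idx))
    }
    # first fs_pairs matings are repeated (two offspring each)
    off_mating <- c(rep(seq_len(fs_pairs), each = 2),
                    seq_len(n_single) + fs_pairs)
    off_ids <- sprintf("C%05d", seq_len(no))
    off_sire <- sire_ids[mating_sire[off_mating]]
    off_dam  <- dam_ids[mating_dam[off_mating]]

    sire_rows <- founder_codes[off_sire, , drop = FALSE]
    dam_rows  <- founder_codes[off_dam, , drop = FALSE]
    off_codes <- matrix(rbinom(no * m, 1, sire_rows / 2) +
                        rbinom(no * m, 1, dam_rows / 2),
                        nrow = no, ncol = m, dimnames = list(off_ids, NULL))
    codes <- rbind(founder_codes, off_codes)
    ped <- rbind(ped, data.frame(id = off_ids, sire = off_sire, dam = off_dam,
                                 generation = 1L, stringsAsFactors = FALSE))
  } else {
    codes <- founder_codes
  }
  colnames(codes) <- sprintf("M%05d", seq_len(m))
  list(pedigree = ped, genotypes = genotype_matrix(codes))
}

#' Substitution effects
#'
#' The allele substitution effect at locus k is `alpha_k = a_k + d_k (q_k -
#' p_k)`, the slope of the breeding value on allele dosage.
#'
#' @param effects a `marker_effects` data.frame with columns `a` and `d`.
#' @param p allele frequencies of the counted allele.
#' @return numeric vector of substitution effects.
#' @export
alpha_effects <- function(effects, p) {
  stopifnot(nrow(effects) == length(p))
  effects$a + effects$d * (1 - 2 * p)
}

#' Assign additive and dominance QTL effects with exact variance targeting
#'
#' `n_qtl` loci (sampled at random) receive additive and dominance effects
#' drawn from standard normals and then rescaled by one multiplicative factor
#' per effect vector so that the implied animal-level variances at the
#' frequencies of `genotypes` equal `target_sigmaA2` and `target_sigmaD2`
#' exactly (see [true_variance_components()]).  Because the substitution
#' effect mixes `a` and `d`, the additive factor solves a quadratic; targets
#' for which the dominance-induced substitution variance alone exceeds
#' `target_sigmaA2` are rejected.
#'
#' @param genotypes a [genotype_matrix()] defining the allele frequencies at
#'   which the variances are evaluated (typically the phenotyped cohort).
#' @param config a [sim_config()].
#' @return A `marker_effects` data.frame with columns `locus`, `a`, `d`.
#' @export
assign_effects <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(config, "sim_config"))
  m <- ncol(genotypes$codes)
  if (config$n_qtl > m) stop("n_qtl exceeds the number of loci")
  if (config$target_sigmaD2 > 0 && config$n_qtl == 0)
    stop("target_sigmaD2 > 0 requires n_qtl > 0")
  if (config$target_sigmaA2 > 0 && config$n_qtl == 0)
    stop("target_sigmaA2 > 0 requires n_qtl > 0")
  set.seed(config$seed + 1L)
  a <- d <- numeric(m)
  if (config$n_qtl > 0) {
    qtl <- sort(sample.int(m, config$n_qtl))
    a0 <- rnorm(config$n_qtl)
    d0 <- rnorm(config$n_qtl)
    p <- genotypes$p[qtl]; q <- 1 - p
    w <- 2 * p * q
    # dominance variance: sum (2 p q c_d d)^2 = target
    sDd <- sum((w * d0)^2)
    c_d <- if (config$target_sigmaD2 == 0) 0 else sqrt(config$target_sigmaD2 / sDd)
    # additive variance: sum 2pq (c_a a + c_d d (q-p))^2 = target, quadratic in c_a
    A2 <- sum(w * a0^2)
    B  <- sum(w * a0 * (c_d * d0) * (q - p))
    C0 <- sum(w * (c_d * d0 * (q - p))^2)
    if (config$target_sigmaA2 == 0 && C0 < 1e-12 && abs(B) < 1e-12) {
      c_a <- 0
    } else {
      disc <- B^2 + A2 * (config$target_sigmaA2 - C0)
      if (A2 <= 0 || disc < 0)
        stop("incompatible variance targets: dominance-induced substitution ",
             "variance exceeds target_sigmaA2")
      c_a <- (-B + sqrt(disc)) / A2
      if (c_a < 0)
        stop("incompatible variance targets: no non-negative additive scaling")
    }
    a[qtl] <- c_a * a0
    d[qtl] <- c_d * d0
  } else {
    qtl <- integer(0)
  }
  structure(data.frame(locus = colnames(genotypes$codes), a = a, d = d,
                       stringsAsFactors = FALSE),
            class = c("marker_effects", "data.frame"))
}

#' Animal-level variances implied by realized marker effects
#'
#' Evaluates the classical single-locus decomposition summed over loci at the
#' allele frequencies of `genotypes`: the additive variance is
#' `sum_k 2 p_k q_k alpha_k^2` with `alpha_k = a_k + d_k (q_k - p_k)`, and the
#' dominance variance is `sum_k (2 p_k q_k d_k)^2`.  Used as ground truth for
#' variance-component recovery experiments.
#'
#' @inheritParams assign_effects
#' @param effects a `marker_effects` data.frame (see [assign_effects()]).
#' @return named numeric vector `c(sigmaA2, sigmaD2)`.
#' @export
true_variance_components <- function(genotypes, effects) {
  stopifnot(inherits(genotypes, "geno_matrix"),
            nrow(effects) == ncol(genotypes$codes))
  p <- genotypes$p; q <- 1 - p
  alpha <- alpha_effects(effects, p)
  c(sigmaA2 = sum(2 * p * q * alpha^2),
    sigmaD2 = sum((2 * p * q * effects$d)^2))
}

#' Simulate EOP-weighted phenotypes
#'
#' Generates one yield-deviation-like record per individual:
#' `y_i = mu + sum_k gv(code_ik) + e_i`, where the genotypic value per locus
#' is `+a_k`, `d_k`, `-a_k` for codes 2, 1, 0 and
#' `e_i ~ N(0, sigmaE2 / EOP_i)` with `EOP_i ~ Uniform(eop_range)`.
#'
#' @inheritParams assign_effects
#' @param effects a `marker_effects` data.frame.
#' @return A data.frame (`phenotypes`) with columns `id`, `yd`, `eop`, plus
#'   attribute `"tgv"` holding the noise-free total genetic values.
#' @export
simulate_phenotypes <- function(genotypes, effects, config) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(config, "sim_config"))
  codes <- genotypes$codes
  if (anyNA(codes)) stop("genotypes contain missing codes; run apply_qc() first")
  set.seed(config$seed + 2L)
  tgv <- drop((codes - 1) %*% effects$a + (codes == 1) %*% effects$d)
  n <- nrow(codes)
  eop <- runif(n, config$eop_range[1], config$eop_range[2])
  e <- rnorm(n, 0, sqrt(config$sigmaE2 / eop))
  out <- data.frame(id = rownames(codes), yd = unname(config$mu + tgv + e),
                    eop = eop, stringsAsFactors = FALSE)
  attr(out, "tgv") <- unname(config$mu + tgv)
  out
}

#' Count full-sib pairs among offspring of a pedigree
#'
#' @param pedigree a pedigree data.frame (`id`, `sire`, `dam`, `generation`).
#' @return list with `n_pairs` (offspring pairs sharing both known parents)
#'   and `frac_individuals` (fraction of offspring belonging to at least one
#'   such pair).
#' @export
full_sib_summary <- function(pedigree) {
  off <- pedigree[!is.na(pedigree$sire) & !is.na(pedigree$dam), ]
  key <- paste(off$sire, off$dam, sep = "|")
  sizes <- table(key)
  n_pairs <- sum(choose(sizes, 2))
  in_pair <- sum(sizes[sizes >= 2])
  list(n_pairs = as.numeric(n_pairs),
       frac_individuals = if (nrow(off) > 0) in_pair / nrow(off) else 0)
}
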