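test_that("degenerate configurations produce founders only", {
  cfg <- sim_config(n_sires = 3, n_dams = 5, n_offspring = 0, m_loci = 50,
                    n_qtl = 0, target_sigmaA2 = 0, target_sigmaD2 = 0, seed = 4)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$pedigree), 8)
  expect_true(all(pop$pedigree$generation == 0L))
  expect_true(all(is.na(pop$pedigree$sire)))
  expect_equal(nrow(pop$genotypes$codes), 8)
})

test_that("offspring genotypes are Mendelian-consistent with their parents", {
  cfg <- sim_config(n_sires = 5, n_dams = 40, n_offspring = 80, m_loci = 120,
                    n_qtl = 20, seed = 2)
  pop <- simulate_population(cfg)
  codes <- pop$genotypes$codes
  off <- pop$pedigree[pop$pedigree$generation == 1L, ]
  for (i in seq_len(nrow(off))) {
    co <- codes[off$id[i], ]
    cs <- codes[off$sire[i], ]
    cd <- codes[off$dam[i], ]
    # the offspring must carry at least one A1 wherever a parent is A1A1,
    # and cannot carry more A1 than heterozygous-or-A1A1 parents can give
    lower <- (cs == 2) + (cd == 2)
    upper <- 2 - ((cs == 0) + (cd == 0))
    expect_true(all(co >= lower & co <= upper))
  }
})

test_that("realized full-sib fraction matches the configured 3%", {
  cfg <- sim_config(n_sires = 20, n_dams = 1000, n_offspring = 2000,
                    full_sib_fraction = 0.03, m_loci = 20, n_qtl = 5, seed = 1)
  pop <- simulate_population(cfg)
  off <- pop$pedigree[pop$pedigree$generation == 1L, ]
  # exhaustive count, independent of full_sib_summary()
  key <- paste(off$sire, off$dam)
  frac <- mean(duplicated(key) | duplicated(key, fromLast = TRUE))
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.04)
  expect_equal(full_sib_summary(pop$pedigree)$frac_individuals, frac)
})

test_that("founder allele frequencies stay within 3 binomial SE of the draw", {
  cfg <- sim_config(n_sires = 50, n_dams = 450, n_offspring = 0, m_loci = 400,
                    n_qtl = 0, target_sigmaA2 = 0, target_sigmaD2 = 0, seed = 9)
  pop <- simulate_population(cfg)
  set.seed(cfg$seed)
  p_drawn <- runif(cfg$m_loci, cfg$maf_range[1], cfg$maf_range[2])
  p_obs <- colMeans(pop$genotypes$codes) / 2
  se <- sqrt(p_drawn * (1 - p_drawn) / (2 * 500))
  # a few 3-SE exceedances among 400 loci are expected by chance
  expect_gt(mean(abs(p_obs - p_drawn) <= 3 * se), 0.99)
})

test_that("simulation is bit-reproducible given the seed", {
  cfg <- sim_config(n_sires = 4, n_dams = 30, n_offspring = 50, m_loci = 80,
                    n_qtl = 30, seed = 13)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a, b)
  ga <- geno_subset(a$genotypes, a$pedigree$id[a$pedigree$generation == 1],
                    recompute_p = TRUE)
  expect_identical(simulate_phenotypes(ga, assign_effects(ga, cfg), cfg),
                   simulate_phenotypes(ga, assign_effects(ga, cfg), cfg))
})

test_that("infeasible mating designs raise explicit errors", {
  cfg <- sim_config(n_sires = 1, n_dams = 2, n_offspring = 5,
                    full_sib_fraction = 0, m_loci = 10, n_qtl = 2, seed = 1)
  expect_error(simulate_population(cfg), "infeasible mating design")
})

test_that("effect assignment hits the variance targets exactly", {
  study <- sim_study(seed = 5, n_offspring = 150, m_loci = 300, n_qtl = 80)
  vc <- true_variance_components(study$cohort, study$effects)
  expect_equal(vc[["sigmaA2"]], 200, tolerance = 1e-12)
  expect_equal(vc[["sigmaD2"]], 100, tolerance = 1e-12)

  # no dominance target: all d forced to zero
  cfg0 <- sim_config(n_sires = 4, n_dams = 40, n_offspring = 60, m_loci = 100,
                     n_qtl = 30, target_sigmaD2 = 0, seed = 6)
  pop0 <- simulate_population(cfg0)
  g0 <- geno_subset(pop0$genotypes, pop0$pedigree$id[pop0$pedigree$generation == 1],
                    recompute_p = TRUE)
  eff0 <- assign_effects(g0, cfg0)
  expect_true(all(eff0$d == 0))
  expect_equal(true_variance_components(g0, eff0)[["sigmaD2"]], 0)

  # dominance target without QTL is impossible
  cfg_bad <- sim_config(n_qtl = 0, target_sigmaA2 = 0, target_sigmaD2 = 10)
  expect_error(assign_effects(g0, cfg_bad), "n_qtl")
})

test_that("single-locus variance decomposition matches textbook values", {
  g <- tiny_geno(matrix(c(0, 2, 1, 1), ncol = 1))  # observed p = 0.5
  a_only <- structure(data.frame(locus = "L1", a = 1, d = 0),
                      class = c("marker_effects", "data.frame"))
  d_only <- structure(data.frame(locus = "L1", a = 0, d = 1),
                      class = c("marker_effects", "data.frame"))
  expect_equal(true_variance_components(g, a_only),
               c(sigmaA2 = 0.5, sigmaD2 = 0))
  expect_equal(true_variance_components(g, d_only),
               c(sigmaA2 = 0, sigmaD2 = 0.25))
})

test_that("phenotypes decompose into mean, genetic value and weighted noise", {
  cfg <- sim_config(n_sires = 4, n_dams = 40, n_offspring = 60, m_loci = 100,
                    n_qtl = 40, sigmaE2 = 0, mu = 5, seed = 3)
  pop <- simulate_population(cfg)
  g <- geno_subset(pop$genotypes, pop$pedigree$id[pop$pedigree$generation == 1],
                   recompute_p = TRUE)
  eff <- assign_effects(g, cfg)
  ph <- simulate_phenotypes(g, eff, cfg)
  # sigmaE2 = 0: phenotype equals mu + total genetic value exactly
  tgv <- drop((g$codes - 1) %*% eff$a + (g$codes == 1) %*% eff$d)
  expect_equal(ph$yd, unname(5 + tgv))
  expect_equal(ph$yd, attr(ph, "tgv"))

  # all effects zero as well: constant phenotype
  eff0 <- eff; eff0$a[] <- 0; eff0$d[] <- 0
  expect_equal(simulate_phenotypes(g, eff0, cfg)$yd, rep(5, nrow(g$codes)))

  # missing genotypes are rejected
  gm <- g; gm$codes[1, 1] <- NA
  expect_error(simulate_phenotypes(gm, eff, cfg), "missing")
})

test_that("realized genetic variance in a large cohort is near its target", {
  cfg <- sim_config(n_sires = 20, n_dams = 1000, n_offspring = 2000,
                    m_loci = 800, n_qtl = 200, seed = 8)
  pop <- simulate_population(cfg)
  g <- geno_subset(pop$genotypes, pop$pedigree$id[pop$pedigree$generation == 1],
                   recompute_p = TRUE)
  eff <- assign_effects(g, cfg)
  ph <- simulate_phenotypes(g, eff, cfg)
  expect_equal(var(attr(ph, "tgv")), 300, tolerance = 0.15)
})
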