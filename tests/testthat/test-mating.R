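# gamete-enumeration oracle: expected offspring genotypic value of one
# mating, averaging over the four equiprobable parental gamete combinations
gamete_oracle_g <- function(cs, cd, a, d) {
  gam <- function(code) switch(as.character(code),
                               "2" = c(1, 1), "1" = c(1, 0), "0" = c(0, 0))
  total <- 0
  for (k in seq_along(cs)) {
    gs <- gam(cs[k]); gd <- gam(cd[k])
    val <- 0
    for (x in gs) for (z in gd) {
      geno <- x + z
      val <- val + c(-a[k], d[k], a[k])[geno + 1] / 4
    }
    total <- total + val
  }
  total
}

test_that("offspring genotype probabilities follow Mendelian transmission", {
  expect_equal(unname(offspring_genotype_probs(2, 0)), rbind(c(0, 1, 0)),
               ignore_attr = TRUE)
  expect_equal(unname(offspring_genotype_probs(1, 1)),
               rbind(c(0.25, 0.5, 0.25)), ignore_attr = TRUE)
  expect_equal(unname(offspring_genotype_probs(2, 1)),
               rbind(c(0.5, 0.5, 0)), ignore_attr = TRUE)
  # probabilities always sum to one and lie on the quarter grid
  set.seed(71)
  cs <- sample(0:2, 50, replace = TRUE)
  cd <- sample(0:2, 50, replace = TRUE)
  pr <- offspring_genotype_probs(cs, cd)
  expect_equal(unname(rowSums(pr)), rep(1, 50))
  expect_true(all(pr %in% c(0, 0.25, 0.5, 1)))
})

test_that("mating predictions match hand-worked single-locus values", {
  eff <- structure(data.frame(locus = "L1", a = 2, d = 1),
                   class = c("marker_effects", "data.frame"))
  pr <- offspring_genotype_probs(1, 1)
  val <- predict_mating(pr, eff, p = 0.5)
  expect_equal(val[["g_hat"]], 0.25 * 2 + 0.5 * 1 - 0.25 * 2)
  expect_equal(val[["u_hat"]], 0)   # centred expected dosage is 0 at p = 0.5
})

test_that("expected values are linear in effects and obey the parent average", {
  set.seed(72)
  codes <- matrix(sample(0:2, 12 * 60, replace = TRUE), 12, 60)
  g <- tiny_geno(codes, ids = c(paste0("b", 1:4), paste0("c", 1:8)))
  eff <- structure(data.frame(locus = colnames(g$codes),
                              a = rnorm(60), d = rnorm(60, 0, 0.5)),
                   class = c("marker_effects", "data.frame"))
  sc <- mating_scores(g, eff, paste0("b", 1:4), paste0("c", 1:8))
  # parent-average law for breeding values (exact)
  alpha <- alpha_effects(eff, g$p)
  bv <- drop(sweep(g$codes, 2, 2 * g$p) %*% alpha)
  for (i in 1:4) for (j in 1:8) {
    expect_equal(sc$u[i, j],
                 (bv[paste0("b", i)] + bv[paste0("c", j)]) / 2,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # total genetic values agree with the gamete-enumeration oracle and with
  # the per-pair probability route
  for (i in c(1, 3)) for (j in c(2, 5, 8)) {
    cs <- g$codes[paste0("b", i), ]; cd <- g$codes[paste0("c", j), ]
    expect_equal(sc$g[i, j], gamete_oracle_g(cs, cd, eff$a, eff$d),
                 tolerance = 1e-10)
    pm <- predict_mating(offspring_genotype_probs(cs, cd), eff, g$p)
    expect_equal(sc$g[i, j], pm[["g_hat"]], tolerance = 1e-10)
    expect_equal(sc$u[i, j], pm[["u_hat"]], tolerance = 1e-10)
  }
  # doubling all effects doubles both scores
  eff2 <- eff; eff2$a <- 2 * eff$a; eff2$d <- 2 * eff$d
  sc2 <- mating_scores(g, eff2, paste0("b", 1:4), paste0("c", 1:8))
  expect_equal(sc2$g, 2 * sc$g, tolerance = 1e-12)
  expect_equal(sc2$u, 2 * sc$u, tolerance = 1e-12)
})

test_that("greedy allocation respects capacity and matches brute force", {
  sc <- list(g = rbind(c(5, 4, 3), c(2, 1, 0)),
             u = rbind(c(5, 4, 3), c(2, 1, 0)),
             bulls = c("b1", "b2"), cows = c("c1", "c2", "c3"))
  class(sc) <- "mating_scores"
  plan <- allocate_matings(sc, "g", cap = 2)
  expect_equal(plan$assignment$bull, c("b1", "b1", "b2"))
  expect_equal(unname(plan$usage), c(2L, 1L))
  # brute force: enumerate all feasible complete assignments, maximize total
  best <- -Inf
  for (b1 in 1:2) for (b2 in 1:2) for (b3 in 1:2) {
    asg <- c(b1, b2, b3)
    if (max(tabulate(asg, 2)) <= 2)
      best <- max(best, sum(sc$g[cbind(asg, 1:3)]))
  }
  expect_equal(sum(plan$assignment$g_hat), best)

  # unconstrained: every cow gets her argmax bull
  plan2 <- allocate_matings(sc, "g", cap = 3)
  expect_equal(plan2$assignment$bull, c("b1", "b1", "b1"))
  expect_error(allocate_matings(sc, "g", cap = 1), "infeasible")
})

test_that("gain summaries are zero when selection cannot choose", {
  # a single bull: the selected matings are all possible matings
  sc <- list(g = matrix(c(1, 2, 3), 1, 3), u = matrix(c(3, 1, 2), 1, 3),
             bulls = "b1", cows = paste0("c", 1:3))
  class(sc) <- "mating_scores"
  gain <- gain_summary(allocate_matings(sc, "g", cap = 5), sc)
  expect_equal(gain$delta_g, 0)
  expect_equal(gain$delta_u, 0)
})

test_that("selection on g dominates selection on u in expected g", {
  means_ok <- vapply(1:5, function(s) {
    set.seed(80 + s)
    codes <- matrix(sample(0:2, 30 * 120, replace = TRUE), 30, 120)
    g <- tiny_geno(codes, ids = c(paste0("b", 1:6), paste0("c", 1:24)))
    eff <- structure(data.frame(locus = colnames(g$codes),
                                a = rnorm(120, 0, 0.3), d = rnorm(120, 0, 0.3)),
                     class = c("marker_effects", "data.frame"))
    sc <- mating_scores(g, eff, paste0("b", 1:6), paste0("c", 1:24))
    pg <- allocate_matings(sc, "g", cap = 6)
    pu <- allocate_matings(sc, "u", cap = 6)
    mean(pg$assignment$g_hat) >= mean(pu$assignment$g_hat) - 1e-12
  }, logical(1))
  expect_true(all(means_ok))
})

test_that("a uniform shift of g scores leaves the gain unchanged", {
  set.seed(85)
  codes <- matrix(sample(0:2, 20 * 80, replace = TRUE), 20, 80)
  g <- tiny_geno(codes, ids = c(paste0("b", 1:4), paste0("c", 1:16)))
  eff <- structure(data.frame(locus = colnames(g$codes),
                              a = rnorm(80, 0, 0.3), d = rnorm(80, 0, 0.3)),
                   class = c("marker_effects", "data.frame"))
  sc <- mating_scores(g, eff, paste0("b", 1:4), paste0("c", 1:16))
  gain <- gain_summary(allocate_matings(sc, "g", cap = 5), sc)
  sc2 <- sc; sc2$g <- sc$g + 42
  gain2 <- gain_summary(allocate_matings(sc2, "g", cap = 5), sc2)
  expect_equal(gain2$delta_g, gain$delta_g, tolerance = 1e-10)
  expect_equal(gain2$rel_g, gain$rel_g, tolerance = 1e-10)
})

test_that("noise-free SNP-BLUP recovers generating effects in the limit", {
  # m < n independent markers, y generated without noise: as shrinkage
  # vanishes the BLUP solutions approach the generating effects
  set.seed(86)
  n <- 120; m <- 15
  codes <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  g <- tiny_geno(codes, ids = paste0("i", 1:n))
  a0 <- rnorm(m); d0 <- rnorm(m)
  y <- stats::setNames(drop((codes - 1) %*% a0 + (codes == 1) %*% d0) + 3,
                       rownames(g$codes))
  eff <- snp_blup_effects(y, g, sigma_a2 = 1e4, sigma_d2 = 1e4, sigmaE2 = 1e-4)
  expect_equal(eff$a, a0, tolerance = 1e-3)
  expect_equal(eff$d, d0, tolerance = 1e-3)
  # infinite dominance shrinkage: all d at zero
  eff0 <- snp_blup_effects(y, g, sigma_a2 = 1, sigma_d2 = 0, sigmaE2 = 1)
  expect_true(all(eff0$d == 0))
  expect_error(snp_blup_effects(y, g, sigma_a2 = 0, sigma_d2 = 1, sigmaE2 = 1),
               "positive")
})

test_that("SNP-BLUP with centred designs equals animal-level GBLUP", {
  study <- sim_study(seed = 87, n_offspring = 90, m_loci = 150, n_qtl = 60,
                     with_A = FALSE)
  p <- study$cohort$p
  mk <- animal_to_marker_variance(200, 100, p)
  eff <- snp_blup_effects(study$phen, study$cohort,
                          sigma_a2 = mk[["sigma_a2"]],
                          sigma_d2 = mk[["sigma_d2"]],
                          sigmaE2 = 150, design = "centered")
  d <- marker_design(study$cohort)
  gv_snp <- drop(d$W_a %*% eff$a + d$W_d %*% eff$d)
  # animal model with unscaled, unblended G* and D* built from the same
  # designs and matched variances
  Gs <- build_G_star(study$cohort)
  Ds <- build_D_star(study$cohort)
  comp <- c(sigmaA2 = mk[["sigma_a2"]] * d$denom_a,
            sigmaD2 = mk[["sigma_d2"]] * d$denom_d,
            sigmaE2 = 150)
  pred <- blup_solve(model_spec(study$phen, model = "MGD"),
                     comp, list(G = Gs, D = Ds))
  expect_equal(gv_snp, pred$g, tolerance = 1e-8, ignore_attr = TRUE)
})
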