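# recursive kinship oracle (independent of the iterative tabular code path):
# additive relationship a(i,j) via the classical recursions on the ordered
# pedigree, memoised
kinship_oracle <- function(ped) {
  id <- as.character(ped$id)
  si <- match(ped$sire, id)
  di <- match(ped$dam, id)
  memo <- new.env()
  rel <- function(i, j) {
    if (i == 0 || j == 0) return(0)
    if (i < j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    s <- ifelse(is.na(si[i]), 0, si[i])
    d <- ifelse(is.na(di[i]), 0, di[i])
    val <- if (i == j) 1 + 0.5 * rel(s, d)
           else 0.5 * (rel(s, j) + rel(d, j))
    memo[[key]] <- val
    val
  }
  n <- length(id)
  outer(1:n, 1:n, Vectorize(rel))
}

test_that("tabular A reproduces textbook relationships", {
  # two unrelated founders
  ped <- data.frame(id = c("a", "b"), sire = NA, dam = NA)
  expect_equal(unclass(pedigree_A(ped)), diag(2), ignore_attr = TRUE)

  # parent-offspring with unknown second parent
  ped <- data.frame(id = c("s", "o"), sire = c(NA, "s"), dam = NA)
  A <- pedigree_A(ped)
  expect_equal(A["s", "o"], 0.5)
  expect_equal(diag(A), c(s = 1, o = 1))

  # full sibs from unrelated parents
  ped <- data.frame(id = c("s", "d", "o1", "o2"),
                    sire = c(NA, NA, "s", "s"), dam = c(NA, NA, "d", "d"))
  A <- pedigree_A(ped)
  expect_equal(A["o1", "o2"], 0.5)
  expect_equal(unname(diag(A)), rep(1, 4))
})

test_that("tabular A agrees with a recursive kinship oracle", {
  # three generations incl. inbreeding: o3 from half sibs
  ped <- data.frame(
    id   = c("f1", "f2", "f3", "h1", "h2", "o1", "o2", "o3"),
    sire = c(NA, NA, NA, "f1", "f1", "h1", "h1", "o1"),
    dam  = c(NA, NA, NA, "f2", "f3", "h2", "f3", "o2"),
    stringsAsFactors = FALSE)
  A <- pedigree_A(ped)
  expect_equal(unclass(A), kinship_oracle(ped),
               ignore_attr = TRUE, tolerance = 1e-12)
  # o3's parents are related -> inbred diagonal > 1
  expect_gt(A["o3", "o3"], 1)
})

test_that("unordered or self-referential pedigrees are rejected", {
  expect_error(pedigree_A(data.frame(id = c("o", "s"),
                                     sire = c("s", NA), dam = NA)),
               "topologically")
  expect_error(pedigree_A(data.frame(id = "x", sire = "x", dam = NA)),
               "topologically")
})

test_that("G* matches its single-locus worked values", {
  # one locus, p fixed at 0.5; both individuals A1A1: w = 1, denom = 0.5
  g <- tiny_geno(matrix(c(2, 2), ncol = 1), p = 0.5)
  Gs <- build_G_star(g)
  expect_equal(Gs[1, 2], 2.0)
  # a heterozygote at p = 0.5 has w = 0: its whole row is zero
  g2 <- tiny_geno(matrix(c(1, 2, 0), ncol = 1), p = 0.5)
  Gs2 <- build_G_star(g2)
  expect_equal(unname(Gs2[1, ]), c(0, 0, 0))
})

test_that("D* matches its single-locus worked values", {
  # p = 0.5: W_d entries are (-0.5, +0.5, -0.5); denominator 0.25
  g <- tiny_geno(matrix(c(1, 1, 2), ncol = 1), p = 0.5)
  Ds <- build_D_star(g)
  expect_equal(Ds[1, 2], 1.0)    # het x het
  expect_equal(Ds[1, 3], -1.0)   # het x hom
  # exact-HWE counts: the W_d column sums to zero
  g3 <- tiny_geno(matrix(c(2, 1, 1, 0), ncol = 1))  # counts 1:2:1, p = 0.5
  expect_equal(sum(marker_design(g3)$W_d[, 1]), 0)
})

test_that("cross-product matrices equal per-pair brute-force accumulation", {
  set.seed(31)
  g <- tiny_geno(matrix(rbinom(15 * 40, 2, runif(40, 0.1, 0.5)),
                        15, 40, byrow = FALSE))
  d <- marker_design(g)
  Gs <- build_G_star(g)
  Ds <- build_D_star(g)
  for (i in 1:15) for (j in i:15) {
    expect_equal(Gs[i, j], sum(d$W_a[i, ] * d$W_a[j, ]) / d$denom_a,
                 tolerance = 1e-12)
    expect_equal(Ds[i, j], sum(d$W_d[i, ] * d$W_d[j, ]) / d$denom_d,
                 tolerance = 1e-12)
  }
})

test_that("scale_to_A solves the two-moment match", {
  # fixed point: G* already matching A's means
  A <- diag(4)
  expect_equal(unclass(scale_to_A(A, A)), diag(4), ignore_attr = TRUE)

  # A = I, G* with mean diagonal 1.2 and mean off-diagonal 0.2
  Gs <- matrix(0.2, 3, 3); diag(Gs) <- 1.2
  Gs[1, 2] <- Gs[2, 1] <- 0.1; Gs[1, 3] <- Gs[3, 1] <- 0.3  # keep mean 0.2
  diag(Gs) <- c(1.0, 1.2, 1.4)
  sc <- scale_to_A(Gs, diag(3))
  expect_equal(unclass(sc), unclass(Gs) - 0.2, ignore_attr = TRUE)

  # property: output moments equal A's to machine precision
  set.seed(5)
  g <- tiny_geno(matrix(rbinom(20 * 100, 2, 0.3), 20, 100))
  Gs2 <- build_G_star(g)
  A2 <- diag(20)
  out <- scale_to_A(Gs2, A2)
  expect_equal(mean(diag(out)), 1, tolerance = 1e-12)
  expect_equal(mean(out[upper.tri(out)]), 0, tolerance = 1e-12)

  expect_error(scale_to_A(matrix(1, 3, 3), diag(3)), "degenerate")
})

test_that("blending bounds eigenvalues and respects its weight", {
  set.seed(11)
  g <- tiny_geno(matrix(rbinom(30 * 200, 2, 0.4), 30, 200))
  Ds <- build_D_star(g)
  expect_equal(blend(Ds, diag(30), weight = 1), Ds, ignore_attr = TRUE)
  expect_equal(unclass(blend(Ds, diag(30), weight = 0)), diag(30),
               ignore_attr = TRUE)
  D <- blend(Ds, diag(30), 0.95, kind = "D")
  expect_gte(min(eigen(D, symmetric = TRUE, only.values = TRUE)$values),
             0.05 - 1e-10)
  expect_equal(D, t(D), ignore_attr = TRUE)
})

test_that("off-diagonal summaries count extremes over the upper triangle", {
  s <- offdiag_summary(diag(3))
  expect_equal(s$mean, 0); expect_equal(s$sd, 0); expect_equal(s$prop_extreme, 0)
  M <- diag(3)
  M[1, 2] <- M[2, 1] <- 0.06
  M[1, 3] <- M[3, 1] <- -0.06
  M[2, 3] <- M[3, 2] <- 0.01
  expect_equal(offdiag_summary(M, 0.05)$prop_extreme, 2 / 3)
})

test_that("an unrelated HWE cohort has centred G* and D* off-diagonals", {
  set.seed(77)
  p <- runif(10000, 0.05, 0.5)
  codes <- matrix(rbinom(500 * 10000, 2, rep(p, each = 500)), 500, 10000)
  g <- genotype_matrix(codes)
  expect_lt(abs(offdiag_summary(build_G_star(g))$mean), 0.005)
  expect_lt(abs(offdiag_summary(build_D_star(g))$mean), 0.005)
})

test_that("in a half-sib cohort D is less dispersed and less informative than G", {
  # family structure loads the additive relationships (half sibs 0.25) but
  # hardly the dominance ones (only full sibs reach 0.25), so the dominance
  # matrix carries far less relationship information
  study <- sim_study(seed = 78, n_sires = 10, n_dams = 250, n_offspring = 400,
                     m_loci = 2000, n_qtl = 100, with_A = FALSE)
  sg <- offdiag_summary(build_G_star(study$cohort))
  sd_ <- offdiag_summary(build_D_star(study$cohort))
  expect_lt(sd_$sd, sg$sd)
  expect_lt(sd_$prop_extreme, sg$prop_extreme)
})
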