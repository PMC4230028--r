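#' SNP-BLUP estimation of additive and dominance marker effects
#'
#' Best linear unbiased prediction of per-marker effects at fixed variance
#' components (the BLUP-SNP model: the marker-level dominance model with
#' known variances).  The default `"genotypic"` design uses incidence
#' matrices `T` coded `{-1, 0, 1}` and `X` coded `{0, 1, 0}`, so `a` and `d`
#' are genotypic additive and dominance effects and the substitution effect
#' is `alpha = a + d (q - p)`.  The `"centered"` design uses the
#' frequency-centered matrices `W_a`, `W_d` of [marker_design()], which makes
#' the fitted genetic values exactly equal to animal-level GBLUP with
#' unscaled, unblended `G*`/`D*` when the variances are matched.
#'
#' Computed through the equivalent n-dimensional system
#' `V = sigma_a2 Z1 Z1' + sigma_d2 Z2 Z2' + sigmaE2 diag(1/EOP)`:
#' `a_hat = sigma_a2 Z1' V^-1 (y - mu_hat)` (ridge-type shrinkage
#' `sigmaE2/sigma_a2` and `sigmaE2/sigma_d2`).
#'
#' @param y named numeric vector of phenotypes or phenotype data.frame
#'   (`id`, `yd`, `eop`).
#' @param genotypes a [genotype_matrix()] without missing codes, covering the
#'   phenotyped individuals.
#' @param sigma_a2,sigma_d2 fixed per-marker variances (e.g. from
#'   [animal_to_marker_variance()]); `sigma_a2` must be positive.
#' @param sigmaE2 fixed residual variance.
#' @param eop residual weights (ignored when `y` is a data.frame).
#' @param design `"genotypic"` (default) or `"centered"`.
#' @return A `marker_effects` data.frame (`locus`, `a`, `d`) with attributes
#'   `"mu"` and `"design"`.
#' @export
snp_blup_effects <- function(y, genotypes, sigma_a2, sigma_d2, sigmaE2,
                             eop = 1, design = c("genotypic", "centered")) {
  design <- match.arg(design)
  if (is.data.frame(y)) {
    eop <- y$eop
    y <- stats::setNames(y$yd, as.character(y$id))
  }
  if (sigma_a2 <= 0) stop("sigma_a2 must be positive")
  if (sigma_d2 < 0) stop("sigma_d2 must be non-negative")
  stopifnot(inherits(genotypes, "geno_matrix"))
  codes <- genotypes$codes[names(y), , drop = FALSE]
  if (anyNA(codes)) stop("genotypes contain missing codes; run apply_qc() first")
  if (design == "genotypic") {
    Z1 <- codes - 1
    Z2 <- (codes == 1) * 1
  } else {
    d <- marker_design(geno_subset(genotypes, names(y)), p = genotypes$p)
    Z1 <- d$W_a
    Z2 <- d$W_d
  }
  n <- length(y)
  w <- rep_len(eop, n)
  V <- sigma_a2 * tcrossprod(Z1) + sigmaE2 * diag(1 / w, n)
  if (sigma_d2 > 0) V <- V + sigma_d2 * tcrossprod(Z2)
  Vinv <- chol2inv(chol(V))
  mu <- sum(Vinv %*% y) / sum(Vinv)
  sol <- Vinv %*% (y - mu)
  a <- drop(sigma_a2 * crossprod(Z1, sol))
  d_eff <- if (sigma_d2 > 0) drop(sigma_d2 * crossprod(Z2, sol)) else numeric(ncol(Z1))
  out <- structure(data.frame(locus = colnames(codes), a = a, d = d_eff,
                              stringsAsFactors = FALSE),
                   class = c("marker_effects", "data.frame"))
  attr(out, "mu") <- mu
  attr(out, "design") <- design
  out
}

#' Mendelian genotype probabilities of an offspring
#'
#' Per-locus distribution of the offspring genotype from independent
#' transmission of one allele per parent: with transmission probabilities
#' `t = code/2` for the A1 allele, `Pr(A1A1) = ts td`,
#' `Pr(A1A2) = ts(1-td) + (1-ts)td`, `Pr(A2A2) = (1-ts)(1-td)`.
#'
#' @param sire_codes,dam_codes numeric vectors of parental genotype codes
#'   (0/1/2), one per locus.
#' @return m x 3 matrix with columns `AA`, `Aa`, `aa`; each row sums to 1.
#' @export
offspring_genotype_probs <- function(sire_codes, dam_codes) {
  stopifnot(length(sire_codes) == length(dam_codes),
            all(sire_codes %in% 0:2), all(dam_codes %in% 0:2))
  ts <- sire_codes / 2
  td <- dam_codes / 2
  cbind(AA = ts * td,
        Aa = ts * (1 - td) + (1 - ts) * td,
        aa = (1 - ts) * (1 - td))
}

#' Expected total genetic value and breeding value of a mating
#'
#' Evaluates, for one sire x dam pair,
#' `g_hat = sum_k Pr(AA) a_k + Pr(Aa) d_k - Pr(aa) a_k` and
#' `u_hat = sum_k [Pr(AA)(2-2p) + Pr(Aa)(1-2p) - Pr(aa) 2p] alpha_k` with
#' `alpha_k = a_k + d_k (q_k - p_k)`.
#'
#' @param probs genotype probabilities from [offspring_genotype_probs()].
#' @param effects a `marker_effects` data.frame.
#' @param p allele frequencies used for centering and substitution effects.
#' @return named numeric vector `c(g_hat, u_hat)`.
#' @export
predict_mating <- function(probs, effects, p) {
  stopifnot(nrow(probs) == nrow(effects), length(p) == nrow(effects))
  alpha <- alpha_effects(effects, p)
  g <- sum((probs[, "AA"] - probs[, "aa"]) * effects$a + probs[, "Aa"] * effects$d)
  dose <- 2 * probs[, "AA"] + probs[, "Aa"]
  u <- sum((dose - 2 * p) * alpha)
  c(g_hat = g, u_hat = u)
}

#' Expected offspring values for all sire x dam pairs
#'
#' Vectorized evaluation of [predict_mating()] over every bull x cow pair.
#' Breeding values obey the parent-average law
#' `u_ij = (u_sire + u_dam) / 2`; total genetic values additionally carry
#' the mating-specific expected dominance deviation.
#'
#' @param genotypes a [genotype_matrix()] holding bulls and cows (allele
#'   frequencies of this matrix are used for centering).
#' @param effects a `marker_effects` data.frame.
#' @param bulls,cows character vectors of ids.
#' @return list of class `mating_scores` with matrices `g` and `u`
#'   (bulls x cows), and the component effects used.
#' @export
mating_scores <- function(genotypes, effects, bulls, cows) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  p <- genotypes$p
  alpha <- alpha_effects(effects, p)
  cb <- genotypes$codes[bulls, , drop = FALSE]
  cc <- genotypes$codes[cows, , drop = FALSE]
  if (anyNA(cb) || anyNA(cc)) stop("missing parental genotypes are not supported")
  tb <- cb / 2
  tc <- cc / 2
  # additive (genotypic-a) part: sum (ts + td - 1) a
  ga_b <- drop((tb - 0.5) %*% effects$a)
  ga_c <- drop((tc - 0.5) %*% effects$a)
  # dominance part: sum (ts + td) d - 2 sum ts td d
  gd_b <- drop(tb %*% effects$d)
  gd_c <- drop(tc %*% effects$d)
  cross <- sweep(tb, 2, effects$d, "*") %*% t(tc)
  g <- outer(ga_b, ga_c, "+") + outer(gd_b, gd_c, "+") - 2 * cross
  # breeding values: parent average of per-animal centered dosages
  bv_b <- drop(sweep(cb, 2, 2 * p) %*% alpha)
  bv_c <- drop(sweep(cc, 2, 2 * p) %*% alpha)
  u <- outer(bv_b / 2, bv_c / 2, "+")
  dimnames(g) <- dimnames(u) <- list(bulls, cows)
  structure(list(g = g, u = u, effects = effects, bulls = bulls, cows = cows),
            class = "mating_scores")
}

#' Select matings under a per-bull capacity constraint
#'
#' Greedy global allocation: all bull x cow pairs are sorted by the selection
#' criterion in decreasing order (ties broken by bull then cow position) and
#' a pair is accepted when the cow is still unassigned and the bull is below
#' the capacity `cap`.  Every cow ends up assigned provided
#' `length(bulls) * cap >= length(cows)`.
#'
#' @param scores a [mating_scores()] object.
#' @param criterion `"g"` (total genetic value, default) or `"u"` (breeding
#'   value).
#' @param cap maximum number of cows per bull, default 200.
#' @return list of class `mating_plan`: `assignment` (data.frame `cow`,
#'   `bull`, `g_hat`, `u_hat`), `usage` (cows per bull), `criterion`, `cap`.
#' @export
allocate_matings <- function(scores, criterion = c("g", "u"), cap = 200) {
  criterion <- match.arg(criterion)
  S <- scores[[criterion]]
  nb <- nrow(S); nc <- ncol(S)
  if (nb * cap < nc)
    stop("infeasible: ", nb, " bulls with capacity ", cap,
         " cannot cover ", nc, " cows")
  bi <- rep(seq_len(nb), times = nc)
  ci <- rep(seq_len(nc), each = nb)
  ord <- order(-as.vector(S), bi, ci)
  assigned <- integer(nc)        # bull index per cow, 0 = unassigned
  usage <- integer(nb)
  left <- nc
  for (k in ord) {
    b <- bi[k]; cw <- ci[k]
    if (assigned[cw] == 0L && usage[b] < cap) {
      assigned[cw] <- b
      usage[b] <- usage[b] + 1L
      left <- left - 1L
      if (left == 0L) break
    }
  }
  assignment <- data.frame(
    cow = scores$cows,
    bull = scores$bulls[assigned],
    g_hat = scores$g[cbind(assigned, seq_len(nc))],
    u_hat = scores$u[cbind(assigned, seq_len(nc))],
    stringsAsFactors = FALSE)
  structure(list(assignment = assignment,
                 usage = stats::setNames(usage, scores$bulls),
                 criterion = criterion, cap = cap),
            class = "mating_plan")
}

#' @export
print.mating_plan <- function(x, ...) {
  cat("<mating_plan> ", nrow(x$assignment), " cows assigned to ",
      sum(x$usage > 0), " bulls (criterion ", x$criterion,
      ", cap ", x$cap, ")\n", sep = "")
  u <- sort(x$usage[x$usage > 0], decreasing = TRUE)
  cat("  cows per used bull:", paste(u, collapse = ", "), "\n")
  invisible(x)
}

#' Expected genetic gain of a mating plan
#'
#' Expected total genetic superiority `Delta G` and additive genetic gain
#' `Delta U`: the difference between the mean expected `g_hat` (resp.
#' `u_hat`) of the selected matings and the mean over all possible matings,
#' in trait units and relative to the standard deviation of `g_hat` (resp.
#' `u_hat`) over all possible matings.
#'
#' @param plan a [allocate_matings()] plan.
#' @param scores the [mating_scores()] the plan was selected from.
#' @return list of class `gain_summary`: `delta_g`, `delta_u`, `sd_g`,
#'   `sd_u`, `rel_g`, `rel_u`, `criterion`.
#' @export
gain_summary <- function(plan, scores) {
  sd_g <- sd(as.vector(scores$g))
  sd_u <- sd(as.vector(scores$u))
  delta_g <- mean(plan$assignment$g_hat) - mean(scores$g)
  delta_u <- mean(plan$assignment$u_hat) - mean(scores$u)
  structure(list(delta_g = delta_g, delta_u = delta_u,
                 sd_g = sd_g, sd_u = sd_u,
                 rel_g = delta_g / sd_g, rel_u = delta_u / sd_u,
                 criterion = plan$criterion),
            class = "gain_summary")
}

#' @export
print.gain_summary <- function(x, ...) {
  cat("<gain_summary> selection on ", x$criterion, "\n",
      "  Delta G = ", format(x$delta_g, digits = 4), " (",
      format(x$rel_g, digits = 3), " SD)\n",
      "  Delta U = ", format(x$delta_u, digits = 4), " (",
      format(x$rel_u, digits = 3), " SD)\n", sep = "")
  invisible(x)
}

#' Compare selection on total genetic value versus breeding value
#'
#' From the SD-relative gains of the two plans, computes the percentage
#' increase in expected total genetic superiority and the percentage
#' reduction in expected additive genetic gain obtained by selecting matings
#' on `g_hat` instead of `u_hat`.
#'
#' @param gain_g a [gain_summary()] of the plan selected on `g` (or the
#'   SD-relative `Delta G` value itself).
#' @param gain_u a [gain_summary()] of the plan selected on `u` (or the
#'   SD-relative value).
#' @param rel_u_g,rel_u_u SD-relative `Delta U` values; only used when
#'   `gain_g`/`gain_u` are given as bare numbers.
#' @return list with `delta_g_increase_pct` and `delta_u_reduction_pct`.
#' @export
compare_mating_criteria <- function(gain_g, gain_u, rel_u_g = NULL,
                                    rel_u_u = NULL) {
  if (inherits(gain_g, "gain_summary")) {
    rel_g_g <- gain_g$rel_g; rel_u_g <- gain_g$rel_u
    rel_g_u <- gain_u$rel_g; rel_u_u <- gain_u$rel_u
  } else {
    rel_g_g <- gain_g; rel_g_u <- gain_u
    stopifnot(!is.null(rel_u_g), !is.null(rel_u_u))
  }
  list(delta_g_increase_pct = 100 * (rel_g_g - rel_g_u) / rel_g_u,
       delta_u_reduction_pct = 100 * (rel_u_u - rel_u_g) / rel_u_u)
}
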