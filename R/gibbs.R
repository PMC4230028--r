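new_mcmc_chain <- function(samples, n_iter, burn_in, thin, seed, extra = list()) {
  structure(c(list(samples = samples, n_iter = n_iter, burn_in = burn_in,
                   thin = thin, seed = seed), extra),
            class = "mcmc_chain")
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat("<mcmc_chain> ", nrow(x$samples), " retained samples (",
      x$n_iter, " iterations, burn-in ", x$burn_in, ", thinning ", x$thin,
      ", seed ", x$seed, ")\n", sep = "")
  print(chain_summary(x))
  invisible(x)
}

#' Posterior summary of a Gibbs chain
#'
#' Posterior mean, posterior standard deviation and Monte-Carlo standard
#' error (posterior SD divided by the square root of the effective sample
#' size, estimated from the AR-fitted spectral density at frequency zero)
#' for each sampled parameter.
#'
#' @param chain an `mcmc_chain`.
#' @return data.frame with columns `parameter`, `mean`, `sd`, `mcse`.
#' @export
chain_summary <- function(chain) {
  stopifnot(inherits(chain, "mcmc_chain"))
  s <- chain$samples
  out <- data.frame(parameter = colnames(s),
                    mean = colMeans(s),
                    sd = apply(s, 2, sd),
                    mcse = apply(s, 2, function(x) {
                      s0 <- .spectrum0(x)
                      if (is.na(s0)) NA_real_ else sqrt(s0 / length(x))
                    }),
                    row.names = NULL)
  out
}

# spectral density at frequency zero via AR fit (order by AIC)
.spectrum0 <- function(x) {
  if (length(unique(x)) < 3 || sd(x) == 0) return(NA_real_)
  fit <- tryCatch(ar(x, aic = TRUE, order.max = min(30, length(x) %/% 4)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NA_real_)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Gibbs sampling of the animal-level dominance model
#'
#' Samples the model of `spec` (MG or MGD) with single-site updates of the
#' location effects and scaled inverse chi-square updates of the variance
#' components under flat (improper) priors, the scheme of classical animal
#' breeding Gibbs software.  Deterministic given `seed` (R's RNG is used
#' inside the compiled sampler).  Variance proposals below
#' `1e-10 * var(y)` are pinned to that floor and counted.
#'
#' @param spec a [model_spec()] with model `"MG"` or `"MGD"`.
#' @param matrices named list with the blended, positive-definite `G` (and
#'   `D` for MGD).
#' @param n_iter,burn_in,thin chain length controls; defaults 20000 / 2000 /
#'   10 give 1800 retained samples.
#' @param seed integer seed.
#' @param start optional named starting values (`sigmaA2`, `sigmaD2`,
#'   `sigmaE2`).
#' @return An `mcmc_chain` whose `samples` matrix has columns `mu`,
#'   `sigmaA2`, (`sigmaD2`,) `sigmaE2` and, for MGD, the per-sample
#'   dominance ratio `dom_ratio = sigmaD2 / (sigmaA2 + sigmaD2)`; posterior
#'   means of `u` (and `v`) are attached as `u_mean`, `v_mean`.
#' @export
gibbs_animal <- function(spec, matrices, n_iter = 20000, burn_in = 2000,
                         thin = 10, seed = 1L, start = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$model == "MA") stop("gibbs_animal supports models MG and MGD")
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  kernels <- .model_kernels(spec, matrices)
  dominance <- spec$model == "MGD"
  Ginv <- chol2inv(chol(kernels[[1]]))
  Dinv <- if (dominance) chol2inv(chol(kernels[[2]])) else matrix(0, 0, 0)
  y <- spec$y
  vy <- var(y)
  s0 <- list(sigmaA2 = vy / 3, sigmaD2 = vy / 3, sigmaE2 = vy / 3)
  if (!is.null(start)) s0[names(start)] <- start
  set.seed(seed)
  res <- .gibbs_animal_cpp(y, spec$eop, Ginv, Dinv, dominance,
                           as.integer(n_iter), as.integer(burn_in),
                           as.integer(thin),
                           s0$sigmaA2, s0$sigmaD2, s0$sigmaE2, 1e-10 * vy)
  samples <- res$samples
  colnames(samples) <- if (dominance) c("mu", "sigmaA2", "sigmaD2", "sigmaE2")
                       else c("mu", "sigmaA2", "sigmaE2")
  if (dominance) {
    ratio <- samples[, "sigmaD2"] / (samples[, "sigmaA2"] + samples[, "sigmaD2"])
    samples <- cbind(samples, dom_ratio = ratio)
  }
  u_mean <- stats::setNames(res$u_mean, spec$ids)
  v_mean <- if (dominance) stats::setNames(res$v_mean, spec$ids) else NULL
  new_mcmc_chain(samples, n_iter, burn_in, thin, seed,
                 extra = list(model = spec$model, u_mean = u_mean,
                              v_mean = v_mean, floor_hits = res$floor_hits))
}

#' Gibbs sampling of the marker-level dominance model (MGD-SNP / BLUP-SNP)
#'
#' Samples `y = mu + T a + X d + e` with incidence matrices `T` coded
#' `{-1, 0, 1}` and `X` coded `{0, 1, 0}` from genotype codes 2/1/0,
#' `V(a) = I sigma_a2`, `V(d) = I sigma_d2` and EOP-weighted residuals.
#' Sampling order within an iteration: mean, all additive effects, all
#' dominance effects, variances (single-site updates).  When
#' `fixed_variances` is supplied the three variances are held fixed
#' (BLUP-SNP mode).  Animal-level components are derived per retained sample
#' via [marker_to_animal_variance()] at the allele frequencies of
#' `genotypes`.
#'
#' @param y named numeric vector of phenotypes (or phenotype data.frame with
#'   `id`, `yd`, `eop`).
#' @param genotypes a [genotype_matrix()] without missing or monomorphic
#'   loci, rows matching `y`.
#' @param eop residual weights (ignored if `y` is a data.frame).
#' @param n_iter,burn_in,thin chain length controls.
#' @param seed integer seed.
#' @param fixed_variances optional named list/vector with `sigma_a2`,
#'   `sigma_d2`, `sigmaE2` to hold fixed.
#' @return An `mcmc_chain` with sampled `mu`, `sigma_a2`, `sigma_d2`,
#'   `sigmaE2`, derived `sigmaA2`, `sigmaD2`, `dom_ratio`, and posterior-mean
#'   marker effects in `effects` (a `marker_effects` data.frame).
#' @export
gibbs_snp <- function(y, genotypes, eop = 1, n_iter = 20000, burn_in = 2000,
                      thin = 10, seed = 1L, fixed_variances = NULL) {
  if (is.data.frame(y)) {
    eop <- y$eop
    ids <- as.character(y$id)
    y <- stats::setNames(y$yd, ids)
  }
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  codes <- genotypes$codes[names(y), , drop = FALSE]
  if (anyNA(codes)) stop("genotypes contain missing codes; run apply_qc() first")
  mono <- genotypes$p <= 0 | genotypes$p >= 1
  if (any(mono)) stop("monomorphic marker columns present (", sum(mono),
                      "); run apply_qc() first")
  Tm <- codes - 1
  Xm <- (codes == 1) * 1
  w <- rep_len(eop, length(y))
  vy <- var(y)
  p <- genotypes$p
  ca <- 2 * sum(p * (1 - p))
  cd <- 4 * sum(p^2 * (1 - p)^2)
  if (is.null(fixed_variances)) {
    s0 <- c(sigma_a2 = vy / 3 / ca, sigma_d2 = vy / 3 / cd, sigmaE2 = vy / 3)
    update <- TRUE
  } else {
    fv <- unlist(fixed_variances)
    stopifnot(all(c("sigma_a2", "sigma_d2", "sigmaE2") %in% names(fv)))
    if (fv[["sigma_a2"]] <= 0) stop("sigma_a2 must be positive")
    s0 <- fv
    update <- FALSE
  }
  set.seed(seed)
  res <- .gibbs_snp_cpp(as.numeric(y), w, Tm, Xm,
                        as.integer(n_iter), as.integer(burn_in),
                        as.integer(thin),
                        s0[["sigma_a2"]], s0[["sigma_d2"]], s0[["sigmaE2"]],
                        update, 1e-14 * vy)
  samples <- res$samples
  colnames(samples) <- c("mu", "sigma_a2", "sigma_d2", "sigmaE2")
  an <- t(apply(samples, 1, function(r)
    marker_to_animal_variance(r[["sigma_a2"]], r[["sigma_d2"]], p)))
  samples <- cbind(samples, an,
                   dom_ratio = an[, "sigmaD2"] / (an[, "sigmaA2"] + an[, "sigmaD2"]))
  effects <- structure(data.frame(locus = colnames(codes),
                                  a = res$a_mean, d = res$d_mean,
                                  stringsAsFactors = FALSE),
                       class = c("marker_effects", "data.frame"))
  new_mcmc_chain(samples, n_iter, burn_in, thin, seed,
                 extra = list(model = if (update) "MGD_SNP" else "BLUP_SNP",
                              effects = effects, p = p,
                              floor_hits = res$floor_hits))
}

#' Geweke convergence diagnostic
#'
#' Z-score comparing the mean of the first `frac1` and the last `frac2` of a
#' retained chain, with variances of the segment means estimated from the
#' spectral density at frequency zero (AR fit).  Large absolute z-scores
#' indicate that the chain has not reached its stationary distribution.
#'
#' @param chain an `mcmc_chain` (or a numeric matrix of samples).
#' @param frac1 fraction of the chain forming the early window, default 0.1.
#' @param frac2 fraction forming the late window, default 0.5.
#' @return named numeric vector of z-scores, `NA` (with a warning) for
#'   degenerate (constant) chains.
#' @export
geweke_diagnostic <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  s <- if (inherits(chain, "mcmc_chain")) chain$samples else as.matrix(chain)
  stopifnot(frac1 > 0, frac2 > 0, frac1 + frac2 <= 1)
  n <- nrow(s)
  i1 <- seq_len(max(2, floor(frac1 * n)))
  i2 <- seq(n - max(2, floor(frac2 * n)) + 1, n)
  z <- apply(s, 2, function(x) {
    x1 <- x[i1]; x2 <- x[i2]
    s1 <- .spectrum0(x1); s2 <- .spectrum0(x2)
    if (is.na(s1) || is.na(s2) || (s1 + s2) == 0) return(NA_real_)
    (mean(x1) - mean(x2)) / sqrt(s1 / length(x1) + s2 / length(x2))
  })
  if (anyNA(z)) warning("degenerate (constant) chain: Geweke z undefined for ",
                        paste(names(z)[is.na(z)], collapse = ", "))
  z
}
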