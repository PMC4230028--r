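#' Model specification for animal-level mixed models
#'
#' All models have the overall mean as the only fixed effect, one record per
#' individual and residual covariance `F sigmaE2` with `F = diag(1/EOP)`:
#' * `MA`:  `y = mu + u + e`, `V(u) = A sigmaA2` (pedigree relationships)
#' * `MG`:  `y = mu + u + e`, `V(u) = G sigmaA2` (genomic relationships)
#' * `MGD`: `y = mu + u + v + e`, `V(u) = G sigmaA2`, `V(v) = D sigmaD2`
#'
#' @param y named numeric vector of yield deviations (names are ids), or a
#'   phenotype data.frame with columns `id`, `yd`, `eop`.
#' @param eop positive residual weights (effective number of own
#'   performances); recycled; ignored when `y` is a phenotype data.frame.
#' @param model one of `"MA"`, `"MG"`, `"MGD"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(y, eop = 1, model = c("MGD", "MG", "MA")) {
  model <- match.arg(model)
  if (is.data.frame(y)) {
    stopifnot(all(c("id", "yd", "eop") %in% names(y)))
    eop <- y$eop
    ids <- as.character(y$id)
    y <- y$yd
  } else {
    ids <- names(y)
    if (is.null(ids)) stop("y must be named by individual id")
  }
  eop <- rep_len(eop, length(y))
  stopifnot(all(eop > 0), !anyNA(y))
  structure(list(y = as.numeric(y), ids = ids, eop = as.numeric(eop),
                 model = model),
            class = "model_spec")
}

# kernel list required by a model, aligned to the model_spec ids
.model_kernels <- function(spec, matrices) {
  need <- switch(spec$model, MA = "A", MG = "G", MGD = c("G", "D"))
  if (!all(need %in% names(matrices)))
    stop("model ", spec$model, " needs matrices: ", paste(need, collapse = ", "))
  lapply(matrices[need], function(M) {
    if (!all(spec$ids %in% rownames(M)))
      stop("relationship matrix does not cover all ids in the model")
    M[spec$ids, spec$ids]
  })
}

# -2 log restricted likelihood and derivative ingredients at theta
# kernels: list of covariance structures; F = diag(1/w) appended internally.
.reml_eval <- function(y, X, kernels, w, theta) {
  n <- length(y)
  nk <- length(kernels)
  V <- diag(theta[nk + 1] / w, n)
  for (i in seq_len(nk)) V <- V + theta[i] * kernels[[i]]
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(NULL)
  Vinv <- chol2inv(cV)
  VX <- Vinv %*% X
  XtVX <- crossprod(X, VX)
  P <- Vinv - VX %*% solve(XtVX, t(VX))
  Py <- P %*% y
  neg2 <- (n - ncol(X)) * log(2 * pi) + 2 * sum(log(diag(cV))) +
    determinant(XtVX, logarithm = TRUE)$modulus[1] + sum(y * Py)
  list(P = P, Py = Py, Vinv = Vinv, XtVX = XtVX, neg2 = as.numeric(neg2))
}

#' REML estimation of variance components (average information)
#'
#' Fits the model in `spec` by restricted maximum likelihood using
#' average-information updates with an expectation-maximization fallback
#' whenever an AI step proposes a negative component or decreases the
#' restricted likelihood.  Convergence is declared when the relative change
#' of every parameter is below `tol`.  Estimates are constrained to a small
#' positive floor (`1e-10 * var(y)`); a component ending on the floor is
#' flagged as a boundary estimate.
#'
#' The reported `-2 log restricted likelihood` includes all terms
#' (`(n-1) log 2 pi + log|V| + log|X'V^-1 X| + y'Py`) with the same fixed
#' mean across models, so differences between nested fits are valid
#' likelihood-ratio statistics.
#'
#' @param spec a [model_spec()].
#' @param matrices named list of relationship matrices; `A` for model MA,
#'   `G` for MG, `G` and `D` for MGD (blended, positive definite).
#' @param tol relative-change convergence tolerance, default `1e-8`.
#' @param max_iter maximum number of iterations, default 200.
#' @param init optional numeric vector of starting values (one per random
#'   component, residual last).
#' @return An object of class `gblup_fit`: list with `components` (named
#'   estimates: `sigmaA2`, `sigmaD2` if applicable, `sigmaE2`), `se`
#'   (asymptotic, from the inverse AI matrix), `neg2logL`, `mu`, `u`, `v`,
#'   `g = u + v`, `converged`, `iterations`, `boundary` and the likelihood
#'   trace.
#' @export
reml_fit <- function(spec, matrices, tol = 1e-8, max_iter = 200, init = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  kernels <- .model_kernels(spec, matrices)
  y <- spec$y
  w <- spec$eop
  n <- length(y)
  X <- matrix(1, n, 1)
  nk <- length(kernels)
  np <- nk + 1
  floor_val <- 1e-10 * var(y)
  theta <- if (is.null(init)) rep(var(y) / np, np) else {
    stopifnot(length(init) == np); pmax(init, floor_val)
  }
  Klist <- c(kernels, list(diag(1 / w, n)))  # residual structure last
  trace <- numeric(0)
  ev <- .reml_eval(y, X, kernels, w, theta)
  if (is.null(ev)) stop("covariance matrix not positive definite at start; ",
                        "check that G and D are blended")
  converged <- FALSE
  iter <- 0
  AI <- NULL
  repeat {
    iter <- iter + 1
    trace <- c(trace, ev$neg2)
    Py <- ev$Py
    KPy <- lapply(Klist, function(K) K %*% Py)
    trPK <- vapply(Klist, function(K) sum(ev$P * K), numeric(1))  # tr(PK), symmetric K
    yPKPy <- vapply(KPy, function(q) sum(Py * q), numeric(1))
    score <- -0.5 * (trPK - yPKPy)
    AI <- matrix(0, np, np)
    PKPy <- lapply(KPy, function(q) ev$P %*% q)
    for (i in seq_len(np)) for (j in i:np) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
    }
    step_ai <- tryCatch(solve(AI, score), error = function(e) NULL)
    used_em <- FALSE
    ev_new <- NULL
    if (!is.null(step_ai)) {
      # AI proposal, clamped at the floor so boundary estimates are reached
      # in one step rather than by slow EM decay
      prop <- pmax(theta + step_ai, floor_val)
      ev_new <- .reml_eval(y, X, kernels, w, prop)
    }
    if (is.null(ev_new) || ev_new$neg2 > ev$neg2 + 1e-8) {
      # EM fallback: monotone in the restricted likelihood
      prop <- pmax(theta + theta^2 * (yPKPy - trPK) / n, floor_val)
      used_em <- TRUE
      ev_new <- .reml_eval(y, X, kernels, w, prop)
    }
    if (is.null(ev_new)) break
    rel <- max(abs(prop - theta) / (abs(theta) + tol))
    theta <- prop
    ev <- ev_new
    if (rel < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  # BLUPs and fixed mean at the final estimates
  XtVXinv <- solve(ev$XtVX)
  mu <- drop(XtVXinv %*% crossprod(X, ev$Vinv %*% y))
  Py <- ev$Py
  u <- drop(theta[1] * kernels[[1]] %*% Py)
  v <- if (nk == 2) drop(theta[2] * kernels[[2]] %*% Py) else NULL
  names(u) <- spec$ids
  if (!is.null(v)) names(v) <- spec$ids
  comp_names <- c(if (spec$model == "MGD") c("sigmaA2", "sigmaD2")
                  else "sigmaA2", "sigmaE2")
  components <- stats::setNames(theta, comp_names)
  se <- tryCatch(sqrt(diag(solve(AI))), error = function(e) rep(NA_real_, np))
  structure(list(
    model = spec$model,
    components = components,
    se = stats::setNames(se, comp_names),
    neg2logL = ev$neg2,
    mu = mu,
    u = u, v = v,
    g = if (!is.null(v)) u + v else u,
    converged = converged,
    iterations = iter,
    boundary = stats::setNames(theta <= floor_val * (1 + 1e-6), comp_names),
    trace = trace
  ), class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("<gblup_fit> model ", x$model, "; -2logL = ", format(x$neg2logL),
      if (!x$converged) "  [NOT converged]", "\n", sep = "")
  print(round(rbind(estimate = x$components, se = x$se), 6))
  invisible(x)
}

#' Mixture chi-square likelihood ratio test for a variance component
#'
#' Tests the null hypothesis that a single variance component is zero using
#' the boundary-corrected reference distribution, an equal mixture of
#' chi-square distributions with 0 and 1 degrees of freedom:
#' `P = 0.5 * Pr(chi2_1 >= statistic)` for positive statistics and `P = 1`
#' otherwise (negative statistics can arise from numerical rounding in the
#' two optimizations and are evidence for the null).
#'
#' @param neg2logL_reduced `-2 log restricted likelihood` of the reduced
#'   model (e.g. MG).
#' @param neg2logL_full same for the full model (e.g. MGD).
#' @return list with `chisq` and `p_value`.
#' @export
mixture_lrt <- function(neg2logL_reduced, neg2logL_full) {
  chisq <- neg2logL_reduced - neg2logL_full
  p <- if (chisq <= 0) 1 else 0.5 * pchisq(chisq, df = 1, lower.tail = FALSE)
  list(chisq = chisq, p_value = p)
}
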