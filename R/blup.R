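#' Solve the mixed-model equations at fixed variance components
#'
#' Best linear unbiased predictions of breeding values (`u`), dominance
#' deviations (`v`, model MGD) and total genetic values (`g = u + v`) for a
#' set of individuals, using the phenotypes of the training individuals only.
#' The overall mean is estimated by generalized least squares within the
#' training set; predictions for individuals outside the training set come
#' from the joint covariance structure,
#' `u_hat = sigmaA2 * K[predict, train] V^-1 (y - mu_hat)`.
#'
#' @param spec a [model_spec()] covering (at least) the training records.
#' @param components named variance components (`sigmaA2`, `sigmaE2`, plus
#'   `sigmaD2` for MGD), e.g. from [reml_fit()].
#' @param matrices named list of relationship matrices covering the union of
#'   training and prediction ids.
#' @param train_ids ids whose phenotypes enter the equations; defaults to all
#'   ids of `spec`.
#' @param predict_ids ids for which predictions are returned; defaults to
#'   `train_ids`.
#' @return data.frame with columns `id`, `u`, (`v`,) `g` and attribute
#'   `"mu"`.
#' @export
blup_solve <- function(spec, components, matrices, train_ids = NULL,
                       predict_ids = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(train_ids)) train_ids <- spec$ids
  if (is.null(predict_ids)) predict_ids <- train_ids
  it <- match(train_ids, spec$ids)
  if (anyNA(it)) stop("train ids missing from the model spec")
  need <- switch(spec$model, MA = "A", MG = "G", MGD = c("G", "D"))
  comp_names <- c("sigmaA2", if (spec$model == "MGD") "sigmaD2", "sigmaE2")
  components <- unlist(components)
  if (!all(comp_names %in% names(components)))
    stop("components must contain: ", paste(comp_names, collapse = ", "))
  for (nm in need) {
    M <- matrices[[nm]]
    if (is.null(M) || !all(c(train_ids, predict_ids) %in% rownames(M)))
      stop("relationship matrix ", nm, " does not cover all train/predict ids")
  }
  y <- spec$y[it]
  w <- spec$eop[it]
  n <- length(y)
  sA <- components[["sigmaA2"]]
  sD <- if (spec$model == "MGD") components[["sigmaD2"]] else 0
  sE <- components[["sigmaE2"]]
  K1 <- matrices[[need[1]]]
  V <- sA * K1[train_ids, train_ids] + diag(sE / w, n)
  if (spec$model == "MGD") {
    K2 <- matrices[["D"]]
    V <- V + sD * K2[train_ids, train_ids]
  }
  cV <- chol(V)
  Vinv <- chol2inv(cV)
  one <- rep(1, n)
  mu <- sum(Vinv %*% y) / sum(Vinv)
  sol <- Vinv %*% (y - mu)
  u <- drop(sA * K1[predict_ids, train_ids, drop = FALSE] %*% sol)
  out <- data.frame(id = predict_ids, u = u, stringsAsFactors = FALSE)
  if (spec$model == "MGD") {
    out$v <- drop(sD * K2[predict_ids, train_ids, drop = FALSE] %*% sol)
    out$g <- out$u + out$v
  } else {
    out$g <- out$u
  }
  attr(out, "mu") <- mu
  out
}

# validation-fold accuracy r and regression slope b of y on predictions,
# optionally EOP-weighted
.cv_stats <- function(yv, pred, wv = rep(1, length(yv)), weighted = FALSE) {
  if (weighted) {
    my <- sum(wv * yv) / sum(wv); mp <- sum(wv * pred) / sum(wv)
    cv <- sum(wv * (yv - my) * (pred - mp)) / sum(wv)
    vp <- sum(wv * (pred - mp)^2) / sum(wv)
    vy <- sum(wv * (yv - my)^2) / sum(wv)
    c(r = cv / sqrt(vp * vy), b = cv / vp)
  } else {
    c(r = cor(yv, pred), b = stats::cov(yv, pred) / var(pred))
  }
}

#' Random K-fold assignment
#'
#' Uniform random partition of `ids` into `K` folds whose sizes differ by at
#' most one; deterministic given `seed`.
#'
#' @param ids individual ids.
#' @param K number of folds, default 10.
#' @param seed integer seed.
#' @return data.frame with columns `id`, `fold`.
#' @export
make_folds <- function(ids, K = 10, seed = 1L) {
  stopifnot(K >= 2, length(ids) >= K)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(K), length(ids)))
  data.frame(id = as.character(ids), fold = fold, stringsAsFactors = FALSE)
}

#' Cross-validated accuracy and bias of genomic predictions
#'
#' For each fold, predictions are computed from the other folds' phenotypes
#' at the fixed variance components, and two statistics are evaluated in the
#' validation fold: the Pearson correlation between yield deviations and
#' predictions (accuracy, `r`) and the least-squares slope of the regression
#' of yield deviations on predictions (bias, `b`; 1 = unbiased).  Both are
#' reported for breeding values (`u`) and, under MGD, for total genetic
#' values (`g`).  Fold statistics are averaged arithmetically and the
#' standard error is the standard deviation over folds divided by `sqrt(K)`.
#'
#' @inheritParams blup_solve
#' @param folds a fold assignment from [make_folds()].
#' @param weighted logical; if `TRUE` the validation statistics are
#'   EOP-weighted (default `FALSE`, unweighted).
#' @return list of class `cv_result` with `per_fold` (data.frame `fold`,
#'   `r_u`, `b_u`, `r_g`, `b_g`) and `summary` (mean and SE per statistic).
#' @export
cross_validate <- function(spec, components, matrices, folds,
                           weighted = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  K <- max(folds$fold)
  sizes <- table(folds$fold)
  if (any(sizes < 3)) stop("every fold needs at least 3 individuals")
  stats_one <- function(yv, pred, wv) .cv_stats(yv, pred, wv, weighted)
  rows <- lapply(seq_len(K), function(k) {
    val_ids <- folds$id[folds$fold == k]
    train_ids <- setdiff(spec$ids, val_ids)
    pred <- blup_solve(spec, components, matrices,
                       train_ids = train_ids, predict_ids = val_ids)
    iv <- match(val_ids, spec$ids)
    yv <- spec$y[iv]; wv <- spec$eop[iv]
    su <- stats_one(yv, pred$u, wv)
    row <- data.frame(fold = k, r_u = su[["r"]], b_u = su[["b"]])
    if (spec$model == "MGD") {
      sg <- stats_one(yv, pred$g, wv)
      row$r_g <- sg[["r"]]; row$b_g <- sg[["b"]]
    }
    row
  })
  per_fold <- do.call(rbind, rows)
  stat_cols <- setdiff(names(per_fold), "fold")
  summary <- data.frame(
    statistic = stat_cols,
    mean = vapply(per_fold[stat_cols], mean, numeric(1)),
    se = vapply(per_fold[stat_cols], function(x) sd(x) / sqrt(K), numeric(1)),
    row.names = NULL)
  structure(list(per_fold = per_fold, summary = summary, K = K,
                 model = spec$model),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$K, "-fold cross-validation, model ", x$model, "\n", sep = "")
  print(transform(x$summary, mean = round(mean, 4), se = round(se, 4)))
  invisible(x)
}
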