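new_rel_matrix <- function(M, kind, ids = rownames(M)) {
  dimnames(M) <- list(ids, ids)
  attr(M, "kind") <- kind
  M
}

#' Kind tag of a relationship matrix
#' @param M a relationship matrix built by this package.
#' @return character tag, e.g. `"A"`, `"G_star"`, `"G"`, `"D_star"`, `"D"`.
#' @export
rel_kind <- function(M) attr(M, "kind")

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Wright's numerator relationships computed by the recursive tabular method.
#' Founders are assumed unrelated and non-inbred.  The pedigree must be
#' topologically ordered (parents before offspring); unknown parents are `NA`.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam`.
#' @return n x n relationship matrix with `id` dimnames, kind `"A"`.
#' @export
pedigree_A <- function(pedigree) {
  id <- as.character(pedigree$id)
  if (anyDuplicated(id)) stop("duplicate ids in pedigree")
  si <- match(pedigree$sire, id)
  di <- match(pedigree$dam, id)
  known_s <- !is.na(pedigree$sire)
  known_d <- !is.na(pedigree$dam)
  if (any(known_s & is.na(si)) || any(known_d & is.na(di)))
    stop("pedigree refers to parents without their own record")
  n <- length(id)
  if (any(si >= seq_len(n) | di >= seq_len(n), na.rm = TRUE))
    stop("pedigree not topologically ordered (or contains a cycle): ",
         "parents must precede offspring")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1)
      row <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) +
                    (if (!is.na(d)) A[j, d] else 0))
      A[j, i] <- A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  new_rel_matrix(A, "A", ids = id)
}

#' Centered marker designs for additive and dominance relationships
#'
#' `W_a` has entries `2 - 2 p_k`, `1 - 2 p_k`, `-2 p_k` for codes 2, 1, 0;
#' `W_d` has entries `-2 q_k^2`, `2 p_k q_k`, `-2 p_k^2`.  Imputed mean
#' dosages (non-integer codes) contribute 0 to both designs.
#'
#' @param genotypes a [genotype_matrix()] without missing codes.
#' @param p optional externally supplied allele frequencies (defaults to the
#'   frequencies stored in `genotypes`).
#' @return list with matrices `W_a`, `W_d` and denominators
#'   `denom_a = 2 sum p q`, `denom_d = 4 sum p^2 q^2`.
#' @export
marker_design <- function(genotypes, p = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  codes <- genotypes$codes
  if (anyNA(codes)) stop("missing genotype codes: run apply_qc() first")
  if (is.null(p)) p <- genotypes$p
  q <- 1 - p
  W_a <- sweep(codes, 2, 2 * p)
  is2 <- codes == 2; is1 <- codes == 1; is0 <- codes == 0
  # imputed (non-integer) codes fall in none of the classes -> 0 in both designs
  W_a[!(is2 | is1 | is0)] <- 0
  W_d <- is2 * rep(-2 * q^2, each = nrow(codes)) +
         is1 * rep(2 * p * q, each = nrow(codes)) +
         is0 * rep(-2 * p^2, each = nrow(codes))
  list(W_a = W_a, W_d = W_d,
       denom_a = 2 * sum(p * q), denom_d = 4 * sum(p^2 * q^2))
}

#' Genomic additive relationship matrix G* (VanRaden)
#'
#' `G* = W_a W_a' / (2 sum p_k q_k)` with the centered additive design of
#' [marker_design()].
#'
#' @inheritParams marker_design
#' @return n x n relationship matrix, kind `"G_star"`.
#' @export
build_G_star <- function(genotypes, p = NULL) {
  d <- marker_design(genotypes, p)
  if (d$denom_a <= 0) stop("all loci monomorphic: additive denominator is zero")
  new_rel_matrix(tcrossprod(d$W_a) / d$denom_a, "G_star",
                 ids = rownames(genotypes$codes))
}

#' Genomic dominance relationship matrix D*
#'
#' `D* = W_d W_d' / (4 sum p_k^2 q_k^2)` with the dominance design of
#' [marker_design()].
#'
#' @inheritParams marker_design
#' @return n x n relationship matrix, kind `"D_star"`.
#' @export
build_D_star <- function(genotypes, p = NULL) {
  d <- marker_design(genotypes, p)
  if (d$denom_d <= 0) stop("all loci monomorphic: dominance denominator is zero")
  new_rel_matrix(tcrossprod(d$W_d) / d$denom_d, "D_star",
                 ids = rownames(genotypes$codes))
}

#' Scale G* so its diagonal and off-diagonal means match A
#'
#' Returns `alpha + beta * G_star`, the unique affine map whose output has the
#' same mean diagonal and mean off-diagonal as `A`.
#'
#' @param G_star,A conformable relationship matrices over the same ids.
#' @return scaled relationship matrix, kind `"G_scaled"`.
#' @export
scale_to_A <- function(G_star, A) {
  stopifnot(all(dim(G_star) == dim(A)))
  n <- nrow(G_star)
  md_g <- mean(diag(G_star)); md_a <- mean(diag(A))
  off <- upper.tri(G_star)
  mo_g <- mean(G_star[off]); mo_a <- mean(A[off])
  if (abs(md_g - mo_g) < 1e-12)
    stop("degenerate scaling: mean diagonal equals mean off-diagonal in G*")
  beta <- (md_a - mo_a) / (md_g - mo_g)
  alpha <- md_a - beta * md_g
  new_rel_matrix(alpha + beta * G_star, "G_scaled", ids = rownames(G_star))
}

#' Blend a genomic matrix with its stabilizing partner
#'
#' `weight * M_star + (1 - weight) * partner`; the partner is `A` for the
#' additive matrix (giving `G = 0.95 G* + 0.05 A` at the default weight) and
#' the identity for the dominance matrix (`D = 0.95 D* + 0.05 I`), which
#' bounds the smallest eigenvalue away from zero.
#'
#' @param M_star genomic relationship matrix (scaled `G*` or `D*`).
#' @param partner blending partner matrix (`A` or `diag(n)`).
#' @param weight blending weight on the genomic matrix, default 0.95.
#' @param kind kind tag of the result, default `"G"` when the partner is a
#'   pedigree matrix and `"D"` otherwise.
#' @return blended relationship matrix.
#' @export
blend <- function(M_star, partner, weight = 0.95, kind = NULL) {
  stopifnot(all(dim(M_star) == dim(partner)), weight >= 0, weight <= 1)
  if (is.null(kind))
    kind <- if (identical(rel_kind(partner), "A")) "G" else "D"
  new_rel_matrix(weight * M_star + (1 - weight) * partner, kind,
                 ids = rownames(M_star))
}

#' Off-diagonal summary of a relationship matrix
#'
#' Mean, standard deviation and the proportion of entries exceeding
#' `threshold` in absolute value, over the strict upper triangle.
#'
#' @param M relationship matrix.
#' @param threshold absolute-value threshold, default 0.05.
#' @return list `mean`, `sd`, `prop_extreme`, `threshold`, `n_pairs`.
#' @export
offdiag_summary <- function(M, threshold = 0.05) {
  v <- M[upper.tri(M)]
  list(mean = mean(v), sd = sd(v),
       prop_extreme = mean(abs(v) > threshold),
       threshold = threshold, n_pairs = length(v))
}
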