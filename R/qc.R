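#' SNP call-rate filter
#'
#' @param genotypes a [genotype_matrix()].
#' @param threshold minimum fraction of non-missing codes; loci with call
#'   rate `>= threshold` are kept (inclusive boundary).
#' @return logical locus mask, `TRUE` = keep.
#' @export
call_rate_filter <- function(genotypes, threshold = 0.9) {
  stopifnot(inherits(genotypes, "geno_matrix"), threshold > 0, threshold <= 1)
  colMeans(!is.na(genotypes$codes)) >= threshold
}

#' Minor-allele-frequency filter
#'
#' The minor allele frequency is computed from non-missing codes.  By default
#' loci with MAF below the threshold are excluded (kept when `MAF >=
#' threshold`), the standard edit; `direction = "exclude_above"` inverts the
#' rule for completeness.
#'
#' @inheritParams call_rate_filter
#' @param threshold MAF threshold.
#' @param direction `"exclude_below"` (default) or `"exclude_above"`.
#' @return logical locus mask, `TRUE` = keep.
#' @export
maf_filter <- function(genotypes, threshold = 0.005,
                       direction = c("exclude_below", "exclude_above")) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  direction <- match.arg(direction)
  p <- colMeans(genotypes$codes, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  if (direction == "exclude_below") maf >= threshold else maf <= threshold
}

#' Hardy-Weinberg equilibrium filter
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of the observed
#' genotype counts against Hardy-Weinberg expectations at the observed allele
#' frequency.  Loci with `P >= alpha` are kept.  Monomorphic loci have an
#' undefined test and are kept by this filter (they are the MAF filter's
#' responsibility).
#'
#' @inheritParams call_rate_filter
#' @param alpha significance level below which a locus is excluded.
#' @return logical locus mask, `TRUE` = keep.
#' @export
hwe_filter <- function(genotypes, alpha = 1e-5) {
  stopifnot(inherits(genotypes, "geno_matrix"), alpha > 0, alpha < 1)
  codes <- genotypes$codes
  keep <- vapply(seq_len(ncol(codes)), function(k) {
    x <- codes[, k]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0) return(TRUE)
    n2 <- sum(x == 2); n1 <- sum(x == 1); n0 <- n - n1 - n2
    p <- (2 * n2 + n1) / (2 * n)
    if (p <= 0 || p >= 1) return(TRUE)  # monomorphic: test undefined
    expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    chi2 <- sum((c(n2, n1, n0) - expd)^2 / expd)
    pchisq(chi2, df = 1, lower.tail = FALSE) >= alpha
  }, logical(1))
  keep
}

#' Apply the SNP editing pipeline
#'
#' Applies the call-rate, MAF and Hardy-Weinberg filters conjunctively (each
#' computed on the input matrix, so the retained set is order-independent),
#' attributes each excluded locus to the first filter it fails in the order
#' call rate, MAF, HWE, and mean-imputes the remaining missing codes with the
#' dosage `2 p_k` so that their centered additive and dominance design
#' contributions are zero.  Allele frequencies of the output are recomputed
#' from the edited data.
#'
#' @inheritParams call_rate_filter
#' @param call_rate,maf,hwe_alpha filter thresholds.
#' @param maf_direction passed to [maf_filter()].
#' @return list with `genotypes` (edited, imputed [genotype_matrix()]) and
#'   `report` (a `qc_report`: thresholds, per-filter exclusion counts with
#'   first-failure attribution, loci retained, codes imputed).
#' @export
apply_qc <- function(genotypes, call_rate = 0.9, maf = 0.005, hwe_alpha = 1e-5,
                     maf_direction = "exclude_below") {
  stopifnot(inherits(genotypes, "geno_matrix"))
  m_cr  <- call_rate_filter(genotypes, call_rate)
  m_maf <- maf_filter(genotypes, maf, maf_direction)
  m_hwe <- hwe_filter(genotypes, hwe_alpha)
  keep <- m_cr & m_maf & m_hwe
  first_fail <- c(call_rate = sum(!m_cr),
                  maf = sum(m_cr & !m_maf),
                  hwe = sum(m_cr & m_maf & !m_hwe))
  codes <- genotypes$codes[, keep, drop = FALSE]
  p <- colMeans(codes, na.rm = TRUE) / 2
  n_imputed <- sum(is.na(codes))
  if (n_imputed > 0) {
    idx <- which(is.na(codes), arr.ind = TRUE)
    codes[idx] <- 2 * p[idx[, 2]]
  }
  report <- structure(list(
    thresholds = list(call_rate = call_rate, maf = maf, hwe_alpha = hwe_alpha,
                      maf_direction = maf_direction),
    n_input = ncol(genotypes$codes),
    n_retained = sum(keep),
    excluded = first_fail,
    n_imputed = n_imputed,
    keep = keep
  ), class = "qc_report")
  list(genotypes = genotype_matrix(codes, p = p), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n",
      "  loci in: ", x$n_input, ", retained: ", x$n_retained, "\n",
      "  excluded (first failing filter): call rate ", x$excluded[["call_rate"]],
      ", MAF ", x$excluded[["maf"]], ", HWE ", x$excluded[["hwe"]], "\n",
      "  thresholds: call rate >= ", x$thresholds$call_rate,
      ", MAF >= ", x$thresholds$maf, " (", x$thresholds$maf_direction, ")",
      ", HWE P >= ", x$thresholds$hwe_alpha, "\n",
      "  missing codes mean-imputed: ", x$n_imputed, "\n", sep = "")
  invisible(x)
}
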