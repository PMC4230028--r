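#' Genotype matrix with allele frequencies
#'
#' Container for SNP genotypes coded as counts of the A1 allele (0, 1, 2;
#' `NA` for missing before quality control).  Allele frequencies `p` refer to
#' the counted (A1) allele and are estimated from the non-missing codes unless
#' supplied.  After mean imputation (see [apply_qc()]) codes may contain the
#' non-integer dosage `2*p`, which contributes zero to the centered additive
#' and dominance designs.
#'
#' @param codes numeric matrix, individuals in rows (rownames are ids), loci
#'   in columns (colnames are locus ids).  Entries must be in `{0, 1, 2, NA}`
#'   or imputed dosages.
#' @param p optional numeric vector of A1 allele frequencies, one per locus.
#'   Computed as `colMeans(codes, na.rm = TRUE)/2` when `NULL`.
#' @return An object of class `geno_matrix`: a list with elements `codes`
#'   and `p`.
#' @seealso [geno_freq()], [geno_subset()], [apply_qc()]
#' @export
genotype_matrix <- function(codes, p = NULL) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes))) rownames(codes) <- paste0("ind", seq_len(nrow(codes)))
  if (is.null(colnames(codes))) colnames(codes) <- paste0("snp", seq_len(ncol(codes)))
  ok <- is.na(codes) | (codes >= 0 & codes <= 2)
  if (!all(ok)) stop("genotype codes must lie in [0, 2] or be NA")
  if (is.null(p)) {
    p <- colMeans(codes, na.rm = TRUE) / 2
    p[is.nan(p)] <- NA_real_
  } else {
    if (length(p) != ncol(codes)) stop("length(p) must equal the number of loci")
  }
  names(p) <- colnames(codes)
  structure(list(codes = codes, p = as.numeric(p)), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", nrow(x$codes), " individuals x ", ncol(x$codes),
      " loci; missing codes: ", sum(is.na(x$codes)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Allele frequencies of a genotype matrix
#'
#' @param g a [genotype_matrix()].
#' @param minor logical; return the minor allele frequency `pmin(p, 1-p)`
#'   instead of the A1 frequency.
#' @return numeric vector of per-locus frequencies.
#' @export
geno_freq <- function(g, minor = FALSE) {
  stopifnot(inherits(g, "geno_matrix"))
  if (minor) pmin(g$p, 1 - g$p) else g$p
}

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param g a [genotype_matrix()].
#' @param ids individual ids (rownames) to keep; `NULL` keeps all.
#' @param loci locus ids or column indices to keep; `NULL` keeps all.
#' @param recompute_p recompute allele frequencies from the subset (default
#'   `FALSE`: keep the frequencies of the full matrix, appropriate when the
#'   subset is e.g. the bull stratum of a cohort whose frequencies define the
#'   breeding-value centering).
#' @return a [genotype_matrix()].
#' @export
geno_subset <- function(g, ids = NULL, loci = NULL, recompute_p = FALSE) {
  stopifnot(inherits(g, "geno_matrix"))
  codes <- g$codes
  p <- g$p
  if (!is.null(ids)) {
    miss <- setdiff(ids, rownames(codes))
    if (length(miss) > 0)
      stop("ids not present in genotype matrix: ", paste(head(miss, 5), collapse = ", "))
    codes <- codes[ids, , drop = FALSE]
  }
  if (!is.null(loci)) {
    codes <- codes[, loci, drop = FALSE]
    p <- p[loci]
  }
  if (recompute_p) genotype_matrix(codes) else genotype_matrix(codes, p = p)
}
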