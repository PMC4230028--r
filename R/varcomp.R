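#' Convert marker-level to animal-level variance components
#'
#' With homogeneous per-marker variances `sigma_a2` and `sigma_d2` and allele
#' frequencies `p_k`, the animal-level components are
#' `sigmaA2 = sum 2 p q sigma_a2 + sum 2 p q (q - p)^2 sigma_d2` and
#' `sigmaD2 = sum 4 p^2 q^2 sigma_d2`.
#'
#' @param sigma_a2,sigma_d2 per-marker additive and dominance variances.
#' @param p allele frequencies of the counted allele.
#' @return named numeric vector `c(sigmaA2, sigmaD2)`.
#' @export
marker_to_animal_variance <- function(sigma_a2, sigma_d2, p) {
  q <- 1 - p
  c(sigmaA2 = sum(2 * p * q) * sigma_a2 + sum(2 * p * q * (q - p)^2) * sigma_d2,
    sigmaD2 = sum(4 * p^2 * q^2) * sigma_d2)
}

#' Convert animal-level to marker-level variance components
#'
#' Exact inverse of [marker_to_animal_variance()]:
#' `sigma_d2 = sigmaD2 / sum 4 p^2 q^2`, then
#' `sigma_a2 = (sigmaA2 - sum 2 p q (q-p)^2 sigma_d2) / sum 2 p q`.  Used to
#' fix the marker variances of the BLUP-SNP model from REML animal-level
#' estimates.
#'
#' @param sigmaA2,sigmaD2 animal-level additive and dominance variances.
#' @param p allele frequencies of the counted allele.
#' @return named numeric vector `c(sigma_a2, sigma_d2)`.
#' @export
animal_to_marker_variance <- function(sigmaA2, sigmaD2, p) {
  q <- 1 - p
  den_d <- sum(4 * p^2 * q^2)
  den_a <- sum(2 * p * q)
  if (den_a <= 0 || den_d <= 0)
    stop("all loci monomorphic: variance conversion denominators are zero")
  sigma_d2 <- sigmaD2 / den_d
  sigma_a2 <- (sigmaA2 - sum(2 * p * q * (q - p)^2) * sigma_d2) / den_a
  if (sigma_a2 < 0)
    stop("incompatible inputs: implied per-marker additive variance is negative")
  c(sigma_a2 = sigma_a2, sigma_d2 = sigma_d2)
}
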