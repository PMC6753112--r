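# SNP genetic relationship matrix and identity-by-state thresholding.

#' Compute the genetic relationship matrix (GRM)
#'
#' Standard GREML estimator from 0/1/2 dosages with sample allele
#' frequencies `p_i`: off-diagonal
#' `A_jk = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' and diagonal
#' `A_jj = 1 + (1/m) * sum_i (x_ij^2 - (1 + 2 p_i) x_ij + 2 p_i^2) / (2 p_i (1 - p_i))`.
#' Missing dosages are skipped pairwise, with a per-entry SNP count.
#' Monomorphic SNPs are excluded with a warning.
#'
#' @param geno Genotype list with `dosage` (individuals x SNPs).
#' @return A `grm` list: matrix `A` (IID dimnames), per-entry SNP count
#'   matrix `n_snps`, `ids` tibble.
#' @export
compute_grm <- function(geno) {
  d <- geno$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warning(sprintf("%d monomorphic SNP(s) excluded from GRM", sum(mono)),
            call. = FALSE)
    d <- d[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  denom <- 2 * p * (1 - p)
  Z <- sweep(d, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(denom), "/")
  obs <- !is.na(Z)
  Zf <- Z
  Zf[!obs] <- 0
  M <- tcrossprod(obs * 1)               # per-pair SNP counts
  A <- tcrossprod(Zf) / pmax(M, 1)
  # diagonal uses the dedicated estimator
  X <- d
  numer <- X^2 - sweep(X, 2, 1 + 2 * p, "*") +
    matrix(2 * p^2, nrow(X), ncol(X), byrow = TRUE)
  numer <- sweep(numer, 2, denom, "/")
  diag(A) <- 1 + rowMeans(numer, na.rm = TRUE)
  rownames(A) <- colnames(A) <- rownames(d)
  fam <- geno$fam
  ids <- tibble::tibble(fid = fam$fid[match(rownames(d), fam$iid)],
                        iid = rownames(d))
  structure(list(A = A, n_snps = M, ids = ids), class = "grm")
}

#' Threshold a GRM at an identity-by-state cutoff
#'
#' Off-diagonal entries below the cutoff are set to zero; the diagonal is
#' untouched. With the default cutoff 0.05 the resulting heritability is
#' driven by close-relative sharing, approximating identity-by-descent
#' estimates in family data.
#'
#' @param grm A `grm` (or bare matrix).
#' @param cutoff Threshold (default 0.05).
#' @return Object of the same shape with thresholded `A`.
#' @export
threshold_grm <- function(grm, cutoff = 0.05) {
  A <- if (inherits(grm, "grm")) grm$A else grm
  off <- row(A) != col(A)
  A[off & A < cutoff] <- 0
  if (inherits(grm, "grm")) {
    grm$A <- A
    grm$cutoff <- cutoff
    grm
  } else {
    A
  }
}
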