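# Genotype quality control: missingness, MAF, Hardy-Weinberg, heterozygosity.

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test P-value for one biallelic SNP: the probability of
#' all heterozygote counts (at the observed allele counts) whose conditional
#' probability does not exceed that of the observed count. Probabilities are
#' computed by the standard recurrence over heterozygote counts.
#'
#' @param n_het Observed heterozygotes.
#' @param n_hom_min Observed minor-allele homozygotes.
#' @param n_hom_maj Observed major-allele homozygotes.
#' @return Exact-test P-value.
#' @export
hwe_exact_test <- function(n_het, n_hom_min, n_hom_maj) {
  n <- n_het + n_hom_min + n_hom_maj
  if (n == 0) return(1)
  n_min <- 2 * n_hom_min + n_het     # minor allele count
  n_maj <- 2 * n - n_min
  if (n_min > n_maj) { tmp <- n_min; n_min <- n_maj; n_maj <- tmp }
  # feasible heterozygote counts share the parity of the minor allele count
  hets <- seq(n_min %% 2, n_min, by = 2)
  probs <- numeric(length(hets))
  # start from the largest feasible het count and recur downwards:
  # P(h-2)/P(h) = h*(h-1) / ((n_min-h+2)*(n_maj-h+2)) / ... (standard ratio)
  k <- length(hets)
  probs[k] <- 1
  for (j in rev(seq_len(k))[seq_len(max(k - 1, 0))]) {
    h <- hets[j]
    probs[j - 1] <- probs[j] * h * (h - 1) /
      ((n_min - h + 2) * (n_maj - h + 2))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

#' Default genotype QC thresholds
#'
#' Individual missingness 0.05, SNP missingness 0.05, minor allele frequency
#' 0.01, Hardy-Weinberg exact P 1e-8 (founders only), heterozygosity
#' outliers at 3 SD of the method-of-moments inbreeding coefficient.
#' @export
qc_thresholds <- function() {
  list(mind = 0.05, geno = 0.05, maf = 0.01, hwe = 1e-8, het_sd = 3)
}

#' Genotype quality control
#'
#' Filters applied in order: (1) individuals with call rate < 95%
#' (`mind`); (2) SNPs with call rate < 95% (`geno`); (3) SNPs with minor
#' allele frequency < 1% (`maf`); (4) SNPs failing the founders-only
#' Hardy-Weinberg exact test at P < 1e-8 (`hwe`); (5) individuals with
#' outlying heterozygosity (|F - mean F| > 3 SD). The report records counts
#' removed per step.
#'
#' @param geno Genotype list (`dosage`, `map`, `fam`, ...).
#' @param ped Pedigree tibble (identifies founders for the HWE test).
#' @param thresholds List as from [qc_thresholds()].
#' @return List: filtered `genotypes` and a `report` tibble.
#' @export
qc_genotypes <- function(geno, ped, thresholds = qc_thresholds()) {
  d <- geno$dosage
  report <- list()
  note <- function(step, kind, removed) {
    report[[length(report) + 1L]] <<- tibble::tibble(
      step = step, kind = kind, removed = as.integer(removed))
  }

  ind_miss <- rowMeans(is.na(d))
  drop_ind <- ind_miss > thresholds$mind
  note("mind", "individual", sum(drop_ind))
  d <- d[!drop_ind, , drop = FALSE]

  snp_miss <- colMeans(is.na(d))
  drop_snp <- snp_miss > thresholds$geno
  note("geno", "snp", sum(drop_snp))
  d <- d[, !drop_snp, drop = FALSE]

  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  drop_snp <- maf < thresholds$maf
  note("maf", "snp", sum(drop_snp))
  d <- d[, !drop_snp, drop = FALSE]

  founders <- ped$iid[ped$pat == "0" & ped$mat == "0"]
  fd <- d[rownames(d) %in% founders, , drop = FALSE]
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- fd[, j]
    x <- x[!is.na(x)]
    hwe_exact_test(sum(x == 1), sum(x == 2), sum(x == 0))
  }, 0)
  drop_snp <- hwe_p < thresholds$hwe
  note("hwe", "snp", sum(drop_snp))
  d <- d[, !drop_snp, drop = FALSE]
  if (ncol(d) == 0) abort_famh2("all SNPs removed by QC")

  # method-of-moments inbreeding coefficient per individual
  p <- colMeans(d, na.rm = TRUE) / 2
  exp_het <- 2 * p * (1 - p)
  called <- !is.na(d)
  obs_het_n <- rowSums(d == 1, na.rm = TRUE)
  exp_het_n <- called %*% exp_het
  f <- 1 - obs_het_n / drop(exp_het_n)
  out_ind <- abs(f - mean(f)) > thresholds$het_sd * stats::sd(f)
  note("het", "individual", sum(out_ind))
  d <- d[!out_ind, , drop = FALSE]

  geno$dosage <- d
  geno$map <- geno$map[geno$map$snp %in% colnames(d), , drop = FALSE]
  geno$fam <- geno$fam[geno$fam$iid %in% rownames(d), , drop = FALSE]
  geno$freq <- NULL  # simulated truth no longer aligned; recompute if needed
  list(genotypes = geno, report = dplyr::bind_rows(report))
}
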