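# Gene-dropping genotype simulation.

#' Specify a synthetic SNP panel
#'
#' Desk-scale stand-in for a genome-wide array: per-SNP minor allele
#' frequencies are drawn uniformly from `maf_range`, and `n_causal` SNPs can
#' carry trait effects in genotype-causal polygenic simulation.
#'
#' @param n_snps Number of SNPs.
#' @param n_causal Number of causal SNPs (`<= n_snps`).
#' @param maf_range Length-2 vector of minor-allele-frequency bounds in
#'   (0, 0.5).
#' @return A `genotype_spec` list.
#' @export
genotype_spec <- function(n_snps = 2000, n_causal = 20,
                          maf_range = c(0.05, 0.5)) {
  maf_range <- pmin(pmax(maf_range, 1e-4), 0.5 - 1e-6)
  if (maf_range[1] > maf_range[2]) abort_famh2("maf_range must be increasing")
  if (n_causal > n_snps) abort_famh2("n_causal must be <= n_snps")
  structure(list(n_snps = as.integer(n_snps), n_causal = as.integer(n_causal),
                 maf_range = maf_range),
            class = "genotype_spec")
}

#' Drop genotypes down a pedigree
#'
#' Founders receive alleles by independent Bernoulli draws at each SNP's
#' minor-allele frequency; each non-founder allele is drawn uniformly from
#' the corresponding parent's two alleles (Mendelian transmission). An
#' individual with an unknown parent draws that gamete from the population
#' frequency.
#'
#' @param ped Pedigree tibble.
#' @param spec A [genotype_spec()].
#' @param seed Integer seed (substream `"genotypes"`).
#' @return Genotype list: `dosage` (individuals x SNPs minor-allele counts),
#'   `map` tibble, `fam` (the pedigree), `freq` (simulated allele
#'   frequencies), `causal` (causal SNP ids).
#' @export
drop_genotypes <- function(ped, spec, seed = 1) {
  stopifnot(inherits(spec, "genotype_spec"))
  ped <- validate_pedigree(ped)
  ped <- ped[pedigree_order(ped), , drop = FALSE]
  set_stream_seed(seed, "genotypes")
  m <- spec$n_snps
  n <- nrow(ped)
  p <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  snp <- sprintf("snp%05d", seq_len(m))
  idx <- stats::setNames(seq_len(n), ped$iid)
  A1 <- matrix(0L, n, m)  # paternal gamete, 1 = minor allele
  A2 <- matrix(0L, n, m)  # maternal gamete
  for (i in seq_len(n)) {
    f <- if (ped$pat[i] %in% ped$iid) idx[[ped$pat[i]]] else 0L
    g <- if (ped$mat[i] %in% ped$iid) idx[[ped$mat[i]]] else 0L
    A1[i, ] <- if (f > 0L) {
      pick <- stats::runif(m) < 0.5
      ifelse(pick, A1[f, ], A2[f, ])
    } else {
      as.integer(stats::runif(m) < p)
    }
    A2[i, ] <- if (g > 0L) {
      pick <- stats::runif(m) < 0.5
      ifelse(pick, A1[g, ], A2[g, ])
    } else {
      as.integer(stats::runif(m) < p)
    }
  }
  dosage <- A1 + A2
  rownames(dosage) <- ped$iid
  colnames(dosage) <- snp
  map <- tibble::tibble(chr = "1", snp = snp, cm = 0,
                        bp = as.integer(seq_len(m) * 1000L))
  causal <- sample(snp, spec$n_causal)
  list(dosage = dosage, map = map, fam = ped, freq = p, causal = causal)
}
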