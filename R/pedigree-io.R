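# Pedigree validation and PLINK-text input/output (FAM, PED/MAP, GCTA GRM).

#' Validate a pedigree table
#'
#' Checks ID uniqueness within family, parent existence, parent sex
#' consistency (a referenced father must be recorded male, a mother female)
#' and acyclicity. One known parent is allowed; the missing parent is treated
#' as an unknown founder.
#'
#' @param ped Pedigree tibble (`fid`, `iid`, `pat`, `mat`, `sex`, optionally
#'   `phenotyped`).
#' @return The pedigree, invisibly, ordered parents-before-children.
#' @export
validate_pedigree <- function(ped) {
  req <- c("fid", "iid", "pat", "mat", "sex")
  if (!all(req %in% names(ped))) {
    abort_famh2("pedigree must have columns %s", paste(req, collapse = ", "))
  }
  if (anyDuplicated(ped$iid)) {
    dup <- ped$iid[duplicated(ped$iid)][1]
    abort_famh2("duplicate individual ID: %s", dup)
  }
  sex_of <- stats::setNames(ped$sex, ped$iid)
  for (col in c("pat", "mat")) {
    p <- ped[[col]]
    known <- p != "0"
    missing_parent <- known & !(p %in% ped$iid)
    if (any(missing_parent)) {
      # tolerate: treat as unknown founder (single known parent allowed)
      next
    }
    want <- if (col == "pat") 1L else 2L
    bad <- known & (p %in% ped$iid) & sex_of[p] != want
    if (any(bad)) {
      abort_famh2("parent sex inconsistency for individual %s (%s %s)",
                  ped$iid[which(bad)[1]], col, p[which(bad)[1]])
    }
  }
  ord <- pedigree_order(ped)   # errors on cycles
  invisible(ped[ord, , drop = FALSE])
}

# topological order (founders first); errors naming an individual on a cycle
pedigree_order <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$iid)
  parent_idx <- function(p) ifelse(p %in% ped$iid, idx[p], NA_integer_)
  pi1 <- parent_idx(ped$pat); pi2 <- parent_idx(ped$mat)
  pi1[ped$pat == "0"] <- NA_integer_; pi2[ped$mat == "0"] <- NA_integer_
  depth <- rep(NA_integer_, n)
  compute_depth <- function(i, seen) {
    if (!is.na(depth[i])) return(depth[i])
    if (seen[i]) abort_famh2("pedigree cycle detected at individual %s", ped$iid[i])
    seen[i] <- TRUE
    d1 <- if (is.na(pi1[i])) -1L else compute_depth(pi1[i], seen)
    d2 <- if (is.na(pi2[i])) -1L else compute_depth(pi2[i], seen)
    depth[i] <<- max(d1, d2) + 1L
    depth[i]
  }
  seen <- rep(FALSE, n)
  for (i in seq_len(n)) compute_depth(i, seen)
  order(depth, seq_len(n))
}

#' Read a PLINK FAM-dialect pedigree file
#'
#' Columns: FID IID PAT MAT SEX PHENO; `0` marks an unknown parent; sex is
#' 1 = male, 2 = female. A phenotype of `-9` (or `0`) marks an unphenotyped
#' individual.
#'
#' @param path FAM file path.
#' @return A validated pedigree tibble (with `phenotyped` from PHENO).
#' @export
parse_pedigree <- function(path) {
  x <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(x) < 6) abort_famh2("FAM file must have 6 columns")
  ped <- tibble::tibble(
    fid = x[[1]], iid = x[[2]], pat = x[[3]], mat = x[[4]],
    sex = as.integer(x[[5]]),
    phenotyped = !(x[[6]] %in% c("-9", "0"))
  )
  validate_pedigree(ped)
  ped
}

#' Write a pedigree as a PLINK FAM file
#' @param ped Pedigree tibble.
#' @param path Output path.
#' @export
write_fam <- function(ped, path) {
  pheno <- if ("phenotyped" %in% names(ped)) ifelse(ped$phenotyped, 1L, -9L) else 1L
  utils::write.table(
    data.frame(ped$fid, ped$iid, ped$pat, ped$mat, ped$sex, pheno),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(path)
}

#' Write genotypes in PLINK text PED/MAP dialect
#'
#' Alleles are coded `1` (major) / `2` (minor); dosage counts the `2` allele.
#' Missing dosage is written as `0 0`.
#'
#' @param geno A genotype object: list with `dosage` (individuals x SNPs
#'   integer matrix, rownames = IID), `map` (tibble: chr, snp, cm, bp) and
#'   the pedigree rows in `fam`.
#' @param prefix Output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @export
write_ped_map <- function(geno, prefix) {
  d <- geno$dosage
  fam <- geno$fam
  al <- matrix("0", nrow(d), 2L * ncol(d))
  a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, "2", "1"))
  a2 <- ifelse(is.na(d), "0", ifelse(d == 2, "2", "1"))
  al[, seq(1, 2 * ncol(d), 2)] <- a1
  al[, seq(2, 2 * ncol(d), 2)] <- a2
  pheno <- if ("phenotyped" %in% names(fam)) ifelse(fam$phenotyped, 1L, -9L) else 1L
  lines <- paste(fam$fid, fam$iid, fam$pat, fam$mat, fam$sex, pheno,
                 apply(al, 1, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
  utils::write.table(as.data.frame(geno$map), paste0(prefix, ".map"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(prefix)
}

#' Read PLINK text PED/MAP genotypes
#' @param prefix Path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @return Genotype list: `dosage` matrix (0/1/2/NA, rows = IID, columns =
#'   SNP ids), `map` tibble, `fam` pedigree tibble.
#' @export
read_ped_map <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           col.names = c("chr", "snp", "cm", "bp"),
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  map <- tibble::as_tibble(map)
  lines <- readLines(paste0(prefix, ".ped"))
  parts <- strsplit(trimws(lines), "[ \t]+")
  m <- nrow(map)
  fam <- tibble::tibble(
    fid = vapply(parts, `[[`, "", 1L), iid = vapply(parts, `[[`, "", 2L),
    pat = vapply(parts, `[[`, "", 3L), mat = vapply(parts, `[[`, "", 4L),
    sex = as.integer(vapply(parts, `[[`, "", 5L)),
    phenotyped = !(vapply(parts, `[[`, "", 6L) %in% c("-9", "0"))
  )
  dosage <- t(vapply(parts, function(p) {
    a <- matrix(p[-(1:6)], nrow = 2)
    miss <- a[1, ] == "0" | a[2, ] == "0"
    d <- (a[1, ] == "2") + (a[2, ] == "2")
    d[miss] <- NA_integer_
    as.integer(d)
  }, integer(m)))
  rownames(dosage) <- fam$iid
  colnames(dosage) <- map$snp
  list(dosage = dosage, map = map, fam = fam)
}

#' Write a relationship matrix in the GCTA text dialect
#'
#' Emits gzip-compressed triples `index_j index_k m_jk A_jk` over the lower
#' triangle (`<prefix>.grm.gz`) and a two-column FID/IID file
#' (`<prefix>.grm.id`). Kinship matrices are written in the same dialect.
#'
#' @param A Square symmetric matrix with IID rownames.
#' @param ids Tibble with `fid`, `iid` matching the matrix order.
#' @param prefix Output prefix.
#' @param n_snps Per-entry SNP counts (matrix or scalar; default 0 for
#'   pedigree kinship).
#' @export
write_grm <- function(A, ids, prefix, n_snps = 0) {
  n <- nrow(A)
  jk <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  m <- if (is.matrix(n_snps)) n_snps[jk] else rep(n_snps, nrow(jk))
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  utils::write.table(
    data.frame(jk[, 1], jk[, 2], m, signif(A[jk], 10)),
    con, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  close(con)
  utils::write.table(data.frame(ids$fid, ids$iid), paste0(prefix, ".grm.id"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(prefix)
}

#' Read a GCTA text-dialect relationship matrix
#' @param prefix Prefix of `<prefix>.grm.gz` / `<prefix>.grm.id`.
#' @return List with matrix `A` (IID dimnames), `ids` tibble, `n_snps` matrix.
#' @export
read_grm <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           col.names = c("fid", "iid"),
                           colClasses = "character")
  tri <- utils::read.table(gzfile(paste0(prefix, ".grm.gz")), header = FALSE)
  n <- nrow(ids)
  A <- matrix(0, n, n, dimnames = list(ids$iid, ids$iid))
  M <- matrix(0, n, n, dimnames = list(ids$iid, ids$iid))
  A[cbind(tri[[1]], tri[[2]])] <- tri[[4]]
  M[cbind(tri[[1]], tri[[2]])] <- tri[[3]]
  A[upper.tri(A)] <- t(A)[upper.tri(A)]
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  list(A = A, ids = tibble::as_tibble(ids), n_snps = M)
}

#' Write a per-individual phenotype table
#'
#' Tab-delimited with header, first columns FID and IID, missing values as
#' `NA`.
#' @param pheno Tibble with `fid`, `iid` and trait/covariate columns.
#' @param path Output path.
#' @export
write_pheno_table <- function(pheno, path) {
  stopifnot(all(c("fid", "iid") %in% names(pheno)))
  utils::write.table(as.data.frame(pheno), path, quote = FALSE,
                     row.names = FALSE, sep = "\t", na = "NA")
  invisible(path)
}

#' Read a phenotype table written by [write_pheno_table()]
#' @param path File path.
#' @return A tibble.
#' @export
read_pheno_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
                         colClasses = NA, stringsAsFactors = FALSE)
  x$fid <- as.character(x$fid)
  x$iid <- as.character(x$iid)
  tibble::as_tibble(x)
}
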