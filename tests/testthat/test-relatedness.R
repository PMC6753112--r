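# Pedigree parsing/validation, kinship, relative pairs, QC, GRM.

test_that("pedigree parsing validates and round-trips", {
  dir <- withr::local_tempdir()
  trio <- tibble::tibble(fid = "F1", iid = c("dad", "mum", "kid"),
                         pat = c("0", "0", "dad"), mat = c("0", "0", "mum"),
                         sex = c(1L, 2L, 1L), phenotyped = TRUE)
  f <- file.path(dir, "trio.fam")
  write_fam(trio, f)
  ped <- parse_pedigree(f)
  expect_equal(nrow(ped), 3)
  expect_equal(ped$pat[ped$iid == "kid"], "dad")
  # own-father cycle
  bad <- trio; bad$pat[1] <- "dad"
  write_fam(bad, f)
  expect_error(parse_pedigree(f), "cycle.*dad")
  # duplicate ID
  dup <- trio; dup$iid[2] <- "dad"
  write_fam(dup, f)
  expect_error(parse_pedigree(f), "duplicate.*dad")
  # father recorded female
  sexswap <- trio; sexswap$sex[1] <- 2L
  write_fam(sexswap, f)
  expect_error(parse_pedigree(f), "sex")
})

test_that("kinship recursion reproduces the canonical relative values", {
  ped <- tibble::tibble(
    fid = "F1",
    iid = c("gf", "gm", "p1", "p2", "sp", "c1", "c2", "gc"),
    pat = c("0", "0", "gf", "gf", "0", "p1", "p1", "c1"),
    mat = c("0", "0", "gm", "gm", "0", "sp", "sp", "spx"),
    sex = c(1L, 2L, 1L, 1L, 2L, 1L, 2L, 1L))
  phi <- kinship_matrix(ped)
  expect_equal(phi["p1", "gf"], 0.25)     # parent-offspring
  expect_equal(phi["p1", "p2"], 0.25)     # full sibs
  expect_equal(phi["c1", "c2"], 0.25)     # full sibs
  expect_equal(phi["c1", "p2"], 0.125)    # avuncular
  expect_equal(phi["gc", "gf"], 0.0625)   # great-grandparent... via c1: gf-c1 grandparent 0.125, gc child of c1
  expect_equal(phi["gf", "gm"], 0)        # unrelated founders
  expect_true(all(diag(phi) == 0.5))
  # half sibs via shared father only
  hs <- tibble::tibble(fid = "F1", iid = c("f", "m1", "m2", "k1", "k2"),
                       pat = c("0", "0", "0", "f", "f"),
                       mat = c("0", "0", "0", "m1", "m2"),
                       sex = c(1L, 2L, 2L, 1L, 1L))
  expect_equal(kinship_matrix(hs)["k1", "k2"], 0.125)
  # first cousins
  fc <- tibble::tibble(
    fid = "F1", iid = c("gf", "gm", "a", "b", "sa", "sb", "ca", "cb"),
    pat = c("0", "0", "gf", "gf", "0", "0", "a", "b"),
    mat = c("0", "0", "gm", "gm", "0", "0", "sa", "sb"),
    sex = c(1L, 2L, 1L, 1L, 2L, 2L, 1L, 1L))
  expect_equal(kinship_matrix(fc)["ca", "cb"], 0.0625)
})

test_that("recursive kinship matches the path-counting oracle on random pedigrees", {
  max_err <- 0
  for (s in 1:100) {
    ped <- random_test_pedigree(n_max = 40, n_gen = 4, seed = s)
    phi <- kinship_matrix(ped)
    oracle <- kinship_path_oracle(ped)
    max_err <- max(max_err, max(abs(phi[ped$iid, ped$iid] -
                                      oracle[ped$iid, ped$iid])))
  }
  expect_lt(max_err, 1e-12)
})

test_that("2*Phi is positive semidefinite on generated panels", {
  for (s in c(1, 7)) {
    ped <- simulate_pedigrees(pedigree_spec(seed = s))
    K <- 2 * kinship_matrix(ped, ids = ped$iid[ped$phenotyped])
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-9)
  }
})

test_that("relative pair enumeration matches combinatorics and kinship", {
  # nuclear family with 3 children: 3 sib pairs, 6 parent-child pairs
  nuc <- tibble::tibble(fid = "F1", iid = c("f", "m", "c1", "c2", "c3"),
                        pat = c("0", "0", "f", "f", "f"),
                        mat = c("0", "0", "m", "m", "m"),
                        sex = c(1L, 2L, 1L, 2L, 1L), phenotyped = TRUE)
  pr <- extract_relative_pairs(nuc)
  expect_equal(sum(pr$class == "sibling"), 3)
  expect_equal(sum(pr$class == "parent-child"), 6)
  expect_equal(sum(pr$class == "avuncular"), 0)
  # parent-child pairs are parent-first
  pc <- pr[pr$class == "parent-child", ]
  expect_true(all(pc$iid1 %in% c("f", "m")))
  # three-generation with one grandchild and parent having one full sib
  tg <- tibble::tibble(fid = "F1",
                       iid = c("gf", "gm", "p", "s", "sp", "g"),
                       pat = c("0", "0", "gf", "gf", "0", "p"),
                       mat = c("0", "0", "gm", "gm", "0", "sp"),
                       sex = c(1L, 2L, 1L, 2L, 2L, 1L), phenotyped = TRUE)
  pr2 <- extract_relative_pairs(tg)
  av <- pr2[pr2$class == "avuncular", ]
  expect_equal(nrow(av), 1)
  expect_setequal(c(av$iid1, av$iid2), c("s", "g"))
  # pair classes agree with kinship coefficients
  phi <- kinship_matrix(tg)
  for (k in seq_len(nrow(pr2))) {
    expected <- c(sibling = 0.25, `parent-child` = 0.25,
                  avuncular = 0.125)[[pr2$class[k]]]
    expect_equal(phi[pr2$iid1[k], pr2$iid2[k]], expected)
  }
  # each unordered pair appears exactly once
  key <- apply(cbind(pmin(pr2$iid1, pr2$iid2), pmax(pr2$iid1, pr2$iid2),
                     pr2$class), 1, paste, collapse = "|")
  expect_false(any(duplicated(key)))
})

test_that("HWE exact test matches the enumeration oracle to 1e-12", {
  cases <- expand.grid(het = 0:12, hom_min = 0:6, hom_maj = c(0, 3, 10, 18))
  for (k in seq_len(nrow(cases))) {
    nh <- cases$het[k]; ni <- cases$hom_min[k]; nj <- cases$hom_maj[k]
    if (2 * ni + 2 * nj + 2 * nh > 60) next
    expect_equal(hwe_exact_test(nh, ni, nj), hwe_enum_oracle(nh, ni, nj),
                 tolerance = 1e-12)
  }
  # perfectly HWE-proportioned counts sit at the distribution mode: P = 1
  # only when every other configuration is less probable; check boundary
  # behaviour against the oracle at a canonical case
  expect_equal(hwe_exact_test(50, 25, 25), hwe_enum_oracle(50, 25, 25),
               tolerance = 1e-12)
})

test_that("genotype QC applies the printed thresholds in order and is idempotent", {
  co <- small_cohort(seed = 4, n_snps = 120)
  g <- co$genotypes
  d <- g$dosage
  set.seed(99)
  # SNP 1: genotyped in 94% of individuals -> dropped at geno step
  miss_n <- ceiling(0.06 * nrow(d))
  d[sample(nrow(d), miss_n), 1] <- NA
  # SNP 2: forced rare (MAF ~ 0.5%)
  d[, 2] <- 0L
  d[sample(nrow(d), max(1, round(0.01 * nrow(d))), replace = FALSE), 2] <- 1L
  # SNP 3: gross HWE failure among founders (all heterozygous)
  d[, 3] <- 1L
  # individual 1: 90% missing -> dropped at mind step
  d[1, sample(ncol(d), round(0.9 * ncol(d)))] <- NA
  g$dosage <- d
  res <- qc_genotypes(g, co$pedigree)
  rep <- res$report
  expect_equal(rep$removed[rep$step == "mind"], 1L)
  expect_gte(rep$removed[rep$step == "geno"], 1L)
  expect_gte(rep$removed[rep$step == "maf"], 1L)
  expect_gte(rep$removed[rep$step == "hwe"], 1L)
  expect_false("snp00001" %in% colnames(res$genotypes$dosage))
  expect_false("snp00002" %in% colnames(res$genotypes$dosage))
  expect_false("snp00003" %in% colnames(res$genotypes$dosage))
  expect_false(rownames(d)[1] %in% rownames(res$genotypes$dosage))
  # removals sum consistently with dimensions
  expect_equal(nrow(d) - sum(rep$removed[rep$kind == "individual"]),
               nrow(res$genotypes$dosage))
  expect_equal(ncol(d) - sum(rep$removed[rep$kind == "snp"]),
               ncol(res$genotypes$dosage))
  # idempotence: second pass removes nothing
  res2 <- qc_genotypes(res$genotypes, co$pedigree)
  expect_true(all(res2$report$removed == 0L))
  expect_equal(res2$genotypes$dosage, res$genotypes$dosage)
})

test_that("GRM entries match the single-SNP closed forms", {
  d <- matrix(c(0L, 1L, 1L, 2L), nrow = 4, ncol = 1,
              dimnames = list(paste0("i", 1:4), "snp1"))
  g <- list(dosage = d,
            fam = tibble::tibble(fid = "F1", iid = paste0("i", 1:4)))
  A <- compute_grm(g)$A
  # p = 0.5: between the 0- and 2-dosage individuals: (-1)(1)/0.5 = -2
  expect_equal(A["i1", "i4"], -2)
  # diagonal for the 0-dosage individual: 1 + (0 - 0 + 0.5)/0.5 = 2
  expect_equal(A["i1", "i1"], 2)
  # heterozygote diagonal: 1 + (1 - 2 + 0.5)/0.5 = 0
  expect_equal(A["i2", "i2"], 0)
  expect_true(isSymmetric(A))
})

test_that("GRM on simulated unrelateds concentrates near the identity", {
  n <- 120; m <- 5000
  set.seed(17)
  p <- stats::runif(m, 0.1, 0.5)
  d <- sapply(p, function(pp) stats::rbinom(n, 2, pp))
  rownames(d) <- paste0("u", seq_len(n))
  colnames(d) <- paste0("s", seq_len(m))
  g <- list(dosage = d, fam = tibble::tibble(fid = rownames(d),
                                             iid = rownames(d)))
  grm <- compute_grm(g)
  off <- grm$A[lower.tri(grm$A)]
  expect_lt(mean(abs(off)), 3 / sqrt(m))
  expect_lt(abs(mean(diag(grm$A)) - 1), 0.05)
})

test_that("expected GRM equals 2*Phi for gene-dropped families", {
  co <- simulate_cohort(pedigree_spec(n_families = 40,
                                      target_total_individuals = 148,
                                      seed = 31),
                        genotype_spec(n_snps = 5000), seed = 31)
  grm <- compute_grm(co$genotypes)
  pairs <- extract_relative_pairs(co$pedigree, "sibling",
                                  phenotyped_only = FALSE)
  sib_a <- grm$A[cbind(pairs$iid1, pairs$iid2)]
  expect_gte(mean(sib_a), 0.45)
  expect_lte(mean(sib_a), 0.55)
})

test_that("GRM thresholding zeroes only sub-cutoff off-diagonals", {
  A <- matrix(c(1.0, 0.04, 0.06,
                0.04, 1.0, -0.2,
                0.06, -0.2, 0.9), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  thr <- threshold_grm(A, cutoff = 0.05)
  expect_equal(thr["a", "b"], 0)
  expect_equal(thr["a", "c"], 0.06)
  expect_equal(thr["b", "c"], 0)      # negatives are below cutoff too
  expect_equal(diag(thr), diag(A))    # diagonal untouched
  expect_true(isSymmetric(thr))
  # an extremely low cutoff is the identity transformation
  expect_equal(threshold_grm(A, cutoff = -10), A)
  # family structure survives, between-family noise does not
  co <- small_cohort(seed = 4, n_snps = 400)
  grm <- compute_grm(co$genotypes)
  tg <- threshold_grm(grm, cutoff = 0.05)
  fid <- co$pedigree$fid[match(rownames(tg$A), co$pedigree$iid)]
  cross <- outer(fid, fid, "!=")
  expect_true(all(tg$A[cross & abs(tg$A) < 0.05] == 0))
  pairs <- extract_relative_pairs(co$pedigree, "sibling",
                                  phenotyped_only = FALSE)
  expect_gt(mean(tg$A[cbind(pairs$iid1, pairs$iid2)]), 0.3)
})

test_that("GRM files round-trip through the GCTA text dialect", {
  co <- small_cohort(seed = 4, n_snps = 100)
  grm <- compute_grm(co$genotypes)
  dir <- withr::local_tempdir()
  write_grm(grm$A, grm$ids, file.path(dir, "g"), grm$n_snps)
  back <- read_grm(file.path(dir, "g"))
  expect_equal(back$A, grm$A, tolerance = 1e-8)
  expect_equal(back$ids$iid, grm$ids$iid)
  expect_equal(back$n_snps, grm$n_snps)
})
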