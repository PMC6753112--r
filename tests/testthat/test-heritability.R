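# Variance-components fits: likelihood oracles, null behaviour, recovery,
# Wald SE and LRT P-value conventions.

test_that("eigendecomposition ML likelihood equals a dense MVN evaluation", {
  # five-member family: brute-force density check at the optimum
  ped5 <- tibble::tibble(fid = "F1", iid = c("f", "m", "c1", "c2", "c3"),
                         pat = c("0", "0", "f", "f", "f"),
                         mat = c("0", "0", "m", "m", "m"),
                         sex = c(1L, 2L, 1L, 2L, 1L), phenotyped = TRUE)
  K5 <- 2 * kinship_matrix(ped5)
  set.seed(1)
  y5 <- drop(chol(0.6 * K5 + 0.4 * diag(5)) %*% stats::rnorm(5)) + 3
  names(y5) <- ped5$iid
  fit5 <- fit_vc_ml(y5, K5)
  V5 <- fit5$sigma_g2 * K5[names(y5), names(y5)] +
    fit5$sigma_e2 * diag(5)
  expect_equal(fit5$loglik_full, dense_mvn_loglik(y5, fit5$mu, V5),
               tolerance = 1e-8)
  # n = 200 panel
  ped <- simulate_pedigrees(pedigree_spec(n_families = 53,
                                          target_total_individuals = 200,
                                          seed = 12))
  panel <- ped$iid[ped$phenotyped]
  K <- 2 * kinship_matrix(ped, ids = panel)
  g <- simulate_polygenic(ped, h2 = 0.5, seed = 12)
  set.seed(13)
  y <- g[panel] + stats::rnorm(length(panel), 0, sqrt(0.5))
  fit <- fit_vc_ml(y, K)
  V <- fit$sigma_g2 * K + fit$sigma_e2 * diag(length(panel))
  expect_equal(fit$loglik_full, dense_mvn_loglik(y[rownames(K)], fit$mu, V),
               tolerance = 1e-8)
  # REML likelihood against its dense counterpart
  gfit <- fit_greml(y, K)
  Vr <- gfit$sigma_g2 * K + gfit$sigma_e2 * diag(length(panel))
  expect_equal(gfit$loglik_full, dense_reml_loglik(y[rownames(K)], Vr),
               tolerance = 1e-8)
})

test_that("full-model log-likelihood never falls below the null", {
  ped <- simulate_pedigrees(pedigree_spec(n_families = 30,
                                          target_total_individuals = 114,
                                          seed = 3))
  panel <- ped$iid[ped$phenotyped]
  kern <- vc_kernel(2 * kinship_matrix(ped, ids = panel))
  for (r in 1:20) {
    set.seed(100 + r)
    y <- stats::setNames(stats::rnorm(length(panel)), panel)
    fit <- fit_vc_ml(y, kern)
    expect_gte(fit$loglik_full, fit$loglik_null - 1e-6)
    expect_gte(fit$lrt, -1e-6)
    gfit <- fit_greml(y, 2 * kinship_matrix(ped, ids = panel))
    expect_gte(gfit$loglik_full, gfit$loglik_null - 1e-6)
  }
})

test_that("pure-noise phenotypes give near-zero heritability and LRT", {
  ped <- simulate_pedigrees(pedigree_spec(seed = 5))
  panel <- ped$iid[ped$phenotyped]
  kern <- vc_kernel(2 * kinship_matrix(ped, ids = panel))
  h2s <- lrts <- numeric(30)
  for (r in seq_len(30)) {
    set.seed(200 + r)
    y <- stats::setNames(stats::rnorm(length(panel)), panel)
    fit <- fit_vc_ml(y, kern)
    h2s[r] <- fit$h2; lrts[r] <- fit$lrt
  }
  expect_lt(stats::median(lrts), 0.5)
  expect_lt(stats::median(h2s), 0.1)
})

test_that("ML recovers h2 = 0.5 on the default panel without bias", {
  ped <- simulate_pedigrees(pedigree_spec(seed = 1))
  panel <- ped$iid[ped$phenotyped]
  kern <- vc_kernel(2 * kinship_matrix(ped, ids = panel))
  est <- numeric(200)
  for (r in seq_len(200)) {
    g <- simulate_polygenic(ped, h2 = 0.5, seed = 1,
                            stream = paste0("rec/", r))
    set.seed(3000 + r)
    y <- g[panel] + stats::rnorm(length(panel), 0, sqrt(0.5))
    est[r] <- fit_vc_ml(y, kern)$h2
  }
  expect_gte(mean(est), 0.45)
  expect_lte(mean(est), 0.55)
})

test_that("permuting phenotype labels destroys heritability", {
  ped <- simulate_pedigrees(pedigree_spec(seed = 8))
  panel <- ped$iid[ped$phenotyped]
  kern <- vc_kernel(2 * kinship_matrix(ped, ids = panel))
  g <- simulate_polygenic(ped, h2 = 0.8, seed = 8)
  set.seed(81)
  y <- g[panel] + stats::rnorm(length(panel), 0, sqrt(0.2))
  expect_gt(fit_vc_ml(y, kern)$h2, 0.5)
  perm_h2 <- vapply(1:11, function(r) {
    set.seed(810 + r)
    yp <- stats::setNames(sample(y), names(y))
    fit_vc_ml(yp, kern)$h2
  }, 0)
  expect_lt(stats::median(perm_h2), 0.05)
})

test_that("GREML recovers heritability from phenotypes simulated off the GRM", {
  co <- simulate_cohort(pedigree_spec(n_families = 132,
                                      target_total_individuals = 500,
                                      seed = 14),
                        genotype_spec(n_snps = 2000), seed = 14)
  grm <- threshold_grm(compute_grm(co$genotypes), 0.05)
  panel <- co$pedigree$iid[co$pedigree$phenotyped]
  panel <- intersect(panel, rownames(grm$A))
  A <- grm$A[panel, panel]
  e <- eigen(A, symmetric = TRUE)
  d <- pmax(e$values, 0)
  est <- numeric(100)
  for (r in seq_len(100)) {
    set.seed(500 + r)
    y <- drop(e$vectors %*% (sqrt(0.4 * d) * stats::rnorm(length(d)))) +
      stats::rnorm(length(panel), 0, sqrt(0.6))
    names(y) <- panel
    est[r] <- fit_greml(y, A)$h2
  }
  expect_gte(mean(est), 0.35)
  expect_lte(mean(est), 0.45)
})

test_that("GREML and pedigree ML agree when the GRM is exactly 2*Phi", {
  ped <- simulate_pedigrees(pedigree_spec(seed = 9))
  panel <- ped$iid[ped$phenotyped]
  K <- 2 * kinship_matrix(ped, ids = panel)
  g <- simulate_polygenic(ped, h2 = 0.5, seed = 9)
  set.seed(91)
  y <- g[panel] + stats::rnorm(length(panel), 0, sqrt(0.5))
  f1 <- fit_vc_ml(y, K)
  f2 <- fit_greml(y, K)
  expect_lt(abs(f1$h2 - f2$h2), 0.02)
})

test_that("unconstrained REML goes negative on about half of null replicates", {
  ped <- simulate_pedigrees(pedigree_spec(n_families = 60,
                                          target_total_individuals = 228,
                                          seed = 10))
  panel <- ped$iid[ped$phenotyped]
  K <- 2 * kinship_matrix(ped, ids = panel)
  kern <- vc_kernel(K)
  neg <- 0L
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    set.seed(700 + r)
    y <- stats::setNames(stats::rnorm(length(panel)), panel)
    fit <- fit_greml(y, kern, constrained = FALSE)
    expect_gt(fit$sigma_g2 + fit$sigma_e2, 0)
    if (fit$sigma_g2 < 0) neg <- neg + 1L
  }
  expect_gte(neg / n_rep, 0.25)
  expect_lte(neg / n_rep, 0.75)
})

test_that("Wald-approximation SE follows se = h2/sqrt(LRT)", {
  expect_equal(wald_se_from_lrt(0.35, 9), 0.35 / 3)
  expect_equal(wald_se_from_lrt(0.5, 25), 0.1)
  expect_true(is.na(wald_se_from_lrt(0.4, 0)))
  expect_error(wald_se_from_lrt(0.4, -1), "non-negative")
})

test_that("LRT P-values follow the boundary-mixture and plain conventions", {
  expect_equal(lrt_pvalue(0, TRUE), 1)
  expect_equal(lrt_pvalue(0, FALSE), 1)
  expect_equal(lrt_pvalue(3.84, FALSE), 0.05, tolerance = 1e-3)
  expect_equal(lrt_pvalue(3.84, TRUE), 0.025, tolerance = 1e-3)
  # monotone decreasing
  lrts <- seq(0.1, 20, by = 0.5)
  expect_true(all(diff(lrt_pvalue(lrts)) < 0))
})

test_that("non-PSD kernels are rejected by the pedigree fit", {
  K <- diag(4); K[1, 2] <- K[2, 1] <- 2
  rownames(K) <- colnames(K) <- paste0("i", 1:4)
  y <- stats::setNames(stats::rnorm(4), rownames(K))
  expect_error(fit_vc_ml(y, K), "positive semidefinite")
})

test_that("tidy/glance methods return the expected one-row summaries", {
  ped <- simulate_pedigrees(pedigree_spec(n_families = 30,
                                          target_total_individuals = 114,
                                          seed = 2))
  panel <- ped$iid[ped$phenotyped]
  K <- 2 * kinship_matrix(ped, ids = panel)
  g <- simulate_polygenic(ped, h2 = 0.6, seed = 2)
  set.seed(21)
  y <- g[panel] + stats::rnorm(length(panel), 0, sqrt(0.4))
  fit <- fit_vc_ml(y, K)
  td <- tidy(fit)
  expect_equal(td$term, c("h2", "sigma_g2", "sigma_e2"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$h2, fit$h2)
  expect_equal(gl$n, length(panel))
})
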