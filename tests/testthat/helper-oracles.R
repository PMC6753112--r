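# Independent oracles used across the suite. Each reimplements a quantity by
# a different route than the package (path counting vs recursion, dense
# matrix algebra vs eigendecomposition, log-factorial enumeration vs
# recurrence), so agreement is evidence, not tautology.

# --- random non-inbred pedigrees --------------------------------------------
# Trees only: every mating pairs a family member with a fresh founder, so no
# individual is inbred and Wright's path-counting formula applies with f = 0.
random_test_pedigree <- function(n_max = 40, n_gen = 4, seed = 1) {
  set.seed(seed)
  ped <- data.frame(fid = "F1", iid = "I1", pat = "0", mat = "0",
                    sex = 1L, stringsAsFactors = FALSE)
  ped <- rbind(ped, data.frame(fid = "F1", iid = "I2", pat = "0", mat = "0",
                               sex = 2L))
  next_id <- 3L
  current_gen <- list(c("I1", "I2"))
  for (gen in seq_len(n_gen - 1)) {
    couples <- current_gen
    new_gen <- list()
    for (cp in couples) {
      if (nrow(ped) >= n_max - 2) break
      n_kids <- sample(0:3, 1, prob = c(0.1, 0.3, 0.4, 0.2))
      for (k in seq_len(n_kids)) {
        if (nrow(ped) >= n_max - 1) break
        kid <- paste0("I", next_id); next_id <- next_id + 1L
        sex <- sample(1:2, 1)
        ped <- rbind(ped, data.frame(fid = "F1", iid = kid, pat = cp[1],
                                     mat = cp[2], sex = sex))
        if (stats::runif(1) < 0.6 && nrow(ped) < n_max) {
          spouse <- paste0("I", next_id); next_id <- next_id + 1L
          ped <- rbind(ped, data.frame(fid = "F1", iid = spouse, pat = "0",
                                       mat = "0", sex = 3L - sex))
          pair <- if (sex == 1L) c(kid, spouse) else c(spouse, kid)
          new_gen[[length(new_gen) + 1L]] <- pair
        }
      }
    }
    if (!length(new_gen)) break
    current_gen <- new_gen
  }
  tibble::as_tibble(ped)
}

# --- Wright path-counting kinship oracle ------------------------------------
# phi(i,j) = sum over common ancestors A and ancestor-path pairs meeting only
# at A of (1/2)^(L1 + L2 + 1); f = 0 by pedigree construction.
kinship_path_oracle <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$iid)
  # all ancestor paths from each individual: list of node-index vectors,
  # path[1] = self, path[length] = the ancestor
  paths_of <- vector("list", n)
  get_paths <- function(i) {
    if (!is.null(paths_of[[i]])) return(paths_of[[i]])
    out <- list(i)
    for (p in c(ped$pat[i], ped$mat[i])) {
      if (p != "0" && p %in% ped$iid) {
        for (pp in get_paths(idx[[p]])) out[[length(out) + 1L]] <- c(i, pp)
      }
    }
    paths_of[[i]] <<- out
    out
  }
  for (i in seq_len(n)) get_paths(i)
  phi <- matrix(0, n, n, dimnames = list(ped$iid, ped$iid))
  for (i in seq_len(n)) {
    phi[i, i] <- 0.5    # non-inbred
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      tot <- 0
      for (p1 in paths_of[[i]]) {
        a1 <- p1[length(p1)]
        for (p2 in paths_of[[j]]) {
          if (p2[length(p2)] != a1) next
          if (length(intersect(p1, p2)) == 1L) {
            tot <- tot + 0.5^(length(p1) - 1 + length(p2) - 1 + 1)
          }
        }
      }
      phi[i, j] <- phi[j, i] <- tot
    }
  }
  phi
}

# --- dense multivariate-normal log-likelihood -------------------------------
dense_mvn_loglik <- function(y, mu, V) {
  n <- length(y)
  ch <- chol(V)
  r <- y - mu
  z <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# dense REML log-likelihood for X = intercept column
dense_reml_loglik <- function(y, V) {
  n <- length(y)
  X <- matrix(1, n, 1)
  Vi <- solve(V)
  XVX <- drop(t(X) %*% Vi %*% X)
  beta <- drop(t(X) %*% Vi %*% y) / XVX
  r <- y - beta
  -0.5 * ((n - 1) * log(2 * pi) + as.numeric(determinant(V)$modulus) +
            log(XVX) +
            drop(t(r) %*% Vi %*% r))
}

# --- Hardy-Weinberg enumeration oracle (log-factorial route) ----------------
hwe_enum_oracle <- function(n_het, n_hom_min, n_hom_maj) {
  n <- n_het + n_hom_min + n_hom_maj
  n_min <- 2 * n_hom_min + n_het
  n_maj <- 2 * n - n_min
  if (n_min > n_maj) { t <- n_min; n_min <- n_maj; n_maj <- t }
  hets <- seq(n_min %% 2, n_min, by = 2)
  logp <- vapply(hets, function(h) {
    hom_min <- (n_min - h) / 2
    hom_maj <- (n_maj - h) / 2
    lgamma(n + 1) - lgamma(hom_min + 1) - lgamma(h + 1) -
      lgamma(hom_maj + 1) + h * log(2) +
      lgamma(n_min + 1) + lgamma(n_maj + 1) - lgamma(2 * n + 1)
  }, 0)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hets)]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

# --- misc -------------------------------------------------------------------
# small default cohort used by several files (cached per session)
cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function(seed = 1, n_snps = 400) {
  key <- paste0("c", seed, "_", n_snps)
  if (is.null(cohort_cache[[key]])) {
    cohort_cache[[key]] <- simulate_cohort(
      pedigree_spec(seed = seed), genotype_spec(n_snps = n_snps),
      trait_model(), seed = seed)
  }
  cohort_cache[[key]]
}
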