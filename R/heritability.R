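# Variance-components heritability: pedigree-kernel maximum likelihood and
# GRM-kernel REML, with LRT, boundary-corrected P-values and standard errors.
#
# Both fits use the same device: one eigendecomposition of the kernel K
# reduces every likelihood evaluation of V = sigma_g2 * K + sigma_e2 * I to
# O(n) diagonal arithmetic, and the model is profiled down to a 1-D search
# over h2 = sigma_g2 / (sigma_g2 + sigma_e2) with the mean and the total
# variance eliminated analytically at their conditional optima.

#' Prepare a variance-components kernel
#'
#' Eigendecomposes a relationship matrix once so that many phenotypes (or
#' many simulation replicates) can be fitted against it cheaply.
#'
#' @param K Square symmetric relationship matrix with IID dimnames
#'   (`2 * Phi` for a pedigree kernel, `A` for a GRM kernel).
#' @return A `vc_kernel`: eigenvectors `U`, eigenvalues `d`, `ids`.
#' @export
vc_kernel <- function(K) {
  if (inherits(K, "vc_kernel")) return(K)
  if (inherits(K, "grm")) K <- K$A
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  e <- eigen(K, symmetric = TRUE)
  structure(list(U = e$vectors, d = e$values, ids = rownames(K)),
            class = "vc_kernel")
}

# rotated data for a kernel: y and the intercept column in the eigenbasis
rotate_phenotype <- function(y, kernel) {
  if (is.data.frame(y)) {
    val_col <- intersect(c("residual", "value"), names(y))[1]
    if (is.na(val_col)) abort_famh2("phenotype table needs a 'residual' or 'value' column")
    y <- stats::setNames(y[[val_col]], y$iid)
  }
  y <- y[!is.na(y)]
  if (!is.null(names(y)) && !is.null(kernel$ids)) {
    if (!setequal(names(y), kernel$ids)) {
      abort_famh2("phenotype IDs do not match kernel IDs; subset the kernel matrix before vc_kernel()")
    }
    y <- y[kernel$ids]
  } else if (length(y) != length(kernel$d)) {
    abort_famh2("phenotype length does not match kernel dimension")
  }
  list(yt = drop(crossprod(kernel$U, y)),
       ut = drop(crossprod(kernel$U, rep(1, length(y)))),
       n = length(y))
}

# profile quantities at a given h2: GLS mean and unit-variance quadratic form
profile_parts <- function(h2, d, yt, ut) {
  w <- h2 * d + (1 - h2)
  mu <- sum(ut * yt / w) / sum(ut^2 / w)
  r <- yt - mu * ut
  list(w = w, mu = mu, q = sum(r^2 / w), xvx = sum(ut^2 / w))
}

ml_profile_ll <- function(h2, d, yt, ut, n) {
  p <- profile_parts(h2, d, yt, ut)
  s2 <- p$q / n
  -0.5 * (n * log(2 * pi) + n * log(s2) + sum(log(p$w)) + n)
}

reml_profile_ll <- function(h2, d, yt, ut, n) {
  p <- profile_parts(h2, d, yt, ut)
  s2 <- p$q / (n - 1)
  -0.5 * ((n - 1) * log(2 * pi) + (n - 1) * log(s2) + sum(log(p$w)) +
            log(p$xvx) + (n - 1))
}

# full (unprofiled-variance) log-likelihoods in (sigma_g2, sigma_e2), mean
# still profiled; used for observed-information standard errors
ml_ll_sigma <- function(theta, d, yt, ut, n) {
  w <- theta[1] * d + theta[2]
  if (any(w <= 0)) return(-Inf)
  mu <- sum(ut * yt / w) / sum(ut^2 / w)
  r <- yt - mu * ut
  -0.5 * (n * log(2 * pi) + sum(log(w)) + sum(r^2 / w))
}

reml_ll_sigma <- function(theta, d, yt, ut, n) {
  w <- theta[1] * d + theta[2]
  if (any(w <= 0)) return(-Inf)
  xvx <- sum(ut^2 / w)
  mu <- sum(ut * yt / w) / xvx
  r <- yt - mu * ut
  -0.5 * ((n - 1) * log(2 * pi) + sum(log(w)) + log(xvx) + sum(r^2 / w))
}

# expected (Fisher) information for h2 in the sigma_p2-profiled
# parameterization; scale-free, so it depends only on the kernel spectrum
h2_fisher_se <- function(h2, d) {
  w <- h2 * d + (1 - h2)
  a <- (d - 1) / w
  n <- length(d)
  info <- 0.5 * sum(a^2) - (0.5 / n) * sum(a)^2
  if (info <= 0) return(NA_real_)
  1 / sqrt(info)
}

# delta-method SE of h2 from an observed-information matrix in
# (sigma_g2, sigma_e2)
h2_se_from_information <- function(ll_fn, sg2, se2) {
  H <- try(fd_hessian2(ll_fn, c(sg2, se2)), silent = TRUE)
  if (inherits(H, "try-error") || any(!is.finite(H))) return(NA_real_)
  Sigma <- try(solve(-H), silent = TRUE)
  if (inherits(Sigma, "try-error") || any(diag(Sigma) < 0)) return(NA_real_)
  tot <- sg2 + se2
  grad <- c(se2, -sg2) / tot^2
  v <- drop(t(grad) %*% Sigma %*% grad)
  if (!is.finite(v) || v < 0) return(NA_real_) else sqrt(v)
}

# feasible h2 interval keeping all rotated variances positive
h2_bounds <- function(d, eps = 1e-6) {
  dmax <- max(d); dmin <- min(d)
  lb <- if (dmax > 1) -1 / (dmax - 1) + eps else -5
  ub <- if (dmin < 1) 1 / (1 - dmin) - eps else 5
  c(lb, ub)
}

new_vc_fit <- function(class, h2, s2, ll_full, ll_null, n, kernel_label,
                       constrained, boundary_mixture, se_h2, mu = NA_real_) {
  lrt <- max(2 * (ll_full - ll_null), 0)
  structure(list(
    sigma_g2 = h2 * s2, sigma_e2 = (1 - h2) * s2, h2 = h2, mu = mu,
    loglik_full = ll_full, loglik_null = ll_null,
    lrt = lrt, p_value = lrt_pvalue(lrt, boundary_mixture),
    se_h2 = se_h2, n = n, kernel = kernel_label,
    constrained = constrained, boundary_mixture = boundary_mixture),
    class = c(class, "vc_fit"))
}

#' Fit the polygenic variance-components model by maximum likelihood
#'
#' Maximizes the multivariate-normal likelihood of `y` with mean `mu` and
#' covariance `V = sigma_g2 * K + sigma_e2 * I` over `(mu, sigma_g2,
#' sigma_e2)` with non-negative components, and compares it by LRT with the
#' nested individual-specific-effects-only model (`sigma_g2 = 0`). This is
#' the pedigree (QTDT-style) heritability model when `K = 2 * Phi`.
#'
#' @param y Named numeric vector (names = IID) of adjusted phenotype
#'   residuals, or a tibble with `iid` and `residual` columns; `NA`s are
#'   dropped.
#' @param kernel Relationship matrix (with IID dimnames) or a prepared
#'   [vc_kernel()]. If a matrix is given it is subset to the phenotyped IDs.
#' @param boundary_mixture Use the 50:50 chi-squared 0/1 mixture for the LRT
#'   P-value (default `TRUE`).
#' @return A `vc_fit` with components, log-likelihoods, `h2`, `lrt`,
#'   `p_value` and an information-based `se_h2` (see [wald_se_from_lrt()]
#'   for the LRT-based approximation).
#' @export
fit_vc_ml <- function(y, kernel, boundary_mixture = TRUE) {
  prep <- prepare_fit(y, kernel)
  if (min(prep$kernel$d) < -1e-6) {
    abort_famh2("kernel is not positive semidefinite (min eigenvalue %.3g)",
                min(prep$kernel$d))
  }
  d <- prep$kernel$d; yt <- prep$rot$yt; ut <- prep$rot$ut; n <- prep$rot$n
  ub <- min(1, h2_bounds(d)[2])
  opt <- stats::optimize(ml_profile_ll, c(0, ub), d = d, yt = yt, ut = ut,
                         n = n, maximum = TRUE, tol = 1e-8)
  # optimize() can miss a boundary maximum; check the endpoints explicitly
  cand_h2 <- c(opt$maximum, 0, ub)
  cand_ll <- c(opt$objective, ml_profile_ll(0, d, yt, ut, n),
               ml_profile_ll(ub, d, yt, ut, n))
  best <- which.max(cand_ll)
  h2 <- cand_h2[best]; ll_full <- cand_ll[best]
  ll_null <- ml_profile_ll(0, d, yt, ut, n)
  s2 <- profile_parts(h2, d, yt, ut)$q / n
  se <- h2_fisher_se(h2, d)
  mu <- profile_parts(h2, d, yt, ut)$mu
  new_vc_fit("vc_ml_fit", h2, s2, ll_full, ll_null, n,
             kernel_label = "pedigree-2phi/ML", constrained = TRUE,
             boundary_mixture = boundary_mixture, se_h2 = se, mu = mu)
}

#' Fit SNP heritability by REML on a (thresholded) GRM
#'
#' Maximizes the restricted likelihood (grand mean profiled out) of the
#' single-kernel model `V = sigma_g2 * A + sigma_e2 * I`. With
#' `constrained = TRUE` (the GCTA default, matching fits run without
#' `--no-constrain`) components are kept non-negative; unconstrained fits
#' allow negative components as long as every rotated variance stays
#' positive. The SE of h2 comes from the observed-information matrix of the
#' restricted likelihood by the delta method.
#'
#' @inheritParams fit_vc_ml
#' @param grm A `grm` object, matrix, or prepared [vc_kernel()].
#' @param constrained Clamp variance components at zero (default `TRUE`).
#' @return A `greml_fit` (also a `vc_fit`).
#' @export
fit_greml <- function(y, grm, constrained = TRUE, boundary_mixture = TRUE) {
  prep <- prepare_fit(y, grm)
  d <- prep$kernel$d; yt <- prep$rot$yt; ut <- prep$rot$ut; n <- prep$rot$n
  bounds <- h2_bounds(d)
  lo <- if (constrained) 0 else bounds[1]
  hi <- if (constrained) min(1, bounds[2]) else bounds[2]
  opt <- stats::optimize(reml_profile_ll, c(lo, hi), d = d, yt = yt,
                         ut = ut, n = n, maximum = TRUE, tol = 1e-8)
  cand_h2 <- c(opt$maximum, lo, hi)
  cand_ll <- c(opt$objective, reml_profile_ll(lo, d, yt, ut, n),
               reml_profile_ll(hi, d, yt, ut, n))
  best <- which.max(cand_ll)
  h2 <- cand_h2[best]; ll_full <- cand_ll[best]
  ll_null <- reml_profile_ll(0, d, yt, ut, n)
  s2 <- profile_parts(h2, d, yt, ut)$q / (n - 1)
  if (s2 <= 0 || h2 * s2 + (1 - h2) * s2 <= 0) {
    abort_famh2("degenerate REML fit: non-positive total variance")
  }
  interior <- if (constrained) (h2 > 1e-6 && h2 < 1 - 1e-6) else
    (h2 > bounds[1] + 1e-4 && h2 < bounds[2] - 1e-4)
  se <- if (interior) {
    h2_se_from_information(function(th) reml_ll_sigma(th, d, yt, ut, n),
                           h2 * s2, (1 - h2) * s2)
  } else NA_real_
  fit <- new_vc_fit("greml_fit", h2, s2, ll_full, ll_null, n,
                    kernel_label = "grm/REML", constrained = constrained,
                    boundary_mixture = boundary_mixture, se_h2 = se,
                    mu = profile_parts(h2, d, yt, ut)$mu)
  fit$cutoff <- if (inherits(grm, "grm")) grm$cutoff %||% NA_real_ else NA_real_
  fit
}

prepare_fit <- function(y, kernel) {
  if (is.data.frame(y)) {
    val_col <- intersect(c("residual", "value"), names(y))[1]
    y <- stats::setNames(y[[val_col]], y$iid)
  }
  y <- y[!is.na(y)]
  if (!inherits(kernel, "vc_kernel")) {
    K <- if (inherits(kernel, "grm")) kernel$A else kernel
    if (!is.null(names(y)) && !is.null(rownames(K))) {
      missing <- setdiff(names(y), rownames(K))
      if (length(missing)) {
        abort_famh2("phenotyped IDs missing from kernel: %s", missing[1])
      }
      K <- K[names(y), names(y), drop = FALSE]
    }
    kern <- vc_kernel(K)
    if (inherits(kernel, "grm")) kern$cutoff <- kernel$cutoff %||% NA_real_
  } else {
    kern <- kernel
  }
  list(kernel = kern, rot = rotate_phenotype(y, kern))
}

#' Wald-approximation standard error from an LRT statistic
#'
#' The reporting convention for pedigree variance-components heritability:
#' treating the LRT as a Wald test gives `se = h2 / sqrt(lrt)`. An LRT of
#' zero yields a missing SE (not an error).
#'
#' @param h2 Heritability estimate.
#' @param lrt Likelihood-ratio statistic (>= 0).
#' @return Approximate standard error, or `NA` when `lrt == 0`.
#' @export
wald_se_from_lrt <- function(h2, lrt) {
  if (any(lrt < 0)) abort_famh2("lrt must be non-negative")
  ifelse(lrt == 0, NA_real_, h2 / sqrt(lrt))
}

#' P-value for the variance-component LRT
#'
#' Because the null (`sigma_g2 = 0`) lies on the boundary of the parameter
#' space, the LRT is asymptotically a 50:50 mixture of a point mass at zero
#' and chi-squared with 1 df; `boundary_mixture = FALSE` gives the plain
#' chi-squared 1 df tail.
#'
#' @param lrt LRT statistic (>= 0).
#' @param boundary_mixture Use the mixture (default `TRUE`).
#' @return P-value.
#' @export
lrt_pvalue <- function(lrt, boundary_mixture = TRUE) {
  if (any(lrt < 0)) abort_famh2("lrt must be non-negative")
  tail <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  if (boundary_mixture) ifelse(lrt == 0, 1, 0.5 * tail) else tail
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d)\n", x$kernel, x$n))
  cat(sprintf("  h2 = %.3f (SE %.3f)   sigma_g2 = %.3f, sigma_e2 = %.3f\n",
              x$h2, x$se_h2, x$sigma_g2, x$sigma_e2))
  cat(sprintf("  LRT = %.3f, P = %.3g%s\n", x$lrt, x$p_value,
              if (x$boundary_mixture) " (boundary mixture)" else ""))
  invisible(x)
}

#' @export
tidy.vc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("h2", "sigma_g2", "sigma_e2"),
    estimate = c(x$h2, x$sigma_g2, x$sigma_e2),
    std_error = c(x$se_h2, NA_real_, NA_real_))
}

#' @export
glance.vc_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, se_h2 = x$se_h2, sigma_g2 = x$sigma_g2,
                 sigma_e2 = x$sigma_e2, loglik_full = x$loglik_full,
                 loglik_null = x$loglik_null, lrt = x$lrt,
                 p_value = x$p_value, n = x$n, kernel = x$kernel,
                 constrained = x$constrained)
}
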