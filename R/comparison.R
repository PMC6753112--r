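# Cross-modality comparison statistics: relative-pair correlations, Fisher z,
# heterogeneity tests, power simulation, Spearman confounding check.

#' Correlation between relatives for a residualized phenotype
#'
#' Symmetric pair classes (sibling, avuncular) use double entry — each pair
#' contributes in both orders — so the correlation is invariant to
#' within-pair ordering; parent-child pairs put the parent on the x axis.
#' Fewer than 3 usable pairs yields an `NA` correlation.
#'
#' @param residuals Named numeric vector (names = IID) or tibble with `iid`
#'   and `residual` columns.
#' @param pairs Pair tibble from [extract_relative_pairs()].
#' @param class Pair class to use.
#' @return Tibble `class`, `r`, `n_pairs` (distinct pairs with both members
#'   observed).
#' @export
relative_pair_correlation <- function(residuals, pairs,
                                      class = c("sibling", "parent-child",
                                                "avuncular")) {
  class <- match.arg(class)
  if (is.data.frame(residuals)) {
    residuals <- stats::setNames(residuals$residual, residuals$iid)
  }
  pr <- pairs[pairs$class == class, , drop = FALSE]
  x <- residuals[pr$iid1]
  y <- residuals[pr$iid2]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n_pairs <- length(x)
  if (n_pairs < 3) {
    return(tibble::tibble(class = class, r = NA_real_, n_pairs = n_pairs))
  }
  r <- if (class == "parent-child") {
    stats::cor(x, y)
  } else {
    stats::cor(c(x, y), c(y, x))   # double entry
  }
  tibble::tibble(class = class, r = r, n_pairs = n_pairs)
}

#' Compare two correlations by Fisher's z-transformation
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal P-value.
#'
#' @param r1,r2 Correlations (|r| < 1).
#' @param n1,n2 Group sizes (> 3).
#' @return Tibble `z`, `p_value`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Heterogeneity test between two heritability estimates
#'
#' Independent-estimates approximation
#' `z = (h2_a - h2_b) / sqrt(se_a^2 + se_b^2)` with a two-sided normal
#' P-value. The covariance between estimates computed on overlapping
#' individuals is ignored; the output notes this.
#'
#' @param h2_a,h2_b Heritability estimates.
#' @param se_a,se_b Their standard errors (> 0).
#' @return Tibble `z`, `p_value`, `note`.
#' @export
heterogeneity_test <- function(h2_a, se_a, h2_b, se_b) {
  stopifnot(se_a > 0, se_b > 0)
  z <- (h2_a - h2_b) / sqrt(se_a^2 + se_b^2)
  tibble::tibble(z = z, p_value = 2 * stats::pnorm(-abs(z)),
                 note = "independent-estimates approximation; covariance from overlapping individuals ignored")
}

#' Spearman correlation for the chest-size confounding check
#'
#' Rank correlation with average-rank ties and a P-value from the
#' t-approximation.
#'
#' @param x,y Paired observations (complete pairs used; `n >= 5`).
#' @return Tibble `rho`, `n`, `p_value`.
#' @export
spearman_confounding <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) abort_famh2("need at least 5 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_famh2("Spearman correlation undefined for constant input")
  }
  rho <- stats::cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  tibble::tibble(rho = rho, n = n,
                 p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Sampling-error power simulation for the family panel
#'
#' Per replicate: simulate a polygenic trait at the true heritability on the
#' phenotyped panel of the family design, fit the maximum-likelihood
#' variance-components model, and record the estimate. The empirical SD of
#' the estimates is the predicted sampling standard error of the design.
#'
#' @param spec A [pedigree_spec()] (the panel design), or a pedigree tibble.
#' @param true_h2 True narrow-sense heritability of the simulated trait.
#' @param n_replicates Number of replicates (>= 100).
#' @param seed Master seed.
#' @return A `power_result`: `true_h2`, `n_replicates`, `mean_h2`,
#'   `se_empirical`, panel descriptor, and the per-replicate estimates.
#' @export
power_simulation <- function(spec = pedigree_spec(), true_h2 = 0.35,
                             n_replicates = 200, seed = 1) {
  if (n_replicates < 100) abort_famh2("n_replicates must be >= 100")
  ped <- if (inherits(spec, "pedigree_spec")) simulate_pedigrees(spec) else spec
  panel <- if ("phenotyped" %in% names(ped)) ped$iid[ped$phenotyped] else ped$iid
  kern <- vc_kernel(2 * kinship_matrix(ped, ids = panel))
  est <- rep(NA_real_, n_replicates)
  for (r in seq_len(n_replicates)) {
    g <- simulate_polygenic(ped, h2 = true_h2, seed = seed,
                            stream = paste0("power/", r))
    set_stream_seed(seed, paste0("power-env/", r))
    y <- g[panel] + stats::rnorm(length(panel), 0, sqrt(1 - true_h2))
    names(y) <- panel
    fit <- try(fit_vc_ml(y, kern), silent = TRUE)
    if (!inherits(fit, "try-error")) est[r] <- fit$h2
  }
  dropped <- sum(is.na(est))
  if (dropped > 0.05 * n_replicates) {
    abort_famh2("more than 5%% of replicates failed to converge (%d/%d)",
                dropped, n_replicates)
  }
  est <- est[!is.na(est)]
  structure(list(
    true_h2 = true_h2, n_replicates = length(est),
    mean_h2 = mean(est), se_empirical = stats::sd(est),
    panel = sprintf("%d families / %d phenotyped individuals",
                    length(unique(ped$fid)), length(panel)),
    estimates = est, dropped = dropped),
    class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Power simulation on %s\n", x$panel))
  cat(sprintf("  true h2 = %.2f; mean estimate = %.3f over %d replicates\n",
              x$true_h2, x$mean_h2, x$n_replicates))
  cat(sprintf("  empirical sampling SE of h2 = %.3f (%.1f%% points)\n",
              x$se_empirical, 100 * x$se_empirical))
  invisible(x)
}

#' @export
tidy.power_result <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$estimates), h2_hat = x$estimates)
}

#' @export
glance.power_result <- function(x, ...) {
  tibble::tibble(true_h2 = x$true_h2, n_replicates = x$n_replicates,
                 mean_h2 = x$mean_h2, se_empirical = x$se_empirical,
                 panel = x$panel)
}

#' @export
autoplot.power_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$h2_hat)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$true_h2, linetype = "dashed") +
    ggplot2::labs(
      x = expression(hat(h)^2),
      y = "replicates",
      title = sprintf("Sampling distribution of the h2 estimate (%s)",
                      object$panel),
      subtitle = sprintf("true h2 = %.2f; empirical SE = %.1f%% points",
                         object$true_h2, 100 * object$se_empirical)) +
    ggplot2::theme_minimal()
}

#' Scatter data and plot for relative-pair residuals
#'
#' @param residuals Named residual vector or tibble (`iid`, `residual`).
#' @param pairs Pair tibble from [extract_relative_pairs()].
#' @return ggplot faceted by pair class, annotated with the double-entry
#'   correlation and distinct-pair count.
#' @export
plot_relative_pairs <- function(residuals, pairs) {
  if (is.data.frame(residuals)) {
    residuals <- stats::setNames(residuals$residual, residuals$iid)
  }
  df <- dplyr::mutate(pairs, x = residuals[.data$iid1],
                      y = residuals[.data$iid2])
  df <- df[!is.na(df$x) & !is.na(df$y), , drop = FALSE]
  ann <- dplyr::bind_rows(lapply(unique(df$class), function(cl) {
    relative_pair_correlation(residuals, pairs, cl)
  }))
  ann$label <- sprintf("r = %.2f (n = %d)", ann$r, ann$n_pairs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~class) +
    ggplot2::geom_text(data = ann, ggplot2::aes(label = .data$label),
                       x = Inf, y = Inf, hjust = 1.1, vjust = 1.5,
                       inherit.aes = FALSE) +
    ggplot2::labs(x = "residual (member 1)", y = "residual (member 2)") +
    ggplot2::theme_minimal()
}
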