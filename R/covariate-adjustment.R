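# Pre-heritability phenotype adjustment: treatment-adjusted blood pressure,
# Box-Cox normalization, stepwise covariate selection, residual extraction.

#' Pre-adjust blood pressure for antihypertensive treatment
#'
#' Treated individuals have 15 mmHg added to systolic and 10 mmHg added to
#' diastolic pressure; untreated values pass through unchanged. Apply exactly
#' once: the operation is deliberately not idempotent.
#'
#' @param sbp Systolic BP, mmHg.
#' @param dbp Diastolic BP, mmHg.
#' @param treated Logical treatment indicator.
#' @return Tibble with `sbp_adj`, `dbp_adj`.
#' @export
treatment_adjust_bp <- function(sbp, dbp, treated) {
  if (any(sbp <= dbp, na.rm = TRUE) || any(dbp <= 0, na.rm = TRUE)) {
    abort_famh2("require sbp > dbp > 0")
  }
  tibble::tibble(sbp_adj = sbp + 15 * as.numeric(treated),
                 dbp_adj = dbp + 10 * as.numeric(treated))
}

boxcox_transform <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

# profile log-likelihood of the Box-Cox model at lambda (normal likelihood
# of the transformed data, variance profiled out, plus the Jacobian term)
boxcox_profile_ll <- function(y, lambda) {
  n <- length(y)
  z <- boxcox_transform(y, lambda)
  s2 <- mean((z - mean(z))^2)
  -n / 2 * log(s2) + (lambda - 1) * sum(log(y))
}

#' Box-Cox maximum-likelihood transformation
#'
#' Finds the power-transform parameter maximizing the profile log-likelihood
#' over lambda in `[-3, 3]` by a 601-point coarse grid refined with
#' golden-section optimization to 1e-4, then transforms the data.
#'
#' @param y Positive values, `n >= 10`.
#' @param interval Search interval for lambda.
#' @return A `boxcox_fit`: `lambda`, `loglik`, `transformed`, plus the grid.
#' @export
boxcox_mle <- function(y, interval = c(-3, 3)) {
  y <- y[!is.na(y)]
  if (length(y) < 10) abort_famh2("Box-Cox needs at least 10 observations")
  if (any(y <= 0)) abort_famh2("Box-Cox requires strictly positive values (no automatic shifting)")
  if (stats::sd(y) < 1e-12) abort_famh2("Box-Cox undefined for constant input")
  grid <- seq(interval[1], interval[2], length.out = 601)
  ll <- vapply(grid, function(l) boxcox_profile_ll(y, l), 0)
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(function(l) boxcox_profile_ll(y, l),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-5)
  lambda <- opt$maximum
  structure(list(lambda = lambda, loglik = opt$objective,
                 transformed = boxcox_transform(y, lambda),
                 grid = tibble::tibble(lambda = grid, loglik = ll)),
            class = "boxcox_fit")
}

#' @export
print.boxcox_fit <- function(x, ...) {
  cat(sprintf("Box-Cox fit: lambda = %.4f (profile logLik %.2f)\n",
              x$lambda, x$loglik))
  invisible(x)
}

# partial t-test P-values for each non-intercept term of an OLS fit
partial_p <- function(fit) {
  s <- summary(fit)$coefficients
  p <- s[, 4]
  p[setdiff(rownames(s), "(Intercept)")]
}

#' Forward-backward stepwise covariate selection
#'
#' Classic stepwise on ordinary least squares: at each step the candidate
#' with the smallest partial-test P-value enters if below the threshold,
#' then any included covariate whose P-value has risen to or above the
#' threshold is removed; iteration stops at a fixed point. Ties are broken
#' by candidate column order, making the procedure deterministic. A
#' candidate whose coefficient is inestimable (perfect collinearity with the
#' current model) is skipped with a warning.
#'
#' @param y Response values (already transformed).
#' @param candidates Data frame of candidate covariates (numeric columns).
#' @param threshold Entry/stay P-value threshold (default 0.01).
#' @return An `adjustment_model`: selected covariate names, coefficients,
#'   the fitted `lm`, threshold, and the observations used.
#' @export
stepwise_select <- function(y, candidates, threshold = 0.01) {
  stopifnot(is.data.frame(candidates))
  dat <- data.frame(.y = y, candidates, check.names = FALSE)
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  cand_names <- names(candidates)
  selected <- character(0)
  fit_model <- function(vars) {
    rhs <- if (length(vars)) paste(sprintf("`%s`", vars), collapse = " + ") else "1"
    stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
  }
  repeat {
    changed <- FALSE
    # forward step
    pool <- setdiff(cand_names, selected)
    if (length(pool)) {
      pvals <- rep(NA_real_, length(pool))
      for (k in seq_along(pool)) {
        fit <- fit_model(c(selected, pool[k]))
        if (any(is.na(stats::coef(fit)))) {
          warning(sprintf("candidate '%s' collinear with current model; skipped",
                          pool[k]), call. = FALSE)
          next
        }
        p <- partial_p(fit)
        pvals[k] <- p[match(pool[k], gsub("`", "", names(p)))]
      }
      ok <- which(!is.na(pvals) & pvals < threshold)
      if (length(ok)) {
        best <- ok[which.min(pvals[ok])]   # ties: first (column order)
        selected <- c(selected, pool[best])
        changed <- TRUE
      }
    }
    # backward step
    repeat {
      if (!length(selected)) break
      fit <- fit_model(selected)
      p <- partial_p(fit)
      names(p) <- gsub("`", "", names(p))
      worst <- which(p[selected] >= threshold)
      if (!length(worst)) break
      drop_ix <- worst[which.max(p[selected][worst])]
      selected <- setdiff(selected, selected[drop_ix])
      changed <- TRUE
    }
    if (!changed) break
  }
  fit <- fit_model(selected)
  structure(list(selected = selected, coefficients = stats::coef(fit),
                 threshold = threshold, fit = fit, cases = cc),
            class = "adjustment_model")
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat("Stepwise adjustment model (P <", x$threshold, ")\n")
  cat("  selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' @export
tidy.adjustment_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1],
                 std_error = s[, 2], statistic = s[, 3], p_value = s[, 4])
}

#' Residualize a phenotype against an adjustment model
#'
#' Returns `y - fitted`; with an empty model this is mean-centering.
#' Residuals have mean zero and are orthogonal to every selected covariate.
#'
#' @param model An `adjustment_model` from [stepwise_select()].
#' @return Numeric residuals, `NA` where the model's casewise deletion
#'   dropped the observation.
#' @export
residualize <- function(model) {
  stopifnot(inherits(model, "adjustment_model"))
  out <- rep(NA_real_, length(model$cases))
  out[model$cases] <- stats::resid(model$fit)
  out
}

#' Full per-trait adjustment pipeline
#'
#' Optionally Box-Cox-transforms the trait, then runs stepwise covariate
#' selection and extracts residuals — the phenotype values entering the
#' heritability fits. Blood-pressure candidates should already be
#' treatment-adjusted (see [treatment_adjust_bp()]).
#'
#' @param data Derived-phenotype tibble (`fid`, `iid`, trait + candidates).
#' @param trait Trait column name.
#' @param candidates Character vector of candidate covariate columns.
#' @param boxcox Apply the Box-Cox transform first? (default `TRUE`).
#' @param threshold Stepwise entry/stay P threshold.
#' @return Tibble `fid`, `iid`, `residual` (NA where unphenotyped), with the
#'   `adjustment_model` and any `boxcox_fit` as attributes.
#' @export
adjust_phenotype <- function(data, trait, candidates, boxcox = TRUE,
                             threshold = 0.01) {
  stopifnot(trait %in% names(data), all(candidates %in% names(data)))
  y <- data[[trait]]
  usable <- !is.na(y) & stats::complete.cases(data[candidates])
  bc <- NULL
  y_t <- y
  if (boxcox) {
    bc <- boxcox_mle(y[usable])
    y_t[usable] <- bc$transformed
  }
  model <- stepwise_select(y_t[usable],
                           as.data.frame(data[usable, candidates,
                                              drop = FALSE]),
                           threshold = threshold)
  res <- rep(NA_real_, nrow(data))
  res[usable] <- residualize(model)
  out <- tibble::tibble(fid = data$fid, iid = data$iid, residual = res)
  attr(out, "model") <- model
  attr(out, "boxcox") <- bc
  out
}
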