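# End-to-end orchestration: simulate/ingest -> derive -> adjust ->
# kinship/GRM -> heritability (both kernels) -> comparisons.

#' Default per-trait adjustment recipes
#'
#' Candidate covariates follow the covariate-screening set: age, sex,
#' height, weight, BSA, BMI and treatment-adjusted SBP/DBP; the
#' chest-adjusted ECG LVM recipe adds the CMR chest lateral diameter.
#' @export
default_recipes <- function() {
  base_cands <- c("age", "sex", "height", "weight", "bsa", "bmi",
                  "sbp_adj", "dbp_adj")
  list(
    list(trait = "ecg_lvm", candidates = base_cands, boxcox = TRUE),
    list(trait = "ecg_lvm", label = "ecg_lvm_chestadj",
         candidates = c(base_cands, "chest_lateral_diameter"),
         boxcox = TRUE),
    list(trait = "cmr_lvm", candidates = base_cands, boxcox = TRUE),
    list(trait = "cmr_lvm_index", candidates = base_cands, boxcox = TRUE),
    list(trait = "rv_mass", candidates = base_cands, boxcox = TRUE),
    list(trait = "sokolow_lyon", candidates = base_cands, boxcox = TRUE),
    list(trait = "sokolow_lyon_product", candidates = base_cands,
         boxcox = TRUE)
  )
}

#' Build a pipeline run configuration
#'
#' @param simulate List of simulation specs (`ped_spec`, `geno_spec`,
#'   `model`) or `NULL` to ingest files.
#' @param inputs List of input paths (`fam`, `ped_map_prefix`, `pheno`) when
#'   not simulating.
#' @param recipes Per-trait adjustment recipes (see [default_recipes()]);
#'   each is a list with `trait`, `candidates`, `boxcox`, optional `label`.
#' @param qc QC thresholds ([qc_thresholds()]).
#' @param grm_cutoff IBS threshold for the GRM (default 0.05).
#' @param voltage_scale ECG LVM voltage rescaling; `NULL` means take it
#'   from the simulated cohort's truth (or 1.0 for ingested data).
#' @param bsa_formula BSA formula for CMR indices.
#' @param constrained,boundary_mixture Heritability fit options.
#' @param threshold Stepwise entry/stay P threshold.
#' @param seed Master seed.
#' @param out_dir Optional directory for intermediate artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = list(ped_spec = pedigree_spec(),
                                       geno_spec = genotype_spec(),
                                       model = trait_model()),
                       inputs = NULL,
                       recipes = default_recipes(),
                       qc = qc_thresholds(),
                       grm_cutoff = 0.05,
                       voltage_scale = NULL,
                       bsa_formula = "dubois",
                       constrained = TRUE,
                       boundary_mixture = TRUE,
                       threshold = 0.01,
                       seed = 1,
                       out_dir = NULL) {
  if (is.null(simulate) && is.null(inputs)) {
    abort_famh2("config needs either a simulation spec or input paths")
  }
  if (length(recipes) == 0) abort_famh2("config has an empty trait list")
  structure(list(simulate = simulate, inputs = inputs, recipes = recipes,
                 qc = qc, grm_cutoff = grm_cutoff,
                 voltage_scale = voltage_scale, bsa_formula = bsa_formula,
                 constrained = constrained,
                 boundary_mixture = boundary_mixture, threshold = threshold,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    s <- y$simulate
    sim <- list(
      ped_spec = pedigree_spec(
        n_families = s$n_families %||% 116,
        target_total_individuals = s$target_total_individuals %||% 427,
        seed = y$seed %||% 1),
      geno_spec = genotype_spec(n_snps = s$n_snps %||% 2000,
                                n_causal = s$n_causal %||% 20),
      model = trait_model())
  }
  recipes <- y$recipes %||% default_recipes()
  run_config(simulate = sim, inputs = y$inputs, recipes = recipes,
             qc = utils::modifyList(qc_thresholds(), y$qc %||% list()),
             grm_cutoff = y$grm_cutoff %||% 0.05,
             voltage_scale = y$voltage_scale,
             bsa_formula = y$bsa_formula %||% "dubois",
             constrained = y$constrained %||% TRUE,
             boundary_mixture = y$boundary_mixture %||% TRUE,
             threshold = y$threshold %||% 0.01,
             seed = y$seed %||% 1, out_dir = y$out_dir)
}

stage_log <- function(run_log, stage, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s", stage, msg))
  c(run_log, stats::setNames(list(msg), stage))
}

#' Run the full heritability pipeline
#'
#' Stage order is fixed: simulate or ingest; derive phenotypes; pre-adjust
#' blood pressure for treatment; per trait Box-Cox, stepwise selection and
#' residualization; pedigree kinship and QC'd, IBS-thresholded GRM; both
#' heritability fits per trait; relative-pair correlations and the
#' chest-confounding check. Rerunning with the same config and seed
#' reproduces the report exactly.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return A `famh2_run`: `report` tibble (one row per trait, both h2
#'   estimates with SEs and P-values), `comparisons`, `qc_report`,
#'   `adjustments`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  run_log <- list()

  # -- stage: input -------------------------------------------------------
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate$ped_spec %||% pedigree_spec(),
                              config$simulate$geno_spec %||% genotype_spec(),
                              config$simulate$model %||% trait_model(),
                              seed = seed)
    ped <- cohort$pedigree
    geno <- cohort$genotypes
    raw <- cohort$phenotypes
    voltage_scale <- config$voltage_scale %||% cohort$truth$voltage_scale
    run_log <- stage_log(run_log, "simulate",
                         "%d families, %d individuals (%d phenotyped), %d SNPs",
                         length(unique(ped$fid)), nrow(ped),
                         sum(ped$phenotyped), ncol(geno$dosage))
  } else {
    ped <- parse_pedigree(config$inputs$fam)
    geno <- read_ped_map(config$inputs$ped_map_prefix)
    raw <- read_pheno_table(config$inputs$pheno)
    cohort <- NULL
    voltage_scale <- config$voltage_scale %||% 1.0
    run_log <- stage_log(run_log, "ingest",
                         "%d individuals, %d SNPs", nrow(ped),
                         ncol(geno$dosage))
  }

  # -- stage: derive ------------------------------------------------------
  derived <- derive_phenotypes(raw, bsa_formula = config$bsa_formula,
                               voltage_scale = voltage_scale)
  derived$bmi <- derived$weight / derived$height^2
  bp <- treatment_adjust_bp(derived$sbp, derived$dbp, derived$treated)
  derived$sbp_adj <- bp$sbp_adj
  derived$dbp_adj <- bp$dbp_adj
  if ("phenotyped" %in% names(derived)) {
    unphenotyped <- !derived$phenotyped
    trait_cols <- setdiff(names(derived),
                          c("fid", "iid", "phenotyped"))
    derived[unphenotyped, trait_cols] <- NA
    run_log <- stage_log(run_log, "derive", "%d phenotyped, %d excluded",
                         sum(!unphenotyped), sum(unphenotyped))
  }

  # -- stage: relatedness -------------------------------------------------
  phi <- kinship_matrix(ped)
  qc <- qc_genotypes(geno, ped, thresholds = config$qc)
  grm <- threshold_grm(compute_grm(qc$genotypes), cutoff = config$grm_cutoff)
  run_log <- stage_log(run_log, "relatedness",
                       "GRM on %d individuals x %d SNPs, IBS cutoff %.2f",
                       nrow(grm$A), ncol(qc$genotypes$dosage),
                       config$grm_cutoff)

  # -- stage: adjust + heritability --------------------------------------
  rows <- list()
  adjustments <- list()
  residuals_by_label <- list()
  for (rec in config$recipes) {
    label <- rec$label %||% rec$trait
    adj <- tryCatch(
      adjust_phenotype(derived, rec$trait, rec$candidates,
                       boxcox = rec$boxcox %||% TRUE,
                       threshold = config$threshold),
      error = function(e) abort_famh2("stage adjust, trait %s: %s",
                                      label, conditionMessage(e)))
    adjustments[[label]] <- attr(adj, "model")
    residuals_by_label[[label]] <- adj
    y <- stats::setNames(adj$residual, adj$iid)
    y <- y[!is.na(y)]
    fit_ped <- tryCatch(
      fit_vc_ml(y, 2 * phi[names(y), names(y)],
                boundary_mixture = config$boundary_mixture),
      error = function(e) abort_famh2("stage h2-pedigree, trait %s: %s",
                                      label, conditionMessage(e)))
    y_g <- y[names(y) %in% rownames(grm$A)]
    fit_grm <- tryCatch(
      fit_greml(y_g, grm, constrained = config$constrained,
                boundary_mixture = config$boundary_mixture),
      error = function(e) abort_famh2("stage h2-grm, trait %s: %s",
                                      label, conditionMessage(e)))
    rows[[label]] <- tibble::tibble(
      trait = label,
      n_phenotyped = length(y),
      h2_pedigree = fit_ped$h2,
      se_pedigree = wald_se_from_lrt(fit_ped$h2, fit_ped$lrt),
      p_pedigree = fit_ped$p_value,
      n_genotyped = length(y_g),
      h2_grm = fit_grm$h2,
      se_grm = fit_grm$se_h2,
      p_grm = fit_grm$p_value,
      covariates = paste(adjustments[[label]]$selected, collapse = "+"))
  }
  report <- dplyr::bind_rows(rows)
  run_log <- stage_log(run_log, "heritability", "%d traits fitted",
                       nrow(report))

  # -- stage: comparisons -------------------------------------------------
  pairs <- extract_relative_pairs(ped)
  comparisons <- list()
  for (label in names(residuals_by_label)) {
    comparisons[[label]] <- dplyr::bind_rows(lapply(
      c("sibling", "parent-child", "avuncular"),
      function(cl) relative_pair_correlation(residuals_by_label[[label]],
                                             pairs, cl)))
  }
  ok <- !is.na(derived$chest_lateral_diameter) & !is.na(derived$ecg_lvm)
  confounding <- spearman_confounding(derived$chest_lateral_diameter[ok],
                                      derived$ecg_lvm[ok])
  run_log <- stage_log(run_log, "compare",
                       "chest/ECG-LVM Spearman rho = %.3f", confounding$rho)

  res <- structure(list(report = report, comparisons = comparisons,
                        confounding = confounding, qc_report = qc$report,
                        adjustments = adjustments, config = config,
                        seed = seed, log = run_log),
                   class = "famh2_run")
  if (!is.null(config$out_dir)) write_run(res, derived, ped, grm, phi)
  res
}

# intermediate artifacts, each independently consumable by its stage
write_run <- function(res, derived, ped, grm, phi) {
  dir <- res$config$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_pheno_table(derived, file.path(dir, "derived.pheno"))
  write_fam(ped, file.path(dir, "pedigree.fam"))
  write_grm(grm$A, grm$ids, file.path(dir, "grm"), grm$n_snps)
  kin_ids <- tibble::tibble(fid = ped$fid[match(rownames(phi), ped$iid)],
                            iid = rownames(phi))
  write_grm(2 * phi, kin_ids, file.path(dir, "kinship2phi"))
  utils::write.table(as.data.frame(res$report),
                     file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(report = res$report, confounding = res$confounding,
         qc = res$qc_report, seed = res$seed),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.famh2_run <- function(x, ...) {
  cat("famh2 pipeline run (seed", x$seed, ")\n\n")
  print(as.data.frame(x$report), digits = 3, row.names = FALSE)
  cat(sprintf("\nchest/ECG-LVM Spearman rho = %.3f (P = %.3g)\n",
              x$confounding$rho, x$confounding$p_value))
  invisible(x)
}

#' @export
tidy.famh2_run <- function(x, ...) x$report

#' @export
autoplot.famh2_run <- function(object, ...) {
  df <- tidyr::pivot_longer(object$report,
                            cols = c("h2_pedigree", "h2_grm"),
                            names_to = "method", values_to = "h2")
  df$se <- ifelse(df$method == "h2_pedigree",
                  object$report$se_pedigree[match(df$trait,
                                                  object$report$trait)],
                  object$report$se_grm[match(df$trait,
                                             object$report$trait)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$h2,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$h2 - 1.96 * .data$se, 0),
                   ymax = pmin(.data$h2 + 1.96 * .data$se, 1)),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::labs(x = NULL, y = expression(hat(h)^2),
                  fill = "kernel / criterion") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
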