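# Polygenic genetic values and the synthetic phenotype/covariate model.

#' Simulate polygenic genetic values on a pedigree
#'
#' `pedigree-mvn` mode draws values with covariance `2 * Phi * sigma_g2` by
#' the founder/segregation decomposition: founders are independent
#' `N(0, sigma_g2)`; each non-founder is the mean of its parents' values plus
#' an independent segregation deviate of variance `sigma_g2 / 2` (non-inbred
#' parents). An unknown parent is replaced by a fresh phantom-founder draw.
#' `genotype-causal` mode sums standardized causal-SNP dosages times
#' `N(0, sigma_g2 / n_causal)` effects.
#'
#' @param ped Pedigree tibble.
#' @param h2 Target narrow-sense heritability in `[0, 1]`; the genetic
#'   variance is `sigma_g2 = h2` on the unit-total-variance scale.
#' @param mode `"pedigree-mvn"` or `"genotype-causal"`.
#' @param genotypes Genotype list from [drop_genotypes()]; required for
#'   genotype-causal mode.
#' @param seed Integer seed.
#' @param stream Substream label, so that several traits can draw
#'   independent genetic values from one master seed.
#' @return Named numeric vector of genetic values (names = IID).
#' @export
simulate_polygenic <- function(ped, h2, mode = c("pedigree-mvn",
                                                 "genotype-causal"),
                               genotypes = NULL, seed = 1,
                               stream = "polygenic") {
  mode <- match.arg(mode)
  if (h2 < 0 || h2 > 1) abort_famh2("h2 must be in [0, 1]")
  ped <- ped[pedigree_order(ped), , drop = FALSE]
  n <- nrow(ped)
  set_stream_seed(seed, paste0("polygenic/", stream))
  sg <- sqrt(h2)
  if (h2 == 0) return(stats::setNames(rep(0, n), ped$iid))
  if (mode == "pedigree-mvn") {
    idx <- stats::setNames(seq_len(n), ped$iid)
    g <- numeric(n)
    for (i in seq_len(n)) {
      f <- if (ped$pat[i] %in% ped$iid) idx[[ped$pat[i]]] else 0L
      m <- if (ped$mat[i] %in% ped$iid) idx[[ped$mat[i]]] else 0L
      if (f == 0L && m == 0L) {
        g[i] <- stats::rnorm(1, 0, sg)
      } else {
        gf <- if (f > 0L) g[f] else stats::rnorm(1, 0, sg)
        gm <- if (m > 0L) g[m] else stats::rnorm(1, 0, sg)
        g[i] <- 0.5 * (gf + gm) + stats::rnorm(1, 0, sg / sqrt(2))
      }
    }
    stats::setNames(g, ped$iid)
  } else {
    if (is.null(genotypes)) {
      abort_famh2("genotype-causal mode requires genotypes")
    }
    X <- genotypes$dosage[, genotypes$causal, drop = FALSE]
    p <- genotypes$freq[match(genotypes$causal, genotypes$map$snp)]
    Z <- sweep(X, 2, 2 * p)
    Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
    beta <- stats::rnorm(ncol(Z), 0, sqrt(h2 / ncol(Z)))
    g <- drop(Z %*% beta)
    stats::setNames(g, ped$iid[match(rownames(X), ped$iid)])
  }
}

#' Ground-truth trait model for the synthetic cohort
#'
#' Defaults emulate the study cohort: age ~ N(59.7, 13^2) truncated to
#' [18, 95]; 52.5% female; height h2 0.75; heritable weight, chest lateral
#' diameter and ECG voltage latents; CMR LV mass residual h2 0.20, RV mass
#' 0.44, LV end-diastolic volume 0.40; and a chest-lateral-diameter loading
#' on the ECG voltage latent (`confounder_loading`, default 0.8 on the
#' standardized scale) calibrated so that Spearman rho between chest lateral
#' diameter and derived ECG LV mass is ~0.67 and chest adjustment attenuates
#' the ECG LVM residual heritability (chest channel more heritable than the
#' direct voltage channel).
#'
#' @param h2 Named vector of target heritabilities for the latent genetic
#'   streams (`height`, `weight`, `chest`, `voltage`, `sokolow`, `cmr_lvm`,
#'   `rv_mass`, `lv_edv`).
#' @param confounder_loading Coefficient of standardized chest lateral
#'   diameter on the standardized ECG voltage latent.
#' @param treatment_prevalence Antihypertensive-treatment prevalence.
#' @param voltage_scale Voltage rescaling under which derived ECG LVM carries
#'   the designed structure (see the methods vignette on the unit ambiguity
#'   of the ECG LVM equation).
#' @param residual_sd Named vector of residual SDs on the measurement scale.
#' @return A `trait_model` list with all generating parameters.
#' @export
trait_model <- function(h2 = c(height = 0.75, weight = 0.55, chest = 0.65,
                               voltage = 0.52, sokolow = 0.55,
                               cmr_lvm = 0.20, rv_mass = 0.44, lv_edv = 0.40),
                        confounder_loading = 0.8,
                        treatment_prevalence = 0.30,
                        voltage_scale = 125,
                        residual_sd = c(cmr_lvm = 20, rv_mass = 10,
                                        lv_edv = 20)) {
  if (any(h2 < 0 | h2 > 1)) abort_famh2("all h2 must be in [0, 1]")
  if (any(residual_sd <= 0)) abort_famh2("residual SDs must be positive")
  if (treatment_prevalence < 0 || treatment_prevalence > 1) {
    abort_famh2("treatment_prevalence must be in [0, 1]")
  }
  structure(list(h2 = h2, confounder_loading = confounder_loading,
                 treatment_prevalence = treatment_prevalence,
                 voltage_scale = voltage_scale, residual_sd = residual_sd),
            class = "trait_model")
}

# streams of genetic values simulate_traits() requires
trait_model_streams <- function(model) names(model$h2)

#' Simulate phenotypes and covariates on a pedigree
#'
#' Builds sex, age, height, weight, blood pressure with a treatment
#' indicator, chest dimensions, CMR ventricular masses/volumes and raw ECG
#' voltages, wiring the supplied standardized genetic values into each trait
#' at the model's target heritabilities. The chest-diameter loading on the
#' ECG voltage latent creates the confounding by which derived ECG LV mass
#' correlates with chest size.
#'
#' @param ped Pedigree tibble.
#' @param model A [trait_model()].
#' @param genetic Named list of standardized (unit-variance) genetic value
#'   vectors, one per stream in `trait_model_streams(model)` (built with
#'   [simulate_polygenic()] at `h2 = 1`).
#' @param seed Integer seed for the environmental draws.
#' @return Tibble of per-individual measurements (one row per pedigree
#'   member, `phenotyped` flag carried through).
#' @export
simulate_traits <- function(ped, model, genetic, seed = 1) {
  stopifnot(inherits(model, "trait_model"))
  ped <- ped[pedigree_order(ped), , drop = FALSE]
  n <- nrow(ped)
  need <- trait_model_streams(model)
  missing <- setdiff(need, names(genetic))
  if (length(missing)) {
    abort_famh2("missing genetic values for heritable trait stream: %s",
                paste(missing, collapse = ", "))
  }
  G <- lapply(genetic, function(g) {
    if (!all(ped$iid %in% names(g))) {
      abort_famh2("genetic values missing for some pedigree members")
    }
    unname(g[ped$iid])
  })
  h2 <- model$h2
  env <- function(stream, n_draw = n) {
    set_stream_seed(seed, paste0("env/", stream))
    stats::rnorm(n_draw)
  }
  set_stream_seed(seed, "env/sex")
  sex <- ifelse(stats::runif(n) < 0.525, 2L, 1L)   # 52.5% female
  s <- ifelse(sex == 1L, 1, -1)                    # +1 male, -1 female
  set_stream_seed(seed, "env/age")
  age <- rnorm_trunc(n, 59.7, 13, 18, 95)

  # standardized latents; each mixes its genetic stream at the target h2
  latent <- function(stream) {
    sqrt(h2[[stream]]) * G[[stream]] + sqrt(1 - h2[[stream]]) * env(stream)
  }
  h_z <- latent("height")
  height <- 1.69 + 0.065 * s + 0.062 * h_z          # metres

  # weight loads on height; g_weight tops the additive variance up to h2
  vg_w <- max(h2[["weight"]] - 0.16 * h2[["height"]], 0)
  w_z <- 0.4 * h_z + sqrt(vg_w) * G[["weight"]] +
    sqrt(max(1 - 0.16 - vg_w, 0.01)) * env("weight")
  weight <- 79.3 + 6 * s + 14 * w_z                 # kg

  # chest loads on height weakly (0.45) so that, net of height, the chest
  # channel stays more heritable than the direct voltage channel below --
  # the mechanism by which chest adjustment attenuates ECG LVM heritability
  vg_c <- max(h2[["chest"]] - 0.2025 * h2[["height"]], 0)
  c_z <- 0.45 * h_z + sqrt(vg_c) * G[["chest"]] +
    sqrt(max(1 - 0.2025 - vg_c, 0.01)) * env("chest")
  chest_lateral_diameter <- 30.5 + 1.3 * s + 2.8 * c_z   # cm
  chest_ap_diameter <- 22 + 1.2 * s + 2 * (0.4 * c_z +
                                             sqrt(0.84) * env("chest_ap"))
  chest_height <- 26 + 1.5 * s + 2.2 * (0.3 * h_z + sqrt(0.91) *
                                          env("chest_height"))

  # ECG voltage latent: the confounder loading routes chest size into the
  # Cornell-lead sum, and through it into derived ECG LV mass
  lam <- model$confounder_loading
  var_gc_z <- 0.2025 * h2[["height"]] + vg_c        # genetic share of c_z
  vg_v <- max(h2[["voltage"]] - lam^2 * var_gc_z, 0)
  ve_v <- max(1 - lam^2 - vg_v, 0.02)
  v_z <- lam * c_z + sqrt(vg_v) * G[["voltage"]] + sqrt(ve_v) * env("voltage")
  cornell_sum <- pmax(12.0 + 0.9 * s + 4.6 * v_z, 0.2)   # RaVL + SV3, mV
  ravl <- 0.35 * cornell_sum
  sv3 <- 0.65 * cornell_sum

  sok_z <- 0.75 * v_z + sqrt(1 - 0.5625) *
    (sqrt(h2[["sokolow"]]) * G[["sokolow"]] +
       sqrt(1 - h2[["sokolow"]]) * env("sokolow"))
  sokolow_sum <- pmax(20.0 + 1.05 * s + 5.5 * sok_z, 0.2) # SV1 + RV5, mV
  sv1 <- 0.45 * sokolow_sum
  rv5 <- 0.55 * sokolow_sum

  qrs_duration <- pmax(92 + 4 * s + 8 * env("qrs"), 60)   # ms
  lead_sum <- pmax(122 + 6.6 * s + 22.7 *
                     (0.8 * v_z + 0.6 * env("leads")), 10)
  lead_w <- c(0.10, 0.07, 0.06, 0.05, 0.06, 0.07,
              0.08, 0.09, 0.10, 0.11, 0.11, 0.10)
  lead_names <- paste0("amp_", c("I", "II", "III", "aVR", "aVL", "aVF",
                                 "V1", "V2", "V3", "V4", "V5", "V6"))
  leads <- outer(lead_sum, lead_w / sum(lead_w))
  colnames(leads) <- lead_names

  set_stream_seed(seed, "env/treatment")
  treated <- stats::runif(n) < model$treatment_prevalence
  bp_z <- env("sbp")
  sbp_underlying <- 140.5 + 3 * s + 18 * bp_z
  dbp_underlying <- 81.5 + 2 * s + 10 * (0.5 * bp_z + sqrt(0.75) * env("dbp"))
  sbp <- sbp_underlying - 15 * treated   # observed under treatment
  dbp <- dbp_underlying - 10 * treated
  sbp <- pmax(sbp, dbp + 5)              # physiological ordering

  rsd <- model$residual_sd
  cmr_lvm <- 127.6 + 21.6 * s + 0.6 * (weight - 79.3) +
    rsd[["cmr_lvm"]] * (sqrt(h2[["cmr_lvm"]]) * G[["cmr_lvm"]] +
                          sqrt(1 - h2[["cmr_lvm"]]) * env("cmr_lvm"))
  cmr_lvm <- pmax(cmr_lvm, 40)
  rv_mass_true <- pmax(
    55 + 9 * s + 0.3 * (weight - 79.3) +
      rsd[["rv_mass"]] * (sqrt(h2[["rv_mass"]]) * G[["rv_mass"]] +
                            sqrt(1 - h2[["rv_mass"]]) * env("rv_mass")), 15)
  lv_edv <- pmax(135 + 14 * s + 0.5 * (weight - 79.3) +
                   rsd[["lv_edv"]] * (sqrt(h2[["lv_edv"]]) * G[["lv_edv"]] +
                                        sqrt(1 - h2[["lv_edv"]]) *
                                        env("lv_edv")), 60)
  esv_frac <- pmin(pmax(0.295 + 0.05 * env("esv"), 0.15), 0.55)
  lv_esv <- lv_edv * esv_frac
  rv_edv <- pmax(lv_edv + 8 + 10 * env("rv_edv"), 60)
  rv_esv <- rv_edv * pmin(pmax(0.35 + 0.05 * env("rv_esv"), 0.15), 0.6)

  out <- tibble::tibble(
    fid = ped$fid, iid = ped$iid, phenotyped = ped$phenotyped %||% TRUE,
    sex = sex, age = age, height = height, weight = weight,
    sbp = sbp, dbp = dbp, treated = treated,
    chest_lateral_diameter = chest_lateral_diameter,
    chest_ap_diameter = chest_ap_diameter, chest_height = chest_height,
    sv1 = sv1, rv5 = rv5, ravl = ravl, sv3 = sv3,
    qrs_duration = qrs_duration,
    lv_tissue_volume = cmr_lvm / 1.05,
    rv_tissue_volume = rv_mass_true / 1.05,
    lv_edv = lv_edv, lv_esv = lv_esv, rv_edv = rv_edv, rv_esv = rv_esv
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(leads))
  attr(out, "truth") <- model
  out
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates [simulate_pedigrees()], [drop_genotypes()],
#' [simulate_polygenic()] (one standardized stream per heritable latent) and
#' [simulate_traits()] from one master seed via named substreams.
#'
#' @param ped_spec A [pedigree_spec()].
#' @param geno_spec A [genotype_spec()].
#' @param model A [trait_model()].
#' @param seed Master seed (defaults to `ped_spec$seed`).
#' @param polygenic_mode Passed to [simulate_polygenic()].
#' @return A `sim_cohort` list: `pedigree`, `genotypes`, `phenotypes`,
#'   `truth` (the trait model plus simulation metadata).
#' @export
simulate_cohort <- function(ped_spec = pedigree_spec(),
                            geno_spec = genotype_spec(),
                            model = trait_model(),
                            seed = ped_spec$seed,
                            polygenic_mode = "pedigree-mvn") {
  ped <- simulate_pedigrees(pedigree_spec(ped_spec$n_families,
                                          ped_spec$templates,
                                          ped_spec$target_total_individuals,
                                          seed))
  geno <- drop_genotypes(ped, geno_spec, seed = seed)
  streams <- trait_model_streams(model)
  genetic <- lapply(streams, function(st) {
    simulate_polygenic(ped, h2 = 1, mode = polygenic_mode,
                       genotypes = geno, seed = seed, stream = st)
  })
  names(genetic) <- streams
  pheno <- simulate_traits(ped, model, genetic, seed = seed)
  structure(
    list(pedigree = ped, genotypes = geno, phenotypes = pheno,
         truth = c(unclass(model),
                   list(seed = seed, n_families = ped_spec$n_families,
                        templates = ped_spec$templates,
                        polygenic_mode = polygenic_mode,
                        note = "family-structure templates are an explicit approximation; the source study does not publish sibship sizes or generation depths"))),
    class = "sim_cohort")
}

#' Write a simulated cohort to disk
#'
#' Emits PED/MAP genotypes, a FAM pedigree, the tab-delimited phenotype
#' table and a flat key-value truth manifest; all files round-trip through
#' the package's readers.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_famh2("cannot create output directory %s", dir)
  }
  write_fam(cohort$pedigree, file.path(dir, "cohort.fam"))
  write_ped_map(cohort$genotypes, file.path(dir, "cohort"))
  write_pheno_table(cohort$phenotypes, file.path(dir, "cohort.pheno"))
  tr <- cohort$truth
  flat <- unlist(tr)
  writeLines(paste0(names(flat), "=", vapply(flat, format, "")),
             file.path(dir, "cohort.truth"))
  invisible(dir)
}
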