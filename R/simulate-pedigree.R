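# Synthetic pedigree generation from family-structure templates.

# Each template lists members as (id, pat, mat, sex, phenotyped); sex NA means
# "draw at random". Nuclear families are phenotyped in full (a recalled
# family attends together); in the extended templates only part of the
# family attends, so grandparents, married-in spouses and some relatives are
# present in the pedigree but unphenotyped. This keeps the phenotyped panel
# near 3.8 members/family (427/116) while maximizing within-family
# relational information, consistent with a design powered for a sampling SE
# of the heritability estimate around 7.5 percentage points.
family_templates <- function() {
  list(
    "nuclear-2child" = tibble::tribble(
      ~id,  ~pat, ~mat, ~sex, ~phenotyped,
      "01", "0",  "0",  1L,   TRUE,
      "02", "0",  "0",  2L,   TRUE,
      "03", "01", "02", NA,   TRUE,
      "04", "01", "02", NA,   TRUE
    ),
    "nuclear-3child" = tibble::tribble(
      ~id,  ~pat, ~mat, ~sex, ~phenotyped,
      "01", "0",  "0",  1L,   TRUE,
      "02", "0",  "0",  2L,   TRUE,
      "03", "01", "02", NA,   TRUE,
      "04", "01", "02", NA,   TRUE,
      "05", "01", "02", NA,   TRUE
    ),
    # grandparents, a parent with one full sib (the avuncular link), a
    # married-in spouse, two grandchildren; the middle generation and one
    # grandchild attend
    "three-generation" = tibble::tribble(
      ~id,  ~pat, ~mat, ~sex, ~phenotyped,
      "01", "0",  "0",  1L,   FALSE,
      "02", "0",  "0",  2L,   FALSE,
      "03", "01", "02", 1L,   TRUE,
      "04", "01", "02", NA,   TRUE,
      "05", "0",  "0",  2L,   FALSE,
      "06", "03", "05", NA,   TRUE,
      "07", "03", "05", NA,   FALSE
    ),
    # three adult sibs; one has a child, giving that child two aunts/uncles;
    # one aunt/uncle and the child attend
    "sibship-with-avuncular" = tibble::tribble(
      ~id,  ~pat, ~mat, ~sex, ~phenotyped,
      "01", "0",  "0",  1L,   FALSE,
      "02", "0",  "0",  2L,   FALSE,
      "03", "01", "02", 1L,   FALSE,
      "04", "01", "02", NA,   TRUE,
      "05", "01", "02", NA,   FALSE,
      "06", "0",  "0",  2L,   FALSE,
      "07", "03", "06", NA,   TRUE
    )
  )
}

default_template_mix <- function() {
  c("nuclear-2child" = 0.5, "nuclear-3child" = 0.2,
    "three-generation" = 0.2, "sibship-with-avuncular" = 0.1)
}

#' Specify a synthetic family panel
#'
#' The default panel emulates the study design: 116 extended families with a
#' phenotyped panel of roughly 427 individuals, mixing nuclear families,
#' three-generation families and adult sibships with avuncular links so that
#' sibling, parent-child and uncle/aunt-nephew/niece relative pairs all occur.
#'
#' @param n_families Number of disjoint families.
#' @param templates Named numeric vector of relative frequencies over the
#'   template names `r paste(names(default_template_mix()), collapse = ", ")`.
#' @param target_total_individuals Target size of the phenotyped panel
#'   (pedigrees also contain unphenotyped connecting members such as
#'   married-in spouses).
#' @param seed Integer seed; fully determines the pedigree.
#' @return A `pedigree_spec` list.
#' @export
pedigree_spec <- function(n_families = 116,
                          templates = default_template_mix(),
                          target_total_individuals = 427,
                          seed = 1) {
  if (n_families < 1) abort_famh2("n_families must be >= 1")
  if (is.null(names(templates)) ||
      !all(names(templates) %in% names(family_templates()))) {
    abort_famh2("templates must be named after known family structures")
  }
  if (abs(sum(templates) - 1) > 1e-8) {
    abort_famh2("template relative frequencies must sum to 1")
  }
  structure(
    list(n_families = as.integer(n_families), templates = templates,
         target_total_individuals = as.integer(target_total_individuals),
         seed = as.integer(seed)),
    class = "pedigree_spec"
  )
}

# largest-remainder apportionment of n_families over template frequencies
apportion_families <- function(freqs, n) {
  raw <- freqs * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

#' Simulate a panel of disjoint family pedigrees
#'
#' Families are instantiated from structure templates (counts apportioned
#' deterministically from the template frequencies); child sexes are drawn at
#' random from the pedigree substream of `spec$seed`.
#'
#' @param spec A [pedigree_spec()].
#' @return A tibble with columns `fid`, `iid`, `pat`, `mat` (`"0"` = unknown
#'   parent), `sex` (1 = male, 2 = female) and `phenotyped` (logical).
#' @export
simulate_pedigrees <- function(spec) {
  stopifnot(inherits(spec, "pedigree_spec"))
  tmpl <- family_templates()
  counts <- apportion_families(spec$templates, spec$n_families)
  n_pheno <- sum(counts * vapply(names(spec$templates),
                                 function(nm) sum(tmpl[[nm]]$phenotyped), 0))
  tol <- 0.05 * spec$target_total_individuals
  if (abs(n_pheno - spec$target_total_individuals) > tol) {
    abort_famh2(
      "infeasible pedigree spec: templates yield %d phenotyped individuals, target %d (+/-5%%)",
      n_pheno, spec$target_total_individuals)
  }
  set_stream_seed(spec$seed, "pedigree")
  labels <- rep(names(spec$templates), counts)
  fam_width <- max(3L, nchar(as.character(spec$n_families)))
  fams <- lapply(seq_along(labels), function(i) {
    fid <- sprintf(paste0("F%0", fam_width, "d"), i)
    fam <- tmpl[[labels[i]]]
    sex <- fam$sex
    sex[is.na(sex)] <- sample(1:2, sum(is.na(sex)), replace = TRUE)
    tibble::tibble(
      fid = fid,
      iid = paste0(fid, "_", fam$id),
      pat = ifelse(fam$pat == "0", "0", paste0(fid, "_", fam$pat)),
      mat = ifelse(fam$mat == "0", "0", paste0(fid, "_", fam$mat)),
      sex = as.integer(sex),
      phenotyped = fam$phenotyped
    )
  })
  ped <- dplyr::bind_rows(fams)
  validate_pedigree(ped)
  ped
}
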