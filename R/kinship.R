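# Expected (pedigree) relatedness: kinship matrix and relative-pair sets.

#' Kinship matrix from a pedigree
#'
#' Computes kinship coefficients by the standard recursion in
#' parents-before-children order: `phi(i,i) = 0.5 * (1 + phi(f_i, m_i))` and
#' `phi(i,j) = 0.5 * (phi(f_i, j) + phi(m_i, j))` for `j` not a descendant of
#' `i`; unknown parents contribute 0. Individuals from different families
#' have kinship 0 by construction.
#'
#' @param ped Pedigree tibble.
#' @param ids Optional character vector of IIDs to retain (e.g. the
#'   phenotyped panel); default all.
#' @return Symmetric matrix of kinship coefficients with IID dimnames.
#'   Multiply by 2 for the additive relationship matrix used as the
#'   variance-components kernel.
#' @export
kinship_matrix <- function(ped, ids = NULL) {
  ped <- validate_pedigree(ped)
  ord <- pedigree_order(ped)
  ped <- ped[ord, , drop = FALSE]
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$iid)
  fi <- ifelse(ped$pat %in% ped$iid, idx[ped$pat], 0L)
  mi <- ifelse(ped$mat %in% ped$iid, idx[ped$mat], 0L)
  phi <- matrix(0, n, n, dimnames = list(ped$iid, ped$iid))
  for (i in seq_len(n)) {
    f <- fi[i]; m <- mi[i]
    phi[i, i] <- 0.5 * (1 + if (f > 0 && m > 0) phi[f, m] else 0)
    if (i > 1L) {
      j <- seq_len(i - 1L)
      # parents precede i, so phi rows for f and m over j are final
      v <- 0.5 * ((if (f > 0) phi[f, j] else 0) + (if (m > 0) phi[m, j] else 0))
      phi[i, j] <- v
      phi[j, i] <- v
    }
  }
  if (!is.null(ids)) {
    missing <- setdiff(ids, ped$iid)
    if (length(missing)) abort_famh2("IDs not in pedigree: %s", missing[1])
    phi <- phi[ids, ids, drop = FALSE]
  }
  phi
}

#' Enumerate relative pairs of given classes
#'
#' Pair classes: `sibling` (both parents shared and known), `parent-child`,
#' and `avuncular` (an individual and a full sib of one of their parents).
#' Each unordered pair is listed once; parent-child pairs are ordered
#' parent-first (`iid1` = parent).
#'
#' @param ped Pedigree tibble.
#' @param classes Character vector of classes to enumerate.
#' @param phenotyped_only If `TRUE` (default), restrict to phenotyped members.
#' @return Tibble with `class`, `fid`, `iid1`, `iid2`.
#' @export
extract_relative_pairs <- function(ped,
                                   classes = c("sibling", "parent-child",
                                               "avuncular"),
                                   phenotyped_only = TRUE) {
  classes <- match.arg(classes, several.ok = TRUE)
  ped <- validate_pedigree(ped)
  keep <- if (phenotyped_only && "phenotyped" %in% names(ped)) {
    stats::setNames(ped$phenotyped, ped$iid)
  } else {
    stats::setNames(rep(TRUE, nrow(ped)), ped$iid)
  }
  parent_key <- paste(ped$pat, ped$mat)
  has_par <- ped$pat != "0" & ped$mat != "0"
  sibs_of <- function(iid) {
    i <- match(iid, ped$iid)
    if (is.na(i) || !has_par[i]) return(character(0))
    same <- has_par & parent_key == parent_key[i] & ped$iid != iid
    ped$iid[same]
  }
  out <- list()
  if ("sibling" %in% classes) {
    rows <- list()
    for (key in unique(parent_key[has_par])) {
      members <- ped$iid[has_par & parent_key == key]
      members <- members[keep[members]]
      if (length(members) >= 2) {
        cmb <- utils::combn(sort(members), 2)
        rows[[key]] <- tibble::tibble(
          class = "sibling", fid = ped$fid[match(cmb[1, ], ped$iid)],
          iid1 = cmb[1, ], iid2 = cmb[2, ])
      }
    }
    out$sibling <- dplyr::bind_rows(rows)
  }
  if ("parent-child" %in% classes) {
    rows <- list()
    for (col in c("pat", "mat")) {
      p <- ped[[col]]
      ok <- p %in% ped$iid & keep[ped$iid] & p %in% names(keep) & keep[p]
      ok[is.na(ok)] <- FALSE
      if (any(ok)) {
        rows[[col]] <- tibble::tibble(
          class = "parent-child", fid = ped$fid[ok],
          iid1 = p[ok], iid2 = ped$iid[ok])
      }
    }
    out$parent_child <- dplyr::bind_rows(rows)
  }
  if ("avuncular" %in% classes) {
    rows <- list()
    for (i in seq_len(nrow(ped))) {
      kid <- ped$iid[i]
      if (!keep[kid]) next
      uncles <- unique(c(sibs_of(ped$pat[i]), sibs_of(ped$mat[i])))
      uncles <- uncles[keep[uncles]]
      for (u in uncles) {
        pr <- sort(c(kid, u))
        rows[[paste(pr, collapse = "|")]] <- tibble::tibble(
          class = "avuncular", fid = ped$fid[i], iid1 = pr[1], iid2 = pr[2])
      }
    }
    out$avuncular <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(class = character(), fid = character(),
                          iid1 = character(), iid2 = character())
  }
  res
}
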