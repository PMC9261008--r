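#' Bundle a cohort's differential-expression profile
#'
#' @param name Cohort name.
#' @param quantified Character vector of all quantified protein ids.
#' @param de A `de_result` from [run_de()] or a data.frame with columns
#'   `protein`, `q`, `fold_change`, and optionally `d`.
#'
#' @return A list of class `cohort_de`.
#' @export
cohort_de <- function(name, quantified, de) {
  tab <- if (inherits(de, "de_result")) de$table else de
  stopifnot(all(c("protein", "q", "fold_change") %in% names(tab)))
  if (!all(tab$protein %in% quantified)) {
    stop("de table contains proteins outside the quantified set")
  }
  structure(list(name = name, quantified = unique(quantified), table = tab),
            class = "cohort_de")
}

#' Proteins quantified in both cohorts
#'
#' @param a,b `cohort_de` objects.
#' @return Character vector, the exact intersection of the quantified sets;
#'   an empty intersection raises a warning.
#' @export
joint_quantified <- function(a, b) {
  out <- intersect(a$quantified, b$quantified)
  if (length(out) == 0) warning("cohorts share no quantified proteins")
  out
}

#' Shared and distinct differential expression between two cohorts
#'
#' Restricts both profiles to the jointly quantified protein set, then
#' classifies proteins significant (q below `alpha`) in both cohorts as
#' shared, and those significant in exactly one as distinct to that cohort.
#' Among shared proteins, direction concordance counts fold changes on the
#' same side of 1. Proteins with a missing q-value in either cohort are
#' excluded (their count is reported).
#'
#' @param a,b `cohort_de` objects.
#' @param alpha q-value threshold (default 0.05).
#'
#' @return A list with `joint` (character), `shared`, `distinct_a`,
#'   `distinct_b` (character vectors), `concordant` (count among shared),
#'   `n_excluded` (missing-q proteins), and per-cohort unrestricted DE
#'   counts `n_de_a`, `n_de_b`.
#' @export
overlap_de <- function(a, b, alpha = 0.05) {
  joint <- joint_quantified(a, b)
  qa <- a$table$q[match(joint, a$table$protein)]
  qb <- b$table$q[match(joint, b$table$protein)]
  fa <- a$table$fold_change[match(joint, a$table$protein)]
  fb <- b$table$fold_change[match(joint, b$table$protein)]
  ok <- !is.na(qa) & !is.na(qb)
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    message(sprintf("excluding %d joint proteins with missing q", n_excluded))
  }
  joint_ok <- joint[ok]
  sig_a <- qa[ok] < alpha
  sig_b <- qb[ok] < alpha
  shared <- joint_ok[sig_a & sig_b]
  concordant <- sum((fa[ok] > 1) == (fb[ok] > 1) & sig_a & sig_b,
                    na.rm = TRUE)
  list(
    joint = joint,
    shared = shared,
    distinct_a = joint_ok[sig_a & !sig_b],
    distinct_b = joint_ok[sig_b & !sig_a],
    concordant = concordant,
    n_excluded = n_excluded,
    n_de_a = sum(a$table$q < alpha, na.rm = TRUE),
    n_de_b = sum(b$table$q < alpha, na.rm = TRUE)
  )
}

#' Paired effect sizes between cohorts for a protein group
#'
#' Pairs the SAM `d` statistics of the two cohorts for a given protein
#' group and summarizes which cohort shows the stronger effects; ties in
#' `|d|` count one half towards each cohort, so identical cohorts give 0.5.
#'
#' @param a,b `cohort_de` objects whose tables carry a `d` column.
#' @param protein_group Character vector of proteins to pair; proteins
#'   absent from either cohort are dropped (count reported via message).
#'
#' @return A list with `pairs` (data.frame: `protein`, `d_a`, `d_b`) and
#'   `prop_stronger_a` (share of proteins with `|d_a| > |d_b|`, ties at
#'   half weight).
#' @export
effect_size_scatter <- function(a, b, protein_group) {
  stopifnot("d" %in% names(a$table), "d" %in% names(b$table))
  da <- a$table$d[match(protein_group, a$table$protein)]
  db <- b$table$d[match(protein_group, b$table$protein)]
  ok <- !is.na(da) & !is.na(db)
  if (any(!ok)) {
    message(sprintf("dropping %d proteins absent or untested in a cohort",
                    sum(!ok)))
  }
  pairs <- data.frame(protein = protein_group[ok], d_a = da[ok], d_b = db[ok],
                      stringsAsFactors = FALSE)
  prop <- if (nrow(pairs) == 0) NA_real_ else {
    (sum(abs(pairs$d_a) > abs(pairs$d_b)) +
       0.5 * sum(abs(pairs$d_a) == abs(pairs$d_b))) / nrow(pairs)
  }
  list(pairs = pairs, prop_stronger_a = prop)
}
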