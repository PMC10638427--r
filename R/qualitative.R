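#' Accessions detected in one run
#'
#' A protein group counts as detected when its raw intensity is strictly
#' greater than 0 in that run; 0 encodes "not detected".
#'
#' @param tbl An `intensity_table`.
#' @param run_code A run code present in `tbl`.
#' @return Character vector of detected accessions.
#' @export
detected_accessions <- function(tbl, run_code) {
  v <- run_column(tbl, run_code)
  tbl$accession[v > 0]
}

#' Triplicate core: proteins detected in all three replicates
#'
#' @param reps A list of exactly three detection sets (character vectors).
#' @return Character vector, the three-way intersection.
#' @export
triplicate_core <- function(reps) {
  if (!is.list(reps) || length(reps) != 3L) {
    stop("arity error: triplicate_core needs exactly three sets",
         call. = FALSE)
  }
  purrr::reduce(reps, intersect)
}

#' Fraction of a sample's proteins reproduced in all three replicates
#'
#' The ratio of the triplicate core to the union of all proteins detected
#' in any replicate ("all different protein IDs" for the sample), as shown
#' on replicate-reproducibility Venn diagrams.
#'
#' @param reps A list of exactly three detection sets.
#' @return A fraction in \[0, 1\], or `NA` when the union is empty.
#' @export
replicate_overlap_fraction <- function(reps) {
  if (!is.list(reps) || length(reps) != 3L) {
    stop("arity error: replicate_overlap_fraction needs exactly three sets",
         call. = FALSE)
  }
  u <- purrr::reduce(reps, union)
  if (length(u) == 0) return(NA_real_)
  length(purrr::reduce(reps, intersect)) / length(u)
}

#' Qualitative hit set for one bait pull-down
#'
#' A protein is a qualitative hit when it is in the triplicate core of the
#' experimental sample and absent from *every* replicate of both negative
#' controls: detection in even a single control replicate rejects it (the
#' union of control detections is subtracted, not the controls' cores).
#'
#' @param core_exp Triplicate core of the experimental sample (character
#'   vector).
#' @param control1_reps,control2_reps Lists of three detection sets for
#'   control 1 (untagged strain) and control 2 (heterologous tagged
#'   strain).
#' @return Character vector of hit accessions.
#' @export
qualitative_hit_set <- function(core_exp, control1_reps, control2_reps) {
  rejected <- unique(c(unlist(control1_reps), unlist(control2_reps)))
  setdiff(core_exp, rejected)
}

#' Qualitative (presence/absence) hit calling for one bait and condition
#'
#' Runs the simple strategy end to end: per-replicate detection (raw
#' intensity > 0), triplicate intersection of the experimental sample, and
#' rejection of any protein detected in any replicate of either control.
#' Normalized intensities of the experimental replicates are carried
#' through so hits can be sorted and compared downstream.
#'
#' @param tbl An `intensity_table` containing the bait's runs and both
#'   controls' runs for `condition`.
#' @param design A `sample_design`.
#' @param bait Bait name.
#' @param condition Condition label.
#' @return A tibble with columns `bait`, `condition`, `accession`, `gene`,
#'   `description` and `norm_rep1..3` (log10 median-normalized intensities
#'   of the experimental replicates).
#' @export
qualitative_hits <- function(tbl, design, bait, condition) {
  exp_runs <- design_runs(design, bait, condition, "experiment")
  c1_runs <- design_runs(design, NULL, condition, "control1")
  c2_runs <- design_runs(design, NULL, condition, "control2")

  core <- triplicate_core(purrr::map(exp_runs,
                                     ~detected_accessions(tbl, .x)))
  hits <- qualitative_hit_set(
    core,
    purrr::map(c1_runs, ~detected_accessions(tbl, .x)),
    purrr::map(c2_runs, ~detected_accessions(tbl, .x))
  )

  norm <- purrr::map(exp_runs, ~normalize_and_log(tbl, .x))
  idx <- match(hits, tbl$accession)
  tibble::tibble(
    bait = bait,
    condition = condition,
    accession = hits,
    gene = tbl$gene[idx],
    description = tbl$description[idx],
    norm_rep1 = norm[[1]][idx],
    norm_rep2 = norm[[2]][idx],
    norm_rep3 = norm[[3]][idx]
  )
}
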