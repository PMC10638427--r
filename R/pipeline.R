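#' Run a hit-calling strategy over every bait and condition
#'
#' Maps [qualitative_hits()] and/or [quantitative_hits()] over all (bait,
#' condition) pairs of the design and collects the results, together with
#' the per-condition global statistics, into one object.
#'
#' @param tbl An `intensity_table` covering all runs of the design (after
#'   [filter_flagged()], typically).
#' @param design A `sample_design`.
#' @param strategy `"quantitative"`, `"qualitative"` or `"both"`.
#' @param cfg A [quant_config()] (used by the quantitative strategy).
#' @return An object of class `apms_result`: a list with tibbles
#'   `qualitative` (hit rows) and/or `quantitative` (all enrichment
#'   records), `global_stats`, plus the `design` and `cfg` used.
#' @export
process_all <- function(tbl, design,
                        strategy = c("both", "qualitative", "quantitative"),
                        cfg = quant_config()) {
  strategy <- match.arg(strategy)
  pairs <- dplyr::distinct(
    dplyr::filter(design, .data$role == "experiment"),
    .data$bait, .data$condition
  )
  out <- list(design = design, cfg = cfg, strategy = strategy)
  if (strategy %in% c("both", "qualitative")) {
    out$qualitative <- purrr::pmap(pairs, function(bait, condition) {
      qualitative_hits(tbl, design, bait, condition)
    }) |> dplyr::bind_rows()
  }
  if (strategy %in% c("both", "quantitative")) {
    out$quantitative <- purrr::pmap(pairs, function(bait, condition) {
      quantitative_hits(tbl, design, bait, condition, cfg)
    }) |> dplyr::bind_rows()
    out$global_stats <- purrr::map(
      unique(pairs$condition),
      ~global_stats(tbl, design, .x, cfg$sd_mode)
    ) |> dplyr::bind_rows()
  }
  structure(out, class = "apms_result")
}

#' @export
print.apms_result <- function(x, ...) {
  cat("<apms_result> strategy:", x$strategy, "\n")
  if (!is.null(x$quantitative)) {
    cat("  quantitative: ", sum(x$quantitative$final_hit), " hits / ",
        nrow(x$quantitative), " records\n", sep = "")
  }
  if (!is.null(x$qualitative)) {
    cat("  qualitative:  ", nrow(x$qualitative), " hits\n", sep = "")
  }
  invisible(x)
}

#' Tidy the records of a pipeline result
#'
#' @param x An `apms_result`.
#' @param strategy Which record set to return when both were run.
#' @param ... Unused.
#' @return A tibble: quantitative enrichment records or qualitative hit
#'   rows.
#' @method tidy apms_result
#' @export
tidy.apms_result <- function(x, strategy = c("quantitative",
                                             "qualitative"), ...) {
  strategy <- match.arg(strategy)
  res <- x[[strategy]]
  if (is.null(res)) {
    stop("result does not contain ", strategy, " records", call. = FALSE)
  }
  res
}

#' One-row summary of a pipeline result
#'
#' @param x An `apms_result`.
#' @param ... Unused.
#' @return A tibble with bait/condition counts and per-strategy hit
#'   totals.
#' @method glance apms_result
#' @export
glance.apms_result <- function(x, ...) {
  exp_design <- dplyr::filter(x$design, .data$role == "experiment")
  tibble::tibble(
    n_baits = dplyr::n_distinct(exp_design$bait),
    n_conditions = dplyr::n_distinct(exp_design$condition),
    n_quantitative_records = if (is.null(x$quantitative)) NA_integer_
                             else nrow(x$quantitative),
    n_quantitative_hits = if (is.null(x$quantitative)) NA_integer_
                          else sum(x$quantitative$final_hit),
    n_qualitative_hits = if (is.null(x$qualitative)) NA_integer_
                         else nrow(x$qualitative)
  )
}

#' @rdname hit_sets
#' @export
quantitative_hit_sets <- function(records) {
  hits <- dplyr::filter(records, .data$final_hit)
  split(hits$accession, list(hits$bait, hits$condition), sep = "/")
}

#' Per-(bait, condition) hit sets from record tibbles
#'
#' Convenience extractors used by the network-reporting summaries.
#'
#' @param records Quantitative records (with `final_hit`) or qualitative
#'   hit rows.
#' @return Named list of accession character vectors, names `bait/condition`.
#' @name hit_sets
#' @export
qualitative_hit_sets <- function(records) {
  split(records$accession, list(records$bait, records$condition),
        sep = "/")
}
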