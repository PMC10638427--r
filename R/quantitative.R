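#' Configuration of the quantitative hit-calling strategy
#'
#' @param fold_threshold_log2 Minimum enrichment of the experimental over
#'   the control average, on the log2 scale (default 1.5). Must be > 0.
#' @param alpha_adjusted Threshold on the Benjamini-Hochberg adjusted
#'   p-value (default 0.01).
#' @param sd_mode `"sample"` (n-1 denominator, default) or `"population"`
#'   for the condition-wide global standard deviation.
#' @param zscore_scale `"raw"` (default): z = (av_exp - av_ctrl) /
#'   global_sd; `"mean_of_three"`: the denominator is additionally scaled
#'   by sqrt(2/3), the standard deviation of a difference of two means of
#'   three values.
#' @param fold_scale `"log2"` (default): the threshold is applied to the
#'   log10 difference rescaled to log2 units, (av_exp - av_ctrl)/log10(2);
#'   `"log10"`: applied directly to the log10 difference.
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(fold_threshold_log2 = 1.5,
                         alpha_adjusted = 0.01,
                         sd_mode = c("sample", "population"),
                         zscore_scale = c("raw", "mean_of_three"),
                         fold_scale = c("log2", "log10")) {
  stopifnot(fold_threshold_log2 > 0,
            alpha_adjusted > 0, alpha_adjusted < 1)
  structure(list(fold_threshold_log2 = fold_threshold_log2,
                 alpha_adjusted = alpha_adjusted,
                 sd_mode = match.arg(sd_mode),
                 zscore_scale = match.arg(zscore_scale),
                 fold_scale = match.arg(fold_scale)),
            class = "quant_config")
}

#' Median-normalize and log10-transform one run
#'
#' Each raw intensity is divided by the median of the run's *nonzero*
#' intensities and log10-transformed. A raw intensity of 0 (not detected)
#' maps to a transformed value of 0, equivalent to replacing the
#' normalized value with 1 before taking logs.
#'
#' @param tbl An `intensity_table`.
#' @param run_code A run code present in `tbl`.
#' @return Numeric vector of log10 normalized intensities, one per
#'   protein, in table row order.
#' @export
normalize_and_log <- function(tbl, run_code) {
  v <- run_column(tbl, run_code)
  nz <- v[v > 0]
  if (length(nz) == 0) {
    warning("run '", run_code, "' has no detected proteins; ",
            "all transformed values are 0", call. = FALSE)
    return(rep(0, length(v)))
  }
  med <- stats::median(nz)
  ifelse(v > 0, log10(v / med), 0)
}

#' Condition-wide global variance and standard deviation
#'
#' Pools every transformed intensity value (including the zero
#' placeholders of undetected proteins) of every run of one growth
#' condition - experimental and control runs alike - and computes their
#' variance and standard deviation. The global SD is the denominator of
#' the quantitative strategy's z-score.
#'
#' @param tbl An `intensity_table`.
#' @param design A `sample_design`.
#' @param condition Condition label.
#' @param sd_mode `"sample"` (n-1) or `"population"` (n) denominator.
#' @return One-row tibble: `condition`, `n_values`, `global_variance`,
#'   `global_sd`.
#' @export
global_stats <- function(tbl, design, condition,
                         sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  cond_runs <- dplyr::filter(design, .data$condition == !!condition)$run_code
  cond_runs <- intersect(cond_runs, run_codes(tbl))
  if (length(cond_runs) == 0) {
    stop("stats error: no runs of condition '", condition,
         "' in the table", call. = FALSE)
  }
  pooled <- unlist(purrr::map(cond_runs, ~normalize_and_log(tbl, .x)),
                   use.names = FALSE)
  pooled_stats(pooled, condition, sd_mode)
}

pooled_stats <- function(values, condition, sd_mode) {
  n <- length(values)
  if (n < 2) stop("stats error: need at least 2 values", call. = FALSE)
  v <- stats::var(values)
  if (sd_mode == "population") v <- v * (n - 1) / n
  tibble::tibble(condition = condition, n_values = n,
                 global_variance = v, global_sd = sqrt(v))
}

#' Average of a replicate triplicate
#'
#' @param values Exactly three log10 normalized intensities.
#' @return Their arithmetic mean (the strategy's `av_intensity`).
#' @export
average_triplicate <- function(values) {
  if (length(values) != 3L) {
    stop("arity error: average_triplicate needs exactly three values",
         call. = FALSE)
  }
  mean(values)
}

#' Enrichment verdict of one protein against one control
#'
#' Applies the per-control decision rule before multiplicity adjustment,
#' vectorized over proteins. When the control average is 0 the protein is
#' absent in that control and counts as significant without a test. When
#' the control average is positive, the log2-scale enrichment is computed
#' and proteins below the fold threshold are rejected; for the rest a
#' one-sided upper-tail z-score against the condition's global standard
#' deviation gives the (pre-adjustment) p-value, and the provisional
#' verdict is `"enriched"` pending Benjamini-Hochberg correction.
#'
#' @param av_exp,av_ctrl Average log10 normalized intensities of the
#'   experimental sample and the control (vectors recycle as usual).
#' @param global_sd The condition's global standard deviation.
#' @param cfg A [quant_config()].
#' @return A tibble with columns `verdict` (`"absent_in_control"`,
#'   `"enriched"`, `"rejected"`), `log2fc`, `z`, `p` (`NA` where no test
#'   was performed).
#' @export
control_verdict <- function(av_exp, av_ctrl, global_sd,
                            cfg = quant_config()) {
  n <- max(length(av_exp), length(av_ctrl))
  av_exp <- rep_len(av_exp, n)
  av_ctrl <- rep_len(av_ctrl, n)
  diff10 <- av_exp - av_ctrl
  log2fc <- diff10 / log10(2)
  fold_stat <- if (cfg$fold_scale == "log2") log2fc else diff10

  absent <- av_ctrl == 0
  passed <- !absent & fold_stat >= cfg$fold_threshold_log2

  s <- if (cfg$zscore_scale == "mean_of_three") sqrt(2 / 3) else 1
  z <- p <- rep(NA_real_, n)
  if (any(passed)) {
    if (global_sd == 0) {
      warning("global SD is 0; p-values of tested proteins set to 0",
              call. = FALSE)
      z[passed] <- Inf
      p[passed] <- 0
    } else {
      z[passed] <- diff10[passed] / (global_sd * s)
      p[passed] <- stats::pnorm(z[passed], lower.tail = FALSE)
    }
  }
  tibble::tibble(
    verdict = dplyr::case_when(absent ~ "absent_in_control",
                               passed ~ "enriched",
                               TRUE ~ "rejected"),
    log2fc = ifelse(absent, NA_real_, log2fc),
    z = z,
    p = p
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a family of p-values for multiple testing, preserving input
#' order; adjusted values lie in \[0, 1\] and never fall below the raw
#' values.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("input error: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Quantitative hit calling for one bait and condition
#'
#' Runs the complex strategy end to end for one pull-down: per-run median
#' normalization and log10 transform, condition-wide global SD, triplicate
#' averaging, per-control verdicts (absence rule, log2 fold threshold,
#' one-sided z-test) with Benjamini-Hochberg correction applied separately
#' per control over the proteins that required a test in this (bait,
#' condition), and the final all-three-replicates rule. One record is
#' emitted per protein detected in at least one experimental replicate,
#' hits flagged by `final_hit`.
#'
#' @param tbl An `intensity_table` containing the bait's and both
#'   controls' runs for `condition`.
#' @param design A `sample_design`.
#' @param bait Bait name.
#' @param condition Condition label.
#' @param cfg A [quant_config()].
#' @return A tibble of enrichment records: `bait`, `condition`,
#'   `accession`, `gene`, `description`, `norm_rep1..3`, `av_exp`,
#'   `av_c1`, `av_c2`, `log2fc_c1/2`, `z_c1/2`, `p_c1/2`, `padj_c1/2`,
#'   `verdict_c1/2`, `present_all_reps`, `final_hit`.
#' @export
quantitative_hits <- function(tbl, design, bait, condition,
                              cfg = quant_config()) {
  exp_runs <- design_runs(design, bait, condition, "experiment")
  c1_runs <- design_runs(design, NULL, condition, "control1")
  c2_runs <- design_runs(design, NULL, condition, "control2")

  gs <- global_stats(tbl, design, condition, cfg$sd_mode)

  norm_of <- function(runs) {
    m <- vapply(runs, function(r) normalize_and_log(tbl, r),
                numeric(nrow(tbl)))
    if (nrow(tbl) == 0) m <- matrix(numeric(0), 0, length(runs))
    m
  }
  exp_norm <- norm_of(exp_runs)
  raw_exp <- vapply(exp_runs, function(r) run_column(tbl, r),
                    numeric(nrow(tbl)))
  if (nrow(tbl) == 0) raw_exp <- matrix(numeric(0), 0, 3)

  row_avg <- function(m) {
    vapply(seq_len(nrow(m)), function(i) average_triplicate(m[i, ]),
           numeric(1))
  }
  keep <- rowSums(raw_exp > 0) >= 1
  av_exp <- row_avg(exp_norm)[keep]
  av_c1 <- row_avg(norm_of(c1_runs))[keep]
  av_c2 <- row_avg(norm_of(c2_runs))[keep]

  v1 <- control_verdict(av_exp, av_c1, gs$global_sd, cfg)
  v2 <- control_verdict(av_exp, av_c2, gs$global_sd, cfg)

  adjust_family <- function(v) {
    padj <- rep(NA_real_, nrow(v))
    tested <- !is.na(v$p)
    padj[tested] <- bh_adjust(v$p[tested])
    verdict <- v$verdict
    verdict[tested & padj > cfg$alpha_adjusted] <- "rejected"
    list(padj = padj, verdict = verdict)
  }
  a1 <- adjust_family(v1)
  a2 <- adjust_family(v2)

  present_all <- rowSums(raw_exp > 0)[keep] == 3L
  final_hit <- present_all & a1$verdict != "rejected" &
    a2$verdict != "rejected"

  tibble::tibble(
    bait = bait,
    condition = condition,
    accession = tbl$accession[keep],
    gene = tbl$gene[keep],
    description = tbl$description[keep],
    norm_rep1 = exp_norm[keep, 1],
    norm_rep2 = exp_norm[keep, 2],
    norm_rep3 = exp_norm[keep, 3],
    av_exp = av_exp,
    av_c1 = av_c1,
    av_c2 = av_c2,
    log2fc_c1 = v1$log2fc,
    log2fc_c2 = v2$log2fc,
    z_c1 = v1$z,
    z_c2 = v2$z,
    p_c1 = v1$p,
    p_c2 = v2$p,
    padj_c1 = a1$padj,
    padj_c2 = a2$padj,
    verdict_c1 = a1$verdict,
    verdict_c2 = a2$verdict,
    present_all_reps = present_all,
    final_hit = final_hit
  )
}
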