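#' Volcano plot of one control comparison
#'
#' Enrichment (log2 fold change) against significance (-log10 adjusted
#' p-value) for every tested protein; final hits highlighted. Proteins
#' absent in the control have no test and are not drawn on the p-value
#' axis.
#'
#' @param records Quantitative enrichment records (one bait/condition at
#'   a time reads best).
#' @param control `"c2"` (default; the tag control) or `"c1"`.
#' @return A ggplot object.
#' @export
plot_volcano <- function(records, control = c("c2", "c1")) {
  control <- match.arg(control)
  vt <- volcano_table(records, control)
  vt <- dplyr::filter(vt, !.data$absent_in_control, !is.na(.data$log2fc))
  ggplot2::ggplot(vt, ggplot2::aes(x = .data$log2fc,
                                   y = .data$neg_log10_padj,
                                   colour = .data$final_hit)) +
    ggplot2::geom_point(alpha = 0.7, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold enrichment",
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = "final hit") +
    ggplot2::theme_minimal()
}

#' Heatmap of the pairwise bait-similarity matrix
#'
#' @param m A matrix from [bait_similarity()].
#' @return A ggplot object.
#' @export
plot_bait_similarity <- function(m) {
  df <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("bait_a", "bait_b", "similarity")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bait_a, y = .data$bait_b,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", .data$similarity)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "% shared") +
    ggplot2::theme_minimal()
}

#' Bar chart of condition-overlap Venn regions
#'
#' @param overlap A region tibble from [condition_overlap()].
#' @return A ggplot object.
#' @export
plot_condition_overlap <- function(overlap) {
  labels <- setdiff(names(overlap), "count")
  region <- apply(overlap[labels], 1, function(r) {
    paste(labels[as.logical(r)], collapse = " & ")
  })
  df <- tibble::tibble(region = factor(region, levels = region),
                       count = overlap$count)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "proteins") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 30, hjust = 1))
}

#' Volcano plot method for pipeline results
#' @param object An `apms_result` with quantitative records.
#' @param ... Passed to [plot_volcano()].
#' @method autoplot apms_result
#' @export
autoplot.apms_result <- function(object, ...) {
  if (is.null(object$quantitative)) {
    stop("autoplot requires quantitative records", call. = FALSE)
  }
  plot_volcano(object$quantitative, ...)
}
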