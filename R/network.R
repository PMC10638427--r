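#' Controlled vocabulary of prey functional categories
#'
#' The ten manually curated functional category labels used to organize
#' prey proteins (uncharacterized/orphan, transcription control, RNA
#' processing, ribosomal & translation, metabolic & transport, cell
#' envelope, DNA architecture/structure, DNA replication, chromosome
#' segregation & cell division, stress & starvation response).
#'
#' @return Character vector of category labels.
#' @export
prey_categories <- function() {
  readLines(system.file("extdata", "prey_categories.txt",
                        package = "apmshits", mustWork = TRUE))
}

#' Build a bait-prey interaction edge list from hit records
#'
#' One edge per final hit. For quantitative records the evidence type
#' distinguishes preys absent in both controls from significantly enriched
#' ones, and enriched edges carry the log2 fold enrichment versus control
#' 2 as their weight (the convention used for edge widths in network
#' visualizations). Qualitative hit lists yield `absent_in_controls`
#' edges without weights.
#'
#' @param records A tibble of quantitative enrichment records (from
#'   [quantitative_hits()]) or qualitative hits (from
#'   [qualitative_hits()]).
#' @param categories Optional named character vector or two-column data
#'   frame (`accession`, `category`) mapping preys to functional
#'   categories; unmapped preys get `"unassigned"`. Labels must come from
#'   [prey_categories()].
#' @return An edge tibble: `bait`, `prey`, `condition`, `evidence`
#'   (`"absent_in_controls"` or `"enriched"`), `weight` (log2fc vs
#'   control 2; `NA` for absent-in-controls edges), `prey_category`.
#' @export
build_network <- function(records, categories = NULL) {
  if ("final_hit" %in% names(records)) {
    hits <- dplyr::filter(records, .data$final_hit)
    edges <- tibble::tibble(
      bait = hits$bait,
      prey = hits$accession,
      condition = hits$condition,
      evidence = ifelse(hits$verdict_c1 == "absent_in_control" &
                          hits$verdict_c2 == "absent_in_control",
                        "absent_in_controls", "enriched"),
      weight = ifelse(hits$verdict_c2 == "enriched", hits$log2fc_c2,
                      NA_real_)
    )
  } else {
    edges <- tibble::tibble(
      bait = records$bait,
      prey = records$accession,
      condition = records$condition,
      evidence = "absent_in_controls",
      weight = NA_real_
    )
  }
  edges$prey_category <- map_categories(edges$prey, categories)
  edges
}

map_categories <- function(accessions, categories) {
  if (is.null(categories)) return(rep("unassigned", length(accessions)))
  if (is.data.frame(categories)) {
    categories <- stats::setNames(categories$category,
                                  categories$accession)
  }
  bad <- setdiff(unique(categories), prey_categories())
  if (length(bad) > 0) {
    stop("unknown prey categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- unname(categories[accessions])
  out[is.na(out)] <- "unassigned"
  out
}

#' Seven-region Venn counts of one bait's hits across three conditions
#'
#' @param hits_by_condition Named list of three hit sets (character
#'   vectors), one per growth condition.
#' @return A tibble with one row per Venn region: logical membership
#'   columns (named after the conditions) and `count`. Region counts sum
#'   to the size of the union.
#' @export
condition_overlap <- function(hits_by_condition) {
  if (length(hits_by_condition) != 3L) {
    stop("arity error: condition_overlap needs exactly three sets",
         call. = FALSE)
  }
  labels <- names(hits_by_condition) %||% paste0("set", 1:3)
  u <- unique(unlist(hits_by_condition))
  member <- purrr::map(hits_by_condition, ~u %in% .x)
  regions <- tidyr::expand_grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                                c = c(TRUE, FALSE)) |>
    dplyr::filter(.data$a | .data$b | .data$c)
  counts <- purrr::pmap_int(regions, function(a, b, c) {
    sum(member[[1]] == a & member[[2]] == b & member[[3]] == c)
  })
  out <- regions
  names(out) <- labels
  out$count <- counts
  out
}

#' Pairwise bait similarity matrix
#'
#' Compares the interaction profiles of all baits, each with each. In the
#' default `"weighted"` mode the percent of shared interactants between
#' two baits (100 x |intersection| / |union|) is weighted by the fraction
#' of all interactants identified in the whole screen that the pair
#' covers (|pairwise union| / |union over all baits|). The `"jaccard"`
#' mode reports the unweighted percentage. The mode used is recorded in
#' the `mode` attribute of the result.
#'
#' @param hit_sets Named list of per-bait hit sets (character vectors);
#'   at least two baits.
#' @param mode `"weighted"` (default) or `"jaccard"`.
#' @return Symmetric numeric matrix of percentages with 100 on the
#'   diagonal, baits as dimnames.
#' @export
bait_similarity <- function(hit_sets, mode = c("weighted", "jaccard")) {
  mode <- match.arg(mode)
  if (length(hit_sets) < 2L) {
    stop("bait_similarity needs at least two baits", call. = FALSE)
  }
  baits <- names(hit_sets) %||% paste0("bait", seq_along(hit_sets))
  total <- length(unique(unlist(hit_sets)))
  k <- length(hit_sets)
  m <- matrix(NA_real_, k, k, dimnames = list(baits, baits))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) { m[i, j] <- 100; next }
      inter <- length(intersect(hit_sets[[i]], hit_sets[[j]]))
      uni <- length(union(hit_sets[[i]], hit_sets[[j]]))
      if (uni == 0 || total == 0) { m[i, j] <- NA_real_; next }
      val <- 100 * inter / uni
      if (mode == "weighted") val <- val * uni / total
      m[i, j] <- val
    }
  }
  attr(m, "mode") <- mode
  m
}

#' Volcano-plot table for one control comparison
#'
#' One row per enrichment record, with log2 fold change and -log10
#' adjusted p-value against the chosen control. Proteins absent in that
#' control were never tested: they are flagged and their fold-change and
#' p fields left missing rather than imputed, so they can be drawn
#' separately.
#'
#' @param records Quantitative enrichment records.
#' @param control `"c1"` or `"c2"`.
#' @return A tibble: `accession`, `gene`, `log2fc`, `neg_log10_padj`,
#'   `absent_in_control`, `final_hit`.
#' @export
volcano_table <- function(records, control = c("c2", "c1")) {
  control <- match.arg(control)
  padj <- records[[paste0("padj_", control)]]
  tibble::tibble(
    accession = records$accession,
    gene = records$gene,
    log2fc = records[[paste0("log2fc_", control)]],
    neg_log10_padj = -log10(padj),
    absent_in_control =
      records[[paste0("verdict_", control)]] == "absent_in_control",
    final_hit = records$final_hit
  )
}

#' Export an interaction network for Cytoscape and graph tooling
#'
#' `"SIF"` writes `bait<TAB>bait-prey<TAB>prey` lines; `"GraphML"` writes
#' a full attributed graph (via igraph); `"TSV"` writes an edge table and
#' a companion node table (`<path>.nodes.tsv`) carrying prey categories.
#'
#' @param edges An edge tibble from [build_network()].
#' @param format `"SIF"`, `"GraphML"` or `"TSV"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_network <- function(edges, format = c("SIF", "GraphML", "TSV"),
                           path) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("argument error: unknown ",
                                              "format", call. = FALSE))
  if (format == "SIF") {
    lines <- sprintf("%s\tbait-prey\t%s", edges$bait, edges$prey)
    writeLines(lines, path)
  } else if (format == "TSV") {
    readr::write_tsv(edges, path, na = "", progress = FALSE)
    nodes <- tibble::tibble(
      node = unique(c(edges$bait, edges$prey)),
      type = ifelse(unique(c(edges$bait, edges$prey)) %in% edges$bait,
                    "bait", "prey")
    )
    cat_map <- stats::setNames(edges$prey_category, edges$prey)
    nodes$category <- ifelse(nodes$type == "prey",
                             unname(cat_map[nodes$node]), NA_character_)
    readr::write_tsv(nodes, paste0(path, ".nodes.tsv"), na = "",
                     progress = FALSE)
  } else {
    g <- network_igraph(edges)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert an edge tibble to an igraph object
#'
#' Nodes carry `type` (bait/prey) and `category`; edges carry
#' `condition`, `evidence` and `weight`.
#'
#' @param edges An edge tibble from [build_network()].
#' @return An `igraph` graph.
#' @export
network_igraph <- function(edges) {
  verts <- tibble::tibble(name = unique(c(edges$bait, edges$prey)))
  verts$type <- ifelse(verts$name %in% edges$bait, "bait", "prey")
  cat_map <- stats::setNames(edges$prey_category, edges$prey)
  verts$category <- ifelse(verts$type == "prey",
                           unname(cat_map[verts$name]), "")
  e <- dplyr::transmute(edges, from = .data$bait, to = .data$prey,
                        condition = .data$condition,
                        evidence = .data$evidence,
                        weight = ifelse(is.na(.data$weight), 0,
                                        .data$weight))
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = verts)
}
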