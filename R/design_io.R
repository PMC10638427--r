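#' Load an AP-MS sample design from a YAML file
#'
#' The design maps every LC-MS/MS run code to a bait (or control label), a
#' growth condition, a replicate index and a role. The expected YAML layout
#' has three blocks: `conditions` (a list of condition labels), `baits`
#' (bait name -> condition -> three run codes) and `controls` (`control1`
#' and `control2`, each with a `label` and a `runs` block of condition ->
#' three run codes).
#'
#' The packaged default design (`default_design()`) encodes the screen of
#' eight SPA-tagged *E. coli* replication baits (DiaA, DnaA, DnaB, DnaG,
#' Hda, HolD, NrdB, SeqA) in three growth conditions, with untagged MG1655
#' as control 1 (resin binders) and SPA-tagged mVenus as control 2 (tag
#' binders), all in biological triplicate: 90 runs in total.
#'
#' @param path Path to a design YAML file.
#' @return A tibble of class `sample_design` with columns `run_code`,
#'   `bait`, `condition`, `replicate` (1-3) and `role` (one of
#'   `"experiment"`, `"control1"`, `"control2"`).
#' @examples
#' design <- default_design()
#' dplyr::filter(design, run_code == "F4")
#' @export
load_design <- function(path) {
  if (!file.exists(path)) {
    stop("design file does not exist: ", path, call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  for (block in c("conditions", "baits", "controls")) {
    if (is.null(raw[[block]])) {
      stop("design error: missing block '", block, "'", call. = FALSE)
    }
  }
  conditions <- as.character(unlist(raw$conditions))

  entry_rows <- function(name, cond_runs, role) {
    purrr::imap(cond_runs, function(codes, cond) {
      codes <- as.character(unlist(codes))
      tibble::tibble(
        run_code = codes,
        bait = name,
        condition = cond,
        replicate = seq_along(codes),
        role = role
      )
    })
  }

  bait_rows <- purrr::imap(raw$baits, function(cond_runs, bait) {
    entry_rows(bait, cond_runs, "experiment")
  })
  ctrl_rows <- purrr::imap(raw$controls, function(ctrl, ctrl_name) {
    if (!ctrl_name %in% c("control1", "control2")) {
      stop("design error: unknown control role '", ctrl_name, "'",
           call. = FALSE)
    }
    label <- ctrl$label %||% ctrl_name
    entry_rows(label, ctrl$runs, ctrl_name)
  })

  design <- dplyr::bind_rows(c(unname(purrr::flatten(bait_rows)),
                               unname(purrr::flatten(ctrl_rows))))
  validate_design(design, conditions)
  new_sample_design(design)
}

new_sample_design <- function(df) {
  structure(tibble::as_tibble(df),
            class = c("sample_design", class(tibble::tibble())))
}

validate_design <- function(design, conditions = unique(design$condition)) {
  bad_cond <- setdiff(design$condition, conditions)
  if (length(bad_cond) > 0) {
    stop("design error: unknown condition label(s): ",
         paste(bad_cond, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(design$run_code)) {
    dup <- unique(design$run_code[duplicated(design$run_code)])
    stop("design error: duplicate run code(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  sizes <- dplyr::count(design, .data$bait, .data$condition, .data$role)
  off <- dplyr::filter(sizes, .data$n != 3L)
  if (nrow(off) > 0) {
    stop("design error: group(s) without exactly 3 replicates: ",
         paste(paste0(off$bait, "/", off$condition), collapse = ", "),
         call. = FALSE)
  }
  for (ctrl in c("control1", "control2")) {
    per_cond <- dplyr::filter(design, .data$role == ctrl) |>
      dplyr::distinct(.data$bait, .data$condition) |>
      dplyr::count(.data$condition)
    if (!setequal(per_cond$condition, conditions) || any(per_cond$n != 1L)) {
      stop("design error: each condition needs exactly one ", ctrl,
           " group", call. = FALSE)
    }
  }
  invisible(design)
}

#' @rdname load_design
#' @export
default_design <- function() {
  load_design(system.file("extdata", "table4_design.yaml",
                          package = "apmshits", mustWork = TRUE))
}

#' Look up the run codes of one (bait, condition) group
#'
#' @param design A `sample_design` tibble.
#' @param bait Bait name (or control label for control roles).
#' @param condition Condition label.
#' @param role Role to select, default `"experiment"`.
#' @return Character vector of three run codes, in replicate order.
#' @export
design_runs <- function(design, bait = NULL, condition, role = "experiment") {
  rows <- dplyr::filter(design, .data$condition == !!condition,
                        .data$role == !!role)
  if (!is.null(bait)) rows <- dplyr::filter(rows, .data$bait == !!bait)
  if (nrow(rows) != 3L) {
    stop("design error: no triplicate group for role '", role,
         "' in condition '", condition, "'",
         if (!is.null(bait)) paste0(" (bait '", bait, "')"), call. = FALSE)
  }
  dplyr::arrange(rows, .data$replicate)$run_code
}

#' Read a MaxQuant-style protein list into an intensity table
#'
#' One row per protein group, with metadata columns and one raw-intensity
#' column per LC-MS/MS run. Accepted dialects: tab-separated text and
#' `.xlsx` spreadsheets (first sheet unless `sheet` is given). Intensity
#' column headers may be bare run codes or MaxQuant's `"Intensity <code>"`
#' convention; both are mapped back to run codes. Missing intensity cells
#' are read as 0 (not detected). Optional logical/marker columns
#' `contaminant` / `reverse` (or MaxQuant's `"Potential contaminant"` /
#' `"Reverse"` with `"+"` marks) populate the flag columns.
#'
#' @param path Path to the protein list.
#' @param dialect `"auto"` (by extension), `"tsv"` or `"xlsx"`.
#' @param sheet Sheet name or index for spreadsheet input.
#' @return A tibble of class `intensity_table` with columns `accession`,
#'   `gene`, `description`, `contaminant`, `reverse`, then one numeric
#'   column per run.
#' @export
read_protein_list <- function(path, dialect = c("auto", "tsv", "xlsx"),
                              sheet = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("protein list does not exist: ", path, call. = FALSE)
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx"
               else "tsv"
  }
  df <- if (dialect == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx requires the readxl package", call. = FALSE)
    }
    readxl::read_excel(path, sheet = sheet)
  } else {
    readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  }
  as_intensity_table(df)
}

#' Coerce a data frame to a validated intensity table
#'
#' @param df A data frame with an accession column (`accession`, `Protein
#'   IDs` or `Majority protein IDs`), optional `gene` / `description` /
#'   flag columns, and one intensity column per run.
#' @return An `intensity_table` tibble.
#' @export
as_intensity_table <- function(df) {
  df <- tibble::as_tibble(df)
  nm <- names(df)
  acc_col <- intersect(c("accession", "Protein IDs", "Majority protein IDs"),
                       nm)[1]
  if (is.na(acc_col)) {
    stop("format error: no accession column found", call. = FALSE)
  }
  gene_col <- intersect(c("gene", "Gene names"), nm)[1]
  desc_col <- intersect(c("description", "Protein names"), nm)[1]
  cont_col <- intersect(c("contaminant", "Potential contaminant"), nm)[1]
  rev_col <- intersect(c("reverse", "Reverse"), nm)[1]

  as_flag <- function(col) {
    if (is.na(col)) return(rep(FALSE, nrow(df)))
    x <- df[[col]]
    if (is.logical(x)) return(tidyr::replace_na(x, FALSE))
    !is.na(x) & x %in% c("+", "TRUE", "true", "1")
  }

  meta_cols <- stats::na.omit(c(acc_col, gene_col, desc_col, cont_col,
                                rev_col))
  run_cols <- setdiff(nm, meta_cols)
  if (length(run_cols) < 1) {
    stop("format error: no intensity columns found", call. = FALSE)
  }
  run_codes <- sub("^Intensity[ .]", "", run_cols)
  values <- purrr::map(df[run_cols], function(x) {
    x <- suppressWarnings(as.numeric(x))
    tidyr::replace_na(x, 0)
  })
  names(values) <- run_codes

  out <- tibble::tibble(
    accession = as.character(df[[acc_col]]),
    gene = if (!is.na(gene_col)) as.character(df[[gene_col]])
           else NA_character_,
    description = if (!is.na(desc_col)) as.character(df[[desc_col]])
                  else NA_character_,
    contaminant = as_flag(cont_col),
    reverse = as_flag(rev_col),
    !!!values
  )
  validate_intensity_table(out)
}

validate_intensity_table <- function(tbl) {
  if (anyDuplicated(tbl$accession)) {
    dup <- unique(tbl$accession[duplicated(tbl$accession)])
    stop("data error: duplicate accession(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  runs <- run_codes(tbl)
  for (rc in runs) {
    v <- tbl[[rc]]
    if (!is.numeric(v)) {
      stop("data error: non-numeric intensity column '", rc, "'",
           call. = FALSE)
    }
    if (any(v < 0, na.rm = TRUE)) {
      stop("data error: negative intensity in run '", rc, "'",
           call. = FALSE)
    }
  }
  structure(tbl, class = unique(c("intensity_table", class(tbl))))
}

#' Run codes of an intensity table
#'
#' @param tbl An `intensity_table`.
#' @return Character vector of run-code column names.
#' @export
run_codes <- function(tbl) {
  setdiff(names(tbl),
          c("accession", "gene", "description", "contaminant", "reverse"))
}

run_column <- function(tbl, run_code) {
  if (!run_code %in% run_codes(tbl)) {
    stop("lookup error: unknown run code '", run_code, "'", call. = FALSE)
  }
  tbl[[run_code]]
}

#' Drop contaminant- and reverse-flagged protein groups
#'
#' Removes rows flagged as common contaminants (keratins, trypsin, ...) or
#' as reverse-database decoys; all other rows are kept unchanged, in their
#' original order. Idempotent.
#'
#' @param tbl An `intensity_table`.
#' @return The filtered `intensity_table`.
#' @export
filter_flagged <- function(tbl) {
  out <- dplyr::filter(tbl, !.data$contaminant, !.data$reverse)
  structure(out, class = unique(c("intensity_table", class(out))))
}

#' Write an intensity table in the tab-separated MaxQuant-like dialect
#'
#' Writes a header row (`accession`, `gene`, `description`, `contaminant`,
#' `reverse`, then one column per run code) and one row per protein group.
#' Zeros are written explicitly as `0`, so `read_protein_list()` round-trips
#' the table exactly.
#'
#' @param tbl An `intensity_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maxquant_like <- function(tbl, path) {
  out <- tibble::as_tibble(tbl)
  out$contaminant <- ifelse(out$contaminant, "+", "")
  out$reverse <- ifelse(out$reverse, "+", "")
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write a sample design back to YAML
#'
#' Emits the `conditions`/`baits`/`controls` layout accepted by
#' [load_design()].
#'
#' @param design A `sample_design` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_yaml <- function(design, path) {
  conditions <- unique(design$condition)
  runs_by <- function(rows) {
    rows <- dplyr::arrange(rows, .data$replicate)
    split(rows$run_code, factor(rows$condition, levels = conditions)) |>
      purrr::map(as.list)
  }
  baits <- dplyr::filter(design, .data$role == "experiment")
  bait_block <- purrr::map(split(baits, baits$bait), runs_by)
  ctrl_block <- purrr::map(c(control1 = "control1", control2 = "control2"),
    function(r) {
      rows <- dplyr::filter(design, .data$role == !!r)
      list(label = unique(rows$bait), runs = runs_by(rows))
    })
  yaml::write_yaml(list(conditions = as.list(conditions),
                        baits = bait_block,
                        controls = ctrl_block), path)
  invisible(path)
}
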