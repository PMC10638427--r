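#' Parameters of the synthetic AP-MS data generator
#'
#' The generator emulates the screen's design: per condition, one
#' experimental triplicate per bait plus a triplicate of each of the two
#' negative controls. Proteins fall into five ground-truth classes:
#'
#' * `bait`: present everywhere at baseline (an endogenous protein),
#'   boosted by `bait_log10_boost` log10 units in its own pull-down;
#' * `specific_prey`: in `"exclusive"` mode present only in its bait's
#'   experimental runs (at baseline + `effect_log10`); in `"enrichment"`
#'   mode present everywhere at baseline and `effect_log10` higher in its
#'   bait's runs;
#' * `resin_binder`: present in every run at baseline (sticks to the
#'   chromatography resins);
#' * `tag_binder`: present in control 2 and all experimental runs, absent
#'   from control 1 (binds the affinity tag);
#' * `bystander`: present everywhere at baseline.
#'
#' Intensities are lognormal: 10^(protein baseline + class/role offset +
#' Normal(0, `replicate_noise_sd`)), then zeroed with probability
#' `dropout_prob` per cell (structural absences stay 0). All log10-scale.
#'
#' @param n_proteins Total protein groups (default 300).
#' @param n_baits Number of baits (default 3).
#' @param preys_per_bait Specific preys planted per bait (default 10).
#' @param n_resin_binders,n_tag_binders Background class sizes (defaults
#'   20 and 10).
#' @param baseline_log10_mean,baseline_log10_sd Protein-level abundance
#'   distribution on the log10 scale (defaults 7 and 0.5, typical of
#'   label-free MS intensities).
#' @param effect_log10 Prey enrichment over controls in log10 units
#'   (default 2).
#' @param replicate_noise_sd Per-run measurement noise, log10 units
#'   (default 0.15).
#' @param dropout_prob Per-cell nondetection probability (default 0).
#' @param bait_log10_boost Bait enrichment in its own pull-down (default 3).
#' @param prey_mode `"exclusive"` (default) or `"enrichment"` (see above).
#' @param conditions Condition labels (default the screen's three).
#' @param seed Integer seed; the same params and seed always reproduce the
#'   identical dataset.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_proteins = 300, n_baits = 3, preys_per_bait = 10,
                       n_resin_binders = 20, n_tag_binders = 10,
                       baseline_log10_mean = 7, baseline_log10_sd = 0.5,
                       effect_log10 = 2, replicate_noise_sd = 0.15,
                       dropout_prob = 0, bait_log10_boost = 3,
                       prey_mode = c("exclusive", "enrichment"),
                       conditions = c("LB_log", "LB_ON", "M9_ac_ON"),
                       seed = 42) {
  prey_mode <- match.arg(prey_mode)
  planted <- n_baits * (1 + preys_per_bait) + n_resin_binders +
    n_tag_binders
  if (planted > n_proteins) {
    stop("parameter error: planted classes (", planted,
         ") exceed n_proteins (", n_proteins, ")", call. = FALSE)
  }
  if (n_baits < 1 || preys_per_bait < 0 || n_resin_binders < 0 ||
      n_tag_binders < 0) {
    stop("parameter error: counts must be nonnegative (n_baits >= 1)",
         call. = FALSE)
  }
  if (baseline_log10_sd < 0 || replicate_noise_sd < 0 ||
      effect_log10 < 0 || bait_log10_boost < 0) {
    stop("parameter error: sds, effect_log10 and bait_log10_boost must ",
         "be >= 0", call. = FALSE)
  }
  if (dropout_prob < 0 || dropout_prob >= 1) {
    stop("parameter error: dropout_prob must lie in [0, 1)", call. = FALSE)
  }
  structure(as.list(environment())[
    c("n_proteins", "n_baits", "preys_per_bait", "n_resin_binders",
      "n_tag_binders", "baseline_log10_mean", "baseline_log10_sd",
      "effect_log10", "replicate_noise_sd", "dropout_prob",
      "bait_log10_boost", "prey_mode", "conditions", "seed")],
    class = "sim_params")
}

sim_design <- function(params) {
  baits <- paste0("BAIT", seq_len(params$n_baits))
  grid <- tidyr::expand_grid(
    condition = params$conditions,
    bait = c(baits, "CTRL1", "CTRL2"),
    replicate = 1:3
  ) |>
    dplyr::mutate(
      role = dplyr::case_when(bait == "CTRL1" ~ "control1",
                              bait == "CTRL2" ~ "control2",
                              TRUE ~ "experiment"),
      run_code = sprintf("%s_%s_r%d", .data$bait, .data$condition,
                         .data$replicate)
    ) |>
    dplyr::select("run_code", "bait", "condition", "replicate", "role")
  new_sample_design(grid)
}

sim_truth <- function(params) {
  baits <- paste0("BAIT", seq_len(params$n_baits))
  classes <- c(
    rep("bait", params$n_baits),
    rep("specific_prey", params$n_baits * params$preys_per_bait),
    rep("resin_binder", params$n_resin_binders),
    rep("tag_binder", params$n_tag_binders)
  )
  classes <- c(classes, rep("bystander", params$n_proteins -
                              length(classes)))
  of_bait <- rep(NA_character_, params$n_proteins)
  of_bait[classes == "bait"] <- baits
  of_bait[classes == "specific_prey"] <-
    rep(baits, each = params$preys_per_bait)
  tibble::tibble(
    accession = sprintf("SIM%04d", seq_len(params$n_proteins)),
    class = classes,
    of_bait = of_bait
  )
}

#' Generate a synthetic AP-MS dataset with known ground truth
#'
#' Draw order (fixed, so outputs are stable): (1) protein baselines, one
#' vector of length `n_proteins`; (2) replicate noise, one proteins-by-runs
#' matrix in design run order; (3) dropout uniforms, one matrix of the
#' same shape. Noise and dropout are drawn for every cell, including
#' structurally absent ones, so the realized values of present cells do
#' not depend on the class layout.
#'
#' @param params A [sim_params()] list.
#' @return A list with elements `table` (an `intensity_table`), `design`
#'   (a `sample_design`) and `truth` (a tibble: `accession`, `class`,
#'   `of_bait`).
#' @export
generate_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  design <- sim_design(params)
  truth <- sim_truth(params)
  n <- params$n_proteins
  runs <- design$run_code

  set.seed(params$seed)
  baseline <- stats::rnorm(n, params$baseline_log10_mean,
                           params$baseline_log10_sd)
  noise <- matrix(stats::rnorm(n * length(runs), 0,
                               params$replicate_noise_sd),
                  nrow = n)
  drop_u <- matrix(stats::runif(n * length(runs)), nrow = n)

  present <- matrix(TRUE, n, length(runs))
  offset <- matrix(0, n, length(runs))
  for (j in seq_along(runs)) {
    role <- design$role[j]
    run_bait <- design$bait[j]
    is_prey_of <- truth$class == "specific_prey" & truth$of_bait == run_bait
    is_bait_of <- truth$class == "bait" & truth$of_bait == run_bait
    if (role == "control1") {
      present[truth$class == "tag_binder", j] <- FALSE
    }
    if (role %in% c("control1", "control2") &&
        params$prey_mode == "exclusive") {
      present[truth$class == "specific_prey", j] <- FALSE
    }
    if (role == "experiment") {
      if (params$prey_mode == "exclusive") {
        other_prey <- truth$class == "specific_prey" & !is_prey_of
        present[other_prey, j] <- FALSE
      }
      offset[is_prey_of, j] <- params$effect_log10
      offset[is_bait_of, j] <- params$bait_log10_boost
    }
  }

  values <- 10^(baseline + offset + noise)
  values[!present] <- 0
  values[drop_u < params$dropout_prob] <- 0
  colnames(values) <- runs

  tbl <- tibble::tibble(
    accession = truth$accession,
    gene = tolower(truth$accession),
    description = paste("synthetic", truth$class),
    contaminant = FALSE,
    reverse = FALSE,
    !!!tibble::as_tibble(values)
  )
  list(table = validate_intensity_table(tbl), design = design,
       truth = truth)
}

#' Write a simulated dataset as a fixture bundle
#'
#' One tab-separated intensity file per condition (runs of that condition
#' only), the design as YAML, and the ground truth as TSV.
#'
#' @param dataset A list as returned by [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture_bundle <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- c("accession", "gene", "description", "contaminant", "reverse")
  paths <- list()
  for (cond in unique(dataset$design$condition)) {
    runs <- dplyr::filter(dataset$design, .data$condition == cond)$run_code
    sub <- dataset$table[, c(meta, runs)]
    p <- file.path(dir, paste0("intensities_", cond, ".tsv"))
    write_maxquant_like(validate_intensity_table(sub), p)
    paths[[cond]] <- p
  }
  paths$design <- file.path(dir, "design.yaml")
  write_design_yaml(dataset$design, paths$design)
  paths$truth <- file.path(dir, "truth.tsv")
  readr::write_tsv(dataset$truth, paths$truth, progress = FALSE)
  invisible(paths)
}
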