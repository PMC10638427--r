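# In-code fixtures for the test suite.

# A minimal one-condition design: one bait triplicate plus both control
# triplicates (the smallest design the strategies accept).
mini_design <- function(condition = "LB_log", bait = "BAIT1") {
  runs <- c(paste0("E", 1:3), paste0("N", 1:3), paste0("M", 1:3))
  apmshits:::new_sample_design(tibble::tibble(
    run_code = runs,
    bait = rep(c(bait, "CTRL1", "CTRL2"), each = 3),
    condition = condition,
    replicate = rep(1:3, 3),
    role = rep(c("experiment", "control1", "control2"), each = 3)
  ))
}

# Build an intensity table directly from a named list of run columns.
make_table <- function(values, accessions = NULL) {
  n <- length(values[[1]])
  accessions <- accessions %||% sprintf("P%02d", seq_len(n))
  as_intensity_table(tibble::tibble(
    accession = accessions,
    gene = tolower(accessions),
    description = "test protein",
    contaminant = FALSE,
    reverse = FALSE,
    !!!values
  ))
}

# Random small instance on the mini design: lognormal intensities with
# random per-cell dropout, so detection patterns vary across proteins.
random_instance <- function(seed, n_proteins = 30, dropout = 0.3) {
  set.seed(seed)
  runs <- mini_design()$run_code
  vals <- purrr::map(stats::setNames(runs, runs), function(r) {
    v <- 10^stats::rnorm(n_proteins, 6, 1)
    v[stats::runif(n_proteins) < dropout] <- 0
    v
  })
  make_table(vals)
}
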