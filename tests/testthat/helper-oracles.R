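# Independent oracles: straight-line transcriptions of the two processing
# strategies and of the BH step-up, deliberately written without any of the
# package's internals so they can cross-check the implementation.

# Qualitative strategy by brute-force set algebra over the raw table.
oracle_qualitative <- function(tbl, exp_runs, c1_runs, c2_runs) {
  detected <- function(run) tbl$accession[tbl[[run]] > 0]
  hits <- character(0)
  for (acc in tbl$accession) {
    in_all_exp <- all(vapply(exp_runs,
                             function(r) acc %in% detected(r), logical(1)))
    in_any_ctrl <- any(vapply(c(c1_runs, c2_runs),
                              function(r) acc %in% detected(r), logical(1)))
    if (in_all_exp && !in_any_ctrl) hits <- c(hits, acc)
  }
  hits
}

# Hand-coded Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank downwards
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Naive transcription of the quantitative strategy, step by step, using
# plain loops over the raw intensity matrix.
oracle_quantitative <- function(tbl, exp_runs, c1_runs, c2_runs,
                                fold_threshold = 1.5, alpha = 0.01) {
  all_runs <- c(exp_runs, c1_runs, c2_runs)
  # steps 1-2: median normalization (nonzero median), 0 -> 1, log10
  trans <- list()
  for (r in all_runs) {
    v <- tbl[[r]]
    med <- median(v[v > 0])
    tv <- numeric(length(v))
    for (i in seq_along(v)) {
      tv[i] <- if (v[i] > 0) log10(v[i] / med) else log10(1)
    }
    trans[[r]] <- tv
  }
  # step 3: global SD over all values of all samples of the condition
  pooled <- unlist(trans, use.names = FALSE)
  gsd <- sd(pooled)
  # step 4: triplicate averages
  avg <- function(runs, i) mean(c(trans[[runs[1]]][i], trans[[runs[2]]][i],
                                  trans[[runs[3]]][i]))
  n <- nrow(tbl)
  res <- data.frame(accession = tbl$accession, av_exp = NA_real_,
                    p_c1 = NA_real_, p_c2 = NA_real_,
                    status_c1 = NA_character_, status_c2 = NA_character_,
                    stringsAsFactors = FALSE)
  # candidate proteins: detected in at least one experimental replicate
  candidate <- logical(n)
  for (i in seq_len(n)) {
    candidate[i] <- any(tbl[[exp_runs[1]]][i] > 0,
                        tbl[[exp_runs[2]]][i] > 0,
                        tbl[[exp_runs[3]]][i] > 0)
  }
  for (i in seq_len(n)) {
    if (!candidate[i]) next
    res$av_exp[i] <- avg(exp_runs, i)
    for (ctrl in c("c1", "c2")) {
      cr <- if (ctrl == "c1") c1_runs else c2_runs
      av_c <- avg(cr, i)
      # step 5: absence rule
      if (av_c == 0) {
        res[[paste0("status_", ctrl)]][i] <- "absent"
        next
      }
      # step 6: log2-scale enrichment with inclusive threshold
      l2 <- (res$av_exp[i] - av_c) / log10(2)
      if (l2 < fold_threshold) {
        res[[paste0("status_", ctrl)]][i] <- "failed_fold"
        next
      }
      # step 7: one-sided z against the global SD
      z <- (res$av_exp[i] - av_c) / gsd
      res[[paste0("p_", ctrl)]][i] <- pnorm(z, lower.tail = FALSE)
      res[[paste0("status_", ctrl)]][i] <- "tested"
    }
  }
  # step 7 continued: BH per control over tested proteins
  for (ctrl in c("c1", "c2")) {
    pcol <- paste0("p_", ctrl)
    scol <- paste0("status_", ctrl)
    tested <- which(res[[scol]] == "tested")
    if (length(tested) > 0) {
      padj <- oracle_bh(res[[pcol]][tested])
      ok <- padj <= alpha
      res[[scol]][tested[ok]] <- "enriched"
      res[[scol]][tested[!ok]] <- "not_significant"
    }
  }
  # steps 9-10: all-three-replicates rule and final verdict
  hits <- character(0)
  for (i in seq_len(n)) {
    if (!candidate[i]) next
    present_all <- all(tbl[[exp_runs[1]]][i] > 0,
                       tbl[[exp_runs[2]]][i] > 0,
                       tbl[[exp_runs[3]]][i] > 0)
    ok1 <- res$status_c1[i] %in% c("absent", "enriched")
    ok2 <- res$status_c2[i] %in% c("absent", "enriched")
    if (present_all && ok1 && ok2) hits <- c(hits, tbl$accession[i])
  }
  list(hits = hits, detail = res[candidate, , drop = FALSE],
       global_sd = gsd)
}
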