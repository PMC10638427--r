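test_that("median normalization and the zero rule", {
  tbl <- make_table(list(E1 = c(10, 20, 40, 0)))
  # nonzero median 20 -> ratios (0.5, 1, 2), zero stays 0 after transform
  expect_equal(normalize_and_log(tbl, "E1"),
               c(log10(0.5), 0, log10(2), 0), tolerance = 1e-12)
  expect_equal(normalize_and_log(tbl, "E1")[1], -0.30103, tolerance = 1e-5)

  same <- make_table(list(E1 = c(7, 7, 7)))
  expect_equal(normalize_and_log(same, "E1"), c(0, 0, 0))

  zero <- make_table(list(E1 = c(0, 0)))
  expect_warning(out <- normalize_and_log(zero, "E1"), "no detected")
  expect_equal(out, c(0, 0))
})

test_that("global stats pool all transformed values of a condition", {
  design <- mini_design()
  # all runs identical constant -> every transformed value is 0
  const <- make_table(purrr::map(
    stats::setNames(design$run_code, design$run_code), ~c(5, 5, 5)))
  gs <- global_stats(const, design, "LB_log")
  expect_equal(gs$global_sd, 0)
  expect_equal(gs$n_values, 27L)

  # pooled multiset {0,0,1,1}: sample SD 1/sqrt(3), population SD 0.5
  expect_equal(apmshits:::pooled_stats(c(0, 0, 1, 1), "x",
                                       "sample")$global_sd,
               0.5773503, tolerance = 1e-6)
  expect_equal(apmshits:::pooled_stats(c(0, 0, 1, 1), "x",
                                       "population")$global_sd, 0.5)
  # grouping-invariant: only the pooled multiset matters
  expect_equal(apmshits:::pooled_stats(c(1, 0, 1, 0), "x", "sample"),
               apmshits:::pooled_stats(c(0, 0, 1, 1), "x", "sample"))
  expect_error(apmshits:::pooled_stats(1, "x", "sample"), "at least 2")
})

test_that("triplicate averaging is the arithmetic mean of three", {
  expect_equal(average_triplicate(c(0, 0, 0)), 0)
  expect_equal(average_triplicate(c(1, 2, 3)), 2)
  expect_equal(average_triplicate(c(3, 1, 2)), average_triplicate(1:3))
  expect_error(average_triplicate(c(1, 2)), "arity")
})

test_that("control verdicts: absence rule, fold threshold, z and p", {
  cfg <- quant_config()
  # absence rule dominates regardless of magnitude
  v <- control_verdict(c(0.1, 5), c(0, 0), global_sd = 0.3, cfg)
  expect_equal(v$verdict, rep("absent_in_control", 2))
  expect_true(all(is.na(v$p)))

  # equal averages -> log2fc 0 -> rejected before any test
  v <- control_verdict(1, 1, 0.3, cfg)
  expect_equal(v$verdict, "rejected")
  expect_equal(v$log2fc, 0)
  expect_true(is.na(v$p))

  # boundary-inclusive threshold: log10 difference of 0.4515449935 is
  # exactly log2fc 1.5 and passes; z and p frozen from an independent
  # numerical oracle (diff/sd and the normal upper tail)
  v <- control_verdict(1.4515449935, 1, 0.2, cfg)
  expect_equal(v$verdict, "enriched")
  expect_equal(v$log2fc, 1.5, tolerance = 1e-9)
  expect_equal(v$z, 2.2577249675, tolerance = 1e-9)
  expect_equal(v$p, 0.011981405817, tolerance = 1e-10)

  # degenerate global SD: tested proteins get p = 0 with a warning
  expect_warning(v0 <- control_verdict(2, 1, 0, cfg), "global SD is 0")
  expect_equal(v0$p, 0)

  # mean_of_three scaling divides by sd * sqrt(2/3)
  cfg2 <- quant_config(zscore_scale = "mean_of_three")
  v3 <- control_verdict(2, 1, 0.2, cfg2)
  expect_equal(v3$z, 1 / (0.2 * sqrt(2 / 3)), tolerance = 1e-12)

  # log10 fold scale applies the threshold to the raw log10 difference
  cfg10 <- quant_config(fold_scale = "log10")
  expect_equal(control_verdict(2.4, 1, 0.2, cfg10)$verdict, "rejected")
  expect_equal(control_verdict(2.6, 1, 0.2, cfg10)$verdict, "enriched")
})

test_that("bh_adjust matches the hand-coded step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "input error")
  expect_error(bh_adjust(c(0.5, -0.1)), "input error")

  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    # monotone on the sorted scale
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("quantitative_hits matches the naive step-by-step oracle", {
  design <- mini_design()
  exp_runs <- design_runs(design, "BAIT1", "LB_log")
  c1_runs <- design_runs(design, NULL, "LB_log", "control1")
  c2_runs <- design_runs(design, NULL, "LB_log", "control2")
  for (seed in 1:25) {
    tbl <- random_instance(seed, n_proteins = 50)
    rec <- quantitative_hits(tbl, design, "BAIT1", "LB_log")
    orc <- oracle_quantitative(tbl, exp_runs, c1_runs, c2_runs)
    expect_setequal(rec$accession[rec$final_hit], orc$hits)
    # averages and p-values agree exactly on the shared proteins
    shared <- intersect(rec$accession, orc$detail$accession)
    i <- match(shared, rec$accession)
    j <- match(shared, orc$detail$accession)
    expect_equal(rec$av_exp[i], orc$detail$av_exp[j])
    expect_equal(rec$p_c1[i], orc$detail$p_c1[j])
    expect_equal(rec$p_c2[i], orc$detail$p_c2[j])
  }
})

test_that("record invariants hold on random instances", {
  design <- mini_design()
  for (seed in c(3, 14, 27)) {
    tbl <- random_instance(seed, n_proteins = 40)
    rec <- quantitative_hits(tbl, design, "BAIT1", "LB_log")
    # absence verdict iff control average is 0
    expect_equal(rec$verdict_c1 == "absent_in_control", rec$av_c1 == 0)
    expect_equal(rec$verdict_c2 == "absent_in_control", rec$av_c2 == 0)
    # final hits need full presence and two non-rejected verdicts
    expect_true(all(rec$present_all_reps[rec$final_hit]))
    expect_true(all(rec$verdict_c1[rec$final_hit] != "rejected"))
    expect_true(all(rec$verdict_c2[rec$final_hit] != "rejected"))
    # adjusted never below raw
    both <- !is.na(rec$p_c1)
    expect_true(all(rec$padj_c1[both] >= rec$p_c1[both]))
    # determinism: identical inputs, identical records
    expect_identical(rec, quantitative_hits(tbl, design, "BAIT1",
                                            "LB_log"))
    # row order never affects results
    perm <- sample(nrow(tbl))
    rec_perm <- quantitative_hits(
      validate_intensity_table(tbl[perm, ]), design, "BAIT1", "LB_log")
    expect_equal(dplyr::arrange(rec_perm, accession),
                 dplyr::arrange(rec, accession))
  }
})

test_that("hit sets are nested across the adjusted-p threshold", {
  design <- mini_design()
  tbl <- random_instance(5, n_proteins = 60, dropout = 0.2)
  strict <- quantitative_hits(tbl, design, "BAIT1", "LB_log",
                              quant_config(alpha_adjusted = 0.01))
  loose <- quantitative_hits(tbl, design, "BAIT1", "LB_log",
                             quant_config(alpha_adjusted = 0.05))
  expect_true(all(strict$accession[strict$final_hit] %in%
                    loose$accession[loose$final_hit]))
})

test_that("raising the experimental average never loses a hit", {
  cfg <- quant_config()
  gsd <- 0.25
  av_ctrl <- 0.4
  verdicts <- purrr::map_chr(seq(0.5, 3, by = 0.25), function(av) {
    control_verdict(av, av_ctrl, gsd, cfg)$verdict
  })
  # once enriched, stays enriched as av_exp grows
  first_enriched <- match("enriched", verdicts)
  expect_false(is.na(first_enriched))
  expect_true(all(verdicts[first_enriched:length(verdicts)] == "enriched"))
})
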