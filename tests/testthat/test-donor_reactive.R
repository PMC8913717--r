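# Pairs with equal total reads: downsampling to the common (= full) depth is
# the identity, so normalized folds equal raw folds exactly.
equal_depth_pair <- function(unstim_reads, stim_reads, nts) {
  tot_u <- sum(unstim_reads); tot_s <- sum(stim_reads)
  filler <- abs(tot_u - tot_s)
  u_nt <- nts; s_nt <- nts
  if (filler > 0 && tot_u < tot_s) {
    unstim_reads <- c(unstim_reads, filler); u_nt <- c(nts, "TGTTTTAAAGGG")
  } else if (filler > 0) {
    stim_reads <- c(stim_reads, filler); s_nt <- c(nts, "TGTTTTAAACCC")
  }
  list(unstim = toy_repertoire(unstim_reads, cdr3_nt = u_nt, condition = "bulk"),
       stim = toy_repertoire(stim_reads, cdr3_nt = s_nt, condition = "stimulated"))
}

test_that("fold threshold applies at equality, on either fold route", {
  p <- equal_depth_pair(c(2L, 2L, 996L), c(10L, 9L, 981L),
                        c("TGTAAA", "TGTCCC", "TGTGGG"))
  for (norm in c(TRUE, FALSE)) {
    dr <- call_donor_reactive(p$unstim, p$stim, threshold = 5,
                              config = downsample_config(10, seed = 1),
                              normalize = norm)
    k <- clonotype_key(c("TGTAAA", "TGTCCC"), "TRBV9", "TRBJ2-7")
    expect_true(k[1] %in% dr$keys)   # fold 5: "equal or greater"
    expect_false(k[2] %in% dr$keys)  # fold 4.5
  }
})

test_that("fold-boundary fixture recovers exactly the >=5 set plus absent rule", {
  d <- tempfile(); write_fixture_suite(d)
  unstim <- read_clonotype_table(file.path(d, "fold_boundary_unstim.tsv"),
                                 "P1", "preTx", "CD4", "bulk", dialect_canonical())
  stim <- read_clonotype_table(file.path(d, "fold_boundary_stim.tsv"),
                               "P1", "preTx", "CD4", "stimulated", dialect_canonical())
  expect_equal(unstim$total_reads, stim$total_reads)  # noise-free: equal depths
  exp <- data.table::fread(file.path(d, "fold_boundary_expected.tsv"))
  dr <- call_donor_reactive(unstim, stim, config = downsample_config(10, seed = 2))
  for (i in seq_len(nrow(exp))) {
    k <- clonotype_key(exp$cdr3_nt[i], "TRBV9", "TRBJ2-7")
    expect_equal(k %in% dr$keys, exp$expected_reactive[i], info = exp$fold[i])
  }
  # nothing beyond the expected reactive keys is called
  expect_setequal(dr$keys, clonotype_key(exp[expected_reactive == TRUE, cdr3_nt],
                                         "TRBV9", "TRBJ2-7"))
})

test_that("absent-in-unstim rule: floor defaults to the threshold, configurable", {
  # equal totals (410 each); TGTAAA and TGTCCC absent from the unstimulated
  unstim <- toy_repertoire(c(400L, 10L), cdr3_nt = c("TGTGGG", "TGTTTT"),
                           condition = "bulk")
  stim <- toy_repertoire(c(400L, 4L, 6L),
                         cdr3_nt = c("TGTGGG", "TGTAAA", "TGTCCC"),
                         condition = "stimulated")
  p <- list(unstim = unstim, stim = stim)
  cfg <- downsample_config(10, seed = 3)
  dr <- call_donor_reactive(p$unstim, p$stim, threshold = 5, config = cfg)
  kA <- clonotype_key("TGTAAA", "TRBV9", "TRBJ2-7")  # absent, 4 reads < 5
  kC <- clonotype_key("TGTCCC", "TRBV9", "TRBJ2-7")  # absent, 6 reads >= 5
  expect_false(kA %in% dr$keys)
  expect_true(kC %in% dr$keys)
  dr2 <- call_donor_reactive(p$unstim, p$stim, threshold = 5, config = cfg,
                             absent_min_reads = 2)
  expect_true(kA %in% dr2$keys)
  dr3 <- call_donor_reactive(p$unstim, p$stim, threshold = 5, config = cfg,
                             absent_min_reads = Inf)
  expect_false(any(c(kA, kC) %in% dr3$keys))
})

test_that("calling is monotone in the threshold", {
  set.seed(17)
  n <- 60
  u_reads <- sample(1:50, n, replace = TRUE)
  s_reads <- pmax(1L, as.integer(round(u_reads * stats::rlnorm(n, 0.3, 1))))
  nts <- sprintf("TGTGCC%03dTTT", 1:n)
  p <- equal_depth_pair(u_reads, s_reads, nts)
  cfg <- downsample_config(10, seed = 4)
  sizes <- vapply(c(1.5, 2, 3, 5, 8, 12), function(th)
    length(call_donor_reactive(p$unstim, p$stim, threshold = th,
                               config = cfg)$keys), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("contract errors on bad inputs", {
  p <- equal_depth_pair(c(10L), c(50L), "TGTAAA")
  expect_error(call_donor_reactive(p$unstim, p$stim, threshold = 1),
               class = "allotrace_config_error")
  post <- toy_repertoire(10L, timepoint = "M1")
  expect_error(call_donor_reactive(post, p$stim), class = "allotrace_contract_error")
  expect_error(call_donor_reactive(p$unstim, p$unstim),
               class = "allotrace_contract_error")
})

test_that("tracking: boundary cases and a constructed fixture", {
  p <- equal_depth_pair(c(2L, 500L), c(20L, 482L), c("TGTAAA", "TGTGGG"))
  dr <- call_donor_reactive(p$unstim, p$stim, config = downsample_config(10, seed = 5))

  # empty intersection
  bulk0 <- toy_repertoire(c(5L, 5L), cdr3_nt = c("TGTGAGAAG", "TGTGAGCCC"))
  t0 <- track_donor_reactive(dr, bulk0)
  expect_equal(c(t0$pct_clonotypes, t0$cum_freq), c(0, 0))

  # bulk consisting only of donor-reactive keys
  bulk1 <- toy_repertoire(77L, cdr3_nt = "TGTAAA")
  t1 <- track_donor_reactive(dr, bulk1)
  expect_equal(c(t1$pct_clonotypes, t1$cum_freq), c(100, 100))

  # 200 clonotypes, 3 reactive keys carrying summed frequency 0.021
  nts <- sprintf("TGTGCC%03dTTT", 1:200)
  freqs <- rep((1 - 0.021) / 197, 200)
  freqs[1:3] <- 0.021 / 3
  bulk2 <- freq_repertoire(freqs, cdr3_nt = nts, scale = 3e6)
  dr2 <- dr; dr2$keys <- clonotype_key(nts[1:3], "TRBV9", "TRBJ2-7")
  t2 <- track_donor_reactive(dr2, bulk2)
  expect_equal(t2$pct_clonotypes, 1.5)
  expect_equal(t2$cum_freq, 2.1, tolerance = 1e-4)  # integer-read rounding
})

test_that("delta_table: per-patient deltas, group summaries, missing preTx", {
  rec <- data.table::data.table(
    patient_id = rep(c("P1", "P2"), each = 4),
    group = rep(c("ATLG", "basiliximab"), each = 4),
    phenotype = "CD4",
    timepoint = rep(c("preTx", "M1", "M3", "M12"), 2),
    pct_clonotypes = c(1.0, 1.67, 1.5, 1.4, 2.0, 2.0, 2.0, 2.0),
    cum_freq = c(1.0, 1.9, 1.8, 1.6, 0.5, 1.4, 1.2, 1.0))
  d <- delta_table(rec)
  expect_equal(d$per_patient[patient_id == "P1", pct_clonotypes_delta], 0.67)
  expect_equal(d$per_patient[patient_id == "P2", pct_clonotypes_delta], 0)
  dm <- delta_table(rec, post_policy = "mean_post")
  expect_equal(dm$per_patient[patient_id == "P1", cum_freq_delta],
               mean(c(1.9, 1.8, 1.6)) - 1.0)
  # all-zero-delta cohort: summary mean 0, sd 0
  rec0 <- data.table::copy(rec)[, `:=`(pct_clonotypes = 1, cum_freq = 1)]
  d0 <- delta_table(rec0)
  expect_true(all(d0$group_summary$pct_clonotypes_delta == 0))
  expect_warning(delta_table(rec[timepoint != "preTx" | patient_id != "P1"]),
                 "P1")
})
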