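# Shared fixture builders. Everything is constructed in code; the only
# on-disk fixture is the bundled synthetic specificity table.

# a repertoire from bare (nt, reads) pairs, constant genes unless given
toy_repertoire <- function(reads, cdr3_nt = NULL, v_gene = "TRBV9",
                           j_gene = "TRBJ2-7", cdr3_aa = NULL,
                           patient_id = "P1", timepoint = "preTx",
                           phenotype = "CD4", condition = "bulk") {
  n <- length(reads)
  if (is.null(cdr3_nt))
    cdr3_nt <- vapply(seq_len(n), function(i)
      paste0("TGTGCC", paste(rep("AAA", i %% 5 + 1), collapse = ""),
             sprintf("C%03dTTC", i)), character(1))
  if (is.null(cdr3_aa)) cdr3_aa <- sprintf("CASX%dF", seq_len(n))
  repertoire(data.frame(cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
                        v_gene = rep_len(v_gene, n), d_gene = "",
                        j_gene = rep_len(j_gene, n), reads = reads),
             patient_id, timepoint, phenotype, condition)
}

# a repertoire with explicit frequencies (scaled to integer reads)
freq_repertoire <- function(freqs, scale = 1e6, ...) {
  toy_repertoire(reads = round(freqs * scale), ...)
}

# long balanced split-plot table: n subjects per group, k timepoints
balanced_table <- function(values, groups, times) {
  n <- nrow(values); k <- ncol(values)
  data.frame(subject = rep(sprintf("S%02d", seq_len(n)), each = k),
             group = rep(groups, each = k),
             time = rep(times, n),
             value = as.vector(t(values)))
}

# independent split-plot oracle via base R model fitters: F/p from aov(),
# Greenhouse-Geisser-corrected p and Mauchly p from the anova.mlm machinery
aov_oracle <- function(values, groups, times) {
  long <- balanced_table(values, groups, times)
  long$subject <- factor(long$subject); long$group <- factor(long$group)
  long$time <- factor(long$time, levels = times)
  fit <- stats::aov(value ~ group * time + Error(subject / time), data = long)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: subject:time"]][[1]]
  rownames(between) <- trimws(rownames(between))
  rownames(within) <- trimws(rownames(within))
  mlm <- stats::lm(values ~ groups)
  idata <- data.frame(time = factor(times, levels = times))
  a <- stats::anova(mlm, idata = idata, X = ~1, test = "Spherical")
  mau <- stats::mauchly.test(mlm, idata = idata, X = ~1)
  list(F_group = between["group", "F value"],
       p_group = between["group", "Pr(>F)"],
       F_time = within["time", "F value"],
       p_time = within["time", "Pr(>F)"],
       F_gt = within["group:time", "F value"],
       p_gt = within["group:time", "Pr(>F)"],
       p_time_gg = a[["G-G Pr"]][1],
       p_gt_gg = a[["G-G Pr"]][2],
       mauchly_p = mau$p.value)
}

# tiny cohort spec for fast end-to-end tests
small_spec <- function(seed = 1L, ...) {
  cohort_spec(n_per_group = c(ATLG = 2L, basiliximab = 2L),
              clonotype_count_range = list(CD4 = c(300L, 1500L),
                                           CD8 = c(300L, 1500L)),
              seed = seed, ...)
}
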