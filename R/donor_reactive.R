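# Defining the donor-reactive clonotype set from the pre-transplant MLR pair
# and tracking it through post-transplant bulk repertoires.

#' Call donor-reactive clonotypes from the pre-transplant MLR pair
#'
#' A clonotype is donor-reactive when its reads expand by at least
#' `threshold`-fold (default 5, applied at equality) in the MLR-stimulated
#' versus the unstimulated pre-transplant sample. By default the fold change
#' is computed on depth-normalized reads: both repertoires are downsampled to
#' a common depth and per-clonotype reads are averaged over
#' `config$n_replicates` replicates, so library-depth differences do not
#' masquerade as expansion. `normalize = FALSE` uses raw reads.
#'
#' Clonotypes absent from the unstimulated sample have infinite fold change;
#' they are included iff their (normalized) stimulated reads reach
#' `absent_min_reads`. The default (`NULL`) uses the fold threshold itself,
#' i.e. an undetected clone is treated as a singleton and must expand at
#' least as much as a singleton would need. A lower floor (e.g. 2) admits
#' large numbers of sampling-noise singletons whose absence from the very
#' sample used for tracking then inflates apparent post-transplant gains
#' (regression to the mean). Set `absent_min_reads = Inf` to exclude
#' undetected clones entirely.
#'
#' @param unstim pre-transplant bulk [repertoire]
#' @param stim pre-transplant MLR-stimulated [repertoire], same
#'   patient/phenotype
#' @param threshold fold-change threshold (> 1); default 5
#' @param config a [downsample_config()] for the normalization replicates
#' @param normalize compute folds on downsampling-replicate mean reads
#'   (default) rather than raw reads
#' @param absent_min_reads minimum (normalized) stimulated reads for a
#'   clonotype undetected in the unstimulated sample to be called reactive
#' @return a `donor_reactive_set`: list with `patient_id`, `phenotype`,
#'   `keys` (character vector), `fold_threshold`, and `details` (per-key
#'   table of unstim/stim reads and fold)
#' @export
call_donor_reactive <- function(unstim, stim, threshold = 5,
                                config = downsample_config(),
                                normalize = TRUE, absent_min_reads = NULL) {
  absent_min_reads <- absent_min_reads %||% threshold
  if (threshold <= 1)
    at_stop("fold threshold must exceed 1", "allotrace_config_error")
  if (unstim$timepoint != "preTx" || stim$timepoint != "preTx")
    at_stop("donor-reactive calling requires preTx repertoires",
            "allotrace_contract_error")
  if (unstim$condition != "bulk" || stim$condition != "stimulated")
    at_stop("expected (bulk, stimulated) pre-transplant pair",
            "allotrace_contract_error")
  check_same_sample(unstim, stim, c("patient_id", "phenotype"))

  if (normalize) {
    depth <- min(unstim$total_reads, stim$total_reads)
    mean_reads <- function(rep, tag) {
      counts <- downsample_counts(rep, depth, config$n_replicates,
                                  derive_seed(config$seed, sample_id(rep), tag))
      rowMeans(counts)
    }
    # as.data.table(list(...)): data.table()'s own `key` argument would
    # otherwise capture a column named "key"
    u <- data.table::as.data.table(list(key = unstim$clonotypes$key,
                                        unstim_reads = mean_reads(unstim, "dr_unstim")))
    s <- data.table::as.data.table(list(key = stim$clonotypes$key,
                                        stim_reads = mean_reads(stim, "dr_stim")))
  } else {
    u <- unstim$clonotypes[, .(key, unstim_reads = reads)]
    s <- stim$clonotypes[, .(key, stim_reads = reads)]
  }
  tab <- merge(s, u, by = "key", all.x = TRUE)  # candidate keys live in stim
  tab[is.na(unstim_reads), unstim_reads := 0]
  tab[, fold := ifelse(unstim_reads > 0, stim_reads / unstim_reads, Inf)]
  tab[, reactive := (unstim_reads > 0 & fold >= threshold) |
        (unstim_reads == 0 & stim_reads >= absent_min_reads)]
  structure(list(patient_id = stim$patient_id, phenotype = stim$phenotype,
                 keys = tab[reactive == TRUE, key],
                 fold_threshold = threshold,
                 details = tab[]),
            class = "donor_reactive_set")
}

#' @export
print.donor_reactive_set <- function(x, ...) {
  cat(sprintf("<donor_reactive_set> %s %s: %d keys (fold >= %g)\n",
              x$patient_id, x$phenotype, length(x$keys), x$fold_threshold))
  invisible(x)
}

#' Track a donor-reactive set through a bulk repertoire
#'
#' Reports the percentage of the bulk repertoire's clonotypes that belong to
#' the set and the cumulative frequency (percent of reads) they carry. Both
#' are in `[0, 100]`; an empty intersection gives `(0, 0)`.
#'
#' @param dr_set a `donor_reactive_set` from [call_donor_reactive()]
#' @param bulk a bulk [repertoire] of the same patient and phenotype
#' @return one-row `data.table` with `patient_id`, `phenotype`, `timepoint`,
#'   `pct_clonotypes`, `cum_freq`
#' @export
track_donor_reactive <- function(dr_set, bulk) {
  if (!identical(dr_set$patient_id, bulk$patient_id) ||
      !identical(dr_set$phenotype, bulk$phenotype))
    at_stop("donor-reactive set and bulk repertoire must share patient and phenotype",
            "allotrace_contract_error")
  hit <- bulk$clonotypes$key %in% dr_set$keys
  data.table::data.table(
    patient_id = bulk$patient_id, phenotype = bulk$phenotype,
    timepoint = bulk$timepoint,
    pct_clonotypes = 100 * sum(hit) / nrow(bulk$clonotypes),
    cum_freq = 100 * sum(bulk$clonotypes$frequency[hit]))
}

#' Tracking metric closure for [downsampled_metric()]
#'
#' Returns a function of one repertoire computing the per-replicate tracking
#' pair `c(pct_clonotypes, cum_freq)` for a fixed donor-reactive set, so the
#' tracked values can be averaged over downsampling replicates.
#'
#' @param dr_set a `donor_reactive_set`
#' @return `function(repertoire) -> named numeric(2)`
#' @export
metric_donor_reactive <- function(dr_set) {
  force(dr_set)
  function(rep) {
    hit <- rep$clonotypes$key %in% dr_set$keys
    c(pct_clonotypes = 100 * sum(hit) / nrow(rep$clonotypes),
      cum_freq = 100 * sum(rep$clonotypes$frequency[hit]))
  }
}

#' Pre- to post-transplant change in donor-reactive metrics
#'
#' From a long tracking table (one row per patient/phenotype/timepoint),
#' computes per patient and phenotype the pre-transplant value, the
#' post-transplant value (the first post timepoint, `M1`, by default — the
#' headline contrast; or the mean over all post timepoints), and their
#' difference, plus per-group mean and SD of each.
#'
#' @param records `data.table` with columns `patient_id`, `group`,
#'   `phenotype`, `timepoint`, and one or more metric columns (e.g.
#'   `pct_clonotypes`, `cum_freq`)
#' @param metrics metric column names to difference
#' @param post_policy `"M1"` (default) or `"mean_post"`
#' @return list with `per_patient` and `group_summary` data.tables
#' @export
delta_table <- function(records, metrics = c("pct_clonotypes", "cum_freq"),
                        post_policy = c("M1", "mean_post")) {
  post_policy <- match.arg(post_policy)
  records <- data.table::as.data.table(records)
  records[, timepoint := as.character(timepoint)]
  out <- list()
  for (pid in unique(records$patient_id)) {
    for (ph in unique(records[patient_id == pid]$phenotype)) {
      sub <- records[patient_id == pid & phenotype == ph]
      if (!"preTx" %in% sub$timepoint) {
        at_warn(sprintf("patient %s %s lacks a preTx record; excluded from delta table",
                        pid, ph))
        next
      }
      post <- if (post_policy == "M1") sub[timepoint == "M1"] else
        sub[timepoint != "preTx"]
      if (nrow(post) == 0L) {
        at_warn(sprintf("patient %s %s lacks post-transplant records; excluded", pid, ph))
        next
      }
      row <- data.table::data.table(patient_id = pid, group = sub$group[1L],
                                    phenotype = ph)
      for (m in metrics) {
        pre_v <- sub[timepoint == "preTx"][[m]][1L]
        post_v <- mean(post[[m]])
        row[, (paste0(m, "_pre")) := pre_v]
        row[, (paste0(m, "_post")) := post_v]
        row[, (paste0(m, "_delta")) := post_v - pre_v]
      }
      out[[length(out) + 1L]] <- row
    }
  }
  per_patient <- data.table::rbindlist(out)
  value_cols <- setdiff(names(per_patient), c("patient_id", "group", "phenotype"))
  group_summary <- per_patient[, c(lapply(.SD, mean), setNames(lapply(.SD, stats::sd),
                                                               paste0(value_cols, "_sd"))),
                               by = .(group, phenotype), .SDcols = value_cols]
  list(per_patient = per_patient, group_summary = group_summary)
}
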