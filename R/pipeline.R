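# End-to-end orchestration: ingest -> ambiguity-correct -> call
# donor-reactive -> downsample-and-measure -> annotate -> test battery.

#' Pipeline run configuration
#'
#' @param manifest path to a manifest TSV/CSV, or a manifest `data.table`
#'   from [read_manifest()] / [generate_cohort()]
#' @param dialect clonotype-table dialect: `"canonical"`, `"mixcr"` or
#'   `"airr"`
#' @param specificity_path optional VDJdb-style TSV for virus-specificity
#'   annotation; `NULL` skips the stage
#' @param n_replicates,seed,target_depth downsampling normalization, see
#'   [downsample_config()]
#' @param fold_threshold donor-reactive fold-change threshold
#' @param normalize_folds compute MLR folds on depth-normalized reads
#' @param absent_min_reads absent-clone rule, see [call_donor_reactive()]
#' @param match_scope specificity matching scope, see
#'   [annotate_specificity()]
#' @param post_policy headline pre-vs-post contrast policy (`"M1"` or
#'   `"mean_post"`)
#' @param top_k top clones entering the turnover JSD
#' @param out_dir optional output directory for figure-ready TSV tables
#' @return a `run_config` list
#' @export
run_config <- function(manifest, dialect = "canonical",
                       specificity_path = NULL, n_replicates = 1000L,
                       seed = 1L, target_depth = "auto", fold_threshold = 5,
                       normalize_folds = TRUE, absent_min_reads = NULL,
                       match_scope = "cdr3_aa", post_policy = "M1",
                       top_k = 1000L, out_dir = NULL) {
  if (fold_threshold <= 1)
    at_stop("fold_threshold must exceed 1", "allotrace_config_error")
  structure(list(manifest = manifest, dialect = dialect,
                 specificity_path = specificity_path,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), target_depth = target_depth,
                 fold_threshold = fold_threshold,
                 normalize_folds = normalize_folds,
                 absent_min_reads = absent_min_reads,
                 match_scope = match_scope, post_policy = post_policy,
                 top_k = as.integer(top_k), out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' Relative paths in the file are resolved against the file's directory.
#'
#' @param path JSON file with any subset of [run_config()]'s fields
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) if (!is.null(p) && !grepl("^(/|[A-Za-z]:)", p))
    file.path(base_dir, p) else p
  raw$manifest <- resolve(raw$manifest)
  raw$specificity_path <- resolve(raw$specificity_path)
  raw$out_dir <- resolve(raw$out_dir)
  do.call(run_config, raw)
}

dialect_by_name <- function(name) {
  switch(name,
         canonical = dialect_canonical(), mixcr = dialect_mixcr(),
         airr = dialect_airr(),
         at_stop(sprintf("unknown dialect '%s'", name), "allotrace_config_error"))
}

#' Run the full repertoire analysis
#'
#' Stages: (1) ingest every repertoire in the manifest; (2) resolve CD4/CD8
#' ambiguity per patient/timepoint/condition; (3) call each patient's
#' donor-reactive set from the pre-transplant MLR pair; (4) normalize depth
#' by repeated downsampling within each phenotype(+condition) group and
#' compute replicate-mean metrics: clonotype counts, clonality, R20,
#' donor-reactive tracking, virus-specific mass; (5) clone- and VJ-usage
#' turnover versus the pre-transplant baseline; (6) VJ pair-usage matrices;
#' (7) the headline statistics battery. All randomness flows from
#' `config$seed`; identical config and seed give identical output.
#'
#' @param config a [run_config()]
#' @param repertoires optional pre-loaded named list of repertoires (as from
#'   [generate_cohort()]); skips file ingestion
#' @return list of result tables: `metrics`, `dr_tracking`, `turnover`,
#'   `specificity`, `dr_specificity`, `vj_matrices`, `stats`,
#'   `ambiguity_reports`, `dr_sets`, `depths`, `provenance`
#' @export
run_pipeline <- function(config, repertoires = NULL) {
  t0 <- Sys.time()
  manifest <- config$manifest
  if (is.character(manifest)) manifest <- read_manifest(manifest, check_files = TRUE)
  manifest <- data.table::as.data.table(manifest)
  if (is.null(repertoires))
    repertoires <- load_cohort(manifest, dialect_by_name(config$dialect))
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  say("ingest: %d samples, %d patients", length(repertoires),
      data.table::uniqueN(manifest$patient_id))

  # --- ambiguity correction on every CD4/CD8 pair ------------------------
  ambiguity_reports <- list()
  cells <- unique(manifest[, .(patient_id, timepoint = as.character(timepoint), condition)])
  for (i in seq_len(nrow(cells))) {
    cc <- cells[i]
    id4 <- paste(cc$patient_id, cc$timepoint, "CD4", cc$condition, sep = "/")
    id8 <- paste(cc$patient_id, cc$timepoint, "CD8", cc$condition, sep = "/")
    if (is.null(repertoires[[id4]]) || is.null(repertoires[[id8]])) next
    corr <- correct_ambiguity(repertoires[[id4]], repertoires[[id8]])
    repertoires[[id4]] <- corr$cd4
    repertoires[[id8]] <- corr$cd8
    ambiguity_reports[[paste(cc$patient_id, cc$timepoint, cc$condition, sep = "/")]] <-
      corr$report
  }
  say("ambiguity: corrected %d CD4/CD8 pairs", length(ambiguity_reports))

  ds_conf <- downsample_config(config$n_replicates, config$target_depth,
                               config$seed)

  # --- donor-reactive calling from the preTx pair ------------------------
  dr_sets <- list()
  pats <- unique(manifest[, .(patient_id, group)])
  for (i in seq_len(nrow(pats))) {
    pid <- pats$patient_id[i]
    for (ph in PHENOTYPES) {
      unstim <- repertoires[[paste(pid, "preTx", ph, "bulk", sep = "/")]]
      stim <- repertoires[[paste(pid, "preTx", ph, "stimulated", sep = "/")]]
      if (is.null(unstim) || is.null(stim)) next
      dr_sets[[paste(pid, ph, sep = "/")]] <- call_donor_reactive(
        unstim, stim, config$fold_threshold, ds_conf,
        normalize = config$normalize_folds,
        absent_min_reads = config$absent_min_reads)
    }
  }
  say("reactive: %d donor-reactive sets called (threshold %g)",
      length(dr_sets), config$fold_threshold)

  # --- depth groups: lowest read count within phenotype(+condition) ------
  depths <- list()
  for (ph in PHENOTYPES) {
    for (cond in CONDITIONS) {
      ids <- manifest[phenotype == ph & condition == cond,
                      paste(patient_id, timepoint, phenotype, condition, sep = "/")]
      ids <- ids[ids %in% names(repertoires)]
      if (!length(ids)) next
      depths[[paste(ph, cond, sep = "/")]] <-
        if (identical(config$target_depth, "auto"))
          min(vapply(repertoires[ids], function(r) r$total_reads, numeric(1)))
        else as.integer(config$target_depth)
    }
  }

  # --- specificity database ---------------------------------------------
  db <- NULL
  species <- character()
  if (!is.null(config$specificity_path)) {
    db <- read_specificity_table(config$specificity_path)
    species <- sort(unique(db$antigen_species))
    say("annotate: %d specificity records, species: %s", nrow(db),
        paste(species, collapse = ", "))
  } else say("annotate: no specificity table given, stage skipped")

  # --- per-sample downsampled metrics ------------------------------------
  metric_rows <- list(); dr_rows <- list(); spc_rows <- list()
  bulk <- manifest[condition == "bulk"]
  for (i in seq_len(nrow(bulk))) {
    row <- bulk[i]
    id <- paste(row$patient_id, row$timepoint, row$phenotype, "bulk", sep = "/")
    rep_obj <- repertoires[[id]]
    if (is.null(rep_obj)) next
    dr_set <- dr_sets[[paste(row$patient_id, row$phenotype, sep = "/")]]
    db_keys <- NULL
    if (!is.null(db)) {
      labels <- annotate_specificity(rep_obj, db, config$match_scope)
      db_keys <- lapply(setNames(species, species), function(sp)
        labels[antigen_species == sp, key])
    }
    metric <- function(r) {
      out <- c(n_clonotypes = as.numeric(n_clonotypes(r)),
               clonality = clonality(r)$clonality, r20 = r20(r))
      if (!is.null(dr_set)) out <- c(out, metric_donor_reactive(dr_set)(r))
      if (!is.null(db_keys)) {
        v <- metric_specificity(db_keys)(r)
        names(v) <- paste0("spc_", names(v))
        out <- c(out, v)
      }
      out
    }
    dm <- downsampled_metric(rep_obj, metric, ds_conf,
                             depth = depths[[paste(row$phenotype, "bulk", sep = "/")]])
    base_cols <- data.table::data.table(
      patient_id = row$patient_id, group = row$group,
      phenotype = row$phenotype, timepoint = as.character(row$timepoint))
    for (m in c("n_clonotypes", "clonality", "r20")) {
      metric_rows[[length(metric_rows) + 1L]] <- cbind(base_cols,
        data.table::data.table(metric = m, mean = dm$mean[[m]], sd = dm$sd[[m]]))
    }
    if (!is.null(dr_set)) {
      dr_rows[[length(dr_rows) + 1L]] <- cbind(base_cols,
        data.table::data.table(pct_clonotypes = dm$mean[["pct_clonotypes"]],
                               pct_clonotypes_sd = dm$sd[["pct_clonotypes"]],
                               cum_freq = dm$mean[["cum_freq"]],
                               cum_freq_sd = dm$sd[["cum_freq"]]))
    }
    for (sp in species) {
      spc_rows[[length(spc_rows) + 1L]] <- cbind(base_cols,
        data.table::data.table(antigen_species = sp,
                               cum_freq = dm$mean[[paste0("spc_", sp)]],
                               cum_freq_sd = dm$sd[[paste0("spc_", sp)]]))
    }
  }
  metrics <- data.table::rbindlist(metric_rows)
  dr_tracking <- data.table::rbindlist(dr_rows)
  specificity <- if (length(spc_rows)) data.table::rbindlist(spc_rows) else
    data.table::data.table()
  say("metrics: %d bulk samples measured at %d replicates", nrow(bulk),
      ds_conf$n_replicates)

  # --- turnover versus pre-transplant baseline ---------------------------
  turn_rows <- list()
  for (i in seq_len(nrow(pats))) {
    pid <- pats$patient_id[i]
    for (ph in PHENOTYPES) {
      baseline <- repertoires[[paste(pid, "preTx", ph, "bulk", sep = "/")]]
      if (is.null(baseline)) next
      for (tp in setdiff(TIMEPOINT_LEVELS, "preTx")) {
        later <- repertoires[[paste(pid, tp, ph, "bulk", sep = "/")]]
        if (is.null(later)) next
        pm <- downsampled_pair_metric(
          baseline, later,
          function(a, b) c(jsd_top_clones = clone_turnover(a, b, config$top_k),
                           jsd_vj_usage = usage_turnover(a, b, "VJ")),
          ds_conf, depth = depths[[paste(ph, "bulk", sep = "/")]])
        turn_rows[[length(turn_rows) + 1L]] <- data.table::data.table(
          patient_id = pid, group = pats$group[i], phenotype = ph,
          timepoint = tp, jsd_top_clones = pm$mean[["jsd_top_clones"]],
          jsd_vj_usage = pm$mean[["jsd_vj_usage"]])
      }
    }
  }
  turnover <- data.table::rbindlist(turn_rows)
  # long form of clone turnover feeds the ANOVA battery alongside the metrics
  if (nrow(turnover)) {
    metrics <- rbind(metrics, turnover[, .(patient_id, group, phenotype, timepoint,
                                           metric = "jsd_top_clones",
                                           mean = jsd_top_clones, sd = NA_real_)])
  }

  # --- VJ matrices (full-depth, circos input) ----------------------------
  vj_matrices <- lapply(repertoires[manifest[condition == "bulk",
    paste(patient_id, timepoint, phenotype, condition, sep = "/")]], vj_matrix)

  # --- CMV/EBV mass inside the donor-reactive set vs the bulk ------------
  dr_spc_rows <- list()
  if (!is.null(db) && length(dr_sets)) {
    for (nm in names(dr_sets)) {
      dr_set <- dr_sets[[nm]]
      bulk_rep <- repertoires[[paste(dr_set$patient_id, "preTx", dr_set$phenotype,
                                     "bulk", sep = "/")]]
      if (is.null(bulk_rep)) next
      labels <- annotate_specificity(bulk_rep, db, config$match_scope)
      ct <- bulk_rep$clonotypes
      in_dr <- ct$key %in% dr_set$keys
      dr_mass <- sum(ct$frequency[in_dr])
      grp <- manifest[patient_id == dr_set$patient_id, group][1L]
      for (sp in species) {
        sp_keys <- labels[antigen_species == sp, key]
        is_sp <- ct$key %in% sp_keys
        dr_spc_rows[[length(dr_spc_rows) + 1L]] <- data.table::data.table(
          patient_id = dr_set$patient_id, group = grp,
          phenotype = dr_set$phenotype, antigen_species = sp,
          bulk_cum_freq = 100 * sum(ct$frequency[is_sp]),
          dr_cum_freq = if (dr_mass > 0)
            100 * sum(ct$frequency[in_dr & is_sp]) / dr_mass else 0)
      }
    }
  }
  dr_specificity <- if (length(dr_spc_rows)) data.table::rbindlist(dr_spc_rows) else
    data.table::data.table()

  results <- list(manifest = manifest, metrics = metrics,
                  dr_tracking = dr_tracking, turnover = turnover,
                  specificity = specificity, dr_specificity = dr_specificity,
                  vj_matrices = vj_matrices,
                  ambiguity_reports = ambiguity_reports, dr_sets = dr_sets,
                  depths = depths)
  results$stats <- headline_contrasts(results, post_policy = config$post_policy)
  say("stats: %d tests in the battery", nrow(results$stats))

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  results$provenance <- list(
    config_hash = derive_seed(0L, paste(deparse(cfg_for_hash), collapse = "")),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("allotrace")),
    n_samples = length(repertoires),
    depths = depths,
    log = log_lines,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(config$out_dir)) write_results(results, config$out_dir)
  results
}

#' Write pipeline result tables as figure-ready TSVs
#'
#' One long-format TSV per metric family, one VJ matrix per sample, the
#' statistics battery, the donor-reactive key lists, and a JSON provenance
#' record.
#'
#' @param results output of [run_pipeline()]
#' @param out_dir output directory
#' @return `out_dir`, invisibly
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(dt, name) if (!is.null(dt) && nrow(dt))
    data.table::fwrite(dt, file.path(out_dir, name), sep = "\t", quote = FALSE)
  wr(results$metrics[metric == "n_clonotypes"], "clonotype_counts.tsv")
  wr(results$metrics[metric == "clonality"], "clonality.tsv")
  wr(results$metrics[metric == "r20"], "r20.tsv")
  wr(results$turnover, "turnover_jsd.tsv")
  wr(results$dr_tracking, "donor_reactive_tracking.tsv")
  wr(results$specificity, "virus_specificity.tsv")
  wr(results$dr_specificity, "donor_reactive_specificity.tsv")
  wr(results$stats, "statistics_battery.tsv")
  vj_dir <- file.path(out_dir, "vj_matrices")
  dir.create(vj_dir, showWarnings = FALSE)
  for (nm in names(results$vj_matrices))
    write_vj_matrix(results$vj_matrices[[nm]],
                    file.path(vj_dir, paste0(gsub("/", "_", nm), ".tsv")))
  dr_rows <- data.table::rbindlist(lapply(results$dr_sets, function(s)
    data.table::as.data.table(list(patient_id = s$patient_id,
                                   phenotype = s$phenotype, key = s$keys))))
  wr(dr_rows, "donor_reactive_keys.tsv")
  jsonlite::write_json(results$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
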