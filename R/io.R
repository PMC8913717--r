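# Reading/writing clonotype tables, cohort manifests and specificity tables.

#' Column-mapping dialects for clonotype tables
#'
#' A dialect maps the canonical clonotype fields to the column headers of a
#' particular export format. `dialect_mixcr()` matches MiXCR `exportClones`
#' headers, `dialect_canonical()` matches the fixed header written by
#' [write_clonotype_table()], and `dialect_airr()` covers AIRR rearrangement
#' TSVs closely enough for ingestion.
#'
#' @return a named character vector mapping canonical field -> file column
#' @export
dialect_mixcr <- function() {
  c(reads = "cloneCount", cdr3_nt = "nSeqCDR3", cdr3_aa = "aaSeqCDR3",
    v_gene = "allVHitsWithScore", d_gene = "allDHitsWithScore",
    j_gene = "allJHitsWithScore")
}

#' @rdname dialect_mixcr
#' @export
dialect_canonical <- function() {
  c(reads = "reads", cdr3_nt = "cdr3_nt", cdr3_aa = "cdr3_aa",
    v_gene = "v_gene", d_gene = "d_gene", j_gene = "j_gene")
}

#' @rdname dialect_mixcr
#' @export
dialect_airr <- function() {
  c(reads = "duplicate_count", cdr3_nt = "junction", cdr3_aa = "junction_aa",
    v_gene = "v_call", d_gene = "d_call", j_gene = "j_call")
}

#' Read one clonotype table into a repertoire
#'
#' Parses a tab-separated clonotype export (MiXCR-style by default; gzip
#' accepted by extension), collapses duplicate clonotype keys by summing
#' reads, strips allele suffixes from gene names, and recomputes frequencies
#' from reads — any frequency column in the file is deliberately ignored so
#' the normalization invariant holds after collapsing.
#'
#' @param path file path (TSV, optionally `.gz`)
#' @param patient_id,timepoint,phenotype,condition sample metadata attached
#'   to the returned repertoire
#' @param dialect named mapping from canonical fields to file columns, see
#'   [dialect_mixcr()]
#' @return a [repertoire]
#' @export
read_clonotype_table <- function(path, patient_id, timepoint, phenotype,
                                 condition, dialect = dialect_mixcr()) {
  if (!file.exists(path))
    at_stop(sprintf("clonotype table not found: %s", path), "allotrace_io_error")
  header <- names(data.table::fread(path, sep = "\t", header = TRUE, nrows = 0L,
                                    showProgress = FALSE))
  required <- c("reads", "cdr3_nt", "cdr3_aa", "v_gene", "j_gene")
  for (f in required) {
    if (!dialect[[f]] %in% header)
      at_stop(sprintf("column '%s' (mapped field '%s') missing from %s",
                      dialect[[f]], f, path), "allotrace_format_error")
  }
  text_cols <- intersect(unname(dialect[c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene")]),
                         header)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = text_cols),
                          encoding = "UTF-8", showProgress = FALSE)
  has_d <- "d_gene" %in% names(dialect) && dialect[["d_gene"]] %in% names(dt)
  ct <- data.table::data.table(
    cdr3_nt = toupper(dt[[dialect[["cdr3_nt"]]]]),
    cdr3_aa = dt[[dialect[["cdr3_aa"]]]],
    v_gene = clean_gene(dt[[dialect[["v_gene"]]]]),
    d_gene = if (has_d) clean_gene(as.character(dt[[dialect[["d_gene"]]]])) else "",
    j_gene = clean_gene(dt[[dialect[["j_gene"]]]]),
    reads = round(as.numeric(dt[[dialect[["reads"]]]])))
  ct <- ct[!is.na(reads) & reads >= 1 & nzchar(cdr3_nt)]
  if (nrow(ct) == 0L)
    at_stop(sprintf("no usable clonotype rows in %s", path), "allotrace_empty_error")
  repertoire(ct, patient_id, timepoint, phenotype, condition)
}

#' Write a repertoire as a canonical clonotype TSV
#'
#' Emits the fixed header `cdr3_nt, cdr3_aa, v_gene, d_gene, j_gene, reads,
#' frequency`; [read_clonotype_table()] with [dialect_canonical()] round-trips
#' it (integer fields bit-exactly, frequencies to better than 12 significant
#' digits).
#'
#' @param rep a [repertoire]
#' @param path output path (`.gz` compresses)
#' @return `path`, invisibly
#' @export
write_clonotype_table <- function(rep, path) {
  out <- rep$clonotypes[, .(cdr3_nt, cdr3_aa, v_gene, d_gene, j_gene,
                            reads = as.integer(reads),
                            frequency = formatC(frequency, digits = 15, format = "g"))]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read and validate a cohort manifest
#'
#' The manifest lists one clonotype file per
#' (patient, timepoint, phenotype, condition) cell. Validation enforces the
#' structure the downstream pipeline needs: no duplicate cells, known
#' timepoint/phenotype/condition labels, one treatment group per patient, and
#' — because donor-reactive calling requires the pre-transplant MLR pair —
#' a `preTx` `bulk` and a `preTx` `stimulated` sample for every
#' patient/phenotype.
#'
#' @param path TSV or CSV with columns `patient_id`, `group`, `timepoint`,
#'   `phenotype`, `condition`, `path`
#' @param check_files also require every referenced clonotype file to exist
#'   (relative paths resolved against the manifest's directory)
#' @return a `data.table` with timepoint as ordered factor
#'   (`preTx < M1 < M3 < M12`) and an added `resolved_path` column
#' @export
read_manifest <- function(path, check_files = FALSE) {
  if (!file.exists(path))
    at_stop(sprintf("manifest not found: %s", path), "allotrace_io_error")
  mf <- data.table::fread(path, header = TRUE, showProgress = FALSE,
                          colClasses = "character")
  required <- c("patient_id", "group", "timepoint", "phenotype", "condition", "path")
  miss <- setdiff(required, names(mf))
  if (length(miss))
    at_stop(paste("manifest missing columns:", paste(miss, collapse = ", ")),
            "allotrace_format_error")
  bad_tp <- setdiff(unique(mf$timepoint), TIMEPOINT_LEVELS)
  if (length(bad_tp))
    at_stop(paste("unknown timepoints:", paste(bad_tp, collapse = ", ")),
            "allotrace_validation_error")
  if (length(setdiff(unique(mf$phenotype), PHENOTYPES)))
    at_stop("phenotype must be CD4 or CD8", "allotrace_validation_error")
  if (length(setdiff(unique(mf$condition), CONDITIONS)))
    at_stop("condition must be bulk or stimulated", "allotrace_validation_error")
  dup <- mf[, .N, by = .(patient_id, timepoint, phenotype, condition)][N > 1L]
  if (nrow(dup))
    at_stop(sprintf("duplicate manifest entry for patient %s %s %s %s",
                    dup$patient_id[1L], dup$timepoint[1L], dup$phenotype[1L],
                    dup$condition[1L]), "allotrace_duplicate_error")
  multi_grp <- mf[, data.table::uniqueN(group), by = patient_id][V1 > 1L]
  if (nrow(multi_grp))
    at_stop(sprintf("patient %s appears in more than one treatment group",
                    multi_grp$patient_id[1L]), "allotrace_validation_error")
  # every patient needs the preTx bulk + stimulated pair in each phenotype it appears in
  for (pid in unique(mf$patient_id)) {
    for (ph in unique(mf[patient_id == pid]$phenotype)) {
      sub <- mf[patient_id == pid & phenotype == ph & timepoint == "preTx"]
      for (cond in CONDITIONS) {
        if (!cond %in% sub$condition)
          at_stop(sprintf("patient %s lacks a preTx %s %s sample; donor-reactive calling impossible",
                          pid, cond, ph), "allotrace_validation_error")
      }
    }
  }
  mf[, timepoint := factor(timepoint, levels = TIMEPOINT_LEVELS, ordered = TRUE)]
  base_dir <- dirname(normalizePath(path))
  mf[, resolved_path := ifelse(grepl("^(/|[A-Za-z]:)", path), path,
                               file.path(base_dir, path))]
  if (check_files) {
    gone <- mf[!file.exists(resolved_path)]
    if (nrow(gone))
      at_stop(sprintf("manifest references missing file: %s", gone$path[1L]),
              "allotrace_io_error")
  }
  mf[]
}

#' Read a VDJdb-style specificity table
#'
#' Keeps TRB / HomoSapiens records only and deduplicates on
#' (CDR3 amino-acid sequence, antigen species). Columns follow the VDJdb TSV
#' dialect: `cdr3`, `gene`, `species`, `antigen.species`.
#'
#' @param path TSV path
#' @return `data.table` with columns `cdr3_aa`, `antigen_species`
#' @export
read_specificity_table <- function(path) {
  if (!file.exists(path))
    at_stop(sprintf("specificity table not found: %s", path), "allotrace_io_error")
  dt <- data.table::fread(path, sep = "\t", header = TRUE, showProgress = FALSE)
  required <- c("cdr3", "gene", "species", "antigen.species")
  miss <- setdiff(required, names(dt))
  if (length(miss))
    at_stop(paste("specificity table missing columns:", paste(miss, collapse = ", ")),
            "allotrace_format_error")
  keep <- dt[gene == "TRB" & species == "HomoSapiens" &
               nzchar(cdr3) & nzchar(`antigen.species`)]
  out <- unique(data.table::data.table(cdr3_aa = toupper(keep$cdr3),
                                       antigen_species = keep$`antigen.species`))
  data.table::setorder(out, antigen_species, cdr3_aa)
  out[]
}

#' Load every repertoire referenced by a manifest
#'
#' @param manifest output of [read_manifest()]
#' @param dialect column mapping for the clonotype files
#' @return named list of [repertoire] objects; names are
#'   `patient/timepoint/phenotype/condition`
#' @export
load_cohort <- function(manifest, dialect = dialect_canonical()) {
  reps <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i]
    reps[[i]] <- read_clonotype_table(row$resolved_path, row$patient_id,
                                      as.character(row$timepoint),
                                      row$phenotype, row$condition, dialect)
  }
  names(reps) <- manifest[, paste(patient_id, timepoint, phenotype, condition, sep = "/")]
  reps
}

sample_id <- function(rep) {
  paste(rep$patient_id, rep$timepoint, rep$phenotype, rep$condition, sep = "/")
}
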