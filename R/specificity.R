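# Annotation of clonotypes with known antigen specificity (e.g. CMV, EBV)
# by CDR3 amino-acid matching against a VDJdb-style table.

#' Annotate clonotypes with antigen specificity
#'
#' A clonotype is labeled with an antigen species iff its CDR3 amino-acid
#' sequence exactly equals a database record's CDR3 (case-insensitive). A
#' clonotype can carry several labels (one per matching species). The
#' stricter scope additionally requires V and J gene equality when the
#' database provides `v_gene`/`j_gene` columns.
#'
#' @param rep a [repertoire]
#' @param db specificity records from [read_specificity_table()] (columns
#'   `cdr3_aa`, `antigen_species`, optionally `v_gene`, `j_gene`)
#' @param match_scope `"cdr3_aa"` (default) or `"cdr3_aa_vj"`
#' @return `data.table` with columns `key`, `antigen_species`; zero rows when
#'   nothing matches or the database is empty
#' @export
annotate_specificity <- function(rep, db, match_scope = c("cdr3_aa", "cdr3_aa_vj")) {
  match_scope <- match.arg(match_scope)
  empty <- data.table::as.data.table(list(key = character(),
                                          antigen_species = character()))
  if (is.null(db) || nrow(db) == 0L) return(empty)
  db <- data.table::as.data.table(db)
  db <- unique(db[, .(cdr3_aa = toupper(cdr3_aa), antigen_species,
                      v_gene = if ("v_gene" %in% names(db)) v_gene else NA_character_,
                      j_gene = if ("j_gene" %in% names(db)) j_gene else NA_character_)])
  ct <- rep$clonotypes[, .(key, cdr3_aa = toupper(cdr3_aa), v_gene, j_gene)]
  hits <- merge(ct, db, by = "cdr3_aa", allow.cartesian = TRUE,
                suffixes = c("", ".db"))
  if (match_scope == "cdr3_aa_vj") {
    if (all(is.na(db$v_gene)))
      at_stop("match scope cdr3_aa_vj requires v_gene/j_gene columns in the database",
              "allotrace_config_error")
    hits <- hits[v_gene == v_gene.db & j_gene == j_gene.db]
  }
  if (nrow(hits) == 0L) return(empty)
  unique(hits[, .(key, antigen_species)])[order(key, antigen_species)]
}

#' Summarize virus-specific repertoire mass per antigen species
#'
#' Counts labeled clonotypes and sums their frequencies (as percent of
#' reads) per antigen species. Species present in `species` but unmatched
#' get explicit zero rows, so longitudinal tables stay complete.
#'
#' @param rep the [repertoire] that was annotated
#' @param labels output of [annotate_specificity()] on `rep`
#' @param species antigen species to report; defaults to those in `labels`
#' @return `data.table` with `patient_id`, `phenotype`, `timepoint`,
#'   `antigen_species`, `n_matched_clonotypes`, `cum_freq` (percent)
#' @export
summarize_specificity <- function(rep, labels, species = NULL) {
  species <- species %||% sort(unique(labels$antigen_species))
  if (length(species) == 0L) species <- character()
  out <- data.table::rbindlist(lapply(species, function(sp) {
    keys <- labels[antigen_species == sp, key]
    hit <- rep$clonotypes$key %in% keys
    data.table::data.table(
      patient_id = rep$patient_id, phenotype = rep$phenotype,
      timepoint = rep$timepoint, antigen_species = sp,
      n_matched_clonotypes = sum(hit),
      cum_freq = 100 * sum(rep$clonotypes$frequency[hit]))
  }))
  if (nrow(out) == 0L)
    out <- data.table::data.table(patient_id = character(), phenotype = character(),
                                  timepoint = character(), antigen_species = character(),
                                  n_matched_clonotypes = integer(), cum_freq = numeric())
  out
}

#' Virus-specific-mass metric closure for [downsampled_metric()]
#'
#' `db_keys` is a named list (species -> clonotype-key vector), precomputed
#' on the full-depth repertoire so CDR3 matching is done once; the returned
#' function computes per-replicate cumulative frequency (%) per species.
#'
#' @param db_keys named list of key vectors per antigen species
#' @return `function(repertoire) -> named numeric`
#' @export
metric_specificity <- function(db_keys) {
  force(db_keys)
  function(rep) {
    vapply(db_keys, function(keys) {
      100 * sum(rep$clonotypes$frequency[rep$clonotypes$key %in% keys])
    }, numeric(1L))
  }
}
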