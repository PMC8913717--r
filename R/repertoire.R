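# The canonical in-memory container: one sorted sample's clonotype multiset.

#' Construct a repertoire object
#'
#' A repertoire is the clonotype multiset of one sorted sample
#' (patient x timepoint x phenotype x condition). Clonotypes sharing the same
#' identity key (CDR3 nucleotide sequence, V gene, J gene) are collapsed by
#' summing reads, and frequencies are always recomputed as
#' `reads / total_reads` so they sum to one regardless of any frequency the
#' caller supplies.
#'
#' @param clonotypes a data.frame with columns `cdr3_nt`, `cdr3_aa`,
#'   `v_gene`, `d_gene`, `j_gene`, `reads` (positive integers); a
#'   `frequency` column, if present, is ignored and recomputed
#' @param patient_id,timepoint,phenotype,condition sample metadata;
#'   `timepoint` must be one of `preTx`, `M1`, `M3`, `M12`; `phenotype` one
#'   of `CD4`/`CD8`; `condition` one of `bulk`/`stimulated`
#' @return an object of class `repertoire`: a list with elements
#'   `clonotypes` (a [data.table::data.table] keyed by the identity string in
#'   column `key`), `total_reads`, and the four metadata fields
#' @examples
#' rep <- repertoire(data.frame(
#'   cdr3_nt = c("TGTGCCAGC", "TGTGCCTTC"), cdr3_aa = c("CAS", "CAF"),
#'   v_gene = "TRBV5-1", d_gene = "", j_gene = "TRBJ2-7", reads = c(6L, 4L)),
#'   patient_id = "P1", timepoint = "preTx", phenotype = "CD4",
#'   condition = "bulk")
#' rep$clonotypes$frequency # 0.6 0.4
#' @export
repertoire <- function(clonotypes, patient_id, timepoint, phenotype, condition) {
  if (!timepoint %in% TIMEPOINT_LEVELS)
    at_stop(sprintf("unknown timepoint '%s'", timepoint), "allotrace_contract_error")
  if (!phenotype %in% PHENOTYPES)
    at_stop(sprintf("unknown phenotype '%s'", phenotype), "allotrace_contract_error")
  if (!condition %in% CONDITIONS)
    at_stop(sprintf("unknown condition '%s'", condition), "allotrace_contract_error")
  ct <- data.table::as.data.table(clonotypes)
  needed <- c("cdr3_nt", "cdr3_aa", "v_gene", "d_gene", "j_gene", "reads")
  miss <- setdiff(needed, names(ct))
  if (length(miss))
    at_stop(paste("missing clonotype columns:", paste(miss, collapse = ", ")),
            "allotrace_format_error")
  if (nrow(ct) == 0L)
    at_stop("repertoire has zero usable clonotypes", "allotrace_empty_error")
  if (any(ct$reads < 1))
    at_stop("clonotype reads must be >= 1", "allotrace_contract_error")
  ct[, reads := as.numeric(reads)]
  ct[, key := clonotype_key(cdr3_nt, v_gene, j_gene)]
  # collapse duplicates on the identity key, summing reads
  ct <- ct[, .(cdr3_nt = cdr3_nt[1L], cdr3_aa = cdr3_aa[1L],
               v_gene = v_gene[1L], d_gene = d_gene[1L], j_gene = j_gene[1L],
               reads = sum(reads)), by = key]
  data.table::setorder(ct, key)  # order-independent ingestion
  total <- sum(ct$reads)
  ct[, frequency := reads / total]
  structure(list(clonotypes = ct[], total_reads = total,
                 patient_id = patient_id, timepoint = timepoint,
                 phenotype = phenotype, condition = condition),
            class = "repertoire")
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("<repertoire> %s %s %s %s: %d clonotypes, %s reads\n",
              x$patient_id, x$timepoint, x$phenotype, x$condition,
              nrow(x$clonotypes), format(x$total_reads, big.mark = ",")))
  invisible(x)
}

#' Number of unique clonotypes in a repertoire
#' @param rep a [repertoire] object
#' @return integer count
#' @export
n_clonotypes <- function(rep) nrow(rep$clonotypes)

# Rebuild a repertoire after its clonotype table was filtered/re-counted.
# Keeps metadata, recomputes total_reads and frequencies.
rebuild_repertoire <- function(rep, clonotypes) {
  if (nrow(clonotypes) == 0L)
    at_stop("operation left the repertoire empty", "allotrace_empty_error")
  total <- sum(clonotypes$reads)
  clonotypes[, frequency := reads / total]
  rep$clonotypes <- clonotypes[]
  rep$total_reads <- total
  rep
}

check_same_sample <- function(a, b, fields = c("patient_id", "timepoint", "condition")) {
  for (f in fields) {
    if (!identical(a[[f]], b[[f]]))
      at_stop(sprintf("repertoires disagree on %s ('%s' vs '%s')",
                      f, a[[f]], b[[f]]), "allotrace_contract_error")
  }
  invisible(TRUE)
}
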