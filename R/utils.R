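# Internal helpers: condition constructors, deterministic seed derivation.

at_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "allotrace_error", "error", "condition")))
}

at_warn <- function(msg) warning(msg, call. = FALSE)

#' Derive a reproducible sub-seed from a master seed and string labels
#'
#' Polynomial string hashing modulo the Mersenne prime 2^31 - 1, so derived
#' seeds stay inside R's 32-bit integer range. Used to give every sample its
#' own RNG substream: adding samples to a run never perturbs the downsampling
#' replicates of existing samples.
#'
#' @param seed master integer seed
#' @param ... character or numeric labels mixed into the hash
#' @return an integer seed in `[0, 2^31 - 2]`
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (part in list(...)) {
    for (b in utf8ToInt(paste0("|", as.character(part)))) {
      h <- (h * 31 + b) %% m
    }
  }
  as.integer(h)
}

# Canonical timepoint ordering used throughout.
TIMEPOINT_LEVELS <- c("preTx", "M1", "M3", "M12")
PHENOTYPES <- c("CD4", "CD8")
CONDITIONS <- c("bulk", "stimulated")

#' Strip allele suffixes and score annotations from a gene name
#'
#' MiXCR-style exports carry names like `"TRBV5-1*00(123.4)"`; comparisons
#' across samples use the gene symbol only. Multiple comma-separated hits are
#' reduced to the first.
#'
#' @param x character vector of gene names
#' @return cleaned character vector
#' @keywords internal
clean_gene <- function(x) {
  x <- sub(",.*$", "", x)
  x <- sub("\\(.*$", "", x)
  x <- sub("\\*.*$", "", x)
  trimws(x)
}

#' Clonotype identity key
#'
#' The identity used for tracking clones within a patient: CDR3 nucleotide
#' sequence plus V and J gene, joined with `|`. The D segment is excluded
#' because it is frequently unassigned.
#'
#' @param cdr3_nt,v_gene,j_gene character vectors
#' @return character vector of identity strings
#' @export
clonotype_key <- function(cdr3_nt, v_gene, j_gene) {
  paste(cdr3_nt, v_gene, j_gene, sep = "|")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
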