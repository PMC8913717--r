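# CD4/CD8 ambiguity resolution and depth normalization by repeated
# downsampling without replacement.

#' Resolve clonotypes detected in both the CD4 and CD8 fraction of a sample
#'
#' Sorting is imperfect, so the same clonotype key can appear in both sorted
#' fractions of one sample. Each shared key is assigned to the fraction with
#' at least twice the reads of the other (reads unchanged, deleted from the
#' losing fraction); keys where neither fraction dominates by 2x are removed
#' from both. Frequencies are then recomputed over the remaining reads.
#'
#' @param cd4,cd8 [repertoire] objects from the same
#'   patient/timepoint/condition with phenotypes CD4 and CD8
#' @param ratio dominance ratio; a shared clonotype stays in fraction A iff
#'   `reads_A >= ratio * reads_B` (the boundary "equal to twice" assigns)
#' @return list with elements `cd4`, `cd8` (corrected repertoires) and
#'   `report` — counts of shared keys assigned to each fraction, keys removed
#'   from both, and the read fraction each repertoire lost
#' @export
correct_ambiguity <- function(cd4, cd8, ratio = 2) {
  if (cd4$phenotype != "CD4" || cd8$phenotype != "CD8")
    at_stop("arguments must be the CD4 and CD8 repertoire, in that order",
            "allotrace_contract_error")
  check_same_sample(cd4, cd8)
  a <- cd4$clonotypes; b <- cd8$clonotypes
  shared <- merge(a[, .(key, reads_a = reads)], b[, .(key, reads_b = reads)],
                  by = "key")
  keep_a_only <- shared[reads_a >= ratio * reads_b, key]
  keep_b_only <- shared[reads_b >= ratio * reads_a, key]
  drop_both <- setdiff(shared$key, c(keep_a_only, keep_b_only))
  reads_a0 <- cd4$total_reads; reads_b0 <- cd8$total_reads
  a2 <- a[!key %in% c(keep_b_only, drop_both)]
  b2 <- b[!key %in% c(keep_a_only, drop_both)]
  report <- list(
    n_shared = nrow(shared),
    n_assigned_cd4 = length(keep_a_only),
    n_assigned_cd8 = length(keep_b_only),
    n_removed = length(drop_both),
    removed_read_fraction_cd4 = 1 - sum(a2$reads) / reads_a0,
    removed_read_fraction_cd8 = 1 - sum(b2$reads) / reads_b0)
  list(cd4 = rebuild_repertoire(cd4, a2), cd8 = rebuild_repertoire(cd8, b2),
       report = report)
}

#' Configuration for downsampling-based depth normalization
#'
#' @param n_replicates number of independent downsampled replicates averaged
#'   per metric (1000 in the full analysis; smaller values trade precision
#'   for speed)
#' @param target_depth integer read depth, or `"auto"` to use the lowest
#'   total read count within each phenotype(+condition) group at run time
#' @param seed master integer seed; every sample derives its own substream
#'   via [derive_seed()]
#' @return a `downsample_config` list
#' @export
downsample_config <- function(n_replicates = 1000L, target_depth = "auto",
                              seed = 1L) {
  if (n_replicates < 1L) at_stop("n_replicates must be >= 1", "allotrace_config_error")
  if (!identical(target_depth, "auto") &&
      (!is.numeric(target_depth) || target_depth < 1))
    at_stop("target_depth must be a positive integer or 'auto'",
            "allotrace_config_error")
  structure(list(n_replicates = as.integer(n_replicates),
                 target_depth = target_depth, seed = as.integer(seed)),
            class = "downsample_config")
}

#' Draw downsampled read-count replicates for one repertoire
#'
#' Samples `depth` reads uniformly without replacement from the repertoire's
#' read multiset (multivariate hypergeometric), independently `n_rep` times.
#'
#' @param rep a [repertoire]
#' @param depth target read depth, at most `rep$total_reads`
#' @param n_rep number of replicates
#' @param seed optional integer; when given, the RNG state is set (and
#'   restored afterwards) so draws are reproducible and isolated
#' @return integer matrix, one row per clonotype (in `rep$clonotypes` order),
#'   one column per replicate; column sums equal `depth`
#' @export
downsample_counts <- function(rep, depth, n_rep = 1L, seed = NULL) {
  depth <- as.integer(depth)
  if (depth < 1L) at_stop("depth must be >= 1", "allotrace_depth_error")
  if (depth > rep$total_reads)
    at_stop(sprintf("depth %d exceeds total reads %d", depth,
                    as.integer(rep$total_reads)), "allotrace_depth_error")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  .downsample_counts_cpp(rep$clonotypes$reads, depth, as.integer(n_rep))
}

#' Downsample a repertoire once
#'
#' Clonotypes drawn zero times are dropped; frequencies are recomputed over
#' `depth`. With `depth == total_reads` this is the identity up to frequency
#' recomputation.
#'
#' @inheritParams downsample_counts
#' @return a [repertoire] with `total_reads == depth`
#' @export
downsample <- function(rep, depth, seed = NULL) {
  counts <- downsample_counts(rep, depth, 1L, seed)[, 1L]
  ct <- data.table::copy(rep$clonotypes)
  ct[, reads := as.numeric(counts)]
  rebuild_repertoire(rep, ct[reads > 0])
}

# Build the lightweight per-replicate repertoire used by metric closures.
replicate_repertoire <- function(rep, counts) {
  keep <- counts > 0L
  ct <- rep$clonotypes[keep]
  ct <- data.table::copy(ct)
  ct[, reads := as.numeric(counts[keep])]
  tot <- sum(ct$reads)
  ct[, frequency := reads / tot]
  rep$clonotypes <- ct
  rep$total_reads <- tot
  rep
}

#' Mean of a repertoire metric over downsampled replicates
#'
#' Depth normalization: every reported metric is the mean over
#' `config$n_replicates` independent downsamples of the repertoire to
#' `depth`. Deterministic for a given `config$seed` (each sample uses its own
#' derived substream, so results do not depend on which other samples are in
#' the run).
#'
#' @param rep a [repertoire]
#' @param metric function taking a [repertoire] and returning a numeric
#'   scalar or named numeric vector
#' @param config a [downsample_config()]; `target_depth` must be numeric here
#'   (the pipeline resolves `"auto"` before calling)
#' @param depth overrides `config$target_depth`
#' @return list with `mean` and `sd` (named numeric vectors over replicates),
#'   plus `n_replicates` and `depth`
#' @export
downsampled_metric <- function(rep, metric, config = downsample_config(),
                               depth = NULL) {
  depth <- depth %||% config$target_depth
  if (identical(depth, "auto"))
    at_stop("target_depth 'auto' must be resolved to a number before downsampled_metric",
            "allotrace_config_error")
  seed <- derive_seed(config$seed, sample_id(rep))
  counts <- downsample_counts(rep, depth, config$n_replicates, seed)
  vals <- vapply(seq_len(ncol(counts)), function(j) {
    metric(replicate_repertoire(rep, counts[, j]))
  }, FUN.VALUE = metric(replicate_repertoire(rep, counts[, 1L])))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  list(mean = rowMeans(vals), sd = apply(vals, 1L, stats::sd),
       n_replicates = config$n_replicates, depth = as.integer(depth))
}

#' Mean of a two-repertoire metric over paired downsampled replicates
#'
#' Both repertoires are downsampled to a common depth in each replicate and
#' the metric (e.g. [clone_turnover()]) is evaluated on the pair.
#'
#' @param rep_a,rep_b [repertoire] objects
#' @param metric2 function of two repertoires returning a numeric scalar
#' @param config a [downsample_config()]
#' @param depth common depth; defaults to the smaller of the two totals when
#'   the config says `"auto"`
#' @return list with `mean`, `sd`, `n_replicates`, `depth`
#' @export
downsampled_pair_metric <- function(rep_a, rep_b, metric2,
                                    config = downsample_config(), depth = NULL) {
  depth <- depth %||% config$target_depth
  if (identical(depth, "auto"))
    depth <- min(rep_a$total_reads, rep_b$total_reads)
  ca <- downsample_counts(rep_a, depth, config$n_replicates,
                          derive_seed(config$seed, sample_id(rep_a), "pairA"))
  cb <- downsample_counts(rep_b, depth, config$n_replicates,
                          derive_seed(config$seed, sample_id(rep_b), "pairB"))
  proto <- metric2(replicate_repertoire(rep_a, ca[, 1L]),
                   replicate_repertoire(rep_b, cb[, 1L]))
  vals <- vapply(seq_len(config$n_replicates), function(j) {
    metric2(replicate_repertoire(rep_a, ca[, j]),
            replicate_repertoire(rep_b, cb[, j]))
  }, FUN.VALUE = proto)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L,
                                         dimnames = list(names(proto)))
  list(mean = rowMeans(vals), sd = apply(vals, 1L, stats::sd),
       n_replicates = config$n_replicates, depth = as.integer(depth))
}
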