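# Repertoire diversity (clonality, R20) and between-repertoire similarity
# (Jensen-Shannon divergence on clone and gene-usage distributions).

#' Clonality (one minus Pielou's evenness)
#'
#' Shannon entropy H of the clonotype frequency distribution is divided by
#' its maximum `log(S)` to give Pielou's evenness P; clonality is `1 - P`.
#' 0 marks a perfectly even repertoire, 1 a monoclonal one. The ratio is
#' invariant to the logarithm base; entropy is reported in bits.
#'
#' A monoclonal repertoire (S = 1) has H = H_max = 0; the 0/0 evenness is
#' resolved as P = 0, clonality = 1 — the limit of a two-clone repertoire as
#' one frequency tends to 1, and the biologically sensible reading (a
#' monoclonal repertoire is maximally clonal).
#'
#' @param rep a [repertoire]
#' @return list with `shannon_entropy` (bits), `entropy_base` (2),
#'   `pielou_index`, `clonality`, `n_clonotypes`
#' @export
clonality <- function(rep) {
  f <- rep$clonotypes$frequency
  s <- length(f)
  if (s == 0L) at_stop("clonality undefined on an empty repertoire",
                       "allotrace_empty_error")
  h <- -sum(ifelse(f > 0, f * log2(f), 0))
  if (s == 1L) {
    pielou <- 0
  } else {
    pielou <- h / log2(s)
  }
  list(shannon_entropy = h, entropy_base = 2, pielou_index = pielou,
       clonality = 1 - pielou, n_clonotypes = s)
}

#' R20: fraction of top clonotypes carrying 20% of the repertoire
#'
#' Clonotypes are ordered by decreasing frequency; `k` is the smallest number
#' whose cumulative frequency reaches `mass` (cumulative >= mass, no
#' fractional interpolation), and R20 = k / S. Small values indicate
#' immunodominance. Ties do not affect the result because only the count
#' matters.
#'
#' @param rep a [repertoire]
#' @param mass cumulative frequency target in (0, 1); default 0.2
#' @return fraction in (0, 1]
#' @export
r20 <- function(rep, mass = 0.2) {
  if (mass <= 0 || mass >= 1)
    at_stop("mass must be in (0, 1)", "allotrace_config_error")
  f <- rep$clonotypes$frequency
  s <- length(f)
  if (s == 0L) at_stop("r20 undefined on an empty repertoire", "allotrace_empty_error")
  cs <- cumsum(sort(f, decreasing = TRUE)) / sum(f)
  k <- which(cs >= mass - 1e-12)[1L]
  k / s
}

#' Jensen-Shannon divergence between two probability vectors
#'
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`, logs base
#' 2 so the result lies in `[0, 1]` (0 iff `p == q`, 1 for disjoint
#' supports). `0 * log 0` is taken as 0. The divergence itself is returned,
#' not its square root.
#'
#' @param p,q numeric vectors over the same (unioned, zero-filled) support,
#'   each summing to 1 within `1e-8`; callers must renormalize explicitly
#' @return divergence in `[0, 1]`
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q))
    at_stop("p and q must share one support (equal length)", "allotrace_contract_error")
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    at_stop("p and q must each sum to 1; renormalize before calling jsd",
            "allotrace_normalization_error")
  m <- (p + q) / 2
  term <- function(a) {
    nz <- a > 0
    sum(a[nz] * (log2(a[nz]) - log2(m[nz])))
  }
  (term(p) + term(q)) / 2
}

#' Clone-level turnover between two repertoires of one patient
#'
#' Takes the union of each repertoire's `top_k` clonotypes by frequency,
#' builds both frequency vectors on that union (absent clones get 0),
#' renormalizes each vector over the union, and returns their
#' Jensen-Shannon divergence. Repertoires with fewer than `top_k` clonotypes
#' contribute all their clonotypes.
#'
#' @param baseline,later [repertoire] objects (same patient/phenotype)
#' @param top_k number of top clones per repertoire entering the support
#' @param support `"union"` (default: clones that vanished or appeared count
#'   toward turnover) or `"intersection"` of the two top-k sets
#' @return JSD in `[0, 1]`
#' @export
clone_turnover <- function(baseline, later, top_k = 1000L,
                           support = c("union", "intersection")) {
  support <- match.arg(support)
  top_keys <- function(rep) {
    ct <- rep$clonotypes
    k <- min(top_k, nrow(ct))
    ct[order(-frequency, key)][seq_len(k), key]
  }
  union_keys <- if (support == "union")
    union(top_keys(baseline), top_keys(later))
  else intersect(top_keys(baseline), top_keys(later))
  if (length(union_keys) == 0L)
    return(1)  # disjoint top sets: maximal turnover
  fa <- baseline$clonotypes[match(union_keys, key), frequency]
  fb <- later$clonotypes[match(union_keys, key), frequency]
  fa[is.na(fa)] <- 0; fb[is.na(fb)] <- 0
  jsd(fa / sum(fa), fb / sum(fb))
}

#' Gene-usage distribution of a repertoire
#'
#' Aggregates clone frequency mass (default) or clonotype counts per V gene,
#' J gene, or VJ pair, normalized to 1.
#'
#' @param rep a [repertoire]
#' @param axis `"V"`, `"J"` or `"VJ"`
#' @param weighting `"frequency"` (clone mass) or `"clonotype"` (each
#'   clonotype counts once)
#' @return `data.table` with columns `gene` (or `v_gene`/`j_gene` for VJ) and
#'   `weight`, weights summing to 1
#' @export
usage_distribution <- function(rep, axis = c("V", "J", "VJ"),
                               weighting = c("frequency", "clonotype")) {
  axis <- match.arg(axis)
  weighting <- match.arg(weighting)
  ct <- rep$clonotypes
  w <- if (weighting == "frequency") ct$frequency else rep(1 / nrow(ct), nrow(ct))
  tab <- switch(axis,
    V = data.table::data.table(gene = ct$v_gene, w = w)[, .(weight = sum(w)), by = gene],
    J = data.table::data.table(gene = ct$j_gene, w = w)[, .(weight = sum(w)), by = gene],
    VJ = data.table::data.table(v_gene = ct$v_gene, j_gene = ct$j_gene, w = w)[
      , .(weight = sum(w)), by = .(v_gene, j_gene)])
  tab[, weight := weight / sum(weight)]
  if (axis == "VJ") data.table::setorder(tab, v_gene, j_gene) else data.table::setorder(tab, gene)
  tab[]
}

#' Gene-usage turnover between two repertoires
#'
#' Usage distributions on the chosen axis are zero-filled onto their unioned
#' support and compared with [jsd()].
#'
#' @inheritParams clone_turnover
#' @param axis `"V"`, `"J"` or `"VJ"`
#' @param weighting passed to [usage_distribution()]
#' @return JSD in `[0, 1]`
#' @export
usage_turnover <- function(baseline, later, axis = c("V", "J", "VJ"),
                           weighting = "frequency") {
  axis <- match.arg(axis)
  ua <- usage_distribution(baseline, axis, weighting)
  ub <- usage_distribution(later, axis, weighting)
  if (axis == "VJ") {
    ua[, gene := paste(v_gene, j_gene, sep = "|")]
    ub[, gene := paste(v_gene, j_gene, sep = "|")]
  }
  support <- union(ua$gene, ub$gene)
  pa <- ua[match(support, gene), weight]; pa[is.na(pa)] <- 0
  pb <- ub[match(support, gene), weight]; pb[is.na(pb)] <- 0
  jsd(pa, pb)
}

#' V x J pair-usage matrix (circos input)
#'
#' Frequency-weighted VJ usage as a matrix whose entries sum to 1; row sums
#' equal the V usage distribution and column sums the J usage distribution.
#'
#' @param rep a [repertoire]
#' @return numeric matrix, rows = V genes, columns = J genes
#' @export
vj_matrix <- function(rep) {
  u <- usage_distribution(rep, "VJ", "frequency")
  vs <- sort(unique(u$v_gene)); js <- sort(unique(u$j_gene))
  m <- matrix(0, length(vs), length(js), dimnames = list(vs, js))
  m[cbind(match(u$v_gene, vs), match(u$j_gene, js))] <- u$weight
  m
}

#' Write a VJ matrix as TSV
#' @param m matrix from [vj_matrix()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_vj_matrix <- function(m, path) {
  dt <- data.table::as.data.table(m, keep.rownames = "v_gene")
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
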