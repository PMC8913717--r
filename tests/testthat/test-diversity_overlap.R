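test_that("clonality: uniform is 0, monoclonal is 1, hand value matches", {
  for (s in c(2L, 5L, 97L)) {
    expect_equal(clonality(toy_repertoire(rep(10L, s)))$clonality, 0,
                 tolerance = 1e-12)
  }
  mono <- toy_repertoire(1000L)
  expect_equal(clonality(mono)$clonality, 1)
  expect_equal(clonality(mono)$pielou_index, 0)

  r <- freq_repertoire(c(0.5, 0.25, 0.25))
  res <- clonality(r)
  expect_equal(res$shannon_entropy, 1.5, tolerance = 1e-12)
  expect_equal(res$clonality, 1 - 1.5 / log2(3), tolerance = 1e-12)

  # near-degenerate two-clone repertoire approaches clonality 1
  skewed <- freq_repertoire(c(1 - 1e-6, 1e-6), scale = 1e9)
  expect_gt(clonality(skewed)$clonality, 0.999)
  expect_equal(clonality(r)$clonality + clonality(r)$pielou_index, 1)
})

test_that("clonality is relabeling-invariant and increases under mass transfer", {
  set.seed(5)
  reads <- sample(1:1000, 50)
  r1 <- toy_repertoire(reads)
  r2 <- toy_repertoire(rev(reads))
  expect_equal(clonality(r1)$clonality, clonality(r2)$clonality)
  # move mass from a rarer to a more abundant clonotype
  f <- sort(reads, decreasing = TRUE)
  f2 <- f; f2[1] <- f2[1] + 30; f2[50] <- f2[50] - 30
  if (f2[50] >= 1)
    expect_gt(clonality(toy_repertoire(f2))$clonality,
              clonality(toy_repertoire(f))$clonality)
})

test_that("r20: uniform identity, immunodominance, cumulative boundary", {
  expect_equal(r20(toy_repertoire(rep(7L, 10))), 0.2)
  # dominant clone alone exceeds the mass target
  r <- freq_repertoire(c(0.25, rep(0.75 / 99, 99)), scale = 1e7)
  expect_equal(r20(r), 0.01)
  # {0.15, 0.10, uniform tail}: k = 2 because 0.15 + 0.10 >= 0.2
  f <- c(0.15, 0.10, rep(0.75 / 18, 18))
  expect_equal(r20(freq_repertoire(f, scale = 1e7)), 2 / 20)
  expect_error(r20(toy_repertoire(5L), mass = 1.2), class = "allotrace_config_error")
})

test_that("jsd: identity, maximum, closed form, oracle equivalence", {
  expect_equal(jsd(c(.2, .3, .5), c(.2, .3, .5)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)
  expect_equal(jsd(c(.5, .5, 0), c(0, .5, .5)), 0.5, tolerance = 1e-12)
  expect_error(jsd(c(.5, .4), c(.5, .5)), class = "allotrace_normalization_error")
  expect_error(jsd(c(1), c(.5, .5)), class = "allotrace_contract_error")

  # independent oracle: JSD = H(m) - (H(p) + H(q))/2
  entropy2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  set.seed(12)
  for (i in 1:25) {
    n <- sample(2:40, 1)
    p <- stats::runif(n); p <- p / sum(p)
    q <- stats::runif(n); q[sample(n, n %/% 3)] <- 0; q <- q / sum(q)
    oracle <- entropy2((p + q) / 2) - (entropy2(p) + entropy2(q)) / 2
    expect_equal(jsd(p, q), oracle, tolerance = 1e-12)
    expect_equal(jsd(p, q), jsd(q, p), tolerance = 1e-14)
    expect_gte(jsd(p, q), 0); expect_lte(jsd(p, q), 1)
  }
})

test_that("clone_turnover: identity, replacement, worked union example", {
  r <- toy_repertoire(c(50L, 30L, 20L))
  expect_equal(clone_turnover(r, r), 0)

  a <- toy_repertoire(c(5L, 5L), cdr3_nt = c("TGTAAA", "TGTCCC"))
  b <- toy_repertoire(c(5L, 5L), cdr3_nt = c("TGTGGG", "TGTTTT"))
  expect_equal(clone_turnover(a, b), 1)

  # baseline {A .5, B .3, C .2}, later {A .2, B .3, D .5}, top_k = 2:
  # union {A, B, D}; p = (.5,.3,0)/.8; q = (.2,.3,.5)/1
  base <- freq_repertoire(c(.5, .3, .2), cdr3_nt = c("TGTAAA", "TGTCCC", "TGTGGG"))
  later <- freq_repertoire(c(.2, .3, .5), cdr3_nt = c("TGTAAA", "TGTCCC", "TGTTTT"))
  expected <- jsd(c(.5, .3, 0) / .8, c(.2, .3, .5))
  expect_equal(clone_turnover(base, later, top_k = 2L), expected, tolerance = 1e-12)
  # fewer clonotypes than top_k: all are used
  expect_equal(clone_turnover(base, later, top_k = 100L),
               jsd(c(.5, .3, .2, 0), c(.2, .3, 0, .5)), tolerance = 1e-12)
  # intersection support restricts to shared top clones:
  # top-3 sets are {A,B,C} and {A,B,D}, so the shared support is {A,B}
  expect_equal(clone_turnover(base, later, top_k = 3L, support = "intersection"),
               jsd(c(.5, .3) / .8, c(.2, .3) / .5), tolerance = 1e-12)
  expect_equal(clone_turnover(a, b, support = "intersection"), 1)
})

test_that("usage distributions aggregate mass correctly", {
  r <- toy_repertoire(c(70L, 30L), v_gene = c("TRBV9", "TRBV5-1"))
  u_f <- usage_distribution(r, "V", "frequency")
  expect_equal(u_f[gene == "TRBV9", weight], 0.7)
  u_c <- usage_distribution(r, "V", "clonotype")
  expect_equal(u_c$weight, c(0.5, 0.5))

  point <- toy_repertoire(c(10L, 20L), v_gene = "TRBV5-1", j_gene = "TRBJ2-7")
  uv <- usage_distribution(point, "VJ")
  expect_equal(nrow(uv), 1L)
  expect_equal(uv$weight, 1)

  # 50-clone fixture against a group-by oracle
  set.seed(31)
  r50 <- toy_repertoire(sample(1:100, 50, replace = TRUE),
                        v_gene = sample(c("TRBV9", "TRBV5-1", "TRBV28"), 50, TRUE),
                        j_gene = sample(c("TRBJ1-1", "TRBJ2-7"), 50, TRUE))
  u <- usage_distribution(r50, "V")
  oracle <- tapply(r50$clonotypes$frequency, r50$clonotypes$v_gene, sum)
  expect_equal(u$weight, as.vector(oracle[u$gene]), tolerance = 1e-12)
})

test_that("vj_matrix marginals equal the V and J usage distributions", {
  set.seed(32)
  r <- toy_repertoire(sample(1:100, 50, replace = TRUE),
                      v_gene = sample(c("TRBV9", "TRBV5-1", "TRBV28"), 50, TRUE),
                      j_gene = sample(c("TRBJ1-1", "TRBJ2-7", "TRBJ2-3"), 50, TRUE))
  m <- vj_matrix(r)
  expect_equal(sum(m), 1, tolerance = 1e-12)
  uv <- usage_distribution(r, "V"); uj <- usage_distribution(r, "J")
  expect_equal(rowSums(m)[uv$gene], setNames(uv$weight, uv$gene), tolerance = 1e-12)
  expect_equal(colSums(m)[uj$gene], setNames(uj$weight, uj$gene), tolerance = 1e-12)

  single <- toy_repertoire(5L, v_gene = "TRBV9", j_gene = "TRBJ1-4")
  expect_equal(as.vector(vj_matrix(single)), 1)
})

test_that("usage_turnover: identity, disjoint, monotone in drift", {
  r1 <- toy_repertoire(c(10L, 20L), v_gene = c("TRBV9", "TRBV5-1"))
  expect_equal(usage_turnover(r1, r1, "V"), 0)
  r2 <- toy_repertoire(c(10L, 20L), v_gene = c("TRBV28", "TRBV30"))
  expect_equal(usage_turnover(r1, r2, "V"), 1)

  # increasing usage drift increases the divergence
  jsds <- vapply(c(0.05, 0.15, 0.3), function(shift) {
    base <- freq_repertoire(c(0.5, 0.5), v_gene = c("TRBV9", "TRBV5-1"))
    drifted <- freq_repertoire(c(0.5 - shift, 0.5 + shift),
                               v_gene = c("TRBV9", "TRBV5-1"))
    usage_turnover(base, drifted, "V")
  }, numeric(1))
  expect_true(all(diff(jsds) > 0))
  expect_true(all(jsds > 0 & jsds < 1))
})
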