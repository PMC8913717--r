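test_that("ingestion collapses duplicate keys and recomputes frequencies", {
  # two rows sharing (cdr3_nt, V, J) collapse by summing reads
  rep1 <- repertoire(data.frame(
    cdr3_nt = c("TGTGCCAAA", "TGTGCCAAA"), cdr3_aa = "CAK",
    v_gene = "TRBV9", d_gene = "", j_gene = "TRBJ2-7", reads = c(3L, 7L)),
    "P1", "preTx", "CD4", "bulk")
  expect_equal(nrow(rep1$clonotypes), 1L)
  expect_equal(rep1$clonotypes$reads, 10)
  expect_equal(rep1$clonotypes$frequency, 1)

  rep2 <- toy_repertoire(c(6L, 4L))
  expect_equal(sort(rep2$clonotypes$frequency), c(0.4, 0.6))
  expect_equal(sum(rep2$clonotypes$frequency), 1, tolerance = 1e-9)
})

test_that("a shuffled-column table parses identically under both dialects", {
  set.seed(11)
  n <- 20
  base <- data.frame(
    cdr3_nt = vapply(1:n, function(i) paste(sample(c("A","C","G","T"), 30,
                                                   replace = TRUE), collapse = ""),
                     character(1)),
    cdr3_aa = sprintf("CASSX%02dF", 1:n),
    v_gene = sample(c("TRBV9", "TRBV5-1", "TRBV20-1"), n, replace = TRUE),
    d_gene = "", j_gene = sample(c("TRBJ1-1", "TRBJ2-7"), n, replace = TRUE),
    reads = sample(1:500, n))
  f_mixcr <- tempfile(fileext = ".tsv"); f_canon <- tempfile(fileext = ".tsv")
  # MiXCR headers, deliberately shuffled column order, allele suffixes added
  mixcr <- data.frame(allJHitsWithScore = paste0(base$j_gene, "*00(120)"),
                      cloneCount = base$reads, aaSeqCDR3 = base$cdr3_aa,
                      allVHitsWithScore = paste0(base$v_gene, "*00(88.1)"),
                      nSeqCDR3 = base$cdr3_nt, allDHitsWithScore = base$d_gene,
                      extraneous = "x")
  write.table(mixcr, f_mixcr, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(base, f_canon, sep = "\t", quote = FALSE, row.names = FALSE)
  r1 <- read_clonotype_table(f_mixcr, "P1", "preTx", "CD4", "bulk", dialect_mixcr())
  r2 <- read_clonotype_table(f_canon, "P1", "preTx", "CD4", "bulk", dialect_canonical())
  expect_equal(r1$clonotypes, r2$clonotypes)
  expect_equal(r1$total_reads, r2$total_reads)
})

test_that("write/read round-trip preserves every field", {
  set.seed(4)
  rep1 <- toy_repertoire(sample(1:10000, 50))
  f <- tempfile(fileext = ".tsv")
  write_clonotype_table(rep1, f)
  rep2 <- read_clonotype_table(f, rep1$patient_id, rep1$timepoint,
                               rep1$phenotype, rep1$condition,
                               dialect_canonical())
  expect_identical(rep2$clonotypes$cdr3_nt, rep1$clonotypes$cdr3_nt)
  expect_identical(rep2$clonotypes$reads, rep1$clonotypes$reads)
  expect_identical(rep2$clonotypes$v_gene, rep1$clonotypes$v_gene)
  expect_equal(rep2$clonotypes$frequency, rep1$clonotypes$frequency,
               tolerance = 1e-12)
})

test_that("ingestion is order-independent and strips allele suffixes", {
  df <- data.frame(cdr3_nt = c("TGTAAA", "TGTCCC", "TGTGGG"),
                   cdr3_aa = c("CK", "CP", "CG"),
                   v_gene = c("TRBV9*01", "TRBV5-1*00(77)", "TRBV9"),
                   d_gene = "", j_gene = "TRBJ2-7*01", reads = c(5L, 2L, 9L))
  r1 <- repertoire(df, "P1", "preTx", "CD4", "bulk")
  r2 <- repertoire(df[c(3, 1, 2), ], "P1", "preTx", "CD4", "bulk")
  expect_equal(r1$clonotypes, r2$clonotypes)
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  r3 <- read_clonotype_table(f, "P1", "preTx", "CD4", "bulk", dialect_canonical())
  expect_setequal(unique(r3$clonotypes$v_gene), c("TRBV9", "TRBV5-1"))
  expect_true(all(r3$clonotypes$j_gene == "TRBJ2-7"))
})

test_that("reader errors name the missing column and reject empty tables", {
  f <- tempfile(fileext = ".tsv")
  write.table(data.frame(nSeqCDR3 = "TGT", aaSeqCDR3 = "C"), f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_clonotype_table(f, "P", "preTx", "CD4", "bulk"),
               "cloneCount", class = "allotrace_format_error")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(paste(dialect_canonical(), collapse = "\t"), f2)
  expect_error(read_clonotype_table(f2, "P", "preTx", "CD4", "bulk",
                                    dialect_canonical()),
               class = "allotrace_empty_error")
})

make_manifest <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("manifest validation enforces structure", {
  full <- expand.grid(patient_id = c("P1", "P2"), timepoint = c("preTx", "M1"),
                      phenotype = c("CD4", "CD8"), condition = "bulk",
                      stringsAsFactors = FALSE)
  stim <- expand.grid(patient_id = c("P1", "P2"), timepoint = "preTx",
                      phenotype = c("CD4", "CD8"), condition = "stimulated",
                      stringsAsFactors = FALSE)
  rows <- rbind(full, stim)
  rows$group <- ifelse(rows$patient_id == "P1", "ATLG", "basiliximab")
  rows$path <- "x.tsv"
  mf <- read_manifest(make_manifest(rows))
  expect_equal(nrow(mf), 12L)
  expect_true(is.ordered(mf$timepoint))
  expect_lt(which(levels(mf$timepoint) == "preTx"),
            which(levels(mf$timepoint) == "M12"))

  # missing preTx stimulated CD4 for P2 names patient and fraction
  broken <- rows[!(rows$patient_id == "P2" & rows$condition == "stimulated" &
                     rows$phenotype == "CD4"), ]
  expect_error(read_manifest(make_manifest(broken)), "P2.*stimulated.*CD4",
               class = "allotrace_validation_error")

  # duplicate cell
  expect_error(read_manifest(make_manifest(rbind(rows, rows[1, ]))),
               class = "allotrace_duplicate_error")
})

test_that("specificity table is filtered to TRB/HomoSapiens and deduplicated", {
  db <- read_specificity_table(system.file("extdata", "vdjdb_synthetic.tsv",
                                           package = "allotrace"))
  # 30 rows: one TRA, one MusMusculus, one duplicate (CDR3, species) pair
  expect_equal(nrow(db), 27L)
  expect_equal(as.vector(table(db$antigen_species)[c("CMV", "EBV")]), c(15L, 12L))
  expect_false(any(duplicated(db[, c("cdr3_aa", "antigen_species")])))

  empty <- tempfile(fileext = ".tsv")
  writeLines("cdr3\tgene\tspecies\tantigen.species", empty)
  expect_equal(nrow(read_specificity_table(empty)), 0L)
  expect_error(read_specificity_table(tempfile()), class = "allotrace_io_error")
})
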