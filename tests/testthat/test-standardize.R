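test_that("TSV reading maps columns and preserves the rest", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus\tjunction_aa\tv_call\tj_call\tantigen\textra",
               "TRB\tCASSF\tTRBV1\tTRBJ1\tNLVPMVATV\tx1",
               "TRB\tCASRF\tTRBV2\tTRBJ1\tGILGFVFTL\tx2",
               "TRA\tCAVRF\tTRAV1\tTRAJ1\tNLVPMVATV\tx3"), tf)
  df <- readBindingTsv(tf, c(junction_aa = "cdr3_aa", antigen = "peptide"))
  expect_equal(nrow(df), 3L)
  expect_true(all(c("cdr3_aa", "peptide", "extra") %in% names(df)))
  expect_equal(df$extra, c("x1", "x2", "x3"))

  # header-only file gives an empty table
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("locus\tjunction_aa", tf2)
  expect_equal(nrow(readBindingTsv(tf2)), 0L)

  # mapping a missing column is a hard error naming it
  expect_error(readBindingTsv(tf, c(epitope = "peptide")),
               "missing column.*epitope")
})

test_that("inclusion/exclusion rules fire in order with the right reasons", {
  raw <- rbind(
    rawRecord(),                                   # clean
    rawRecord(peptide = "NLVPMVA"),                # 7-mer: too short
    rawRecord(mhc = "H-2Kb"),                      # mouse MHC
    rawRecord(beta_cdr3 = "CASSXEQYF"),            # ambiguous residue
    rawRecord(mhc = "HLA-DRB1*04:01"),             # class II code
    rawRecord(mhc = "HLA-DQA1*01:01"))             # class II code
  res <- applyFilters(raw)
  expect_equal(res$reasons,
               c("accepted", "peptide_length", "non_human_mhc",
                 "ambiguous_residue", "class_ii_mhc", "class_ii_mhc"))
  expect_equal(retained(res$report), 1L)
  # conservation: counters + retained = input
  expect_equal(inputCount(res$report), nrow(raw))

  # missing chain fields and bad locus
  raw2 <- rawRecord()
  raw2$beta_cdr3 <- NA; raw2$alpha_cdr3 <- NA
  expect_equal(applyFilters(raw2)$reasons, "missing_chain_fields")
  raw3 <- rawRecord(); raw3$beta_v <- "TRAV1"   # beta chain with alpha V
  expect_equal(applyFilters(raw3)$reasons, "invalid_locus")
})

test_that("filters are idempotent and outputs satisfy the contracts", {
  set.seed(4)
  peps <- vapply(1:40, function(i)
    paste(sample(c(standardAminoAcids(), "X"),
                 sample(6:14, 1), TRUE), collapse = ""), character(1))
  raw <- do.call(rbind, lapply(peps, function(p) rawRecord(peptide = p)))
  res <- applyFilters(raw)
  df <- records(res$set)
  expect_true(all(nchar(df$peptide) >= 8 & nchar(df$peptide) <= 12))
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", df$peptide)))
  # bare V genes were completed to *01
  expect_true(all(grepl("\\*01$", df$beta_v)))
  # records that pass, pass again unchanged
  res2 <- applyFilters(df)
  expect_equal(records(res2$set), df)
  expect_equal(retained(res2$report), nrow(df))
})

test_that("group-level HLA labels impute to the most frequent allele", {
  expect_equal(imputeHlaAllele("HLA-A*02"), "HLA-A*02:01")
  expect_equal(imputeHlaAllele("HLA-B*07:02"), "HLA-B*07:02")
  # higher-than-2-field labels trim to two fields
  expect_equal(imputeHlaAllele("HLA-A*02:01:01"), "HLA-A*02:01")
  # lexicographic tie-break
  ft <- data.frame(allele = c("HLA-C*05:09", "HLA-C*05:01"),
                   frequency = c(0.1, 0.1))
  expect_equal(imputeHlaAllele("HLA-C*05", ft), "HLA-C*05:01")
  expect_error(imputeHlaAllele("HLA-C*99", ft), "unresolvable allele group")
  expect_error(imputeHlaAllele("B*07", hlaFrequencyTable()), "not a parsable")
})

test_that("merge keeps one record per dedup key, first occurrence wins", {
  a <- bindingRecordSet(rbind(rawRecord(), rawRecord(peptide = "GILGFVFTL")))
  b <- bindingRecordSet(rbind(rawRecord(),          # exact duplicate of a[1]
                              rawRecord(label = "nonbinder")))
  md <- mergeAndDedup(list(a, b))
  # 4 in, 1 duplicate out; binder/nonbinder contradiction survives
  expect_equal(length(md$set), 3L)
  expect_equal(unname(rejections(md$report)[["duplicate"]]), 1L)
  expect_setequal(labels(md$set), c("binder", "binder", "nonbinder"))
  # idempotence
  md2 <- mergeAndDedup(md$set)
  expect_equal(records(md2$set), records(md$set))
  # empty input
  expect_equal(length(mergeAndDedup(bindingRecordSet(
    rawRecord()[0, ]))$set), 0L)
})

test_that("complementary missing fields coalesce across sources before dedup", {
  full <- rawRecord()
  partial <- rawRecord()
  partial[, c("alpha_v", "alpha_j", "alpha_cdr3")] <- NA
  partial$source <- "other_db"
  md <- mergeAndDedup(list(bindingRecordSet(full),
                           bindingRecordSet(partial)))
  expect_equal(length(md$set), 1L)
  expect_equal(records(md$set)$alpha_cdr3, "CAVRDF")
})

test_that("standardized TSV round-trips", {
  set <- smallRecordSet(c(NLVPMVATV = 3, GILGFVFTL = 2))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeStandardizedTsv(set, tf)
  back <- readStandardizedTsv(tf)
  expect_equal(records(back)$peptide, peptides(set))
  expect_equal(records(back)$beta_cdr3, records(set)$beta_cdr3)
})
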