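test_that("CDR3 distance follows the trim/align/substitute rule", {
  # identity
  expect_equal(cdr3Distance("CASSLGQYF", "CASSLGQYF"), 0)
  # cores SLGQ vs SLGE differ at one position: blosum62(Q,E) = 2
  # cost = min(4, 4 - 2) = 2, weighted by 3
  expect_equal(cdr3Distance("CASSLGQYF", "CASSLGEYF"), 6)
  # length mismatch: centre gap against a residue costs 4 (times weight 3)
  expect_equal(cdr3Distance("CASSLGQYF", "CASSLGGQYF"),
               cdr3Distance("CASSLGGQYF", "CASSLGQYF"))
  expect_error(cdr3Distance("CASSF", "CASSLGQYF"), "shorter than 6")
})

test_that("CDR3 distance is a symmetric non-negative form on random pairs", {
  set.seed(71)
  mk <- function() paste0("C", paste(sample(standardAminoAcids(),
                                            sample(7:13, 1), TRUE),
                                     collapse = ""), "F")
  for (i in 1:100) {
    a <- mk(); b <- mk()
    dab <- cdr3Distance(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, cdr3Distance(b, a))
    expect_equal(cdr3Distance(a, a), 0)
  }
})

test_that("the all-pairs distance matrix matches the scalar metric", {
  set.seed(72)
  mk <- function() paste0("C", paste(sample(standardAminoAcids(),
                                            sample(7:12, 1), TRUE),
                                     collapse = ""), "F")
  A <- replicate(6, mk()); B <- replicate(5, mk())
  dm <- cdr3DistanceMatrix(A, B)
  for (i in seq_along(A)) for (j in seq_along(B))
    expect_equal(dm[i, j], cdr3Distance(A[i], B[j]))
})

test_that("aligned BLOSUM62 scores match known values and the DP oracle", {
  expect_equal(peptideBlosumScore("AAA", "AAA"), 12)
  expect_equal(peptideBlosumScore("AAAA", "AAA"), 8)   # 3*4 - one gap
  expect_error(peptideBlosumScore("", "AAA"), "empty")
  # self-alignment is optimal and equals the diagonal sum
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  set.seed(73)
  for (i in 1:10) {
    p <- paste(sample(standardAminoAcids(), 9, TRUE), collapse = "")
    q <- paste(sample(standardAminoAcids(), sample(8:12, 1), TRUE),
               collapse = "")
    self <- sum(diag(e$BLOSUM62)[strsplit(p, "")[[1]]])
    expect_equal(peptideBlosumScore(p, p), self)
    expect_lte(peptideBlosumScore(p, q), self)
  }
})

test_that("alignment equals brute-force DP over short and full-length pairs", {
  # exhaustive over a tiny alphabet at short lengths
  ab <- c("A", "C", "G", "W")
  shorts <- c(ab, as.vector(outer(ab, ab, paste0)))
  for (p in shorts[1:8]) for (q in shorts)
    expect_equal(peptideBlosumScore(p, q), nwOracle(p, q))
  # random longer pairs
  set.seed(74)
  for (i in 1:60) {
    p <- paste(sample(standardAminoAcids(), sample(3:12, 1), TRUE),
               collapse = "")
    q <- paste(sample(standardAminoAcids(), sample(3:12, 1), TRUE),
               collapse = "")
    expect_equal(peptideBlosumScore(p, q), nwOracle(p, q))
  }
})

test_that("fold features summarize train/test relationships", {
  set <- tinyLabelledData(seed = 41, n_epitopes = 4, tcrs = 15)
  plan <- makeFolds(set, minRecords = 20)
  expect_gt(length(plan), 1L)
  feat <- tractabilityFeatures(plan, set)
  expect_equal(nrow(feat), length(plan))
  expect_true(all(feat$cdr3b_similarity >= 0))
  expect_true(all(feat$hla_log_count >= 0))
  # held-out peptide never equals a training peptide, so its similarity
  # score stays below the self-score
  for (i in seq_len(nrow(feat))) {
    self <- peptideBlosumScore(feat$peptide[i], feat$peptide[i])
    expect_lt(feat$peptide_distance[i], self)
  }
  # fold allele absent from training gives log(1 + 0) = 0
  df <- records(set)
  one <- df[1, , drop = FALSE]
  one$hla_allele <- "HLA-C*07:02"     # allele unique to the new fold
  one$peptide <- "QQQQWWWWK"          # peptide unique to the new fold
  aug <- bindingRecordSet(rbind(df, one[rep(1, 25), ]))
  plan2 <- makeFolds(aug, minRecords = 20)
  f <- folds(plan2)[[which(heldOutPeptides(plan2) == one$peptide)]]
  expect_equal(foldFeatures(f, aug)$hla_log_count, 0)
})

test_that("stronger motif sharing lowers the CDR3beta distance feature", {
  med_sim <- vapply(c(0, 1), function(strength) {
    sims <- vapply(1:3, function(s) {
      cfg <- synthConfig(n_epitopes = 4, tcrs_per_epitope = 15,
                        motif_strength = strength, n_families = 2,
                        seed = 100 + s)
      db <- genGermlineDb(cfg)
      gen <- genBindingDataset(cfg, db)
      plan <- makeFolds(gen$set, minRecords = 10)
      mean(tractabilityFeatures(plan, gen$set)$cdr3b_similarity)
    }, numeric(1))
    mean(sims)
  }, numeric(1))
  # shared planted motifs make nearest training CDR3betas closer
  expect_lt(med_sim[2], med_sim[1])
})

test_that("Pearson correlations recover exact linear relations", {
  feat <- data.frame(peptide = letters[1:5],
                     cdr3b_similarity = c(5, 4, 3, 2, 1),
                     hla_log_count = c(1, 2, 3, 4, 5),
                     peptide_distance = c(2, 2, 2, 2, 2))
  auc <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  out <- correlateFeatures(feat, auc)
  per <- out$per_feature
  expect_equal(per$r[per$feature == "cdr3b_similarity"], -1)
  expect_equal(per$r[per$feature == "hla_log_count"], 1)
  expect_true(is.na(per$r[per$feature == "peptide_distance"]))
  # hand-computed 4-point Pearson
  x <- c(1, 2, 4, 7); yv <- c(0.3, 0.2, 0.8, 0.9)
  r_hand <- sum((x - mean(x)) * (yv - mean(yv))) /
    sqrt(sum((x - mean(x))^2) * sum((yv - mean(yv))^2))
  feat2 <- data.frame(peptide = letters[1:4], cdr3b_similarity = x,
                      hla_log_count = 1:4, peptide_distance = 4:1)
  out2 <- correlateFeatures(feat2, yv)
  expect_equal(out2$per_feature$r[1], r_hand)
  expect_equal(dim(out2$matrix), c(4L, 4L))
  expect_equal(out2$matrix, t(out2$matrix))
  expect_error(correlateFeatures(feat2[1:2, ], yv[1:2]), "at least 3")
})
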