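chainRow <- function(bc, locus, cdr3 = "CASSF", v = paste0(locus, "V1"),
                     productive = TRUE, hc = TRUE) {
  data.frame(barcode = bc, locus = locus, v_call = v,
             j_call = paste0(locus, "J1"), cdr3_aa = cdr3,
             productive = productive, high_confidence = hc,
             stringsAsFactors = FALSE)
}

test_that("cell pairing keeps exactly one TRA plus one TRB", {
  tab <- rbind(
    chainRow("c1", "TRA"), chainRow("c1", "TRB"),            # clean pair
    chainRow("c2", "TRA"), chainRow("c2", "TRA", "CAVXF"),   # two alphas
    chainRow("c2", "TRB"),                                   # -> 3 chains
    chainRow("c3", "TRB"),                                   # single chain
    chainRow("c4", "TRA"), chainRow("c4", "TRA", "CAAAF"),   # same-locus pair
    chainRow("c5", "TRB"), chainRow("c5", "TRB"),            # duplicate rows
    chainRow("c6", "TRA", productive = FALSE),               # filtered out
    chainRow("c6", "TRB", productive = FALSE))
  res <- selectPairedCells(tab)
  expect_equal(res$pairs$barcode, "c1")
  expect_equal(res$dropped[["too_many_chains"]], 1L)   # c2
  # c5 duplicate rows collapse to one distinct chain -> single_chain
  expect_equal(res$dropped[["single_chain"]], 2L)      # c3, c5
  expect_equal(res$dropped[["same_locus_pair"]], 1L)   # c4
  expect_equal(res$dropped[["no_chains"]], 1L)         # c6
  # conservation over distinct barcodes
  expect_equal(nrow(res$pairs) + sum(res$dropped), 6L)
})

test_that("binder calls use a 3-SD threshold over the pooled control", {
  # negctrl [0,0,2,2]: sample SD = 1.1547, 3*SD = 3.4641
  umi <- cbind(pepA = c(10L, 3L, 0L, 4L), negctrl = c(0L, 0L, 2L, 2L))
  rownames(umi) <- paste0("c", 1:4)
  flags <- callBinders(umi, "negctrl")
  # cell1: 10 > 0 + 3.4641 -> binder; cell2: 3 <= 3.4641 -> not
  # cell4: 4 <= 2 + 3.4641 -> not
  expect_equal(unname(flags[, "pepA"]), c(TRUE, FALSE, FALSE, FALSE))

  # degenerate all-zero control: any positive count is a binder, ties lose
  umi0 <- cbind(pepA = c(1L, 0L), negctrl = c(0L, 0L))
  rownames(umi0) <- c("c1", "c2")
  expect_equal(unname(callBinders(umi0, "negctrl")[, "pepA"]),
               c(TRUE, FALSE))

  expect_error(callBinders(umi[1, , drop = FALSE], "negctrl"),
               "SD undefined")
  expect_error(callBinders(umi, "nope"), "not found")
})

test_that("raising a peptide count never flips binder to nonbinder", {
  gen <- genUmiTable(n_cells = 50, effect = 3, seed = 8)
  f1 <- callBinders(gen$umi, "negctrl")
  bumped <- gen$umi
  bumped[, colnames(bumped) != "negctrl"] <-
    bumped[, colnames(bumped) != "negctrl"] + 5L
  f2 <- callBinders(bumped, "negctrl")
  expect_true(all(f2[f1]))
})

test_that("only positive calls on kept cells become records", {
  flags <- matrix(c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE), 3, 2,
                  dimnames = list(c("c1", "c2", "c3"), c("p1", "p2")))
  pairs <- data.frame(barcode = c("c1", "c2"),
                      alpha_v = "TRAV1*01", alpha_j = "TRAJ1*01",
                      alpha_cdr3 = "CAVRF", beta_v = "TRBV1*01",
                      beta_j = "TRBJ1*01", beta_cdr3 = "CASSF",
                      stringsAsFactors = FALSE)
  set <- positivesOnly(flags, pairs, c(p1 = "HLA-A*02:01",
                                       p2 = "HLA-B*07:02"))
  # c3 flags ignored (dropped barcode); only binder flags emitted
  expect_equal(length(set), 1L)
  expect_equal(records(set)$peptide, "p1")
  expect_equal(records(set)$label, "binder")
  # no flags -> empty set
  expect_equal(length(positivesOnly(flags & FALSE, pairs,
                                    c(p1 = "x", p2 = "y"))), 0L)
})

test_that("UMI simulation with a strong effect is recovered by the caller", {
  lam <- 10; eff <- 6
  gen <- genUmiTable(n_cells = 500, effect = eff, lambda_bg = lam,
                     seed = 21)
  # exact Poisson oracle for the per-cell-baseline recovery rate:
  # E_c~Pois(lam) P( Pois(lam + eff*sqrt(lam)) > c + 3*sqrt(lam) )
  s <- sqrt(lam)
  cvals <- 0:ceiling(lam + 8 * s)
  oracle <- sum(dpois(cvals, lam) *
                  (1 - ppois(floor(cvals + 3 * s), lam + eff * s)))
  flags <- callBinders(gen$umi, "negctrl")
  recovered <- sum(flags & gen$truth) / sum(gen$truth)
  expect_lt(abs(recovered - oracle), 0.03)
  # pooled-mean baseline: oracle P(Pois(lam+6s) > lam + 3s) sits at the
  # >= 95% operating point; observed recovery matches it
  oracle_m <- 1 - ppois(floor(lam + 3 * s), lam + eff * s)
  expect_gte(oracle_m, 0.95)
  flags_m <- callBinders(gen$umi, "negctrl", baseline = "mean")
  expect_lt(abs(sum(flags_m & gen$truth) / sum(gen$truth) - oracle_m),
            0.03)
  # with no effect, false positives stay at the 3-SD tail rate
  gen0 <- genUmiTable(n_cells = 500, effect = 0, lambda_bg = lam,
                      seed = 22)
  fpr <- mean(callBinders(gen0$umi, "negctrl"))
  fpr_oracle <- sum(dpois(cvals, lam) *
                      (1 - ppois(floor(cvals + 3 * s), lam)))
  expect_lt(fpr, fpr_oracle + 0.02)
  # determinism
  gen2 <- genUmiTable(n_cells = 500, effect = eff, lambda_bg = lam,
                      seed = 21)
  expect_identical(gen$umi, gen2$umi)
})
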