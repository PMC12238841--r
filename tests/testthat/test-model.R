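test_that("tokenizer emits the prefixed component layout", {
  vocab <- aaVocabulary()
  ids <- tokenizeRecord("CAV", "CAS", "AAA", "WW", vocab, max_len = 20)
  toks <- vocab$tokens[ids]
  expect_equal(toks[1:14],
               c("[cls]", "[tra]", "C", "A", "V", "[trb]", "C", "A", "S",
                 "[peptide]", "A", "A", "A", "[mhc]"))
  expect_equal(attr(ids, "n_real"), 14L + 2L)
  expect_equal(toks[17:20], rep("[pad]", 4))
  # token count identity: 5 specials in play + component lengths
  expect_equal(attr(ids, "n_real"), 5L + 3L + 3L + 3L + 2L)
  expect_error(tokenizeRecord(NA, "CAS", "AAA", "WW", vocab, 20),
               "must be present")
  expect_error(tokenizeRecord("CAV", "CAS", "AaA", "WW", vocab, 20),
               "outside vocabulary")
})

test_that("truncation protects peptide and pseudosequence, keeps chain tails", {
  vocab <- aaVocabulary()
  alpha <- paste(rep("A", 30), collapse = "")
  beta <- paste0(paste(rep("G", 25), collapse = ""), "WYWYW")
  ids <- tokenizeRecord(alpha, beta, "KLMNKLMNK", "WWHH", vocab,
                        max_len = 40)
  toks <- vocab$tokens[ids]
  # peptide and pseudo survive intact ([peptide] + 9 + [mhc] + 4 = 15)
  expect_equal(paste(toks[26:40], collapse = ""),
               "[peptide]KLMNKLMNK[mhc]WWHH")
  # the beta tail (with its distinctive suffix) survives truncation
  expect_true(grepl("WYWYW", paste(toks, collapse = "")))
  expect_equal(sum(toks == "[pad]"), 0L)
})

test_that("vocabulary ids are dense and stable", {
  vocab <- aaVocabulary()
  expect_equal(unname(vocab$id), seq_len(vocab$size))
  expect_equal(vocab$size, 27L)
  expect_equal(vocab$tokens[vocab$aa_first:(vocab$aa_first + 19)],
               standardAminoAcids())
})

test_that("zeroed relative embeddings reduce to standard attention", {
  set.seed(51)
  L <- 4L; d <- 8L; k <- 3L
  H <- matrix(rnorm(L * d), L, d)
  Wq <- matrix(rnorm(d * d, sd = 0.3), d, d)
  Wk <- matrix(rnorm(d * d, sd = 0.3), d, d)
  Wv <- matrix(rnorm(d * d, sd = 0.3), d, d)
  P0 <- matrix(0, 2 * k + 1, d)
  for (heads in c(1L, 2L)) {
    got <- disentangledAttention(H, P0, Wq, Wk, Wv, heads, k)
    want <- standardAttentionOracle(H, Wq, Wk, Wv, heads,
                                    sqrt(3 * d / heads))
    expect_lt(max(abs(got$out - want)), 1e-6)
    # softmax rows always sum to one
    for (h in seq_len(heads))
      expect_equal(rowSums(got$attn[, , h]), rep(1, L))
  }
  expect_error(disentangledAttention(H, P0, Wq, Wk, Wv, 1L, k = 0L),
               "must be positive")
})

test_that("relative offsets make attention shift-covariant in the interior", {
  # with non-zero positional embeddings, shifting the whole sequence by one
  # leaves pairwise offsets unchanged, so interior scores are identical
  set.seed(52)
  d <- 8L; k <- 10L; L <- 6L
  P <- matrix(rnorm((2 * k + 1) * d, sd = 0.3), 2 * k + 1, d)
  Wq <- matrix(rnorm(d * d, sd = 0.3), d, d)
  Wk <- matrix(rnorm(d * d, sd = 0.3), d, d)
  Wv <- matrix(rnorm(d * d, sd = 0.3), d, d)
  H <- matrix(rnorm((L + 1) * d), L + 1, d)
  a1 <- disentangledAttention(H[1:L, ], P, Wq, Wk, Wv, 1L, k)
  a2 <- disentangledAttention(H[2:(L + 1), ], P, Wq, Wk, Wv, 1L, k)
  # scores of the shared content block (rows/cols 2..L in the first call,
  # 1..L-1 in the second) coincide because deltas are equal
  s1 <- a1$attn[2:L, 2:L, 1] / rowSums(a1$attn[2:L, 2:L, 1])
  s2 <- a2$attn[1:(L - 1), 1:(L - 1), 1] /
    rowSums(a2$attn[1:(L - 1), 1:(L - 1), 1])
  expect_lt(max(abs(s1 - s2)), 1e-10)
})

test_that("the full encoder with zeroed positional terms matches a plain
           transformer encoder built independently", {
  ns <- asNamespace("tcrbind")
  cfg <- modelConfig(layers = 1, heads = 2, d = 8, ff = 12, k = 2,
                     max_len = 6, seed = 9)
  enc <- initEncoder(cfg)
  enc$L1_P[] <- 0
  ids <- matrix(c(2L, 4L, 9L, 15L, 20L, 27L), 1, 6)
  got <- ns$.enc_forward(enc, ids, cfg)$Xf
  # independent plain-attention forward pass
  ln <- function(x, g, b) {
    mu <- mean(x); s <- sqrt(mean((x - mu)^2) + 1e-5)
    (x - mu) / s * g + b
  }
  X <- enc$embed[ids[1, ], ]
  Xn <- t(apply(X, 1, ln, g = enc$L1_ln1_g, b = enc$L1_ln1_b))
  att <- standardAttentionOracle(Xn, enc$L1_Wq, enc$L1_Wk, enc$L1_Wv,
                                 2L, sqrt(3 * 4))
  # oracle omits biases; add them through the same projections
  Qb <- matrix(enc$L1_bq, 6, 8, byrow = TRUE)
  expect_true(all(enc$L1_bq == 0))  # zero-initialized biases keep it exact
  att <- att %*% enc$L1_Wo + matrix(enc$L1_bo, 6, 8, byrow = TRUE)
  X2 <- X + att
  Xn2 <- t(apply(X2, 1, ln, g = enc$L1_ln2_g, b = enc$L1_ln2_b))
  Hp <- Xn2 %*% enc$L1_W1 + matrix(enc$L1_b1, 6, 12, byrow = TRUE)
  Hg <- Hp * pnorm(Hp)
  X3 <- X2 + Hg %*% enc$L1_W2 + matrix(enc$L1_b2, 6, 8, byrow = TRUE)
  want <- t(apply(X3, 1, ln, g = enc$lnf_g, b = enc$lnf_b))
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("masking never selects special or prefix tokens", {
  ns <- asNamespace("tcrbind")
  vocab <- aaVocabulary()
  set <- tinyLabelledData(seed = 61, n_epitopes = 3, tcrs = 6)
  ids <- tokenizeSet(set, vocab, max_len = 96)
  rng <- ns$.seeded_rng(7)
  for (i in 1:10) {
    mk <- ns$.mask_tokens(ids, vocab, 0.3, rng)
    expect_true(all(ids[mk$sel] >= vocab$aa_first))
    expect_true(all(mk$targets >= 1 & mk$targets <= 20))
    # unselected positions are untouched
    expect_equal(mk$ids[!mk$sel], ids[!mk$sel])
    # every sequence has at least one target
    expect_true(all(rowSums(mk$sel) >= 1))
  }
})

test_that("masked-LM loss at initialization is the uniform baseline", {
  cfg <- modelConfig(seed = 5, max_len = 96)
  enc <- initEncoder(cfg)
  set <- tinyLabelledData(seed = 62, n_epitopes = 3, tcrs = 8)
  ids <- tokenizeSet(set, max_len = 96)
  loss <- mlmLoss(enc, ids, seed = 2)
  expect_lt(abs(loss - log(20)) / log(20), 0.1)
})

test_that("pretraining reduces the masked-LM loss and is reproducible", {
  set <- tinyLabelledData(seed = 63, n_epitopes = 6, tcrs = 12)
  df <- records(set)[labels(set) == "binder", ]
  ids <- t(vapply(seq_len(nrow(df)), function(i)
    tokenizeChains(df$alpha_aa[i], df$beta_aa[i], max_len = 88),
    integer(88)))
  cfg <- modelConfig(epochs = 8, batch = 16, lr = 3e-3, max_len = 88,
                     seed = 1)
  pt <- pretrainMlm(ids, cfg)
  expect_length(pt$loss, 8L)
  expect_lt(mean(tail(pt$loss, 2)), pt$loss[1])
  # bitwise-identical loss trace under the same seed and config
  pt2 <- pretrainMlm(ids, cfg)
  expect_identical(pt$loss, pt2$loss)
  expect_error(pretrainMlm(ids[1:4, ], cfg), "shorter than one batch")
  expect_error(modelConfig(mask_rate = 0), "nothing to learn")
  expect_error(modelConfig(d = 30, heads = 4), "divisible")
})

test_that("finetuning contracts: classes, determinism, prediction bounds", {
  set <- tinyLabelledData(seed = 64, n_epitopes = 3, tcrs = 8)
  ids <- tokenizeSet(set, max_len = 96)
  y <- as.integer(labels(set) == "binder")
  cfg <- modelConfig(epochs = 2, batch = 8, max_len = 96, seed = 4)
  expect_error(finetune(ids, rep(1, nrow(ids)), cfg), "single-class")
  clf <- finetune(ids, y, cfg)
  expect_false(clf$meta$pretrained)
  clf2 <- finetune(ids, y, cfg)
  expect_identical(clf$loss, clf2$loss)
  s <- predictScores(clf, ids)
  expect_true(all(s >= 0 & s <= 1))
  expect_length(s, nrow(ids))
  # duplicate records score identically; batched equals one-by-one
  dup <- predictScores(clf, ids[c(1, 1), ])
  expect_equal(dup[1], dup[2])
  one_by_one <- vapply(1:8, function(i)
    predictScores(clf, ids[i, , drop = FALSE]), numeric(1))
  expect_lt(max(abs(one_by_one - predictScores(clf, ids[1:8, ]))), 1e-6)
})

test_that("models round-trip through the text serialization", {
  set <- tinyLabelledData(seed = 65, n_epitopes = 3, tcrs = 6)
  ids <- tokenizeSet(set, max_len = 96)
  y <- as.integer(labels(set) == "binder")
  cfg <- modelConfig(epochs = 1, batch = 8, max_len = 96, seed = 4)
  clf <- finetune(ids, y, cfg)
  dir <- withr::local_tempdir()
  saveModel(clf, dir)
  back <- loadModel(dir)
  expect_equal(predictScores(back, ids), predictScores(clf, ids))
  expect_equal(back$meta$pretrained, FALSE)
})

test_that("encoder gradients agree with finite differences", {
  ns <- asNamespace("tcrbind")
  cfg <- modelConfig(layers = 2, heads = 2, d = 8, ff = 12, k = 2,
                     max_len = 10, seed = 3)
  enc <- initEncoder(cfg)
  vocab <- aaVocabulary()
  set.seed(31)
  ids <- matrix(sample(8:27, 20, TRUE), 2, 10)
  ids[1, 9:10] <- 1L
  ids[, 1] <- 2L
  rng <- ns$.seeded_rng(5)
  mk <- ns$.mask_tokens(ids, vocab, 0.3, rng)
  lossfun <- function(p) {
    fw <- ns$.enc_forward(p, mk$ids, cfg, need_cache = TRUE)
    lg <- ns$.mlm_loss_grad(p, fw$Xf, fw$cache, mk$sel, mk$targets)
    cl <- ns$.cls_loss_grad(p, fw$Xf, 2, 10, c(1, 0))
    list(loss = lg$loss + cl$loss, lg = lg, cl = cl, fw = fw)
  }
  r <- lossfun(enc)
  gr <- ns$.enc_backward(enc, r$fw$cache, r$lg$dXf + r$cl$dXf, cfg)
  eps <- 1e-5
  for (nm in c("embed", "L1_Wq", "L1_P", "L2_Wk", "L2_W1", "lnf_g")) {
    idx <- sample(length(enc[[nm]]), 3)
    for (ii in idx) {
      p2 <- enc; p2[[nm]][ii] <- p2[[nm]][ii] + eps
      p3 <- enc; p3[[nm]][ii] <- p3[[nm]][ii] - eps
      num <- (lossfun(p2)$loss - lossfun(p3)$loss) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][ii]) /
                  max(1e-6, abs(num) + abs(gr[[nm]][ii])), 1e-3)
    }
  }
})
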