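# Shared fixtures and independent oracles used across the suite.

# toy germline db: V = "MKTAC" (anchor Cys at 5), J = "FGQGT" (anchor Phe
# at 1), for both loci, with CDR spans on the V
toyGermlineDb <- function() {
  seg <- function(name, locus, type, aa, anchor, c1s = NA, c1e = NA,
                  c2s = NA, c2e = NA)
    data.frame(name = name, locus = locus, segment_type = type, aa = aa,
               anchor = anchor, cdr1_start = c1s, cdr1_end = c1e,
               cdr2_start = c2s, cdr2_end = c2e, stringsAsFactors = FALSE)
  new("GermlineDb", segments = rbind(
    seg("TRAV1*01", "TRA", "V", "MKTAC", 5L, 1L, 2L, 3L, 4L),
    seg("TRAJ1*01", "TRA", "J", "FGQGT", 1L),
    seg("TRBV1*01", "TRB", "V", "MKTAC", 5L, 1L, 2L, 3L, 4L),
    seg("TRBJ1*01", "TRB", "J", "FGQGT", 1L)))
}

# minimal valid wide-format raw record
rawRecord <- function(peptide = "NLVPMVATV", mhc = "HLA-A*02:01",
                      beta_cdr3 = "CASSLGQYF", label = "binder") {
  data.frame(alpha_v = "TRAV1", alpha_j = "TRAJ1", alpha_cdr3 = "CAVRDF",
             beta_v = "TRBV1", beta_j = "TRBJ1", beta_cdr3 = beta_cdr3,
             peptide = peptide, hla_allele = mhc, label = label,
             source = "test", stringsAsFactors = FALSE)
}

smallRecordSet <- function(peptide_counts, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_along(peptide_counts), function(i) {
    n <- peptide_counts[[i]]
    pep <- names(peptide_counts)[i]
    do.call(rbind, lapply(seq_len(n), function(j)
      data.frame(alpha_v = NA, alpha_j = NA, alpha_cdr3 = NA,
                 beta_v = "TRBV1*01", beta_j = "TRBJ1*01",
                 beta_cdr3 = paste0("CASS", paste(
                   sample(standardAminoAcids(), 6, TRUE), collapse = ""),
                   "F"),
                 peptide = pep, hla_allele = "HLA-A*02:01",
                 label = "binder", source = "test",
                 stringsAsFactors = FALSE)))
  })
  bindingRecordSet(do.call(rbind, rows))
}

# brute-force all-pairs AUC oracle (independent of the rank formula)
bruteForceAuc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force Needleman-Wunsch with linear gap -4 under BLOSUM62
nwOracle <- function(p1, p2, gap = -4) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  a <- strsplit(p1, "")[[1]]; b <- strsplit(p2, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)
  M[, 1] <- gap * (0:n); M[1, ] <- gap * (0:m)
  for (i in 1:n) for (j in 1:m)
    M[i + 1, j + 1] <- max(M[i, j] + B[a[i], b[j]],
                           M[i, j + 1] + gap, M[i + 1, j] + gap)
  M[n + 1, m + 1]
}

# plain scaled dot-product multi-head attention (oracle for the zeroed-
# relative-embedding case; note the sqrt(3 d_head) scale is shared)
standardAttentionOracle <- function(H, Wq, Wk, Wv, heads, scale) {
  L <- nrow(H); d <- ncol(H); dh <- d %/% heads
  Q <- H %*% Wq; K <- H %*% Wk; V <- H %*% Wv
  out <- matrix(0, L, d)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- (Q[, cols] %*% t(K[, cols])) / scale
    E <- exp(S - apply(S, 1, max))
    A <- E / rowSums(E)
    out[, cols] <- A %*% V[, cols]
  }
  out
}

# a small stitched labelled dataset for model-level tests
tinyLabelledData <- function(seed = 11, n_epitopes = 4, tcrs = 12) {
  cfg <- synthConfig(n_epitopes = n_epitopes, tcrs_per_epitope = tcrs,
                     seed = seed)
  db <- genGermlineDb(cfg)
  gen <- genBindingDataset(cfg, db)
  st <- stitchRecords(gen$set, db, readHlaFasta())
  neg <- simulateNegatives(st$set, seed = seed + 1)
  mergeAndDedup(list(st$set, neg), coalesce = FALSE)$set
}
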