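# Train/test relationship features correlated with per-peptide AUC:
# CDR3beta similarity (TCRdist-style CDR3 metric), HLA allele
# representation, and aligned BLOSUM62 peptide similarity.

.pkg_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.pkg_cache$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$B62 <- e$BLOSUM62
  }
  .pkg_cache$B62
}

# 21x21 per-position substitution cost over the 20 amino acids plus gap
# (index 21): 0 for identity, else min(4, 4 - blosum62), 4 for gap-residue
.cdr3_cost_lookup <- function() {
  if (is.null(.pkg_cache$cdr3cost)) {
    aa <- standardAminoAcids()
    B <- .blosum62()[aa, aa]
    cost <- 4 - B
    cost[cost > 4] <- 4
    diag(cost) <- 0
    cost <- rbind(cbind(cost, rep(4, 20)), c(rep(4, 20), 0))
    rownames(cost) <- colnames(cost) <- c(aa, "-")
    .pkg_cache$cdr3cost <- cost
  }
  .pkg_cache$cdr3cost
}

.cdr3_core <- function(x) {
  n <- nchar(x)
  if (any(n < 6L))
    stop("CDR3 shorter than 6 residues leaves an empty trimmed core")
  substr(x, 4L, n - 2L)
}

# centre-gap alignment map: which character of the length-m core sits at
# each of the n positions of the padded alignment (0 = gap)
.centre_gap_map <- function(m, n) {
  if (m == n) return(seq_len(n))
  left <- ceiling(m / 2)
  out <- integer(n)
  out[seq_len(left)] <- seq_len(left)
  right <- m - left
  if (right > 0L)
    out[(n - right + 1L):n] <- (left + 1L):m
  out
}

.encode_core <- function(core, n, amap) {
  # integer codes at padded positions; 21 = gap
  aa <- standardAminoAcids()
  chars <- strsplit(core, "")[[1]]
  codes <- match(chars, aa)
  if (anyNA(codes)) stop("non-standard residue in CDR3 core: ", core)
  out <- rep(21L, n)
  out[amap != 0L] <- codes[amap[amap != 0L]]
  out
}

#' TCRdist-style distance between two CDR3 sequences
#'
#' Both junction-inclusive CDR3s are trimmed (3 residues from the start, 2
#' from the end); the shorter trimmed core is gap-padded at its centre to
#' the length of the longer; per-position cost is 0 for identical residues,
#' otherwise \code{min(4, 4 - blosum62)}, and 4 for a gap against a residue;
#' the summed cost is weighted by 3 (the CDR3 loop weight). This follows the
#' published CDR3 component of the TCRdist metric; it is not a bit-exact
#' port of the tcrdist3 software.
#'
#' @param a,b CDR3 amino-acid strings (at least 6 residues).
#' @return Non-negative distance; 0 iff the trimmed cores are identical.
#' @export
cdr3Distance <- function(a, b) {
  ca <- .cdr3_core(a); cb <- .cdr3_core(b)
  la <- nchar(ca); lb <- nchar(cb)
  n <- max(la, lb)
  ea <- .encode_core(ca, n, .centre_gap_map(la, n))
  eb <- .encode_core(cb, n, .centre_gap_map(lb, n))
  cost <- .cdr3_cost_lookup()
  3 * sum(cost[cbind(ea, eb)])
}

#' All-pairs CDR3 distance matrix
#'
#' Vectorized [cdr3Distance()] over two sequence sets, grouped by core
#' length so each length pair is computed with one table lookup per aligned
#' position.
#'
#' @param A,B Character vectors of CDR3 sequences.
#' @return A \code{length(A) x length(B)} matrix of distances.
#' @export
cdr3DistanceMatrix <- function(A, B) {
  cost <- .cdr3_cost_lookup()
  coresA <- .cdr3_core(A); coresB <- .cdr3_core(B)
  lensA <- nchar(coresA); lensB <- nchar(coresB)
  out <- matrix(NA_real_, length(A), length(B))
  for (la in unique(lensA)) {
    ia <- which(lensA == la)
    for (lb in unique(lensB)) {
      ib <- which(lensB == lb)
      n <- max(la, lb)
      mapA <- .centre_gap_map(la, n)
      mapB <- .centre_gap_map(lb, n)
      EA <- t(vapply(coresA[ia], .encode_core, integer(n), n = n,
                     amap = mapA))
      EB <- t(vapply(coresB[ib], .encode_core, integer(n), n = n,
                     amap = mapB))
      S <- matrix(0, length(ia), length(ib))
      for (pos in seq_len(n))
        S <- S + cost[EA[, pos], EB[, pos], drop = FALSE]
      out[ia, ib] <- 3 * S
    }
  }
  out
}

#' Aligned BLOSUM62 similarity score between two peptides
#'
#' Global (Needleman-Wunsch) alignment score under BLOSUM62 with a linear
#' gap penalty of -4 per gap position. Higher means more similar; a peptide
#' against itself scores the sum of its diagonal BLOSUM62 entries.
#'
#' @param p1,p2 Non-empty peptide amino-acid strings.
#' @return The optimal global alignment score.
#' @export
#' @examples
#' peptideBlosumScore("AAA", "AAA")   # 12
peptideBlosumScore <- function(p1, p2) {
  if (!nzchar(p1) || !nzchar(p2)) stop("empty peptide")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 0, gapExtension = 4)
  Biostrings::score(aln)
}

#' Train/test relationship features for one holdout fold
#'
#' Three features of how a held-out peptide's records relate to the
#' training set: \code{cdr3b_similarity} -- the median over test records of
#' the minimum CDR3beta distance to any training record (lower = training
#' contains similar beta chains); \code{hla_log_count} -- \code{log(1 + n)}
#' training records sharing the fold's modal test HLA allele; and
#' \code{peptide_distance} -- the maximum aligned BLOSUM62 score between
#' the held-out peptide and any training peptide (higher = a similar
#' peptide was trained on).
#'
#' @param fold One element of [folds()].
#' @param set The [BindingRecordSet-class] the fold indexes.
#' @return A one-row \code{data.frame} with the three features (NA where a
#'   feature is not computable, e.g. no beta chains in the test fold).
#' @export
foldFeatures <- function(fold, set) {
  df <- records(set)
  test <- df[fold$test_idx, , drop = FALSE]
  train <- df[fold$train_idx, , drop = FALSE]

  ok_cdr3 <- function(x) !is.na(x) & nchar(x) >= 6L
  tb <- test$beta_cdr3[ok_cdr3(test$beta_cdr3)]
  rb <- unique(train$beta_cdr3[ok_cdr3(train$beta_cdr3)])
  cdr3b <- if (length(tb) == 0L || length(rb) == 0L) NA_real_
  else {
    dm <- cdr3DistanceMatrix(unique(tb), rb)
    mins <- apply(dm, 1L, min)
    # median over test records, weighting each distinct test CDR3beta by
    # its record multiplicity
    stats::median(mins[match(tb, unique(tb))])
  }

  allele_tab <- sort(table(test$hla_allele), decreasing = TRUE)
  modal <- names(allele_tab)[1L]
  hla_log <- log(1 + sum(train$hla_allele == modal, na.rm = TRUE))

  train_peps <- unique(train$peptide)
  pep_dist <- if (length(train_peps) == 0L) NA_real_
  else max(vapply(train_peps, peptideBlosumScore, numeric(1),
                  p1 = fold$peptide))

  data.frame(peptide = fold$peptide, cdr3b_similarity = cdr3b,
             hla_log_count = hla_log, peptide_distance = pep_dist,
             stringsAsFactors = FALSE)
}

#' Features for every fold of a plan
#'
#' @param plan A [SplitPlan-class].
#' @param set The record set the plan indexes.
#' @return A \code{data.frame}, one row per fold.
#' @export
tractabilityFeatures <- function(plan, set) {
  do.call(rbind, lapply(folds(plan), foldFeatures, set = set))
}

#' Pearson correlation of tractability features with per-peptide AUC
#'
#' @param features From [tractabilityFeatures()].
#' @param auc Per-peptide AUC vector aligned with \code{features} rows.
#' @return A list with \code{per_feature} (data.frame: feature, r, p;
#'   zero-variance features reported as NA) and \code{matrix} (symmetric
#'   Pearson matrix over AUC plus the features, pairwise-complete).
#' @export
correlateFeatures <- function(features, auc) {
  feat_cols <- c("cdr3b_similarity", "hla_log_count", "peptide_distance")
  if (length(auc) < 3L) stop("need at least 3 peptides to correlate")
  per <- do.call(rbind, lapply(feat_cols, function(fc) {
    x <- features[[fc]]
    ok <- !is.na(x) & !is.na(auc)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(auc[ok]) == 0)
      return(data.frame(feature = fc, r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x[ok], auc[ok], method = "pearson")
    data.frame(feature = fc, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  m <- cbind(auc = auc, as.matrix(features[, feat_cols]))
  list(per_feature = per,
       matrix = suppressWarnings(
         stats::cor(m, use = "pairwise.complete.obs")))
}
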