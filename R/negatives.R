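#' Downsample the dominant epitope to the runner-up count
#'
#' When one peptide dominates the positive set (as a single CMV epitope does
#' in public binding data), its records are subsampled uniformly without
#' replacement down to the count of the second most frequent peptide; all
#' other records are untouched. A no-op when the top two counts are already
#' equal.
#'
#' @param set A [BindingRecordSet-class] of positive records.
#' @param seed Integer seed for the subsample.
#' @return A [BindingRecordSet-class].
#' @export
downsampleTopEpitope <- function(set, seed = 1L) {
  df <- records(set)
  counts <- sort(table(df$peptide), decreasing = TRUE)
  if (length(counts) < 2L)
    stop("need at least 2 distinct peptides to downsample")
  top <- names(counts)[1L]
  target <- as.integer(counts[2L])
  if (counts[1L] <= target) return(set)
  idx_top <- which(df$peptide == top)
  rng <- .seeded_rng(seed)
  keep_top <- sort(.sample_int(rng, length(idx_top), target))
  keep <- sort(c(setdiff(seq_len(nrow(df)), idx_top), idx_top[keep_top]))
  set[keep]
}

.tcr_key <- function(df) {
  paste(ifelse(is.na(df$alpha_v), "", df$alpha_v),
        ifelse(is.na(df$alpha_j), "", df$alpha_j),
        ifelse(is.na(df$alpha_cdr3), "", df$alpha_cdr3),
        ifelse(is.na(df$beta_v), "", df$beta_v),
        ifelse(is.na(df$beta_j), "", df$beta_j),
        ifelse(is.na(df$beta_cdr3), "", df$beta_cdr3), sep = "\r")
}

.phla_key <- function(df) paste(df$peptide, df$hla_allele, sep = "\r")

#' Simulate non-binders by screened random mispairing
#'
#' Draws TCRs and peptide-HLA-I complexes independently and uniformly from
#' the positive set's marginals and pairs them; any pair observed among the
#' positives is screened out (no true positive can appear as a simulated
#' negative), and pairs are unique within the output. Rejection sampling
#' errors out rather than silently under-delivering.
#'
#' @param set A [BindingRecordSet-class] of positive records.
#' @param ratio Negatives per positive (default 1, i.e. the 50/50 design).
#' @param seed Integer seed.
#' @param max_attempts Cap on sampling attempts (default
#'   \code{100 * n_requested}).
#' @param weighting \code{"unique"} (default): marginals over unique TCRs /
#'   unique pHLA; \code{"record"}: record-weighted marginals.
#' @return A [BindingRecordSet-class] of \code{floor(ratio * length(set))}
#'   nonbinder-labelled records.
#' @export
simulateNegatives <- function(set, ratio = 1, seed = 1L,
                              max_attempts = NULL,
                              weighting = c("unique", "record")) {
  weighting <- match.arg(weighting)
  stopifnot(ratio > 0)
  df <- records(set)
  n_req <- as.integer(floor(ratio * nrow(df)))
  if (is.null(max_attempts)) max_attempts <- 100L * max(n_req, 1L)
  if (max_attempts < n_req)
    stop("max_attempts (", max_attempts, ") below requested negatives (",
         n_req, ")")

  tcr_keys <- .tcr_key(df)
  phla_keys <- .phla_key(df)
  tcr_idx <- if (weighting == "unique") which(!duplicated(tcr_keys))
             else seq_len(nrow(df))
  phla_idx <- if (weighting == "unique") which(!duplicated(phla_keys))
              else seq_len(nrow(df))
  if (length(unique(tcr_keys)) < 2L || length(unique(phla_keys)) < 2L)
    stop("need at least 2 distinct TCRs and 2 distinct pHLA")

  positive_pairs <- unique(paste(tcr_keys, phla_keys, sep = "\n"))

  rng <- .seeded_rng(seed)
  seen <- character(0)
  out_t <- integer(n_req)
  out_p <- integer(n_req)
  got <- 0L
  attempts <- 0L
  while (got < n_req) {
    if (attempts >= max_attempts)
      stop("mispairing rejection sampling exhausted: ", attempts,
           " attempts yielded ", got, " of ", n_req, " negatives")
    attempts <- attempts + 1L
    ti <- tcr_idx[.sample_int(rng, length(tcr_idx), 1L)]
    pi <- phla_idx[.sample_int(rng, length(phla_idx), 1L)]
    pair <- paste(tcr_keys[ti], phla_keys[pi], sep = "\n")
    if (pair %in% positive_pairs || pair %in% seen) next
    got <- got + 1L
    seen[got] <- pair
    out_t[got] <- ti
    out_p[got] <- pi
  }

  neg <- df[out_t, c("alpha_v", "alpha_j", "alpha_cdr3",
                     "beta_v", "beta_j", "beta_cdr3"), drop = FALSE]
  neg$peptide <- df$peptide[out_p]
  neg$hla_allele <- df$hla_allele[out_p]
  neg$label <- "nonbinder"
  neg$source <- "mispairing"
  # carry stitched columns when present: chains from the TCR side,
  # pseudosequence from the pHLA side
  if ("alpha_aa" %in% names(df)) neg$alpha_aa <- df$alpha_aa[out_t]
  if ("beta_aa" %in% names(df)) neg$beta_aa <- df$beta_aa[out_t]
  if ("pseudo" %in% names(df)) neg$pseudo <- df$pseudo[out_p]
  rownames(neg) <- NULL
  bindingRecordSet(neg)
}
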