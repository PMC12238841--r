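#' Token vocabulary for the sequence encoder
#'
#' Seven special tokens followed by the 20 standard amino acids. The prefix
#' tokens \code{[tra]}, \code{[trb]}, \code{[peptide]} and \code{[mhc]}
#' delimit the four input components; \code{[cls]} heads every sequence and
#' pools for classification; \code{[mask]} is the masked-LM placeholder.
#' Token ids are dense, 1-based and stable: they are defined by position in
#' this vector, and the amino-acid block always occupies ids 8..27.
#'
#' @return A list with \code{tokens} (character vector), \code{id} (named
#'   integer lookup), \code{aa_first} (id of the first amino-acid token) and
#'   \code{size}.
#' @export
aaVocabulary <- function() {
  tokens <- c("[pad]", "[cls]", "[mask]", "[tra]", "[trb]",
              "[peptide]", "[mhc]", standardAminoAcids())
  list(tokens = tokens,
       id = stats::setNames(seq_along(tokens), tokens),
       aa_first = 8L,
       size = length(tokens))
}

.aa_ids <- function(x, vocab) {
  chars <- strsplit(x, "")[[1]]
  ids <- vocab$id[chars]
  if (anyNA(ids))
    stop("residue outside vocabulary in: ", x)
  unname(ids)
}

#' Tokenize one binding record
#'
#' Emits \code{[cls] [tra] alpha [trb] beta [peptide] peptide [mhc] pseudo},
#' padded with \code{[pad]} to \code{max_len}. When the sequence overruns
#' \code{max_len}, residues are dropped from the \emph{front} of the chain
#' components only (framework-1 end), never from the peptide or the
#' pseudosequence and never the CDR3-bearing chain tail; the longer chain is
#' trimmed first.
#'
#' @param alpha_aa,beta_aa Full variable-domain chain strings.
#' @param peptide Peptide string.
#' @param pseudo HLA pseudosequence string.
#' @param vocab From [aaVocabulary()].
#' @param max_len Padded length.
#' @return Integer id vector of length \code{max_len} (attribute
#'   \code{"n_real"} holds the unpadded length).
#' @export
tokenizeRecord <- function(alpha_aa, beta_aa, peptide, pseudo,
                           vocab = aaVocabulary(), max_len = 128L) {
  for (comp in list(alpha_aa, beta_aa, peptide, pseudo))
    if (is.na(comp) || !nzchar(comp))
      stop("all four components (alpha, beta, peptide, pseudosequence) ",
           "must be present")
  fixed <- 5L + nchar(peptide) + nchar(pseudo)
  budget <- max_len - fixed
  if (budget < 2L)
    stop("max_len too small for peptide + pseudosequence")
  la <- nchar(alpha_aa); lb <- nchar(beta_aa)
  if (la + lb > budget) {
    # trim chain fronts; longer chain gives first
    ta <- la; tb <- lb
    while (ta + tb > budget) {
      if (ta >= tb) ta <- ta - 1L else tb <- tb - 1L
    }
    alpha_aa <- substr(alpha_aa, la - ta + 1L, la)
    beta_aa <- substr(beta_aa, lb - tb + 1L, lb)
  }
  ids <- c(vocab$id[["[cls]"]],
           vocab$id[["[tra]"]], .aa_ids(alpha_aa, vocab),
           vocab$id[["[trb]"]], .aa_ids(beta_aa, vocab),
           vocab$id[["[peptide]"]], .aa_ids(peptide, vocab),
           vocab$id[["[mhc]"]], .aa_ids(pseudo, vocab))
  n_real <- length(ids)
  out <- c(ids, rep(vocab$id[["[pad]"]], max_len - n_real))
  attr(out, "n_real") <- n_real
  out
}

#' Tokenize paired chains only (pretraining corpus)
#'
#' Emits \code{[cls] [tra] alpha [trb] beta}, the unlabelled paired-chain
#' representation used for masked-LM pretraining.
#'
#' @inheritParams tokenizeRecord
#' @return Integer id vector of length \code{max_len}.
#' @export
tokenizeChains <- function(alpha_aa, beta_aa, vocab = aaVocabulary(),
                           max_len = 128L) {
  if (is.na(alpha_aa) || is.na(beta_aa) ||
      !nzchar(alpha_aa) || !nzchar(beta_aa))
    stop("both chains must be present")
  budget <- max_len - 3L
  la <- nchar(alpha_aa); lb <- nchar(beta_aa)
  if (la + lb > budget) {
    ta <- la; tb <- lb
    while (ta + tb > budget) if (ta >= tb) ta <- ta - 1L else tb <- tb - 1L
    alpha_aa <- substr(alpha_aa, la - ta + 1L, la)
    beta_aa <- substr(beta_aa, lb - tb + 1L, lb)
  }
  ids <- c(vocab$id[["[cls]"]],
           vocab$id[["[tra]"]], .aa_ids(alpha_aa, vocab),
           vocab$id[["[trb]"]], .aa_ids(beta_aa, vocab))
  n_real <- length(ids)
  out <- c(ids, rep(vocab$id[["[pad]"]], max_len - n_real))
  attr(out, "n_real") <- n_real
  out
}

#' Tokenize every record of a stitched record set
#'
#' @param set A [BindingRecordSet-class] whose records carry
#'   \code{alpha_aa}, \code{beta_aa} and \code{pseudo} columns (see
#'   [stitchRecords()]).
#' @param vocab From [aaVocabulary()].
#' @param max_len Padded length.
#' @return An integer matrix, one row per record.
#' @export
tokenizeSet <- function(set, vocab = aaVocabulary(), max_len = 128L) {
  df <- records(set)
  need <- c("alpha_aa", "beta_aa", "peptide", "pseudo")
  if (!all(need %in% names(df)))
    stop("record set must be stitched first (columns ",
         paste(setdiff(need, names(df)), collapse = ", "), " missing)")
  m <- matrix(0L, nrow = nrow(df), ncol = max_len)
  for (i in seq_len(nrow(df))) {
    m[i, ] <- tryCatch(
      tokenizeRecord(df$alpha_aa[i], df$beta_aa[i], df$peptide[i],
                     df$pseudo[i], vocab, max_len),
      error = function(e) stop("record ", i, ": ", conditionMessage(e)))
  }
  m
}
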