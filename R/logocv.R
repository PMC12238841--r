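#' Build leave-one-peptide-out cross-validation folds
#'
#' One fold is created per peptide whose total record count (binders plus
#' simulated non-binders carrying that peptide) reaches \code{minRecords};
#' the fold's test set is every record of that peptide and its training set
#' is every other record. Folds are ordered by descending record count, then
#' lexicographically by peptide. With no qualifying peptide an empty plan is
#' returned with a warning.
#'
#' @param set A [BindingRecordSet-class].
#' @param minRecords Minimum records for a peptide to be held out
#'   (inclusive; default 50).
#' @return A [SplitPlan-class].
#' @export
makeFolds <- function(set, minRecords = 50L) {
  pep <- peptides(set)
  n <- length(pep)
  counts <- table(pep)
  qual <- counts[counts >= minRecords]
  if (length(qual) == 0L) {
    warning("no peptide reaches ", minRecords, " records; empty plan")
    return(new("SplitPlan", folds = list(), n_records = n))
  }
  ord <- order(-as.integer(qual), names(qual))
  qual <- qual[ord]
  folds <- lapply(names(qual), function(p) {
    test_idx <- which(pep == p)
    list(peptide = p, test_idx = test_idx,
         train_idx = setdiff(seq_len(n), test_idx))
  })
  new("SplitPlan", folds = folds, n_records = n)
}

#' Verify that held-out peptides are unseen in training
#'
#' For each fold, checks that the held-out peptide string occurs nowhere
#' among the fold's training records. The check is exact string identity: a
#' one-mismatch neighbour in training does not violate it.
#'
#' @param plan A [SplitPlan-class].
#' @param set The [BindingRecordSet-class] the plan was built from.
#' @return Named logical vector, one entry per fold.
#' @export
unseenCheck <- function(plan, set) {
  pep <- peptides(set)
  vapply(folds(plan), function(f) {
    !f$peptide %in% pep[f$train_idx]
  }, logical(1), USE.NAMES = FALSE) |>
    stats::setNames(heldOutPeptides(plan))
}

#' Serialize / read a SplitPlan as JSON
#'
#' Folds are stored as arrays of 1-based row indices into the standardized
#' record TSV the plan was built from.
#'
#' @param plan A [SplitPlan-class].
#' @param path JSON path.
#' @return \code{writeSplitPlan}: the path invisibly; \code{readSplitPlan}:
#'   a \code{SplitPlan}.
#' @export
writeSplitPlan <- function(plan, path) {
  jsonlite::write_json(
    list(n_records = plan@n_records,
         folds = lapply(folds(plan), function(f)
           list(peptide = f$peptide,
                test_idx = f$test_idx, train_idx = f$train_idx))),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSplitPlan
#' @export
readSplitPlan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  folds <- lapply(seq_len(nrow(x$folds)), function(i)
    list(peptide = x$folds$peptide[i],
         test_idx = as.integer(x$folds$test_idx[[i]]),
         train_idx = as.integer(x$folds$train_idx[[i]])))
  new("SplitPlan", folds = folds, n_records = as.integer(x$n_records))
}
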