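#' @import methods
NULL

#' The 20 standard amino acids
#'
#' Single-letter codes of the 20 standard amino acids, in the alphabetical
#' order used throughout the package (tokenizer, synthetic generator,
#' alphabet filters).
#'
#' @return A character vector of length 20.
#' @export
#' @examples
#' standardAminoAcids()
standardAminoAcids <- function() {
  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
}

.STD_COLS <- c("alpha_v", "alpha_j", "alpha_cdr3",
               "beta_v", "beta_j", "beta_cdr3",
               "peptide", "hla_allele", "label", "source")

#' BindingRecordSet: standardized TCR-peptide-HLA-I binding records
#'
#' An S4 container for standardized binding records. Each row describes one
#' alpha/beta TCR (by V call, J call and junction-inclusive CDR3 per chain;
#' either chain may be missing but not both), the peptide it was assayed
#' against, the presenting HLA class I allele at two-field resolution, a
#' binary label (\code{"binder"} or \code{"nonbinder"}) and a free-text
#' provenance tag. Optional columns added downstream (stitched chains,
#' pseudosequence) are carried along untouched.
#'
#' @slot records A \code{data.frame} with at least the ten standard columns
#'   \code{alpha_v, alpha_j, alpha_cdr3, beta_v, beta_j, beta_cdr3, peptide,
#'   hla_allele, label, source}.
#'
#' @seealso [bindingRecordSet()], [applyFilters()], [mergeAndDedup()]
#' @export
setClass("BindingRecordSet", representation(records = "data.frame"))

setValidity("BindingRecordSet", function(object) {
  df <- object@records
  missing_cols <- setdiff(.STD_COLS, names(df))
  if (length(missing_cols) > 0L)
    return(paste("missing standard columns:",
                 paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (!all(df$label %in% c("binder", "nonbinder")))
    return("label must be 'binder' or 'nonbinder'")
  has_alpha <- !is.na(df$alpha_cdr3) & nzchar(df$alpha_cdr3)
  has_beta <- !is.na(df$beta_cdr3) & nzchar(df$beta_cdr3)
  if (!all(has_alpha | has_beta))
    return("every record needs an alpha and/or beta chain")
  if (anyNA(df$peptide) || !all(nzchar(df$peptide)))
    return("peptide must be non-empty")
  TRUE
})

#' Construct a BindingRecordSet
#'
#' @param records A \code{data.frame} carrying the ten standard columns (see
#'   [BindingRecordSet-class]); extra columns are preserved.
#' @return A \code{BindingRecordSet}.
#' @export
#' @examples
#' df <- data.frame(alpha_v = NA, alpha_j = NA, alpha_cdr3 = NA,
#'                  beta_v = "TRBV19*01", beta_j = "TRBJ2-1*01",
#'                  beta_cdr3 = "CASSIRSSYEQYF", peptide = "NLVPMVATV",
#'                  hla_allele = "HLA-A*02:01", label = "binder",
#'                  source = "example")
#' bindingRecordSet(df)
bindingRecordSet <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in .STD_COLS)
    if (!col %in% names(records)) records[[col]] <- NA_character_
  rownames(records) <- NULL
  new("BindingRecordSet", records = records)
}

#' Accessors for BindingRecordSet
#'
#' \code{records()} returns the underlying data.frame; \code{peptides()},
#' \code{labels()} and \code{hlaAlleles()} the corresponding columns;
#' \code{dedupKey()} the per-record deduplication key (all six chain fields
#' plus peptide, allele and label).
#'
#' @param x A \code{BindingRecordSet}.
#' @return \code{records()}: a data.frame; the others: character vectors of
#'   length \code{nrow(records(x))}.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "BindingRecordSet", function(x) x@records)

#' @rdname records
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' @rdname records
#' @export
setMethod("peptides", "BindingRecordSet", function(x) x@records$peptide)

#' @rdname records
#' @export
setGeneric("hlaAlleles", function(x) standardGeneric("hlaAlleles"))

#' @rdname records
#' @export
setMethod("hlaAlleles", "BindingRecordSet", function(x) x@records$hla_allele)

#' @rdname records
#' @export
setGeneric("dedupKey", function(x) standardGeneric("dedupKey"))

#' @rdname records
#' @export
setMethod("dedupKey", "BindingRecordSet", function(x) {
  df <- x@records
  key_cols <- c("alpha_v", "alpha_j", "alpha_cdr3",
                "beta_v", "beta_j", "beta_cdr3",
                "peptide", "hla_allele", "label")
  do.call(paste, c(lapply(df[key_cols], function(v) {
    v <- as.character(v)
    v[is.na(v)] <- ""
    v
  }), sep = "\r"))
})

#' @export
setMethod("length", "BindingRecordSet", function(x) nrow(x@records))

#' @export
setMethod("labels", "BindingRecordSet", function(object, ...) {
  object@records$label
})

#' Subset a BindingRecordSet by row
#'
#' @param x A \code{BindingRecordSet}.
#' @param i Row indices (integer or logical).
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "BindingRecordSet", function(x, i, j, ..., drop = FALSE) {
  df <- x@records[i, , drop = FALSE]
  rownames(df) <- NULL
  new("BindingRecordSet", records = df)
})

setMethod("show", "BindingRecordSet", function(object) {
  df <- object@records
  n_pep <- length(unique(df$peptide))
  tab <- table(factor(df$label, levels = c("binder", "nonbinder")))
  cat("BindingRecordSet with", nrow(df), "records\n")
  cat("  binders:", tab[["binder"]],
      " nonbinders:", tab[["nonbinder"]], "\n")
  cat("  distinct peptides:", n_pep,
      " distinct HLA alleles:", length(unique(df$hla_allele)), "\n")
  extra <- setdiff(names(df), .STD_COLS)
  if (length(extra)) cat("  extra columns:", paste(extra, collapse = ", "), "\n")
})

#' FilterReport: accounting of record-level filtering
#'
#' Counts of records rejected per reason, plus the retained count. The
#' counters and the retained count always sum to the number of input records.
#'
#' @slot counters Named integer vector of per-reason rejection counts.
#' @slot retained Integer count of records that passed all filters.
#' @export
setClass("FilterReport",
         representation(counters = "integer", retained = "integer"))

setValidity("FilterReport", function(object) {
  if (length(object@retained) != 1L || object@retained < 0L)
    return("retained must be a single non-negative count")
  if (any(object@counters < 0L)) return("counters must be non-negative")
  TRUE
})

#' @describeIn FilterReport-class Number of input records accounted for.
#' @param x A \code{FilterReport}.
#' @export
setGeneric("inputCount", function(x) standardGeneric("inputCount"))

#' @rdname FilterReport-class
#' @export
setMethod("inputCount", "FilterReport",
          function(x) x@retained + sum(x@counters))

#' @rdname FilterReport-class
#' @export
setGeneric("rejections", function(x) standardGeneric("rejections"))

#' @rdname FilterReport-class
#' @export
setMethod("rejections", "FilterReport", function(x) x@counters)

#' @rdname FilterReport-class
#' @export
setGeneric("retained", function(x) standardGeneric("retained"))

#' @rdname FilterReport-class
#' @export
setMethod("retained", "FilterReport", function(x) x@retained)

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport:", inputCount(object), "records in,",
      object@retained, "retained\n")
  nz <- object@counters[object@counters > 0L]
  if (length(nz))
    for (r in names(nz)) cat("  rejected[", r, "]: ", nz[[r]], "\n", sep = "")
})

#' GermlineDb: amino-acid level V/J germline reference
#'
#' Holds germline V and J segment amino-acid sequences with their junction
#' anchors and, for V segments, CDR1/CDR2 spans. Anchors and spans are
#' 1-based positions on the segment sequence: for a V segment the anchor is
#' the conserved cysteine that opens the junction; for a J segment it is the
#' conserved Phe/Trp of the F/W-G-X-G motif. Lookup is exact on the full
#' allele name with a fallback from the bare gene name to its *01 allele.
#'
#' @slot segments A \code{data.frame} with columns \code{name, locus,
#'   segment_type, aa, anchor, cdr1_start, cdr1_end, cdr2_start, cdr2_end}.
#' @seealso [stitchChain()], [annotateCdrs()], [readGermlineFasta()]
#' @export
setClass("GermlineDb", representation(segments = "data.frame"))

setValidity("GermlineDb", function(object) {
  df <- object@segments
  need <- c("name", "locus", "segment_type", "aa", "anchor",
            "cdr1_start", "cdr1_end", "cdr2_start", "cdr2_end")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)),
                                           collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (anyDuplicated(df$name)) return("duplicate segment names")
  if (!all(df$segment_type %in% c("V", "J")))
    return("segment_type must be 'V' or 'J'")
  if (any(df$anchor < 1L | df$anchor > nchar(df$aa)))
    return("anchor outside sequence")
  isV <- df$segment_type == "V"
  anchor_res <- substr(df$aa, df$anchor, df$anchor)
  if (!all(anchor_res[isV] == "C"))
    return("V anchor residue must be the conserved Cys")
  if (!all(anchor_res[!isV] %in% c("F", "W")))
    return("J anchor residue must be Phe or Trp")
  j_next <- substr(df$aa[!isV], df$anchor[!isV] + 1L, df$anchor[!isV] + 1L)
  if (!all(j_next %in% c("G", "")))
    return("J anchor must open an F/W-G-X-G motif")
  ok_span <- function(s, e) is.na(s) | (s >= 1L & e >= s & e <= nchar(df$aa))
  if (!all(ok_span(df$cdr1_start, df$cdr1_end)) ||
      !all(ok_span(df$cdr2_start, df$cdr2_end)))
    return("CDR span outside sequence")
  TRUE
})

#' @describeIn GermlineDb-class Segment table accessor.
#' @param x A \code{GermlineDb}.
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname GermlineDb-class
#' @export
setMethod("segments", "GermlineDb", function(x) x@segments)

setMethod("show", "GermlineDb", function(object) {
  df <- object@segments
  cat("GermlineDb with", nrow(df), "segments (",
      sum(df$segment_type == "V"), "V,",
      sum(df$segment_type == "J"), "J )\n")
  cat("  loci:", paste(sort(unique(df$locus)), collapse = ", "), "\n")
})

#' SplitPlan: leave-one-peptide-out cross-validation folds
#'
#' One fold per qualifying held-out peptide. Within each fold the test set is
#' every record whose peptide equals the held-out peptide (exact string
#' match) and the training set is every other record, so test and train
#' partition the full record set.
#'
#' @slot folds A list; each element has \code{peptide} (character),
#'   \code{test_idx} and \code{train_idx} (1-based row indices into the
#'   record set the plan was built from).
#' @slot n_records Number of records the plan refers to.
#' @seealso [makeFolds()], [unseenCheck()]
#' @export
setClass("SplitPlan",
         representation(folds = "list", n_records = "integer"))

setValidity("SplitPlan", function(object) {
  n <- object@n_records
  for (f in object@folds) {
    if (!all(c("peptide", "test_idx", "train_idx") %in% names(f)))
      return("each fold needs peptide, test_idx, train_idx")
    if (length(intersect(f$test_idx, f$train_idx)) > 0L)
      return("test and train overlap")
    if (length(union(f$test_idx, f$train_idx)) != n)
      return("test and train do not cover all records")
  }
  TRUE
})

#' @describeIn SplitPlan-class List of folds.
#' @param x A \code{SplitPlan}.
#' @export
setGeneric("folds", function(x) standardGeneric("folds"))

#' @rdname SplitPlan-class
#' @export
setMethod("folds", "SplitPlan", function(x) x@folds)

#' @rdname SplitPlan-class
#' @export
setGeneric("heldOutPeptides", function(x) standardGeneric("heldOutPeptides"))

#' @rdname SplitPlan-class
#' @export
setMethod("heldOutPeptides", "SplitPlan",
          function(x) vapply(x@folds, `[[`, character(1), "peptide"))

#' @export
setMethod("length", "SplitPlan", function(x) length(x@folds))

setMethod("show", "SplitPlan", function(object) {
  cat("SplitPlan:", length(object@folds), "peptide-holdout folds over",
      object@n_records, "records\n")
  for (f in object@folds)
    cat("  ", f$peptide, ": ", length(f$test_idx), " test / ",
        length(f$train_idx), " train\n", sep = "")
})
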