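#' Select cells with exactly one alpha and one beta chain
#'
#' From a per-cell chain table (rows pre-filtered to productive,
#' high-confidence chains), keeps only barcodes with exactly two distinct
#' chain sequences, one TRA and one TRB; this removes dual-receptor T cells
#' and experimental artefacts (doublets, empty GEMs). Duplicate rows of the
#' same chain collapse to one distinct sequence before counting.
#'
#' @param table A \code{data.frame} with columns \code{barcode, locus,
#'   v_call, j_call, cdr3_aa} and optionally logical \code{productive},
#'   \code{high_confidence} columns (rows with FALSE are dropped first).
#' @return A list with \code{pairs} (data.frame, one row per kept barcode:
#'   \code{barcode, alpha_v, alpha_j, alpha_cdr3, beta_v, beta_j,
#'   beta_cdr3}) and \code{dropped} (named integer counts per drop reason:
#'   \code{no_chains, single_chain, too_many_chains, same_locus_pair}).
#' @export
selectPairedCells <- function(table) {
  tab <- as.data.frame(table, stringsAsFactors = FALSE)
  for (flag in c("productive", "high_confidence"))
    if (flag %in% names(tab))
      tab <- tab[as.logical(tab[[flag]]) %in% TRUE, , drop = FALSE]
  all_bc <- unique(table$barcode)
  chain_id <- paste(tab$locus, tab$v_call, tab$j_call, tab$cdr3_aa,
                    sep = "\r")
  tab <- tab[!duplicated(paste(tab$barcode, chain_id, sep = "\r")), ,
             drop = FALSE]
  dropped <- c(no_chains = 0L, single_chain = 0L,
               too_many_chains = 0L, same_locus_pair = 0L)
  keep_rows <- list()
  for (bc in all_bc) {
    sub <- tab[tab$barcode == bc, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0L) { dropped[["no_chains"]] <- dropped[["no_chains"]] + 1L }
    else if (n == 1L) { dropped[["single_chain"]] <- dropped[["single_chain"]] + 1L }
    else if (n > 2L) { dropped[["too_many_chains"]] <- dropped[["too_many_chains"]] + 1L }
    else if (!setequal(sub$locus, c("TRA", "TRB"))) {
      dropped[["same_locus_pair"]] <- dropped[["same_locus_pair"]] + 1L
    } else {
      a <- sub[sub$locus == "TRA", ]
      b <- sub[sub$locus == "TRB", ]
      keep_rows[[length(keep_rows) + 1L]] <- data.frame(
        barcode = bc,
        alpha_v = a$v_call, alpha_j = a$j_call, alpha_cdr3 = a$cdr3_aa,
        beta_v = b$v_call, beta_j = b$j_call, beta_cdr3 = b$cdr3_aa,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(keep_rows)) do.call(rbind, keep_rows)
           else data.frame(barcode = character(), alpha_v = character(),
                           alpha_j = character(), alpha_cdr3 = character(),
                           beta_v = character(), beta_j = character(),
                           beta_cdr3 = character(),
                           stringsAsFactors = FALSE)
  list(pairs = pairs, dropped = dropped)
}

#' Call binders from a peptide-UMI count matrix
#'
#' A cell-peptide combination is called a binder when its UMI count exceeds
#' the same cell's negative-control count by more than three standard
#' deviations, where the standard deviation is that of the negative-control
#' column pooled across all cells. Ties at the threshold are non-binders
#' (strict inequality); the negative-control column itself is never flagged.
#'
#' @param umi Integer matrix of UMI counts, rows = cell barcodes (rownames),
#'   columns = peptides (colnames).
#' @param negctrl Name of the negative-control column.
#' @param k Number of standard deviations (default 3).
#' @param sd_type \code{"sample"} (n-1 denominator, default) or
#'   \code{"population"}.
#' @param baseline \code{"per_cell"} (default): each cell's own
#'   negative-control count is the baseline; \code{"mean"}: the column mean
#'   is used for every cell.
#' @return Logical matrix of the same rows and the non-control columns;
#'   TRUE = binder.
#' @export
callBinders <- function(umi, negctrl, k = 3,
                        sd_type = c("sample", "population"),
                        baseline = c("per_cell", "mean")) {
  sd_type <- match.arg(sd_type)
  baseline <- match.arg(baseline)
  umi <- as.matrix(umi)
  if (!negctrl %in% colnames(umi))
    stop("negative-control column not found: ", negctrl)
  if (sum(colnames(umi) == negctrl) != 1L)
    stop("negative-control column must appear exactly once")
  if (any(umi < 0) || any(umi != round(umi)))
    stop("UMI counts must be non-negative integers")
  n <- nrow(umi)
  if (n < 2L) stop("SD undefined: need at least 2 cells")
  neg <- umi[, negctrl]
  s <- stats::sd(neg)
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  base <- if (baseline == "per_cell") neg else rep(mean(neg), n)
  pep <- umi[, colnames(umi) != negctrl, drop = FALSE]
  sweep(pep, 1L, base + k * s, ">")
}

#' Binder-labelled records from paired cells and binding flags
#'
#' Joins binder flags onto kept paired cells; only positive calls are
#' emitted (non-binder flags are discarded, as are flags on barcodes that
#' were not kept as clean alpha/beta pairs).
#'
#' @param flags Logical matrix from [callBinders()] (rownames = barcodes).
#' @param pairs \code{pairs} data.frame from [selectPairedCells()].
#' @param peptideHla Named character vector mapping peptide column names to
#'   HLA alleles (one allele per assayed peptide).
#' @param source Provenance tag for the emitted records.
#' @return A [BindingRecordSet-class] of binder-labelled records.
#' @export
positivesOnly <- function(flags, pairs, peptideHla, source = "10x") {
  hits <- which(flags, arr.ind = TRUE)
  out <- list()
  for (r in seq_len(nrow(hits))) {
    bc <- rownames(flags)[hits[r, 1L]]
    pep <- colnames(flags)[hits[r, 2L]]
    p <- pairs[pairs$barcode == bc, , drop = FALSE]
    if (nrow(p) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      alpha_v = p$alpha_v, alpha_j = p$alpha_j, alpha_cdr3 = p$alpha_cdr3,
      beta_v = p$beta_v, beta_j = p$beta_j, beta_cdr3 = p$beta_cdr3,
      peptide = pep,
      hla_allele = if (pep %in% names(peptideHla)) peptideHla[[pep]]
                   else NA_character_,
      label = "binder", source = source, stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out)
        else stats::setNames(
          as.data.frame(matrix(character(), ncol = 10),
                        stringsAsFactors = FALSE), .STD_COLS)
  bindingRecordSet(df)
}

#' Read a UMI count TSV (rows = barcodes, columns = peptides)
#'
#' @param path TSV path; first column must be the barcode.
#' @return Integer matrix with barcode rownames.
#' @export
readUmiTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
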