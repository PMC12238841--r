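#' Look up a germline segment, with gene-to-*01 fallback
#'
#' Lookup is exact on the full allele name (e.g. \code{TRBV19*01}); a bare
#' gene name (e.g. \code{TRBV19}) falls back to its \code{*01} allele.
#'
#' @param db A [GermlineDb-class].
#' @param name Allele or gene name.
#' @return One row of the segment table.
#' @export
lookupSegment <- function(db, name) {
  df <- segments(db)
  hit <- which(df$name == name)
  if (length(hit) == 0L && !grepl("\\*", name))
    hit <- which(df$name == paste0(name, "*01"))
  if (length(hit) == 0L)
    stop("unresolvable allele: ", name)
  df[hit[1L], , drop = FALSE]
}

#' Reconstitute a full variable-domain chain from V/J/CDR3
#'
#' Builds the complete variable-domain amino-acid sequence from its minimal
#' description: the germline V segment up to (but not including) its
#' conserved Cys anchor, then the junction-inclusive CDR3 verbatim, then the
#' germline J segment after its conserved Phe/Trp anchor. CDR3 residues
#' always come from \code{cdr3_aa}, even where a somatic junction disagrees
#' with germline.
#'
#' @param v_call,j_call Segment names resolvable in \code{db}.
#' @param cdr3_aa Junction-inclusive CDR3: starts with \code{C}, ends with
#'   \code{F} or \code{W}.
#' @param db A [GermlineDb-class].
#' @return The stitched amino-acid string; the CDR3 occupies positions
#'   \code{V.anchor .. V.anchor + nchar(cdr3_aa) - 1}.
#' @export
#' @seealso [annotateCdrs()], [stitchRecords()]
stitchChain <- function(v_call, j_call, cdr3_aa, db) {
  if (is.na(cdr3_aa) || nchar(cdr3_aa) < 2L ||
      substr(cdr3_aa, 1L, 1L) != "C" ||
      !substr(cdr3_aa, nchar(cdr3_aa), nchar(cdr3_aa)) %in% c("F", "W"))
    stop("non-canonical junction: ", cdr3_aa)
  vseg <- lookupSegment(db, v_call)
  jseg <- lookupSegment(db, j_call)
  if (vseg$segment_type != "V") stop(v_call, " is not a V segment")
  if (jseg$segment_type != "J") stop(j_call, " is not a J segment")
  paste0(substr(vseg$aa, 1L, vseg$anchor - 1L),
         cdr3_aa,
         substr(jseg$aa, jseg$anchor + 1L, nchar(jseg$aa)))
}

#' Germline CDR1/CDR2 loops of a V allele
#'
#' CDR1 and CDR2 are completely determined by the V gene allele; this
#' returns the annotated germline substrings.
#'
#' @param v_call V allele (or gene) name.
#' @param db A [GermlineDb-class].
#' @return A list with \code{cdr1_aa} and \code{cdr2_aa}.
#' @export
annotateCdrs <- function(v_call, db) {
  seg <- lookupSegment(db, v_call)
  if (seg$segment_type != "V") stop(v_call, " is not a V segment")
  if (is.na(seg$cdr1_start) || is.na(seg$cdr2_start))
    stop("no CDR annotation for ", v_call)
  list(cdr1_aa = substr(seg$aa, seg$cdr1_start, seg$cdr1_end),
       cdr2_aa = substr(seg$aa, seg$cdr2_start, seg$cdr2_end))
}

#' Extract an HLA pseudosequence
#'
#' Concatenates the residues of the mature HLA heavy chain at the listed
#' 1-based positions, in the listed order. With the packaged 34-position
#' list (residues within 4.0 Angstrom of bound 9-mer peptides) the result is
#' always 34 residues.
#'
#' @param hla_aa Mature heavy-chain amino-acid string.
#' @param positions Integer vector of 1-based positions; defaults to the
#'   packaged 34-position list ([pseudoPositions()]).
#' @return A string of \code{length(positions)} residues.
#' @export
#' @examples
#' pseudoSequence("MKTAY", c(1, 3, 5))  # "MTY"
pseudoSequence <- function(hla_aa, positions = pseudoPositions()) {
  stopifnot(length(hla_aa) == 1L, !is.na(hla_aa))
  if (max(positions) > nchar(hla_aa))
    stop("sequence too short: length ", nchar(hla_aa),
         " < position ", max(positions))
  paste(strsplit(hla_aa, "")[[1]][positions], collapse = "")
}

#' The packaged 34-residue pseudosequence position list
#'
#' 1-based, strictly increasing positions on the mature HLA class I heavy
#' chain (the 34 peptide-contact residues used by NetMHCpan-style
#' pseudosequences). The position list is a parameter of
#' [pseudoSequence()]; only this 34-position fixture ships with the package.
#'
#' @param path Optional path to a one-position-per-line text file.
#' @return Integer vector of positions.
#' @export
pseudoPositions <- function(path = system.file("extdata",
                                               "pseudo_positions_34.txt",
                                               package = "tcrbind")) {
  pos <- as.integer(readLines(path))
  if (any(is.na(pos)) || any(diff(pos) <= 0L))
    stop("positions must be strictly increasing integers")
  pos
}

#' Read / write a germline reference FASTA
#'
#' Segments are stored as amino-acid FASTA with structured headers
#' \code{name|locus|segment_type|anchor|cdr1_start-cdr1_end|cdr2_start-cdr2_end}
#' (1-based closed spans; \code{-} for absent spans on J segments).
#'
#' @param path FASTA path.
#' @return \code{readGermlineFasta}: a [GermlineDb-class].
#' @export
readGermlineFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  parse_span <- function(x) {
    if (x == "-") c(NA_integer_, NA_integer_)
    else as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
  }
  rows <- lapply(seq_along(seqs), function(i) {
    p <- parts[[i]]
    s1 <- parse_span(p[5]); s2 <- parse_span(p[6])
    data.frame(name = p[1], locus = p[2], segment_type = p[3],
               aa = as.character(seqs[[i]]), anchor = as.integer(p[4]),
               cdr1_start = s1[1], cdr1_end = s1[2],
               cdr2_start = s2[1], cdr2_end = s2[2],
               stringsAsFactors = FALSE)
  })
  new("GermlineDb", segments = do.call(rbind, rows))
}

#' @rdname readGermlineFasta
#' @param db A [GermlineDb-class].
#' @export
writeGermlineFasta <- function(db, path) {
  df <- segments(db)
  span_str <- function(s, e) ifelse(is.na(s), "-", paste0(s, "-", e))
  headers <- paste(df$name, df$locus, df$segment_type, df$anchor,
                   span_str(df$cdr1_start, df$cdr1_end),
                   span_str(df$cdr2_start, df$cdr2_end), sep = "|")
  seqs <- Biostrings::AAStringSet(df$aa)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read HLA heavy-chain sequences from FASTA
#'
#' @param path FASTA keyed by allele name (e.g. \code{HLA-A*02:01}); the
#'   packaged file is a synthetic desk-scale stand-in generated by
#'   [genHlaFasta()], not real HLA sequences.
#' @return Named character vector of amino-acid sequences.
#' @export
readHlaFasta <- function(path = system.file("extdata",
                                            "hla_synthetic.fasta",
                                            package = "tcrbind")) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Stitch full chains and pseudosequences onto a record set
#'
#' Adds \code{alpha_aa}/\code{beta_aa} columns by stitching each present
#' chain against the germline reference, and a \code{pseudo} column from the
#' HLA sequences. Records that fail to stitch (unresolvable allele,
#' non-canonical junction, unknown HLA allele) are dropped and counted.
#'
#' @param set A [BindingRecordSet-class].
#' @param db A [GermlineDb-class].
#' @param hlaSeqs Named amino-acid vector from [readHlaFasta()].
#' @param positions Pseudosequence position list.
#' @return A list with \code{set} (augmented records) and \code{n_dropped}.
#' @export
stitchRecords <- function(set, db, hlaSeqs,
                          positions = pseudoPositions()) {
  df <- records(set)
  n <- nrow(df)
  alpha_aa <- rep(NA_character_, n)
  beta_aa <- rep(NA_character_, n)
  pseudo <- rep(NA_character_, n)
  ok <- rep(TRUE, n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      if (!is.na(df$alpha_cdr3[i]) && nzchar(df$alpha_cdr3[i]))
        alpha_aa[i] <- stitchChain(df$alpha_v[i], df$alpha_j[i],
                                   df$alpha_cdr3[i], db)
      if (!is.na(df$beta_cdr3[i]) && nzchar(df$beta_cdr3[i]))
        beta_aa[i] <- stitchChain(df$beta_v[i], df$beta_j[i],
                                  df$beta_cdr3[i], db)
      hla <- df$hla_allele[i]
      if (!hla %in% names(hlaSeqs)) stop("no HLA sequence for ", hla)
      pseudo[i] <- pseudoSequence(hlaSeqs[[hla]], positions)
      TRUE
    }, error = function(e) FALSE)
    ok[i] <- res
  }
  df$alpha_aa <- alpha_aa
  df$beta_aa <- beta_aa
  df$pseudo <- pseudo
  list(set = bindingRecordSet(df[ok, , drop = FALSE]),
       n_dropped = sum(!ok))
}
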