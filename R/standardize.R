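#' Read a binding-data table in an AIRR-style TSV dialect
#'
#' Reads a tab-separated table with a header row and renames source-specific
#' columns to the package's standard names via \code{columnMap}. Columns not
#' mentioned in the map are preserved untouched as provenance.
#'
#' @param path Path to a TSV file.
#' @param columnMap Named character vector mapping source column names to
#'   standard names, e.g. \code{c(junction_aa = "cdr3_aa")}. May be empty.
#' @return A \code{data.frame} with one row per data row of the file;
#'   zero-row files (header only) give a zero-row data.frame.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("locus\tjunction_aa", "TRB\tCASSF"), tf)
#' readBindingTsv(tf, c(junction_aa = "cdr3_aa"))
readBindingTsv <- function(path, columnMap = character()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  if (length(columnMap) > 0) {
    absent <- setdiff(names(columnMap), names(df))
    if (length(absent) > 0)
      stop("missing column in ", path, ": ",
           paste(absent, collapse = ", "))
    idx <- match(names(columnMap), names(df))
    names(df)[idx] <- unname(columnMap)
  }
  df
}

.is_std_aa <- function(x) {
  !is.na(x) & nzchar(x) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}

.has_field <- function(df, col) {
  if (!col %in% names(df)) return(rep(FALSE, nrow(df)))
  !is.na(df[[col]]) & nzchar(df[[col]])
}

#' Normalize raw rows to the wide alpha/beta record layout
#'
#' Raw tables may describe one chain per row (AIRR style, with a
#' \code{locus} column and \code{v_call/j_call/cdr3_aa}) or both chains per
#' row (wide \code{alpha_*}/\code{beta_*} columns). This helper rewrites the
#' single-chain layout into the wide layout; wide rows pass through.
#'
#' @param raw A column-mapped \code{data.frame}.
#' @return A \code{data.frame} with \code{alpha_v, alpha_j, alpha_cdr3,
#'   beta_v, beta_j, beta_cdr3} columns (plus all other input columns).
#' @keywords internal
.widen_chains <- function(raw) {
  wide_cols <- c("alpha_v", "alpha_j", "alpha_cdr3",
                 "beta_v", "beta_j", "beta_cdr3")
  for (col in wide_cols)
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  if ("locus" %in% names(raw)) {
    is_a <- !is.na(raw$locus) & raw$locus == "TRA"
    is_b <- !is.na(raw$locus) & raw$locus == "TRB"
    for (src in c(v = "v_call", j = "j_call", cdr3 = "cdr3_aa")) {
      if (!src %in% names(raw)) next
      tgt <- c(v_call = "v", j_call = "j", cdr3_aa = "cdr3")[[src]]
      raw[[paste0("alpha_", tgt)]][is_a] <- raw[[src]][is_a]
      raw[[paste0("beta_", tgt)]][is_b] <- raw[[src]][is_b]
    }
  }
  raw
}

.FILTER_REASONS <- c("invalid_locus", "missing_chain_fields",
                     "peptide_length", "ambiguous_residue",
                     "non_human_mhc", "class_ii_mhc", "unresolvable_allele")

#' Apply inclusion/exclusion filters to raw binding records
#'
#' Implements the record-level curation rules: every record must carry at
#' least one fully specified chain (CDR3 plus V and J calls) on a TRA or TRB
#' locus, a peptide of 8-12 residues over the 20 standard amino acids, a
#' CDR3 free of non-standard or ambiguous residues, and a human class I MHC
#' label (mouse alleles such as H-2Kb and class II codes such as DRB/DQ/DP
#' are excluded). The first rule that fires is recorded as the rejection
#' reason; rejection is a return value, never an error.
#'
#' @param raw A column-mapped \code{data.frame} (single-chain AIRR layout or
#'   wide layout; see [readBindingTsv()]). Expected columns: the chain
#'   fields, \code{peptide}, \code{hla_allele} (raw MHC label),
#'   \code{label}, optionally \code{source}.
#' @param minPeptideLen,maxPeptideLen Inclusive peptide length bounds
#'   (default 8 and 12).
#' @return A list with \code{set} (a [BindingRecordSet-class] of accepted
#'   records, chain V calls completed to *01 where the allele suffix was
#'   missing), \code{report} (a [FilterReport-class]) and \code{reasons}
#'   (per-input-row character: \code{"accepted"} or the rejection reason).
#' @export
applyFilters <- function(raw, minPeptideLen = 8L, maxPeptideLen = 12L) {
  raw <- .widen_chains(as.data.frame(raw, stringsAsFactors = FALSE))
  n <- nrow(raw)
  reason <- rep(NA_character_, n)

  mhc <- if ("hla_allele" %in% names(raw)) raw$hla_allele
         else rep(NA_character_, n)
  pep <- if ("peptide" %in% names(raw)) raw$peptide else rep(NA_character_, n)

  # rule 1: locus sanity (single-chain rows with an unknown locus, or wide
  # rows whose V/J calls contradict their chain side)
  bad_locus <- rep(FALSE, n)
  if ("locus" %in% names(raw)) {
    has_locus <- !is.na(raw$locus) & nzchar(raw$locus)
    bad_locus <- bad_locus | (has_locus & !raw$locus %in% c("TRA", "TRB"))
  }
  chk_prefix <- function(col, prefix) {
    v <- raw[[col]]
    !is.na(v) & nzchar(v) & !startsWith(v, prefix)
  }
  bad_locus <- bad_locus |
    chk_prefix("alpha_v", "TRAV") | chk_prefix("alpha_j", "TRAJ") |
    chk_prefix("beta_v", "TRBV") | chk_prefix("beta_j", "TRBJ")

  # rule 2: at least one chain must be fully specified (CDR3 + V + J);
  # partially specified chains are blanked on accepted records
  a_full <- .has_field(raw, "alpha_v") & .has_field(raw, "alpha_j") &
    .has_field(raw, "alpha_cdr3")
  b_full <- .has_field(raw, "beta_v") & .has_field(raw, "beta_j") &
    .has_field(raw, "beta_cdr3")
  missing_fields <- !(a_full | b_full)

  # rule 3: peptide length window
  plen <- nchar(ifelse(is.na(pep), "", pep))
  bad_len <- plen < minPeptideLen | plen > maxPeptideLen

  # rule 4: non-standard / ambiguous residues in peptide or any CDR3
  bad_res <- !.is_std_aa(pep) |
    (a_full & !.is_std_aa(raw$alpha_cdr3)) |
    (b_full & !.is_std_aa(raw$beta_cdr3))

  # rule 5: MHC label must be human class I
  mhc_chr <- ifelse(is.na(mhc), "", mhc)
  non_human <- grepl("H-2", mhc_chr, fixed = TRUE)
  class_ii <- grepl("DRB|DQ|DP", mhc_chr)
  no_hla1 <- !grepl("^HLA-[ABC]", mhc_chr)

  reason[!bad_locus & !missing_fields & !bad_len & !bad_res &
           (non_human | (!class_ii & no_hla1))] <- "non_human_mhc"
  reason[!bad_locus & !missing_fields & !bad_len & !bad_res & !non_human &
           class_ii] <- "class_ii_mhc"
  reason[!bad_locus & !missing_fields & !bad_len & bad_res] <-
    "ambiguous_residue"
  reason[!bad_locus & !missing_fields & bad_len] <- "peptide_length"
  reason[!bad_locus & missing_fields] <- "missing_chain_fields"
  reason[bad_locus] <- "invalid_locus"

  accepted <- is.na(reason)
  reason[accepted] <- "accepted"

  out <- raw[accepted, , drop = FALSE]
  out[!a_full[accepted], c("alpha_v", "alpha_j", "alpha_cdr3")] <-
    NA_character_
  out[!b_full[accepted], c("beta_v", "beta_j", "beta_cdr3")] <-
    NA_character_
  # complete bare V/J gene names to their *01 allele (IMGT default)
  for (col in c("alpha_v", "alpha_j", "beta_v", "beta_j")) {
    v <- out[[col]]
    fix <- !is.na(v) & nzchar(v) & !grepl("\\*", v)
    out[[col]][fix] <- paste0(v[fix], "*01")
  }
  if (!"source" %in% names(out)) out$source <- "unspecified"
  out$source[is.na(out$source)] <- "unspecified"
  keep <- c(.STD_COLS)
  for (col in keep) if (!col %in% names(out)) out[[col]] <- NA_character_
  set <- bindingRecordSet(out[, keep, drop = FALSE])

  counters <- vapply(.FILTER_REASONS,
                     function(r) sum(reason == r, na.rm = TRUE), integer(1))
  report <- new("FilterReport", counters = counters,
                retained = sum(accepted))
  list(set = set, report = report, reasons = reason)
}

#' Impute a full two-field HLA allele from a group-level label
#'
#' Labels already at two-field resolution (e.g. \code{HLA-A*02:01}) are
#' returned unchanged (higher-resolution fields are trimmed). Group-level
#' labels (e.g. \code{HLA-A*02}) are completed to the most frequent allele of
#' that group in \code{freqTable}, mirroring assignment by global HLA class I
#' allele frequencies; ties break lexicographically by allele name.
#'
#' @param label An HLA class I label matching \code{HLA-[ABC]*dd} or
#'   \code{HLA-[ABC]*dd:dd}.
#' @param freqTable A \code{data.frame} with columns \code{allele} (two-field
#'   names) and \code{frequency}. The packaged table is returned by
#'   [hlaFrequencyTable()].
#' @return The two-field allele name.
#' @export
#' @examples
#' imputeHlaAllele("HLA-A*02", hlaFrequencyTable())  # "HLA-A*02:01"
imputeHlaAllele <- function(label, freqTable = hlaFrequencyTable()) {
  stopifnot(length(label) == 1L)
  if (grepl("^HLA-[ABC]\\*\\d+:\\d+", label)) {
    m <- regmatches(label, regexpr("^HLA-[ABC]\\*\\d+:\\d+", label))
    return(m)
  }
  if (!grepl("^HLA-[ABC]\\*\\d+$", label))
    stop("not a parsable HLA class I label: ", label)
  in_group <- startsWith(freqTable$allele, paste0(label, ":"))
  if (!any(in_group))
    stop("unresolvable allele group: ", label)
  cand <- freqTable[in_group, , drop = FALSE]
  cand <- cand[order(-cand$frequency, cand$allele), , drop = FALSE]
  cand$allele[[1L]]
}

#' Packaged global HLA class I allele frequency table
#'
#' A small fixture of common two-field HLA-A/B/C alleles with approximate
#' global frequencies, used for deterministic group-to-allele imputation
#' without network access.
#'
#' @return A \code{data.frame} with columns \code{allele}, \code{frequency}.
#' @export
hlaFrequencyTable <- function() {
  path <- system.file("extdata", "hla_allele_freq.tsv", package = "tcrbind")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Resolve every HLA label of a record set to two-field resolution
#'
#' Applies [imputeHlaAllele()] row-wise. Records whose allele group cannot be
#' resolved are dropped and counted, not raised as errors.
#'
#' @param set A [BindingRecordSet-class].
#' @param freqTable See [imputeHlaAllele()].
#' @return A list with \code{set} (resolved records) and \code{n_dropped}.
#' @export
resolveHlaAlleles <- function(set, freqTable = hlaFrequencyTable()) {
  df <- records(set)
  resolved <- vapply(df$hla_allele, function(x) {
    tryCatch(imputeHlaAllele(x, freqTable), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  keep <- !is.na(resolved)
  df$hla_allele <- resolved
  list(set = bindingRecordSet(df[keep, , drop = FALSE]),
       n_dropped = sum(!keep))
}

.coalesce_complementary <- function(df) {
  chain_cols <- c("alpha_v", "alpha_j", "alpha_cdr3",
                  "beta_v", "beta_j", "beta_cdr3")
  grp <- paste(df$peptide, df$hla_allele, df$label, sep = "\r")
  for (g in unique(grp[duplicated(grp)])) {
    idx <- which(grp == g)
    if (length(idx) < 2L) next
    sub <- df[idx, chain_cols, drop = FALSE]
    for (i in seq_along(idx)) {
      nas <- which(is.na(sub[i, ]) | !nzchar(as.character(sub[i, ])))
      if (length(nas) == 0L) next
      for (j in seq_along(idx)) {
        if (i == j) next
        donor <- sub[j, ]
        agree <- all(vapply(setdiff(seq_along(chain_cols), nas), function(kk) {
          a <- as.character(sub[i, kk]); b <- as.character(donor[[kk]])
          !is.na(b) && nzchar(b) && identical(a, b)
        }, logical(1)))
        donor_has <- all(!is.na(unlist(donor[nas])) &
                           nzchar(as.character(unlist(donor[nas]))))
        if (agree && donor_has) {
          sub[i, nas] <- donor[nas]
          break
        }
      }
    }
    df[idx, chain_cols] <- sub
  }
  df
}

#' Merge standardized record sets and remove duplicates
#'
#' Concatenates the given sets and removes exact duplicates on the
#' deduplication key (all six chain fields, peptide, HLA allele, label);
#' first occurrence wins and the original order is preserved. A record
#' labelled binder and its nonbinder twin have different keys, so
#' contradictory pairs both survive. Optionally, records from different
#' sources that agree on every specified field but miss complementary chain
#' fields are coalesced (missing fields filled from the more complete record)
#' before deduplication.
#'
#' @param sets A list of [BindingRecordSet-class] objects (or a single one).
#' @param coalesce Fill complementary missing chain fields across sources
#'   before deduplication (default TRUE).
#' @return A list with \code{set} (deduplicated records) and \code{report}
#'   (a [FilterReport-class] whose only counter is \code{duplicate}).
#' @export
mergeAndDedup <- function(sets, coalesce = TRUE) {
  if (is(sets, "BindingRecordSet")) sets <- list(sets)
  dfs <- lapply(sets, records)
  all_cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (col in setdiff(all_cols, names(d))) d[[col]] <- NA
    d[, all_cols, drop = FALSE]
  })
  df <- do.call(rbind, dfs)
  rownames(df) <- NULL
  n_in <- nrow(df)
  if (n_in > 0L && coalesce) df <- .coalesce_complementary(df)
  set_all <- bindingRecordSet(df)
  keys <- dedupKey(set_all)
  keep <- !duplicated(keys)
  report <- new("FilterReport",
                counters = c(duplicate = sum(!keep)),
                retained = sum(keep))
  list(set = set_all[keep], report = report)
}

#' Write / read the standardized record TSV
#'
#' The standardized table has the fixed column order \code{alpha_v, alpha_j,
#' alpha_cdr3, beta_v, beta_j, beta_cdr3, peptide, hla_allele, label,
#' source}, followed by any extra columns (stitched chains, pseudosequence).
#'
#' @param set A [BindingRecordSet-class].
#' @param path Output (input) TSV path.
#' @return \code{writeStandardizedTsv}: the path, invisibly;
#'   \code{readStandardizedTsv}: a \code{BindingRecordSet}.
#' @export
writeStandardizedTsv <- function(set, path) {
  df <- records(set)
  extra <- setdiff(names(df), .STD_COLS)
  df <- df[, c(.STD_COLS, extra), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeStandardizedTsv
#' @export
readStandardizedTsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character",
                          na.strings = c("NA", ""))
  bindingRecordSet(df)
}

#' Serialize a FilterReport to JSON
#'
#' @param report A [FilterReport-class].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
writeFilterReport <- function(report, path) {
  jsonlite::write_json(
    list(retained = retained(report),
         rejections = as.list(rejections(report)),
         input = inputCount(report)),
    path, auto_unbox = TRUE)
  invisible(path)
}
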