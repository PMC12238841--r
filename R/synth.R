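# Synthetic-data generator: germline fixtures, HLA sequences, motif-planted
# labelled binding data and 10x-style UMI tables. Everything the pipeline
# reads can be generated here, seeded, with controllable signal strength.

#' Synthetic-data configuration
#'
#' Defaults emulate the statistical structure of public binding data at desk
#' scale: a handful of V/J segments per locus, 8 epitopes with 75 cognate
#' TCRs each, per-epitope CDR3beta motifs planted with probability
#' \code{motif_strength}, skewed HLA usage, and peptide lengths concentrated
#' on 9-mers within the 8-12 window.
#'
#' @param n_v,n_j Germline V/J segments per locus.
#' @param n_epitopes Number of epitopes (distinct peptides).
#' @param tcrs_per_epitope Cognate TCRs per epitope.
#' @param motif_len Length of the planted CDR3beta motif.
#' @param motif_strength Probability in \code{[0,1]} that a binder's
#'   CDR3beta carries its epitope's motif uncorrupted.
#' @param n_families Number of motif families; epitopes in the same family
#'   share a motif and have similar peptides (1-residue variants), so
#'   \code{n_families < n_epitopes} creates cross-epitope similarity
#'   structure. Default: one family per epitope (no sharing).
#' @param n_hla Number of HLA alleles in play.
#' @param hla_freqs Optional frequency vector (length \code{n_hla}, sums to
#'   1); default is a skewed geometric-like profile.
#' @param peptide_len_probs Probabilities of peptide lengths 8..12.
#' @param dominant Give the first epitope half of all positives (exercises
#'   top-epitope downsampling).
#' @param seed Integer seed, recorded in all outputs.
#' @return A validated list of class \code{"SynthConfig"}.
#' @export
synthConfig <- function(n_v = 6L, n_j = 4L, n_epitopes = 8L,
                        tcrs_per_epitope = 75L, motif_len = 4L,
                        motif_strength = 1.0, n_families = n_epitopes,
                        n_hla = 4L, hla_freqs = NULL,
                        peptide_len_probs = c(0.15, 0.5, 0.15, 0.1, 0.1),
                        dominant = FALSE, seed = 1L) {
  if (is.null(hla_freqs)) {
    w <- 0.5^(seq_len(n_hla) - 1L)
    hla_freqs <- w / sum(w)
  }
  stopifnot(length(hla_freqs) == n_hla,
            abs(sum(hla_freqs) - 1) < 1e-8,
            motif_strength >= 0, motif_strength <= 1,
            length(peptide_len_probs) == 5L,
            n_families >= 1L, n_families <= n_epitopes)
  structure(list(n_v = as.integer(n_v), n_j = as.integer(n_j),
                 n_epitopes = as.integer(n_epitopes),
                 tcrs_per_epitope = as.integer(tcrs_per_epitope),
                 motif_len = as.integer(motif_len),
                 motif_strength = motif_strength,
                 n_families = as.integer(n_families),
                 n_hla = as.integer(n_hla), hla_freqs = hla_freqs,
                 peptide_len_probs = peptide_len_probs / sum(peptide_len_probs),
                 dominant = dominant, seed = as.integer(seed)),
            class = "SynthConfig")
}

.rand_aa <- function(rng, n) {
  paste(standardAminoAcids()[.sample_int(rng, 20L, n, replace = TRUE)],
        collapse = "")
}

#' Generate a synthetic germline V/J reference
#'
#' V segments are 80-100 random residues ending in the conserved Cys anchor
#' with annotated CDR1/CDR2 spans; J segments are 12-18 residues containing
#' an F-G-X-G motif with the anchor on the Phe. Names follow IMGT-style
#' \code{TRxV#*01} / \code{TRxJ#*01}.
#'
#' @param cfg A [synthConfig()].
#' @return A [GermlineDb-class].
#' @export
genGermlineDb <- function(cfg = synthConfig()) {
  rng <- .seeded_rng(.child_seed(cfg$seed, 10L))
  rows <- list()
  for (locus in c("TRA", "TRB")) {
    for (i in seq_len(cfg$n_v)) {
      len <- 79L + .sample_int(rng, 21L, 1L)      # 80..100
      aa <- paste0(.rand_aa(rng, len - 1L), "C")  # anchor Cys at the end
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("%sV%d*01", locus, i), locus = locus,
        segment_type = "V", aa = aa, anchor = len,
        cdr1_start = 27L, cdr1_end = 32L,
        cdr2_start = 48L, cdr2_end = 55L, stringsAsFactors = FALSE)
    }
    for (i in seq_len(cfg$n_j)) {
      len <- 11L + .sample_int(rng, 7L, 1L)       # 12..18
      anchor <- 1L + .sample_int(rng, len - 4L, 1L)
      xres <- standardAminoAcids()[.sample_int(rng, 20L, 1L)]
      aa <- paste0(.rand_aa(rng, anchor - 1L), "FG", xres, "G",
                   .rand_aa(rng, len - anchor - 3L))
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("%sJ%d*01", locus, i), locus = locus,
        segment_type = "J", aa = aa, anchor = anchor,
        cdr1_start = NA_integer_, cdr1_end = NA_integer_,
        cdr2_start = NA_integer_, cdr2_end = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  new("GermlineDb", segments = do.call(rbind, rows))
}

#' Generate synthetic HLA heavy-chain sequences
#'
#' Random 190-residue stand-ins for mature HLA class I heavy chains, keyed
#' by the most frequent alleles of the packaged frequency table. These are
#' synthetic sequences for desk-scale testing, not real HLA alleles.
#'
#' @param cfg A [synthConfig()].
#' @param path Optional FASTA output path.
#' @return Named character vector of sequences (invisibly also written to
#'   \code{path} when given).
#' @export
genHlaFasta <- function(cfg = synthConfig(), path = NULL) {
  rng <- .seeded_rng(.child_seed(cfg$seed, 11L))
  freq <- hlaFrequencyTable()
  freq <- freq[order(-freq$frequency, freq$allele), ]
  alleles <- freq$allele[seq_len(cfg$n_hla)]
  seqs <- vapply(alleles, function(a) .rand_aa(rng, 190L), character(1))
  if (!is.null(path)) {
    x <- Biostrings::AAStringSet(seqs)
    names(x) <- alleles
    Biostrings::writeXStringSet(x, path, width = 80L)
  }
  invisible(seqs)
}

.gen_cdr3 <- function(rng, v_anchor_aa = "C", motif = NULL) {
  core_len <- 8L + .sample_int(rng, 5L, 1L)  # core 9..13 -> CDR3 11..15
  core <- .rand_aa(rng, core_len)
  if (!is.null(motif)) {
    if (nchar(motif) > core_len - 2L)
      stop("motif longer than the CDR3 core")
    # plant inside the trimmed core (offsets avoid the first/last residues
    # so the motif survives TCRdist-style trimming)
    at <- 1L + .sample_int(rng, core_len - nchar(motif) - 1L, 1L)
    substr(core, at, at + nchar(motif) - 1L) <- motif
  }
  paste0("C", core, "F")
}

.mutate_peptide <- function(rng, pep, n_sub = 1L) {
  chars <- strsplit(pep, "")[[1]]
  pos <- .sample_int(rng, length(chars), n_sub)
  chars[pos] <- standardAminoAcids()[.sample_int(rng, 20L, n_sub,
                                                 replace = TRUE)]
  paste(chars, collapse = "")
}

#' Generate a motif-planted positive binding dataset
#'
#' Per epitope: a peptide (length drawn from the configured distribution),
#' an HLA allele drawn from the frequency vector, a CDR3beta motif, and
#' \code{tcrs_per_epitope} TCRs whose CDR3beta embeds the motif with
#' probability \code{motif_strength} (otherwise fully random). Epitopes in
#' the same family share their motif and have 1-residue-variant peptides.
#' In \code{dominant} mode the first epitope receives as many positives as
#' all others combined, mimicking a dataset dominated by one CMV epitope.
#'
#' @param cfg A [synthConfig()].
#' @param db Optional [GermlineDb-class] (default generated from
#'   \code{cfg}).
#' @return A list with \code{set} (a binder-only [BindingRecordSet-class]),
#'   \code{truth} (epitope table: peptide, hla, motif, family) and
#'   \code{motif_carried} (logical per record).
#' @export
genBindingDataset <- function(cfg = synthConfig(), db = NULL) {
  if (is.null(db)) db <- genGermlineDb(cfg)
  rng <- .seeded_rng(.child_seed(cfg$seed, 12L))
  freq <- hlaFrequencyTable()
  freq <- freq[order(-freq$frequency, freq$allele), ]
  alleles <- freq$allele[seq_len(cfg$n_hla)]

  fam_of <- rep(seq_len(cfg$n_families), length.out = cfg$n_epitopes)
  fam_motif <- vapply(seq_len(cfg$n_families),
                      function(i) .rand_aa(rng, cfg$motif_len), character(1))
  fam_pep <- vapply(seq_len(cfg$n_families), function(i) {
    len <- (8:12)[.with_rng(rng, sample.int(5L, 1L,
                                            prob = cfg$peptide_len_probs))]
    .rand_aa(rng, len)
  }, character(1))

  peptide <- character(cfg$n_epitopes)
  for (e in seq_len(cfg$n_epitopes)) {
    base <- fam_pep[fam_of[e]]
    first_in_fam <- which(fam_of == fam_of[e])[1L] == e
    peptide[e] <- if (first_in_fam) base else .mutate_peptide(rng, base, 1L)
  }
  # resolve accidental collisions between epitope peptides
  while (anyDuplicated(peptide)) {
    d <- which(duplicated(peptide))[1L]
    peptide[d] <- .mutate_peptide(rng, peptide[d], 1L)
  }
  hla <- alleles[.with_rng(rng, sample.int(cfg$n_hla, cfg$n_epitopes,
                                           replace = TRUE,
                                           prob = cfg$hla_freqs))]
  truth <- data.frame(epitope = seq_len(cfg$n_epitopes),
                      peptide = peptide, hla = hla,
                      motif = fam_motif[fam_of], family = fam_of,
                      stringsAsFactors = FALSE)

  n_per <- rep(cfg$tcrs_per_epitope, cfg$n_epitopes)
  if (cfg$dominant && cfg$n_epitopes >= 2L)
    n_per[1L] <- sum(n_per[-1L])

  segs <- segments(db)
  pick <- function(locus, type) {
    nm <- segs$name[segs$locus == locus & segs$segment_type == type]
    nm[.sample_int(rng, length(nm), 1L)]
  }
  rows <- vector("list", sum(n_per))
  carried <- logical(sum(n_per))
  r <- 0L
  for (e in seq_len(cfg$n_epitopes)) {
    for (i in seq_len(n_per[e])) {
      r <- r + 1L
      with_motif <- .runif(rng, 1L) < cfg$motif_strength
      carried[r] <- with_motif
      rows[[r]] <- data.frame(
        alpha_v = pick("TRA", "V"), alpha_j = pick("TRA", "J"),
        alpha_cdr3 = .gen_cdr3(rng),
        beta_v = pick("TRB", "V"), beta_j = pick("TRB", "J"),
        beta_cdr3 = .gen_cdr3(rng, motif = if (with_motif)
          truth$motif[e] else NULL),
        peptide = truth$peptide[e], hla_allele = truth$hla[e],
        label = "binder", source = "synthetic",
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  # motif-free CDR3s may still contain a motif by chance; the truth flag
  # records the planting decision, not the realized occurrence
  list(set = bindingRecordSet(df), truth = truth, motif_carried = carried)
}

#' Generate a 10x-style UMI count table with known truth
#'
#' Negative-control counts are Poisson(\code{lambda_bg}) in every cell; a
#' seeded half of the cells are true binders of one cognate peptide whose
#' count is Poisson(\code{lambda_bg + effect * sqrt(lambda_bg)}), i.e.
#' \code{effect} is the mean binder excess in background-SD units. All other
#' peptide counts are background.
#'
#' @param n_cells,n_peptides Table dimensions (peptides exclude the
#'   negative-control column, which is added as \code{"negctrl"}).
#' @param effect Mean binder excess in SD units (>= 0).
#' @param lambda_bg Background Poisson mean.
#' @param binder_frac Fraction of cells that truly bind their cognate
#'   peptide.
#' @param seed Integer seed.
#' @return A list with \code{umi} (integer matrix, rows = barcodes) and
#'   \code{truth} (logical matrix of true binding flags, same shape minus
#'   the control column).
#' @export
genUmiTable <- function(n_cells = 500L, n_peptides = 4L, effect = 6,
                        lambda_bg = 10, binder_frac = 0.5, seed = 1L) {
  stopifnot(effect >= 0)
  rng <- .seeded_rng(seed)
  peptide_names <- sprintf("pep%02d", seq_len(n_peptides))
  barcodes <- sprintf("cell%04d", seq_len(n_cells))
  umi <- matrix(.rpois(rng, n_cells * (n_peptides + 1L), lambda_bg),
                n_cells, n_peptides + 1L,
                dimnames = list(barcodes, c(peptide_names, "negctrl")))
  truth <- matrix(FALSE, n_cells, n_peptides,
                  dimnames = list(barcodes, peptide_names))
  n_bind <- round(binder_frac * n_cells)
  if (n_bind > 0L) {
    binders <- .sample_int(rng, n_cells, n_bind)
    cognate <- .sample_int(rng, n_peptides, n_bind, replace = TRUE)
    lam <- lambda_bg + effect * sqrt(lambda_bg)
    umi[cbind(binders, cognate)] <- .rpois(rng, n_bind, lam)
    truth[cbind(binders, cognate)] <- TRUE
  }
  list(umi = umi, truth = truth)
}

#' Generate a single-cell chain table with known pairing artefacts
#'
#' Produces productive, high-confidence chain rows per cell: most cells get
#' exactly one TRA and one TRB; configurable fractions get extra chains
#' (dual-receptor/doublet artefacts) or a single chain.
#'
#' @param n_cells Number of barcodes.
#' @param db A [GermlineDb-class] naming the V/J pools.
#' @param extra_frac Fraction of cells with a third chain.
#' @param single_frac Fraction with only one chain.
#' @param seed Integer seed.
#' @return A \code{data.frame} in the layout [selectPairedCells()] expects.
#' @export
genCellChainTable <- function(n_cells = 100L, db = genGermlineDb(),
                              extra_frac = 0.1, single_frac = 0.05,
                              seed = 1L) {
  rng <- .seeded_rng(seed)
  segs <- segments(db)
  pick <- function(locus, type) {
    nm <- segs$name[segs$locus == locus & segs$segment_type == type]
    nm[.sample_int(rng, length(nm), 1L)]
  }
  chain_row <- function(bc, locus) data.frame(
    barcode = bc, locus = locus,
    v_call = pick(locus, "V"), j_call = pick(locus, "J"),
    cdr3_aa = .gen_cdr3(rng), productive = TRUE, high_confidence = TRUE,
    stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(n_cells)) {
    bc <- sprintf("cell%04d", i)
    u <- .runif(rng, 1L)
    if (u < single_frac) {
      rows[[length(rows) + 1L]] <- chain_row(bc, "TRB")
    } else {
      rows[[length(rows) + 1L]] <- chain_row(bc, "TRA")
      rows[[length(rows) + 1L]] <- chain_row(bc, "TRB")
      if (u < single_frac + extra_frac)
        rows[[length(rows) + 1L]] <-
          chain_row(bc, c("TRA", "TRB")[.sample_int(rng, 2L, 1L)])
    }
  }
  do.call(rbind, rows)
}
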