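#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' \code{(number of positive-negative pairs ranked correctly + half the
#' ties) / (n_pos * n_neg)}, computed from ranks.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (1/\code{"binder"} = positive).
#' @return AUC in \code{[0, 1]}.
#' @export
#' @examples
#' aucScore(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))  # 0.75
aucScore <- function(scores, labels) {
  y <- if (is.character(labels)) as.integer(labels == "binder")
       else as.integer(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0L, 1L)))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes required to compute AUC")
  r <- rank(scores)            # midranks handle ties as half-wins
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Null AUC distribution of a random model
#'
#' Draws every record's prediction from uniform[0,1] and computes the AUC
#' against the true labels, repeated \code{n_reps} times with a seeded
#' stream; the reference distribution for "no better than random".
#'
#' @param labels Binary labels of the test fold.
#' @param n_reps Number of replicates (default 1000).
#' @param seed Integer seed.
#' @return Numeric vector of \code{n_reps} AUC values.
#' @export
randomNull <- function(labels, n_reps = 1000L, seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be at least 1")
  y <- if (is.character(labels)) as.integer(labels == "binder")
       else as.integer(labels)
  n <- length(y)
  rng <- .seeded_rng(seed)
  vapply(seq_len(n_reps),
         function(i) aucScore(.runif(rng, n), y), numeric(1))
}

#' Mean and 95\% percentile interval of a null AUC distribution
#'
#' @param null_aucs Numeric vector (at least 2 values).
#' @return A list with \code{mean}, \code{lo} (2.5th percentile) and
#'   \code{hi} (97.5th percentile), linear-interpolation percentile rule.
#' @export
nullInterval <- function(null_aucs) {
  if (length(null_aucs) < 2L) stop("need at least 2 null AUC values")
  q <- stats::quantile(null_aucs, c(0.025, 0.975), names = FALSE, type = 7)
  list(mean = mean(null_aucs), lo = q[1], hi = q[2])
}

#' Empirical significance of a model AUC against the random null
#'
#' Primary definition: the add-one empirical upper-tail p-value
#' \code{(1 + #\{null >= model\}) / (1 + n_null)} (one-sided,
#' better-than-random); the lower tail is reported symmetrically so
#' worse-than-random behaviour is visible too. A secondary bootstrap mode
#' resamples the fold's records with replacement \code{n_boot} times to
#' produce a model-AUC distribution and reports the fraction of bootstrap
#' AUCs at or below the null's 97.5th percentile.
#'
#' @param model_auc Observed model AUC.
#' @param null_aucs Null distribution from [randomNull()].
#' @param alpha Significance level for the flag (default 0.05).
#' @param scores,labels Optional fold scores/labels enabling the bootstrap
#'   mode.
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed Seed for the bootstrap.
#' @return A list with \code{p} (upper-tail), \code{p_lower},
#'   \code{significant} (\code{p < alpha}) and, when scores are supplied,
#'   \code{p_boot}.
#' @export
significance <- function(model_auc, null_aucs, alpha = 0.05,
                         scores = NULL, labels = NULL,
                         n_boot = 10000L, seed = 1L) {
  if (length(null_aucs) == 0L) stop("empty null distribution")
  p <- (1 + sum(null_aucs >= model_auc)) / (1 + length(null_aucs))
  p_lower <- (1 + sum(null_aucs <= model_auc)) / (1 + length(null_aucs))
  out <- list(p = p, p_lower = p_lower, significant = p < alpha)
  if (!is.null(scores)) {
    y <- if (is.character(labels)) as.integer(labels == "binder")
         else as.integer(labels)
    rng <- .seeded_rng(seed)
    hi <- stats::quantile(null_aucs, 0.975, names = FALSE, type = 7)
    n <- length(scores)
    boot <- vapply(seq_len(n_boot), function(i) {
      idx <- .sample_int(rng, n, n, replace = TRUE)
      if (length(unique(y[idx])) < 2L) return(NA_real_)
      aucScore(scores[idx], y[idx])
    }, numeric(1))
    boot <- boot[!is.na(boot)]
    out$p_boot <- mean(boot <= hi)
  }
  out
}

#' Evaluate predictions over a peptide-holdout plan
#'
#' For each fold: the model AUC on the held-out peptide's records, the
#' random-model null mean and 95\% interval, and the empirical p-value of
#' the model against that null.
#'
#' @param plan A [SplitPlan-class].
#' @param set The [BindingRecordSet-class] the plan indexes.
#' @param scores Per-record scores aligned with \code{set}.
#' @param n_reps Null replicates per fold (default 1000).
#' @param seed Base seed (each fold uses a derived child seed).
#' @param alpha Significance level.
#' @return A \code{data.frame} of class \code{"EvalReport"} with one row per
#'   held-out peptide: \code{peptide, n_records, auc, null_mean, null_lo,
#'   null_hi, p, significant}.
#' @export
evaluateFolds <- function(plan, set, scores, n_reps = 1000L, seed = 1L,
                          alpha = 0.05) {
  labs <- labels(set)
  rows <- lapply(seq_along(folds(plan)), function(i) {
    f <- folds(plan)[[i]]
    y <- labs[f$test_idx]
    s <- scores[f$test_idx]
    a <- aucScore(s, y)
    null <- randomNull(y, n_reps, seed = .child_seed(seed, i))
    ci <- nullInterval(null)
    sig <- significance(a, null, alpha)
    data.frame(peptide = f$peptide, n_records = length(f$test_idx),
               auc = a, null_mean = ci$mean, null_lo = ci$lo,
               null_hi = ci$hi, p = sig$p,
               significant = sig$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("EvalReport", "data.frame")
  out
}

#' Write an evaluation report as TSV and JSON
#'
#' @param report From [evaluateFolds()].
#' @param path Output path without extension; \code{.tsv} and \code{.json}
#'   files are written.
#' @return The two paths, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  tsv <- paste0(path, ".tsv")
  jsn <- paste0(path, ".json")
  utils::write.table(report, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(report, jsn, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(c(tsv, jsn))
}
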