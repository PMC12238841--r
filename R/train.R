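# Masked-LM pretraining, binary finetuning and prediction on top of the
# encoder in nn.R.

# BERT-style masking: each residue token is selected with prob mask_rate;
# of the selected, 80% become [mask], 10% a random amino acid, 10% stay.
# Special and prefix tokens are never selected. Returns the corrupted ids
# and the selected positions with their original amino-acid classes.
.mask_tokens <- function(ids, vocab, mask_rate, rng) {
  B <- nrow(ids); L <- ncol(ids)
  is_res <- ids >= vocab$aa_first
  sel <- matrix(FALSE, B, L)
  u <- matrix(.runif(rng, B * L), B, L)
  sel[is_res & u < mask_rate] <- TRUE
  for (b in seq_len(B)) {       # guarantee at least one target per sequence
    if (!any(sel[b, ]) && any(is_res[b, ])) {
      cand <- which(is_res[b, ])
      sel[b, cand[.sample_int(rng, length(cand), 1L)]] <- TRUE
    }
  }
  corrupted <- ids
  pos <- which(sel)
  u2 <- .runif(rng, length(pos))
  to_mask <- pos[u2 < 0.8]
  to_rand <- pos[u2 >= 0.8 & u2 < 0.9]
  corrupted[to_mask] <- vocab$id[["[mask]"]]
  if (length(to_rand) > 0L)
    corrupted[to_rand] <- vocab$aa_first - 1L +
      .sample_int(rng, 20L, length(to_rand), replace = TRUE)
  # targets in the row-grouped order of the hidden-state layout, matching
  # how the loss gathers selected positions
  list(ids = corrupted, sel = sel,
       targets = as.vector(t(ids))[as.vector(t(sel))] -
         vocab$aa_first + 1L)
}

# cross-entropy over the 20 amino-acid classes at the selected positions;
# returns loss, gradient w.r.t. final hidden states and head gradients
.mlm_loss_grad <- function(p, Xf, cache, sel, targets) {
  B <- cache$B; L <- cache$L
  sel_rows <- which(as.vector(t(sel)))   # row-grouped layout (b-1)*L + t
  Xs <- Xf[sel_rows, , drop = FALSE]
  logits <- .add_bias(Xs %*% p$mlm_W, p$mlm_b)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  n <- length(targets)
  pick <- cbind(seq_len(n), targets)
  loss <- -mean(log(pmax(probs[pick], 1e-12)))
  dlogits <- probs
  dlogits[pick] <- dlogits[pick] - 1
  dlogits <- dlogits / n
  dXf <- matrix(0, nrow(Xf), ncol(Xf))
  dXf[sel_rows, ] <- dlogits %*% t(p$mlm_W)
  list(loss = loss, dXf = dXf,
       g_mlm_W = t(Xs) %*% dlogits, g_mlm_b = colSums(dlogits))
}

.cls_rows <- function(B, L) ((seq_len(B) - 1L) * L) + 1L

.cls_loss_grad <- function(p, Xf, B, L, y) {
  rows <- .cls_rows(B, L)
  Xc <- Xf[rows, , drop = FALSE]
  z <- as.vector(Xc %*% p$cls_w) + p$cls_b
  pr <- 1 / (1 + exp(-z))
  loss <- -mean(y * log(pmax(pr, 1e-12)) +
                  (1 - y) * log(pmax(1 - pr, 1e-12)))
  dz <- (pr - y) / B
  dXf <- matrix(0, nrow(Xf), ncol(Xf))
  dXf[rows, ] <- outer(dz, as.vector(p$cls_w))
  list(loss = loss, dXf = dXf,
       g_cls_w = t(Xc) %*% matrix(dz, ncol = 1L), g_cls_b = sum(dz))
}

#' Masked-LM loss of an encoder on a token batch
#'
#' Applies seeded masking and computes the mean cross-entropy per masked
#' position over the 20 amino-acid classes, without updating the model. At
#' random initialization this is close to \code{log(20)} (a uniform guess).
#'
#' @param encoder An encoder from [initEncoder()] or [pretrainMlm()].
#' @param ids Integer token matrix (rows = sequences).
#' @param seed Masking seed.
#' @return The scalar loss.
#' @export
mlmLoss <- function(encoder, ids, seed = 0L) {
  cfg <- attr(encoder, "cfg")
  vocab <- attr(encoder, "vocab")
  rng <- .seeded_rng(seed)
  mk <- .mask_tokens(ids, vocab, cfg$mask_rate, rng)
  fw <- .enc_forward(encoder, mk$ids, cfg, need_cache = TRUE)
  .mlm_loss_grad(encoder, fw$Xf, fw$cache, mk$sel, mk$targets)$loss
}

#' Pretrain the encoder with masked language modelling
#'
#' Trains on unlabelled token sequences (typically paired-chain sequences
#' from [tokenizeChains()]): per batch, a seeded fraction of residue tokens
#' is selected, corrupted BERT-style, and the model is optimized (Adam) to
#' recover the original residues. Special and prefix tokens are never
#' selected as targets.
#'
#' @param corpus Integer token matrix, one sequence per row; needs at least
#'   \code{cfg$batch} rows.
#' @param cfg A [modelConfig()].
#' @param encoder Optional warm-start encoder; default fresh
#'   [initEncoder()].
#' @return A list with \code{encoder} (trained parameters) and \code{loss}
#'   (per-epoch mean masked-LM loss).
#' @export
pretrainMlm <- function(corpus, cfg = modelConfig(), encoder = NULL) {
  corpus <- as.matrix(corpus)
  if (nrow(corpus) < cfg$batch)
    stop("corpus (", nrow(corpus), " sequences) is shorter than one batch (",
         cfg$batch, ")")
  if (is.null(encoder)) encoder <- initEncoder(cfg)
  vocab <- attr(encoder, "vocab")
  rng <- .seeded_rng(.child_seed(cfg$seed, 1L))
  st <- .adam_init(encoder)
  trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- .sample_int(rng, nrow(corpus), nrow(corpus))
    losses <- c()
    for (start in seq(1L, nrow(corpus), by = cfg$batch)) {
      idx <- ord[start:min(start + cfg$batch - 1L, nrow(corpus))]
      ids <- corpus[idx, , drop = FALSE]
      mk <- .mask_tokens(ids, vocab, cfg$mask_rate, rng)
      fw <- .enc_forward(encoder, mk$ids, cfg, need_cache = TRUE,
                         train = TRUE, rng = rng)
      lg <- .mlm_loss_grad(encoder, fw$Xf, fw$cache, mk$sel, mk$targets)
      gr <- .enc_backward(encoder, fw$cache, lg$dXf, cfg)
      gr$mlm_W <- lg$g_mlm_W
      gr$mlm_b <- lg$g_mlm_b
      up <- .adam_step(encoder, gr, st, cfg$lr,
                       weight_decay = cfg$weight_decay)
      encoder <- up$p; st <- up$st
      losses <- c(losses, lg$loss)
    }
    trace[ep] <- mean(losses)
  }
  list(encoder = encoder, loss = trace)
}

#' Finetune a binary binding classifier
#'
#' Puts a logistic head on the \code{[cls]} state of the (optionally
#' pretrained) encoder and trains the whole network on labelled records with
#' binary cross-entropy. Training is deterministic given the config seed.
#'
#' @param ids Integer token matrix from [tokenizeSet()].
#' @param y Binary labels (1 = binder), one per row of \code{ids}.
#' @param cfg A [modelConfig()].
#' @param encoder Optional pretrained encoder; default random
#'   initialization (the \code{pretrained} flag in the returned metadata
#'   records which was used).
#' @return A list of class \code{"tcrbindClassifier"} with \code{encoder},
#'   \code{cfg}, \code{loss} (per-epoch mean) and \code{meta}.
#' @export
finetune <- function(ids, y, cfg = modelConfig(), encoder = NULL) {
  ids <- as.matrix(ids)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(ids))
  if (length(unique(y)) < 2L)
    stop("single-class training set: both binders and non-binders required")
  pretrained <- !is.null(encoder)
  if (is.null(encoder)) encoder <- initEncoder(cfg)
  rng <- .seeded_rng(.child_seed(cfg$seed, 2L))
  st <- .adam_init(encoder)
  trace <- numeric(cfg$epochs)
  n <- nrow(ids)
  for (ep in seq_len(cfg$epochs)) {
    ord <- .sample_int(rng, n, n)
    losses <- c()
    for (start in seq(1L, n, by = cfg$batch)) {
      idx <- ord[start:min(start + cfg$batch - 1L, n)]
      xb <- ids[idx, , drop = FALSE]
      fw <- .enc_forward(encoder, xb, cfg, need_cache = TRUE,
                         train = TRUE, rng = rng)
      lg <- .cls_loss_grad(encoder, fw$Xf, nrow(xb), ncol(xb), y[idx])
      gr <- .enc_backward(encoder, fw$cache, lg$dXf, cfg)
      gr$cls_w <- lg$g_cls_w
      gr$cls_b <- lg$g_cls_b
      up <- .adam_step(encoder, gr, st, cfg$lr,
                       weight_decay = cfg$weight_decay)
      encoder <- up$p; st <- up$st
      losses <- c(losses, lg$loss)
    }
    trace[ep] <- mean(losses)
  }
  structure(list(encoder = encoder, cfg = cfg, loss = trace,
                 meta = list(pretrained = pretrained,
                             n_train = n, seed = cfg$seed)),
            class = "tcrbindClassifier")
}

#' Predict binding scores
#'
#' Runs the classifier over records (or a pre-tokenized matrix) and returns
#' the per-record sigmoid score in \code{[0, 1]}, order-aligned with the
#' input. Batched evaluation equals record-by-record evaluation.
#'
#' @param clf A classifier from [finetune()].
#' @param x A stitched [BindingRecordSet-class] or an integer token matrix.
#' @param batch Evaluation batch size.
#' @return Numeric score vector.
#' @export
predictScores <- function(clf, x, batch = 32L) {
  cfg <- clf$cfg
  ids <- if (is(x, "BindingRecordSet"))
    tokenizeSet(x, attr(clf$encoder, "vocab"), cfg$max_len)
  else as.matrix(x)
  n <- nrow(ids)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    fw <- .enc_forward(clf$encoder, ids[idx, , drop = FALSE], cfg)
    rows <- .cls_rows(length(idx), ncol(ids))
    z <- as.vector(fw$Xf[rows, , drop = FALSE] %*% clf$encoder$cls_w) +
      clf$encoder$cls_b
    out[idx] <- 1 / (1 + exp(-z))
  }
  out
}

#' Save / load a model directory
#'
#' The model is stored as plain text: \code{manifest.json} (config,
#' vocabulary, metadata) and \code{weights.json} (full-precision parameter
#' arrays with dimensions).
#'
#' @param clf A \code{"tcrbindClassifier"} (or the \code{encoder} element of
#'   [pretrainMlm()] output wrapped by [finetune()]).
#' @param dir Directory to create/read.
#' @return \code{saveModel}: \code{dir} invisibly; \code{loadModel}: the
#'   classifier.
#' @export
saveModel <- function(clf, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  enc <- clf$encoder
  vocab <- attr(enc, "vocab")
  jsonlite::write_json(
    list(config = unclass(clf$cfg), tokens = vocab$tokens,
         meta = clf$meta, loss = clf$loss),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  weights <- lapply(enc, function(w)
    list(dim = if (is.matrix(w)) dim(w) else length(w),
         data = as.vector(w)))
  jsonlite::write_json(weights, file.path(dir, "weights.json"),
                       digits = NA, auto_unbox = FALSE)
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  cfg <- do.call(modelConfig, as.list(man$config))
  vocab <- aaVocabulary()
  if (!identical(vocab$tokens, man$tokens))
    stop("saved vocabulary does not match this package version")
  weights <- jsonlite::read_json(file.path(dir, "weights.json"),
                                 simplifyVector = TRUE)
  enc <- lapply(weights, function(w) {
    if (length(w$dim) == 2L) matrix(w$data, w$dim[1], w$dim[2])
    else if (identical(as.integer(w$dim), 1L)) w$data[[1]]
    else as.numeric(w$data)
  })
  attr(enc, "cfg") <- cfg
  attr(enc, "vocab") <- vocab
  class(enc) <- "tcrbindEncoder"
  structure(list(encoder = enc, cfg = cfg, loss = man$loss,
                 meta = as.list(man$meta)),
            class = "tcrbindClassifier")
}

#' Documented default training recipe for motif-planted benchmarks
#'
#' The configuration the package uses for its own desk-scale benchmark on
#' generator-default data (8 epitopes x 75 TCRs): the tiny encoder with 4
#' heads and a narrow relative-position window (k = 3, a local inductive
#' bias that suits short contiguous motifs), AdamW at 2e-3 with weight
#' decay 0.02 (suppresses pure memorization of unique CDR3s), batch 32,
#' 12 epochs. All fields can be overridden.
#'
#' @param ... Overrides passed to [modelConfig()].
#' @return A [modelConfig()].
#' @export
trainingDefaults <- function(...) {
  args <- list(heads = 4L, k = 3L, epochs = 12L, batch = 32L, lr = 2e-3,
               weight_decay = 0.02, max_len = 128L)
  over <- list(...)
  args[names(over)] <- over
  do.call(modelConfig, args)
}
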