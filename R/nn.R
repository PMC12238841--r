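# Disentangled-attention encoder: forward and backward passes in base R
# matrix algebra. Hidden states are stored as a (B*L) x d matrix with rows
# grouped by example; attention runs per example and head.

#' Encoder/training configuration
#'
#' All sizes of the sequence model are configuration, not constants. The
#' tiny default (2 layers, 2 heads, hidden size 32) is chosen for desk-scale
#' training on a single CPU; the architecture scales through these fields
#' alone.
#'
#' @param layers Number of encoder blocks.
#' @param heads Attention heads; must divide \code{d}.
#' @param d Hidden size.
#' @param ff Feed-forward inner size.
#' @param k Relative-position window: offsets are clipped to \code{[-k, k]}.
#' @param max_len Padded sequence length.
#' @param dropout Dropout rate in \code{[0, 1)} applied to attention and
#'   feed-forward outputs during training.
#' @param mask_rate Masked-LM selection rate in \code{(0, 1)}.
#' @param lr Adam learning rate.
#' @param weight_decay Decoupled (AdamW) weight decay on weight matrices.
#' @param batch Minibatch size.
#' @param epochs Training epochs.
#' @param seed Integer seed controlling initialization, masking and
#'   shuffling.
#' @return A validated list of class \code{"ModelConfig"}.
#' @export
modelConfig <- function(layers = 2L, heads = 2L, d = 32L, ff = 64L,
                        k = 8L, max_len = 128L, dropout = 0,
                        mask_rate = 0.15, lr = 1e-3, weight_decay = 0,
                        batch = 16L, epochs = 10L, seed = 0L) {
  cfg <- list(layers = as.integer(layers), heads = as.integer(heads),
              d = as.integer(d), ff = as.integer(ff), k = as.integer(k),
              max_len = as.integer(max_len), dropout = dropout,
              mask_rate = mask_rate, lr = lr, weight_decay = weight_decay,
              batch = as.integer(batch),
              epochs = as.integer(epochs), seed = as.integer(seed))
  if (cfg$d %% cfg$heads != 0L)
    stop("hidden size must be divisible by the number of heads")
  if (cfg$k <= 0L) stop("relative-position window k must be positive")
  if (cfg$mask_rate <= 0 || cfg$mask_rate >= 1)
    stop("mask rate must lie in (0,1): nothing to learn otherwise")
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    stop("dropout must lie in [0,1)")
  class(cfg) <- "ModelConfig"
  cfg
}

.ln_eps <- 1e-5

# column-wise scale / shift without sweep's overhead (column-major recycle)
.scale_cols <- function(X, g) X * rep(g, each = nrow(X))
.shift_cols <- function(X, b) X + rep(b, each = nrow(X))

.ln_forward <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + .ln_eps)
  xn <- xc * inv
  list(out = .shift_cols(.scale_cols(xn, g), b), xn = xn, inv = inv)
}

.ln_backward <- function(dout, cache, g) {
  xn <- cache$xn
  dxn <- .scale_cols(dout, g)
  dx <- cache$inv * (dxn - rowMeans(dxn) - xn * rowMeans(dxn * xn))
  list(dx = dx, dg = colSums(dout * xn), db = colSums(dout))
}

.gelu <- function(x) gelu_cpp(x)
.dgelu <- function(x) dgelu_cpp(x)

# relative-position gather/scatter machinery for a fixed (L, k). Offsets are
# clipped to [-k, k]; the interior buckets each correspond to one diagonal
# of the L x L score matrix, and only the two clipped buckets pool several
# columns, which keeps both directions index-assignment cheap. Cached per
# (L, k).
.relidx <- function(L, k) {
  key <- paste0("rel_", L, "_", k)
  if (!is.null(.pkg_cache[[key]])) return(.pkg_cache[[key]])
  nb <- 2L * k + 1L
  D <- outer(seq_len(L), seq_len(L),
             function(i, j) pmin(pmax(j - i, -k), k) + k + 1L)
  ii <- rep(seq_len(L), times = L)     # column-major row indices
  dd <- as.vector(D)
  jj <- rep(seq_len(L), each = L)
  # per interior bucket: the (i, j) pairs on its diagonal
  diag_idx <- lapply(2:(nb - 1L), function(r) {
    delta <- r - k - 1L
    i <- seq_len(L)[seq_len(L) + delta >= 1L & seq_len(L) + delta <= L]
    cbind(i, i + delta)
  })
  low_mask <- matrix(as.numeric(dd == 1L), L, L)       # delta <= -k
  high_mask <- matrix(as.numeric(dd == nb), L, L)      # delta >= k
  Dm <- matrix(as.integer(dd), L, L)
  g <- list(nb = nb, L = L, k = k, gidx = cbind(ii, dd), Dm = Dm,
            diag_idx = diag_idx, low_mask = low_mask, high_mask = high_mask)
  .pkg_cache[[key]] <- g
  g
}

.rel_gather <- function(M, g) matrix(M[g$gidx], g$L, g$L)

.rel_scatter <- function(dS, g) {
  out <- matrix(0, g$L, g$nb)
  for (r in 2:(g$nb - 1L)) {
    idx <- g$diag_idx[[r - 1L]]
    out[cbind(idx[, 1L], r)] <- dS[idx]
  }
  out[, 1L] <- rowSums(dS * g$low_mask)
  out[, g$nb] <- rowSums(dS * g$high_mask)
  out
}

.row_max <- function(S) S[cbind(seq_len(nrow(S)), max.col(S, "first"))]

#' Disentangled self-attention over one sequence
#'
#' Scores position pairs with three terms: content-to-content, content-to-
#' relative-position (the query content against the key's relative position
#' embedding) and relative-position-to-content (the query position against
#' the key content), scaled by \code{sqrt(3 * d_head)} and row-softmaxed.
#' Relative offsets are clipped to \code{[-k, k]}. This standalone entry
#' point runs the same arithmetic as the encoder's internal attention and
#' exists so the mechanism can be inspected and checked in isolation.
#'
#' @param H Content states, an \code{L x d} matrix.
#' @param P Relative-position embeddings, a \code{(2k+1) x d} matrix (row
#'   \code{k+1} is offset 0).
#' @param Wq,Wk,Wv \code{d x d} projection matrices.
#' @param heads Number of attention heads.
#' @param k Relative-position window; must be positive.
#' @return A list with \code{out} (\code{L x d} attention-weighted states,
#'   heads concatenated) and \code{attn} (an \code{L x L x heads} array of
#'   attention weights).
#' @export
disentangledAttention <- function(H, P, Wq, Wk, Wv, heads = 1L, k) {
  if (k <= 0L) stop("relative-position window k must be positive")
  L <- nrow(H); d <- ncol(H); dh <- d %/% heads
  stopifnot(nrow(P) == 2L * k + 1L, d %% heads == 0L)
  g <- .relidx(L, as.integer(k))
  Q <- H %*% Wq; K <- H %*% Wk; V <- H %*% Wv
  Qr <- P %*% Wq; Kr <- P %*% Wk
  out <- matrix(0, L, d)
  attn <- array(0, c(L, L, heads))
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) +
      .rel_gather(Q[, cols, drop = FALSE] %*%
                    t(Kr[, cols, drop = FALSE]), g) +
      t(.rel_gather(K[, cols, drop = FALSE] %*%
                      t(Qr[, cols, drop = FALSE]), g))
    S <- S / sqrt(3 * dh)
    S <- S - .row_max(S)
    E <- exp(S)
    A <- E / rowSums(E)
    attn[, , h] <- A
    out[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  list(out = out, attn = attn)
}

# Xavier/Glorot initialization: keeps activation variance stable for the
# small hidden sizes used here
.init_mat <- function(rng, nr, nc, sd = sqrt(2 / (nr + nc))) {
  matrix(.rnorm(rng, nr * nc, sd = sd), nr, nc)
}

#' Initialize encoder parameters
#'
#' @param cfg A [modelConfig()].
#' @param vocab From [aaVocabulary()].
#' @return A flat named list of parameter matrices/vectors of class
#'   \code{"tcrbindEncoder"}; carries \code{cfg} and \code{vocab} as
#'   attributes.
#' @export
initEncoder <- function(cfg, vocab = aaVocabulary()) {
  rng <- .seeded_rng(cfg$seed)
  d <- cfg$d; ff <- cfg$ff; nb <- 2L * cfg$k + 1L
  p <- list(embed = .init_mat(rng, vocab$size, d, sd = 0.1))
  for (l in seq_len(cfg$layers)) {
    pre <- paste0("L", l, "_")
    p[[paste0(pre, "Wq")]] <- .init_mat(rng, d, d)
    p[[paste0(pre, "bq")]] <- numeric(d)
    p[[paste0(pre, "Wk")]] <- .init_mat(rng, d, d)
    p[[paste0(pre, "bk")]] <- numeric(d)
    p[[paste0(pre, "Wv")]] <- .init_mat(rng, d, d)
    p[[paste0(pre, "bv")]] <- numeric(d)
    p[[paste0(pre, "Wo")]] <- .init_mat(rng, d, d)
    p[[paste0(pre, "bo")]] <- numeric(d)
    p[[paste0(pre, "P")]] <- .init_mat(rng, nb, d)
    p[[paste0(pre, "ln1_g")]] <- rep(1, d)
    p[[paste0(pre, "ln1_b")]] <- numeric(d)
    p[[paste0(pre, "ln2_g")]] <- rep(1, d)
    p[[paste0(pre, "ln2_b")]] <- numeric(d)
    p[[paste0(pre, "W1")]] <- .init_mat(rng, d, ff)
    p[[paste0(pre, "b1")]] <- numeric(ff)
    p[[paste0(pre, "W2")]] <- .init_mat(rng, ff, d)
    p[[paste0(pre, "b2")]] <- numeric(d)
  }
  p$lnf_g <- rep(1, d)
  p$lnf_b <- numeric(d)
  # output heads start near zero so the initial predictions are uniform
  # (masked-LM loss ~ log 20) / uncommitted (score ~ 0.5)
  p$mlm_W <- .init_mat(rng, d, 20L, sd = 0.02)
  p$mlm_b <- numeric(20L)
  p$cls_w <- matrix(.rnorm(rng, d, sd = 0.02), d, 1L)
  p$cls_b <- 0
  attr(p, "cfg") <- cfg
  attr(p, "vocab") <- vocab
  class(p) <- "tcrbindEncoder"
  p
}

.add_bias <- function(X, b) .shift_cols(X, b)

# Forward pass. ids: B x L integer matrix (pad id 1). Returns final hidden
# states (B*L x d, rows grouped by example) and, if need_cache, everything
# the backward pass needs.
.enc_forward <- function(p, ids, cfg, need_cache = FALSE,
                         train = FALSE, rng = NULL) {
  B <- nrow(ids); L <- ncol(ids); d <- cfg$d
  H <- cfg$heads; dh <- d %/% H
  g <- .relidx(L, cfg$k)
  flat_ids <- as.vector(t(ids))
  X <- p$embed[flat_ids, , drop = FALSE]
  real <- ids != 1L
  realm <- matrix(as.integer(real), B, L)
  scale <- sqrt(3 * dh)
  cache <- if (need_cache) list(flat_ids = flat_ids, g = g, real = real,
                                layers = vector("list", cfg$layers))
  drop_p <- if (train) cfg$dropout else 0

  for (l in seq_len(cfg$layers)) {
    pre <- paste0("L", l, "_")
    c1 <- .ln_forward(X, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    Q <- .add_bias(c1$out %*% p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]])
    K <- .add_bias(c1$out %*% p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]])
    V <- .add_bias(c1$out %*% p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]])
    Qr <- p[[paste0(pre, "P")]] %*% p[[paste0(pre, "Wq")]]
    Kr <- p[[paste0(pre, "P")]] %*% p[[paste0(pre, "Wk")]]
    aw <- attn_forward_cpp(Q, K, V, Qr, Kr, g$Dm, realm, B, L, H, scale)
    O <- aw$O
    attn <- .add_bias(O %*% p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
    dm1 <- NULL
    if (drop_p > 0) {
      dm1 <- matrix(.runif(rng, length(attn)) >= drop_p,
                    nrow(attn), ncol(attn)) / (1 - drop_p)
      attn <- attn * dm1
    }
    Xmid <- X + attn
    c2 <- .ln_forward(Xmid, p[[paste0(pre, "ln2_g")]],
                      p[[paste0(pre, "ln2_b")]])
    H1pre <- .add_bias(c2$out %*% p[[paste0(pre, "W1")]],
                       p[[paste0(pre, "b1")]])
    H1 <- .gelu(H1pre)
    F2 <- .add_bias(H1 %*% p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
    dm2 <- NULL
    if (drop_p > 0) {
      dm2 <- matrix(.runif(rng, length(F2)) >= drop_p,
                    nrow(F2), ncol(F2)) / (1 - drop_p)
      F2 <- F2 * dm2
    }
    Xout <- Xmid + F2
    if (need_cache)
      cache$layers[[l]] <- list(Xin = X, c1 = c1, Q = Q, K = K, V = V,
                                Qr = Qr, Kr = Kr, O = O, A = aw$A,
                                dm1 = dm1, Xmid = Xmid, c2 = c2,
                                H1pre = H1pre, H1 = H1, dm2 = dm2)
    X <- Xout
  }
  cf <- .ln_forward(X, p$lnf_g, p$lnf_b)
  if (need_cache) {
    cache$cf <- cf
    cache$B <- B; cache$L <- L
  }
  list(Xf = cf$out, cache = cache)
}

# Backward pass: dXf is the gradient w.r.t. the final hidden states.
# Returns a flat named list of parameter gradients.
.enc_backward <- function(p, cache, dXf, cfg) {
  B <- cache$B; L <- cache$L; d <- cfg$d
  H <- cfg$heads; dh <- d %/% H
  g <- cache$g
  scale <- sqrt(3 * dh)
  gr <- list()

  bf <- .ln_backward(dXf, cache$cf, p$lnf_g)
  gr$lnf_g <- bf$dg; gr$lnf_b <- bf$db
  dX <- bf$dx

  for (l in rev(seq_len(cfg$layers))) {
    pre <- paste0("L", l, "_")
    lc <- cache$layers[[l]]

    # feed-forward branch
    dF2 <- if (is.null(lc$dm2)) dX else dX * lc$dm2
    gr[[paste0(pre, "W2")]] <- crossprod(lc$H1, dF2)
    gr[[paste0(pre, "b2")]] <- colSums(dF2)
    dH1 <- tcrossprod(dF2, p[[paste0(pre, "W2")]])
    dH1pre <- dH1 * .dgelu(lc$H1pre)
    gr[[paste0(pre, "W1")]] <- crossprod(lc$c2$out, dH1pre)
    gr[[paste0(pre, "b1")]] <- colSums(dH1pre)
    dXn2 <- tcrossprod(dH1pre, p[[paste0(pre, "W1")]])
    b2l <- .ln_backward(dXn2, lc$c2, p[[paste0(pre, "ln2_g")]])
    gr[[paste0(pre, "ln2_g")]] <- b2l$dg
    gr[[paste0(pre, "ln2_b")]] <- b2l$db
    dXmid <- dX + b2l$dx

    # attention branch
    dattn <- if (is.null(lc$dm1)) dXmid else dXmid * lc$dm1
    gr[[paste0(pre, "Wo")]] <- crossprod(lc$O, dattn)
    gr[[paste0(pre, "bo")]] <- colSums(dattn)
    dO <- tcrossprod(dattn, p[[paste0(pre, "Wo")]])

    ab <- attn_backward_cpp(lc$Q, lc$K, lc$V, lc$Qr, lc$Kr, g$Dm, lc$A,
                            dO, B, L, H, scale)
    dQ <- ab$dQ; dK <- ab$dK; dV <- ab$dV
    dQr <- ab$dQr; dKr <- ab$dKr
    Xn1 <- lc$c1$out
    Pm <- p[[paste0(pre, "P")]]
    gr[[paste0(pre, "Wq")]] <- crossprod(Xn1, dQ) + crossprod(Pm, dQr)
    gr[[paste0(pre, "bq")]] <- colSums(dQ)
    gr[[paste0(pre, "Wk")]] <- crossprod(Xn1, dK) + crossprod(Pm, dKr)
    gr[[paste0(pre, "bk")]] <- colSums(dK)
    gr[[paste0(pre, "Wv")]] <- crossprod(Xn1, dV)
    gr[[paste0(pre, "bv")]] <- colSums(dV)
    gr[[paste0(pre, "P")]] <- tcrossprod(dQr, p[[paste0(pre, "Wq")]]) +
      tcrossprod(dKr, p[[paste0(pre, "Wk")]])
    dXn1 <- tcrossprod(dQ, p[[paste0(pre, "Wq")]]) +
      tcrossprod(dK, p[[paste0(pre, "Wk")]]) +
      tcrossprod(dV, p[[paste0(pre, "Wv")]])
    b1l <- .ln_backward(dXn1, lc$c1, p[[paste0(pre, "ln1_g")]])
    gr[[paste0(pre, "ln1_g")]] <- b1l$dg
    gr[[paste0(pre, "ln1_b")]] <- b1l$db
    dX <- dXmid + b1l$dx
  }

  dE <- rowsum(dX, cache$flat_ids)
  dEmb <- matrix(0, nrow(p$embed), d)
  dEmb[as.integer(rownames(dE)), ] <- dE
  gr$embed <- dEmb
  gr
}

# Adam optimizer state and update over the flat parameter list
.adam_init <- function(p) {
  list(m = lapply(p, function(x) x * 0),
       v = lapply(p, function(x) x * 0),
       t = 0L)
}

.adam_step <- function(p, gr, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1L
  # decoupled (AdamW) decay on weight matrices only, never on biases,
  # LayerNorm parameters or the relative-position table
  decay <- weight_decay > 0
  for (nm in names(gr)) {
    gx <- gr[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gx
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gx * gx
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    upd <- mhat / (sqrt(vhat) + eps)
    if (decay && (nm == "embed" || nm == "cls_w" || grepl("_W", nm)))
      upd <- upd + weight_decay * p[[nm]]
    p[[nm]] <- p[[nm]] - lr * upd
  }
  list(p = p, st = st)
}
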