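# Temporal classifier: the 1-D session embedding is sliced into frame-width
# tokens with Fourier positions; a learned latent array cross-attends once
# (1 head) and is refined by three 8-head self-attention blocks, each
# followed by a residual GELU FCN; mean-pooled latents feed the linear
# class head. Forward and reverse passes are implemented together so the
# module can be trained without an autodiff framework.

#' @title Temporal classifier configuration
#' @slot internalDim internal width (128 at full size).
#' @slot crossHeads,selfHeads heads of the cross/self attention blocks.
#' @slot selfBlocks number of self-attention blocks (3).
#' @slot nLatents learned latent vectors.
#' @slot nClasses output classes (2 for the binary task, 5 multi-level).
#' @slot fourierBands Fourier position bands.
#' @slot fcnHidden FCN hidden width.
#' @slot dToken token width the embedding is sliced into (the per-frame
#'   embedding width, 100).
#' @exportClass TemporalConfig
setClass("TemporalConfig",
         representation(internalDim = "integer", crossHeads = "integer",
                        selfBlocks = "integer", selfHeads = "integer",
                        nLatents = "integer", nClasses = "integer",
                        fourierBands = "integer", fcnHidden = "integer",
                        dToken = "integer"),
         validity = function(object) {
           if (object@internalDim %% object@selfHeads != 0L)
             return("internalDim must be divisible by selfHeads")
           if (object@internalDim %% object@crossHeads != 0L)
             return("internalDim must be divisible by crossHeads")
           TRUE
         })

#' Construct a TemporalConfig
#'
#' Defaults give the full-size classifier (1.63 M parameters): width 128,
#' one 1-head cross-attention block, three 8-head self-attention blocks,
#' 32 latents, 16 Fourier bands, FCN hidden width 1304, 100-wide tokens.
#'
#' @param internalDim,crossHeads,selfBlocks,selfHeads,nLatents,nClasses,fourierBands,fcnHidden,dToken
#'   see the class slots.
#' @return A [TemporalConfig-class].
#' @export
temporalConfig <- function(internalDim = 128L, crossHeads = 1L,
                           selfBlocks = 3L, selfHeads = 8L, nLatents = 32L,
                           nClasses = 5L, fourierBands = 16L,
                           fcnHidden = 1304L, dToken = 100L) {
  methods::new("TemporalConfig", internalDim = as.integer(internalDim),
               crossHeads = as.integer(crossHeads),
               selfBlocks = as.integer(selfBlocks),
               selfHeads = as.integer(selfHeads),
               nLatents = as.integer(nLatents),
               nClasses = as.integer(nClasses),
               fourierBands = as.integer(fourierBands),
               fcnHidden = as.integer(fcnHidden), dToken = as.integer(dToken))
}

#' @title Temporal classifier module
#' @slot config a [TemporalConfig-class].
#' @slot weights flat named list of weight arrays.
#' @exportClass TemporalModule
setClass("TemporalModule",
         representation(config = "TemporalConfig", weights = "list"))

setMethod("nParameters", "TemporalModule",
          function(object) countWeights(object@weights))

#' Instantiate a temporal classifier
#' @param cfg a [TemporalConfig-class].
#' @param seed RNG seed.
#' @return A [TemporalModule-class].
#' @export
temporalModule <- function(cfg = temporalConfig(), seed = 1L) {
  d <- cfg@internalDim
  w <- withSeed(seed, {
    p <- list(tokW = initMat(cfg@dToken, d), tokB = numeric(d),
              fourW = initMat(2L * cfg@fourierBands + 1L, d),
              fourB = numeric(d),
              lnCtxG = rep(1, d), lnCtxB = numeric(d),
              lat = initMat(cfg@nLatents, d),
              c.ln1G = rep(1, d), c.ln1B = numeric(d),
              c.Wq = initMat(d, d), c.bq = numeric(d),
              c.Wk = initMat(d, d), c.bk = numeric(d),
              c.Wv = initMat(d, d), c.bv = numeric(d),
              c.Wo = initMat(d, d), c.bo = numeric(d),
              c.ln2G = rep(1, d), c.ln2B = numeric(d),
              c.W1 = initMat(d, cfg@fcnHidden), c.b1 = numeric(cfg@fcnHidden),
              c.W2 = initMat(cfg@fcnHidden, d), c.b2 = numeric(d))
    for (i in seq_len(cfg@selfBlocks)) {
      pre <- sprintf("s%d.", i)
      p[[paste0(pre, "ln1G")]] <- rep(1, d)
      p[[paste0(pre, "ln1B")]] <- numeric(d)
      p[[paste0(pre, "Wqkv")]] <- initMat(d, 3L * d)
      p[[paste0(pre, "bqkv")]] <- numeric(3L * d)
      p[[paste0(pre, "Wo")]] <- initMat(d, d)
      p[[paste0(pre, "bo")]] <- numeric(d)
      p[[paste0(pre, "ln2G")]] <- rep(1, d)
      p[[paste0(pre, "ln2B")]] <- numeric(d)
      p[[paste0(pre, "W1")]] <- initMat(d, cfg@fcnHidden)
      p[[paste0(pre, "b1")]] <- numeric(cfg@fcnHidden)
      p[[paste0(pre, "W2")]] <- initMat(cfg@fcnHidden, d)
      p[[paste0(pre, "b2")]] <- numeric(d)
    }
    p$lnFinG <- rep(1, d); p$lnFinB <- numeric(d)
    p$headW <- initMat(d, cfg@nClasses); p$headB <- numeric(cfg@nClasses)
    p
  })
  methods::new("TemporalModule", config = cfg, weights = w)
}

#' Slice an embedding into frame-width tokens with Fourier positions
#'
#' Reshapes the 1-D embedding into `ceiling(N / dToken)` consecutive
#' `dToken`-wide slices (zero-padded to a multiple; the padding amount is
#' reported), reconstituting the per-frame structure of the video
#' embedding so attention positions align with session time.
#'
#' @param e numeric embedding.
#' @param dToken token width.
#' @param fourierBands bands for the position features.
#' @return List with `tokens` (`T x dToken`), `positions`
#'   (`T x (2*bands+1)`) and `padded` (zeros appended).
#' @export
tokenizeEmbedding <- function(e, dToken = 100L, fourierBands = 16L) {
  N <- length(e)
  Tn <- as.integer(ceiling(N / dToken))
  pad <- as.integer(Tn * dToken - N)
  if (pad > 0L) e <- c(e, numeric(pad))
  list(tokens = matrix(e, Tn, dToken, byrow = TRUE),
       positions = fourierPositions(Tn, fourierBands), padded = pad)
}

# ---- forward with cache ------------------------------------------------

lnFwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  invstd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * invstd
  list(y = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, invstd = invstd)
}

lnBwd <- function(dy, cache, g) {
  dxhat <- sweep(dy, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- cache$invstd * (dxhat - m1 - cache$xhat * m2)
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

geluFwd <- function(x) list(y = x * stats::pnorm(x), x = x)
geluBwd <- function(dy, cache) {
  dy * (stats::pnorm(cache$x) + cache$x * stats::dnorm(cache$x))
}

# single-head-block attention forward over given Q,K,V column blocks
attnHeadsFwd <- function(Q, K, V, heads) {
  d <- ncol(Q); dh <- d %/% heads
  out <- matrix(0, nrow(Q), d)
  As <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    A <- softmaxRows(Q[, cols, drop = FALSE] %*%
                       t(K[, cols, drop = FALSE]) / sqrt(dh))
    out[, cols] <- A %*% V[, cols, drop = FALSE]
    As[[h]] <- A
  }
  list(out = out, As = As)
}

attnHeadsBwd <- function(dOut, Q, K, V, As, heads) {
  d <- ncol(Q); dh <- d %/% heads
  dQ <- matrix(0, nrow(Q), d); dK <- matrix(0, nrow(K), d)
  dV <- matrix(0, nrow(V), d)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    A <- As[[h]]
    dO <- dOut[, cols, drop = FALSE]
    dA <- dO %*% t(V[, cols, drop = FALSE])
    dV[, cols] <- t(A) %*% dO
    dS <- (dA - rowSums(dA * A)) * A
    dQ[, cols] <- dS %*% K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- t(dS) %*% Q[, cols, drop = FALSE] / sqrt(dh)
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

temporalForwardCache <- function(p, cfg, e) {
  tk <- tokenizeEmbedding(e, cfg@dToken, cfg@fourierBands)
  ctx0 <- tk$tokens %*% p$tokW + rep(p$tokB, each = nrow(tk$tokens)) +
    tk$positions %*% p$fourW + rep(p$fourB, each = nrow(tk$tokens))
  lnC <- lnFwd(ctx0, p$lnCtxG, p$lnCtxB)
  ctx <- lnC$y
  cache <- list(tk = tk, lnC = lnC, ctx = ctx)

  # cross-attention block: latents query the embedding tokens
  lat <- p$lat
  ln1 <- lnFwd(lat, p$c.ln1G, p$c.ln1B)
  Q <- ln1$y %*% p$c.Wq + rep(p$c.bq, each = nrow(lat))
  K <- ctx %*% p$c.Wk + rep(p$c.bk, each = nrow(ctx))
  V <- ctx %*% p$c.Wv + rep(p$c.bv, each = nrow(ctx))
  at <- attnHeadsFwd(Q, K, V, cfg@crossHeads)
  lat1 <- lat + at$out %*% p$c.Wo + rep(p$c.bo, each = nrow(lat))
  ln2 <- lnFwd(lat1, p$c.ln2G, p$c.ln2B)
  z1 <- ln2$y %*% p$c.W1 + rep(p$c.b1, each = nrow(lat1))
  g1 <- geluFwd(z1)
  lat2 <- lat1 + g1$y %*% p$c.W2 + rep(p$c.b2, each = nrow(lat1))
  cache$cross <- list(ln1 = ln1, Q = Q, K = K, V = V, at = at, lat1 = lat1,
                      ln2 = ln2, g1 = g1)

  # self-attention blocks over the latents
  lat <- lat2
  cache$selfB <- vector("list", cfg@selfBlocks)
  for (i in seq_len(cfg@selfBlocks)) {
    pre <- sprintf("s%d.", i)
    ln1 <- lnFwd(lat, p[[paste0(pre, "ln1G")]], p[[paste0(pre, "ln1B")]])
    qkv <- ln1$y %*% p[[paste0(pre, "Wqkv")]] +
      rep(p[[paste0(pre, "bqkv")]], each = nrow(lat))
    d <- cfg@internalDim
    at <- attnHeadsFwd(qkv[, 1:d, drop = FALSE],
                       qkv[, (d + 1):(2 * d), drop = FALSE],
                       qkv[, (2 * d + 1):(3 * d), drop = FALSE],
                       cfg@selfHeads)
    lat1 <- lat + at$out %*% p[[paste0(pre, "Wo")]] +
      rep(p[[paste0(pre, "bo")]], each = nrow(lat))
    ln2 <- lnFwd(lat1, p[[paste0(pre, "ln2G")]], p[[paste0(pre, "ln2B")]])
    z1 <- ln2$y %*% p[[paste0(pre, "W1")]] +
      rep(p[[paste0(pre, "b1")]], each = nrow(lat1))
    g1 <- geluFwd(z1)
    lat2 <- lat1 + g1$y %*% p[[paste0(pre, "W2")]] +
      rep(p[[paste0(pre, "b2")]], each = nrow(lat1))
    cache$selfB[[i]] <- list(latIn = lat, ln1 = ln1, qkv = qkv, at = at,
                             lat1 = lat1, ln2 = ln2, g1 = g1)
    lat <- lat2
  }

  lnF <- lnFwd(lat, p$lnFinG, p$lnFinB)
  pool <- colMeans(lnF$y)
  logits <- drop(pool %*% p$headW) + p$headB
  cache$latOut <- lat; cache$lnF <- lnF; cache$pool <- pool
  list(logits = logits, cache = cache)
}

temporalBackward <- function(p, cfg, cache, dlogits) {
  g <- list()
  L <- cfg@nLatents
  g$headW <- outer(cache$pool, dlogits)
  g$headB <- dlogits
  dpool <- drop(p$headW %*% dlogits)
  dlnFy <- matrix(rep(dpool / L, each = L), L)
  bl <- lnBwd(dlnFy, cache$lnF, p$lnFinG)
  g$lnFinG <- bl$dg; g$lnFinB <- bl$db
  dlat <- bl$dx

  for (i in rev(seq_len(cfg@selfBlocks))) {
    pre <- sprintf("s%d.", i)
    cb <- cache$selfB[[i]]
    d <- cfg@internalDim
    # FCN residual
    g[[paste0(pre, "W2")]] <- t(cb$g1$y) %*% dlat
    g[[paste0(pre, "b2")]] <- colSums(dlat)
    dg1 <- dlat %*% t(p[[paste0(pre, "W2")]])
    dz1 <- geluBwd(dg1, cb$g1)
    g[[paste0(pre, "W1")]] <- t(cb$ln2$y) %*% dz1
    g[[paste0(pre, "b1")]] <- colSums(dz1)
    dln2y <- dz1 %*% t(p[[paste0(pre, "W1")]])
    bl <- lnBwd(dln2y, cb$ln2, p[[paste0(pre, "ln2G")]])
    g[[paste0(pre, "ln2G")]] <- bl$dg; g[[paste0(pre, "ln2B")]] <- bl$db
    dlat1 <- dlat + bl$dx
    # attention residual
    g[[paste0(pre, "Wo")]] <- t(cb$at$out) %*% dlat1
    g[[paste0(pre, "bo")]] <- colSums(dlat1)
    dato <- dlat1 %*% t(p[[paste0(pre, "Wo")]])
    ab <- attnHeadsBwd(dato, cb$qkv[, 1:d, drop = FALSE],
                       cb$qkv[, (d + 1):(2 * d), drop = FALSE],
                       cb$qkv[, (2 * d + 1):(3 * d), drop = FALSE],
                       cb$at$As, cfg@selfHeads)
    dqkv <- cbind(ab$dQ, ab$dK, ab$dV)
    g[[paste0(pre, "Wqkv")]] <- t(cb$ln1$y) %*% dqkv
    g[[paste0(pre, "bqkv")]] <- colSums(dqkv)
    dln1y <- dqkv %*% t(p[[paste0(pre, "Wqkv")]])
    bl <- lnBwd(dln1y, cb$ln1, p[[paste0(pre, "ln1G")]])
    g[[paste0(pre, "ln1G")]] <- bl$dg; g[[paste0(pre, "ln1B")]] <- bl$db
    dlat <- dlat1 + bl$dx
  }

  # cross block
  cb <- cache$cross
  g$c.W2 <- t(cb$g1$y) %*% dlat
  g$c.b2 <- colSums(dlat)
  dz1 <- geluBwd(dlat %*% t(p$c.W2), cb$g1)
  g$c.W1 <- t(cb$ln2$y) %*% dz1
  g$c.b1 <- colSums(dz1)
  bl <- lnBwd(dz1 %*% t(p$c.W1), cb$ln2, p$c.ln2G)
  g$c.ln2G <- bl$dg; g$c.ln2B <- bl$db
  dlat1 <- dlat + bl$dx
  g$c.Wo <- t(cb$at$out) %*% dlat1
  g$c.bo <- colSums(dlat1)
  dato <- dlat1 %*% t(p$c.Wo)
  ab <- attnHeadsBwd(dato, cb$Q, cb$K, cb$V, cb$at$As, cfg@crossHeads)
  g$c.Wq <- t(cb$ln1$y) %*% ab$dQ; g$c.bq <- colSums(ab$dQ)
  g$c.Wk <- t(cache$ctx) %*% ab$dK; g$c.bk <- colSums(ab$dK)
  g$c.Wv <- t(cache$ctx) %*% ab$dV; g$c.bv <- colSums(ab$dV)
  bl <- lnBwd(ab$dQ %*% t(p$c.Wq), cb$ln1, p$c.ln1G)
  g$c.ln1G <- bl$dg; g$c.ln1B <- bl$db
  g$lat <- dlat1 + bl$dx                    # residual + query path

  # context path back to the embedding tokens
  dctx <- ab$dK %*% t(p$c.Wk) + ab$dV %*% t(p$c.Wv)
  bl <- lnBwd(dctx, cache$lnC, p$lnCtxG)
  g$lnCtxG <- bl$dg; g$lnCtxB <- bl$db
  dctx0 <- bl$dx
  tk <- cache$tk
  g$tokW <- t(tk$tokens) %*% dctx0
  g$tokB <- colSums(dctx0)
  g$fourW <- t(tk$positions) %*% dctx0
  g$fourB <- colSums(dctx0)
  dTokens <- dctx0 %*% t(p$tokW)
  dInput <- as.numeric(t(dTokens))
  if (tk$padded > 0L)
    dInput <- dInput[seq_len(length(dInput) - tk$padded)]
  list(grads = g, dInput = dInput)
}

#' Classify a session embedding
#'
#' Runs the cross/self-attention classifier on an embedding and returns the
#' class scores.
#'
#' @param module a [TemporalModule-class].
#' @param e numeric session embedding (the fused `VD + Bh`, a video-only
#'   `VD`, or an expanded heart-rate embedding).
#' @return A [Prediction-class].
#' @export
temporalForward <- function(module, e) {
  res <- temporalForwardCache(module@weights, module@config, e)
  pr <- exp(res$logits - max(res$logits))
  pr <- pr / sum(pr)
  methods::new("Prediction", logits = res$logits, probabilities = pr,
               label = which.max(res$logits))
}

#' Token-level attention map of the temporal classifier
#'
#' Scores each input token by the cross-attention mass it receives from the
#' final latents, weighted by the class-head contribution of each latent,
#' arranges the scores as a strip, bicubic-interpolates to a display
#' rectangle and min-max normalises to `[0, 1]`.
#'
#' @param module a [TemporalModule-class].
#' @param e session embedding.
#' @param height,width display rectangle size in pixels; the width defaults
#'   to 4 pixels per token.
#' @return A `height x width` matrix with values in `[0, 1]`.
#' @export
temporalAttentionMap <- function(module, e, height = 32L, width = NULL) {
  p <- module@weights; cfg <- module@config
  res <- temporalForwardCache(p, cfg, e)
  A <- Reduce(`+`, res$cache$cross$at$As) / length(res$cache$cross$at$As)
  headImp <- rowSums(abs(p$headW))           # contribution per latent dim
  latW <- abs(res$cache$lnF$y) %*% headImp   # per-latent readout weight
  scores <- drop(t(A) %*% latW)              # per-token received attention
  if (is.null(width)) width <- 4L * length(scores)
  mp <- bicubicResize(matrix(scores, 1L), height, as.integer(width))
  rng <- range(mp)
  if (diff(rng) < 1e-12) return(matrix(0, nrow(mp), ncol(mp)))
  (mp - rng[1L]) / diff(rng)
}
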