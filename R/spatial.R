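# Transformer-in-transformer spatial encoder: patch/sub-patch decomposition,
# inner (sub-patch) and outer (patch) pre-norm attention blocks, class-token
# readout, tile fusion and video-level concatenation.

#' @title Spatial encoder configuration
#' @description Geometry and width settings of the transformer-in-transformer
#'   image encoder. At the defaults a 224 x 224 input yields `n = 196`
#'   patches of 16 x 16 pixels, each split into `m = 16` sub-patches of
#'   4 x 4; twelve blocks produce a `d = 100` embedding per image, and the
#'   five images of a frame are fused with tile coefficient `c = 0.1`.
#' @slot imageSize,patchSize,subPatchSize pixel geometry.
#' @slot embedDim outer token width d.
#' @slot innerDim inner (sub-patch) token width.
#' @slot innerHeads,outerHeads attention heads of the two encoders.
#' @slot depth number of blocks.
#' @slot fcnInner,fcnOuter hidden widths of the inner/outer FCNs.
#' @slot tileCoeff fusion coefficient c.
#' @exportClass SpatialConfig
setClass("SpatialConfig",
         representation(imageSize = "integer", patchSize = "integer",
                        subPatchSize = "integer", embedDim = "integer",
                        innerDim = "integer", innerHeads = "integer",
                        outerHeads = "integer", depth = "integer",
                        fcnInner = "integer", fcnOuter = "integer",
                        tileCoeff = "numeric"),
         validity = function(object) {
           if (object@imageSize %% object@patchSize != 0L)
             return("patchSize must divide imageSize")
           if (object@patchSize %% object@subPatchSize != 0L)
             return("subPatchSize must divide patchSize")
           if (object@embedDim %% object@outerHeads != 0L)
             return("embedDim must be divisible by outerHeads")
           if (object@innerDim %% object@innerHeads != 0L)
             return("innerDim must be divisible by innerHeads")
           TRUE
         })

#' Construct a SpatialConfig
#'
#' Defaults give the full-size encoder whose trainable-parameter count is
#' 2.57 M: `d = 100`, inner width 24, 4/10 heads, depth 12, FCN hidden
#' widths 96 (inner) and 586 (outer).
#'
#' @param imageSize,patchSize,subPatchSize pixel geometry.
#' @param embedDim,innerDim token widths.
#' @param innerHeads,outerHeads head counts.
#' @param depth block count.
#' @param fcnInner,fcnOuter FCN hidden widths.
#' @param tileCoeff tile fusion coefficient c.
#' @return A [SpatialConfig-class].
#' @export
spatialConfig <- function(imageSize = 224L, patchSize = 16L,
                          subPatchSize = 4L, embedDim = 100L, innerDim = 24L,
                          innerHeads = 4L, outerHeads = 10L, depth = 12L,
                          fcnInner = 96L, fcnOuter = 586L, tileCoeff = 0.1) {
  methods::new("SpatialConfig", imageSize = as.integer(imageSize),
               patchSize = as.integer(patchSize),
               subPatchSize = as.integer(subPatchSize),
               embedDim = as.integer(embedDim), innerDim = as.integer(innerDim),
               innerHeads = as.integer(innerHeads),
               outerHeads = as.integer(outerHeads), depth = as.integer(depth),
               fcnInner = as.integer(fcnInner), fcnOuter = as.integer(fcnOuter),
               tileCoeff = tileCoeff)
}

nPatches <- function(cfg) (cfg@imageSize %/% cfg@patchSize)^2
nSubPatches <- function(cfg) (cfg@patchSize %/% cfg@subPatchSize)^2

#' @title Spatial encoder module
#' @slot config a [SpatialConfig-class].
#' @slot weights named list of weight arrays.
#' @exportClass SpatialModule
setClass("SpatialModule",
         representation(config = "SpatialConfig", weights = "list"))

setMethod("nParameters", "SpatialModule",
          function(object) countWeights(object@weights))

attnFusedInit <- function(d, sd = 0.02) {
  list(Wqkv = initMat(d, 3L * d, sd), bqkv = numeric(3L * d),
       Wo = initMat(d, d, sd), bo = numeric(d))
}

fcnInitW <- function(d, hidden, sd = 0.02) {
  list(W1 = initMat(d, hidden, sd), b1 = numeric(hidden),
       W2 = initMat(hidden, d, sd), b2 = numeric(d))
}

lnInit <- function(d) list(g = rep(1, d), b = numeric(d))

#' Instantiate a spatial encoder
#' @param cfg a [SpatialConfig-class].
#' @param seed RNG seed for the weight initialisation.
#' @return A [SpatialModule-class].
#' @export
spatialModule <- function(cfg = spatialConfig(), seed = 1L) {
  n <- nPatches(cfg); m <- nSubPatches(cfg)
  d <- cfg@embedDim; ci <- cfg@innerDim
  subPix <- 3L * cfg@subPatchSize^2
  patchPix <- 3L * cfg@patchSize^2
  w <- withSeed(seed, {
    blocks <- lapply(seq_len(cfg@depth), function(b) {
      list(innerLn1 = lnInit(ci), innerAttn = attnFusedInit(ci),
           innerLn2 = lnInit(ci), innerFcn = fcnInitW(ci, cfg@fcnInner),
           projLn = lnInit(m * ci),
           projW = initMat(m * ci, d), projB = numeric(d),
           outerLn1 = lnInit(d), outerAttn = attnFusedInit(d),
           outerLn2 = lnInit(d), outerFcn = fcnInitW(d, cfg@fcnOuter))
    })
    list(subEmbedW = initMat(subPix, ci), subEmbedB = numeric(ci),
         patchEmbedW = initMat(patchPix, d), patchEmbedB = numeric(d),
         clsToken = initMat(1L, d), posPatch = initMat(n + 1L, d),
         posSub = initMat(m, ci), blocks = blocks,
         finalLn = lnInit(d), readoutW = initMat(d, d), readoutB = numeric(d))
  })
  methods::new("SpatialModule", config = cfg, weights = w)
}

#' Decompose an image into patches and sub-patches
#'
#' Splits an image into `n` non-overlapping `p x p` patches in raster order
#' (left-to-right, top-to-bottom) and each patch into `m` `s x s`
#' sub-patches, also raster order. The decomposition reassembles the image
#' exactly.
#'
#' @param image an `imageSize x imageSize x 3` array.
#' @param p,s patch and sub-patch edge length in pixels.
#' @return A list with `patches` (`n x p x p x 3`) and `subPatches`
#'   (`n x m x s x s x 3`).
#' @export
patchify <- function(image, p = 16L, s = 4L) {
  d <- dim(image)
  if (length(d) != 3L || d[1L] != d[2L] || d[1L] %% p != 0L || p %% s != 0L)
    pfStop("invalidArgument", "image must be square with p | size and s | p")
  g <- d[1L] %/% p          # patch grid side
  gs <- p %/% s             # sub-patch grid side
  n <- g * g; m <- gs * gs
  patches <- array(0, c(n, p, p, 3L))
  subPatches <- array(0, c(n, m, s, s, 3L))
  for (r in seq_len(g)) for (cc in seq_len(g)) {
    i <- (r - 1L) * g + cc
    blk <- image[((r - 1L) * p + 1L):(r * p), ((cc - 1L) * p + 1L):(cc * p), ,
                 drop = FALSE]
    patches[i, , , ] <- blk
    for (sr in seq_len(gs)) for (sc in seq_len(gs)) {
      j <- (sr - 1L) * gs + sc
      subPatches[i, j, , , ] <-
        blk[((sr - 1L) * s + 1L):(sr * s), ((sc - 1L) * s + 1L):(sc * s), ]
    }
  }
  list(patches = patches, subPatches = subPatches)
}

# flattened matrices used by the forward pass: Xpatch (n x p*p*3) and
# Xsub ((n*m) x s*s*3), rows grouped by patch then sub-patch raster index
patchMatrices <- function(image, p, s) {
  pc <- patchify(image, p, s)
  n <- dim(pc$patches)[1L]; m <- dim(pc$subPatches)[2L]
  Xp <- matrix(pc$patches, n)               # n x (p*p*3), column-major slices
  # aperm puts the sub-patch index fastest, so rows come out grouped by
  # patch: row (i-1)*m + j is sub-patch j of patch i
  Xs <- matrix(aperm(pc$subPatches, c(2L, 1L, 3L, 4L, 5L)), n * m)
  list(Xpatch = Xp, Xsub = Xs, n = n, m = m)
}

# fused-projection self-attention over one token matrix
selfAttnFused <- function(tok, w, heads, collect = FALSE) {
  d <- ncol(tok)
  dh <- d %/% heads
  qkv <- tok %*% w$Wqkv + rep(w$bqkv, each = nrow(tok))
  out <- matrix(0, nrow(tok), d)
  weights <- if (collect) vector("list", heads) else NULL
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    a <- scaledDotAttention(qkv[, cols, drop = FALSE],
                            qkv[, d + cols, drop = FALSE],
                            qkv[, 2L * d + cols, drop = FALSE], dk = dh)
    out[, cols] <- a$out
    if (collect) weights[[h]] <- a$weights
  }
  list(out = out %*% w$Wo + rep(w$bo, each = nrow(tok)), weights = weights)
}

preNormBlock <- function(tok, ln1, attnW, ln2, fcnW, heads, collect = FALSE) {
  a <- selfAttnFused(layerNormRows(tok, ln1$g, ln1$b), attnW, heads, collect)
  tok <- tok + a$out
  h <- layerNormRows(tok, ln2$g, ln2$b)
  h <- gelu(h %*% fcnW$W1 + rep(fcnW$b1, each = nrow(h)))
  tok <- tok + h %*% fcnW$W2 + rep(fcnW$b2, each = nrow(tok))
  list(tok = tok, weights = a$weights)
}

#' One transformer-in-transformer block
#'
#' The inner encoder updates the sub-patch tokens of every patch; the
#' flattened inner tokens of each patch are layer-normalised, linearly
#' projected to the outer width and added to the patch token; the outer
#' encoder then updates the patch tokens (class token included). Both
#' encoders are pre-norm residual blocks with a GELU FCN.
#'
#' @param Z `(n+1) x d` patch tokens (class token first).
#' @param Y `(n*m) x innerDim` sub-patch tokens, rows grouped by patch.
#' @param bw the block's weight list.
#' @param cfg a [SpatialConfig-class].
#' @param collectWeights if `TRUE`, attach the attention weight matrices.
#' @return List with updated `Z`, `Y` and (optionally) `innerWeights`,
#'   `outerWeights`.
#' @export
tntBlock <- function(Z, Y, bw, cfg, collectWeights = FALSE) {
  n <- nrow(Z) - 1L
  m <- nrow(Y) %/% n
  ci <- ncol(Y)
  # inner encoder: attention runs within each patch's m sub-tokens
  Yn <- layerNormRows(Y, bw$innerLn1$g, bw$innerLn1$b)
  qkv <- Yn %*% bw$innerAttn$Wqkv + rep(bw$innerAttn$bqkv, each = nrow(Yn))
  dh <- ci %/% cfg@innerHeads
  attnOut <- matrix(0, nrow(Y), ci)
  innerW <- if (collectWeights) list() else NULL
  for (pIdx in seq_len(n)) {
    rows <- ((pIdx - 1L) * m + 1L):(pIdx * m)
    for (h in seq_len(cfg@innerHeads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      a <- scaledDotAttention(qkv[rows, cols, drop = FALSE],
                              qkv[rows, ci + cols, drop = FALSE],
                              qkv[rows, 2L * ci + cols, drop = FALSE], dk = dh)
      attnOut[rows, cols] <- a$out
      if (collectWeights) innerW[[length(innerW) + 1L]] <- a$weights
    }
  }
  Y <- Y + attnOut %*% bw$innerAttn$Wo + rep(bw$innerAttn$bo, each = nrow(Y))
  Hy <- layerNormRows(Y, bw$innerLn2$g, bw$innerLn2$b)
  Hy <- gelu(Hy %*% bw$innerFcn$W1 + rep(bw$innerFcn$b1, each = nrow(Hy)))
  Y <- Y + Hy %*% bw$innerFcn$W2 + rep(bw$innerFcn$b2, each = nrow(Y))

  # inject flattened inner tokens into the patch tokens
  flat <- matrix(t(Y), nrow = n, byrow = TRUE)        # n x (m*ci)
  flat <- layerNormRows(flat, bw$projLn$g, bw$projLn$b)
  Z[-1L, ] <- Z[-1L, , drop = FALSE] + flat %*% bw$projW +
    rep(bw$projB, each = n)

  outer <- preNormBlock(Z, bw$outerLn1, bw$outerAttn, bw$outerLn2,
                        bw$outerFcn, cfg@outerHeads, collectWeights)
  list(Z = outer$tok, Y = Y, innerWeights = innerW,
       outerWeights = outer$weights)
}

#' Encode one 224 x 224 image to a d-vector
#'
#' Full forward pass: patch/sub-patch decomposition, linear projections,
#' learned 1-D position encodings, `depth` transformer-in-transformer
#' blocks, final layer norm and class-token readout.
#'
#' @param module a [SpatialModule-class].
#' @param image `imageSize x imageSize x 3` array.
#' @param collectWeights if `TRUE`, also return all attention weights.
#' @return A numeric vector of length `embedDim` (with attribute
#'   `attnWeights` when requested).
#' @export
imageForward <- function(module, image, collectWeights = FALSE) {
  cfg <- module@config; w <- module@weights
  pm <- patchMatrices(image, cfg@patchSize, cfg@subPatchSize)
  Y <- pm$Xsub %*% w$subEmbedW + rep(w$subEmbedB, each = nrow(pm$Xsub))
  Y <- Y + w$posSub[rep(seq_len(pm$m), times = pm$n), , drop = FALSE]
  Zp <- pm$Xpatch %*% w$patchEmbedW + rep(w$patchEmbedB, each = pm$n)
  Z <- rbind(w$clsToken, Zp) + w$posPatch
  allW <- if (collectWeights) list() else NULL
  for (b in seq_len(cfg@depth)) {
    res <- tntBlock(Z, Y, w$blocks[[b]], cfg, collectWeights)
    Z <- res$Z; Y <- res$Y
    if (collectWeights)
      allW[[b]] <- list(inner = res$innerWeights, outer = res$outerWeights)
  }
  Z <- layerNormRows(Z, w$finalLn$g, w$finalLn$b)
  out <- as.numeric(Z[1L, ] %*% w$readoutW + w$readoutB)
  if (collectWeights) attr(out, "attnWeights") <- allW
  if (collectWeights) attr(out, "patchTokens") <- Z[-1L, , drop = FALSE]
  out
}

#' Fuse the five per-frame part embeddings
#'
#' `D = d_full + c * (d_tile1 + d_tile2 + d_tile3 + d_tile4)`: the resized
#' full frame carries the embedding at full weight while the four
#' higher-resolution tiles contribute a proportion `c` of their
#' information.
#'
#' @param parts list of 5 numeric d-vectors, full frame first.
#' @param c tile coefficient.
#' @return A [FrameEmbedding-class].
#' @export
frameFuse <- function(parts, c = 0.1) {
  if (length(parts) != 5L ||
      length(unique(vapply(parts, length, integer(1)))) != 1L)
    pfStop("invalidArgument", "parts must be 5 equal-length vectors")
  D <- parts[[1L]] + c * (parts[[2L]] + parts[[3L]] + parts[[4L]] + parts[[5L]])
  methods::new("FrameEmbedding", D = D, components = parts)
}

#' Encode a frame sequence into the concatenated video embedding
#'
#' Per frame: tile decomposition, five shared-weight image encodings, tile
#' fusion; the per-frame embeddings are concatenated in frame order into
#' `VD` of length `N = d * f`.
#'
#' @param module a [SpatialModule-class].
#' @param frames list of [FaceCrop-class] objects or 448 x 448 x 3 arrays.
#' @return A [VideoEmbedding-class].
#' @export
videoForward <- function(module, frames) {
  if (!length(frames)) pfStop("invalidArgument", "at least one frame required")
  d <- module@config@embedDim
  Ds <- lapply(frames, function(fr) {
    ts <- makeTileset(fr)
    parts <- lapply(c(list(ts@full), ts@tiles),
                    function(img) imageForward(module, img))
    frameFuse(parts, module@config@tileCoeff)@D
  })
  methods::new("VideoEmbedding", vd = unlist(Ds), d = d,
               f = length(frames))
}

#' Patch-level attention map of the spatial encoder
#'
#' Scores every patch by the magnitude of its final-layer token passed
#' through the readout weights, arranges the scores on the patch grid,
#' bicubic-interpolates to the input resolution and min-max normalises to
#' `[0, 1]`.
#'
#' @param module a [SpatialModule-class].
#' @param image input image.
#' @return A matrix of the input's spatial size with values in `[0, 1]`.
#' @export
spatialAttentionMap <- function(module, image) {
  out <- imageForward(module, image, collectWeights = TRUE)
  tokens <- attr(out, "patchTokens")
  scores <- sqrt(rowSums((tokens %*% module@weights$readoutW)^2))
  g <- as.integer(sqrt(length(scores)))
  mp <- bicubicResize(matrix(scores, g, g, byrow = TRUE),
                      dim(image)[1L], dim(image)[2L])
  rng <- range(mp)
  if (diff(rng) < 1e-12) return(matrix(0, nrow(mp), ncol(mp)))
  (mp - rng[1L]) / diff(rng)
}
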