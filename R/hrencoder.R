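# Perceiver-style heart-rate encoder: a small learned latent array
# cross-attends once over the Fourier-featurised per-second heart-rate
# values, passes through a residual FCN and is flattened to a 2048-vector,
# then expanded to the video-embedding length by bicubic interpolation.

#' @title Heart-rate encoder configuration
#' @slot internalDim internal embedding width (512 at full size).
#' @slot crossHeads cross-attention heads (1).
#' @slot nLatents learned latent vectors; `nLatents * internalDim` is the
#'   flattened output width (4 x 512 = 2048 at full size).
#' @slot fourierBands Fourier position-encoding bands.
#' @slot fcnHidden hidden width of the post-attention FCN.
#' @exportClass HREncoderConfig
setClass("HREncoderConfig",
         representation(internalDim = "integer", crossHeads = "integer",
                        nLatents = "integer", fourierBands = "integer",
                        fcnHidden = "integer"),
         validity = function(object) {
           if (object@internalDim %% object@crossHeads != 0L)
             return("internalDim must be divisible by crossHeads")
           TRUE
         })

#' Construct an HREncoderConfig
#'
#' Defaults give the full-size encoder: internal width 512, one
#' cross-attention head, depth 1, four latents flattened to a 2048-d
#' output, 16 Fourier bands, FCN hidden width 3245 (4.40 M parameters).
#'
#' @param internalDim,crossHeads,nLatents,fourierBands,fcnHidden see slots.
#' @return An [HREncoderConfig-class].
#' @export
hrEncoderConfig <- function(internalDim = 512L, crossHeads = 1L,
                            nLatents = 4L, fourierBands = 16L,
                            fcnHidden = 3245L) {
  methods::new("HREncoderConfig", internalDim = as.integer(internalDim),
               crossHeads = as.integer(crossHeads),
               nLatents = as.integer(nLatents),
               fourierBands = as.integer(fourierBands),
               fcnHidden = as.integer(fcnHidden))
}

#' @title Heart-rate encoder module
#' @slot config an [HREncoderConfig-class].
#' @slot weights named list of weight arrays.
#' @exportClass HREncoder
setClass("HREncoder",
         representation(config = "HREncoderConfig", weights = "list"))

setMethod("nParameters", "HREncoder",
          function(object) countWeights(object@weights))

#' Instantiate a heart-rate encoder
#' @param cfg an [HREncoderConfig-class].
#' @param seed RNG seed.
#' @return An [HREncoder-class].
#' @export
hrEncoder <- function(cfg = hrEncoderConfig(), seed = 1L) {
  D <- cfg@internalDim
  inDim <- 2L * cfg@fourierBands + 2L       # value + Fourier features
  w <- withSeed(seed, {
    list(inProjW = initMat(inDim, D), inProjB = numeric(D),
         latents = initMat(cfg@nLatents, D),
         lnCtx = lnInit(D), lnLat = lnInit(D),
         attn = mhAttentionInit(D),
         lnFcn = lnInit(D), fcn = fcnInitW(D, cfg@fcnHidden))
  })
  methods::new("HREncoder", config = cfg, weights = w)
}

#' Encode a heart-rate vector
#'
#' Each of the theta per-second BPM values is concatenated with its Fourier
#' position features and projected to the internal width; the learned
#' latent array cross-attends once over these tokens (pre-norm, residual),
#' passes through a residual GELU FCN, and the latents are flattened
#' row-major into the output embedding.
#'
#' @param module an [HREncoder-class].
#' @param h a [HeartRateSeries-class] or numeric BPM vector.
#' @return Numeric embedding of length `nLatents * internalDim` (2048 at
#'   the default configuration).
#' @export
hrEncode <- function(module, h) {
  if (methods::is(h, "HeartRateSeries")) h <- h@values
  if (!length(h)) pfStop("invalidArgument", "empty heart-rate vector")
  cfg <- module@config; w <- module@weights
  feats <- cbind(h, fourierPositions(length(h), cfg@fourierBands),
                 deparse.level = 0)
  ctx <- feats %*% w$inProjW + rep(w$inProjB, each = length(h))
  ctx <- layerNormRows(ctx, w$lnCtx$g, w$lnCtx$b)
  lat <- w$latents
  a <- mhAttention(layerNormRows(lat, w$lnLat$g, w$lnLat$b), ctx, w$attn,
                   cfg@crossHeads)
  lat <- lat + a$out
  hdn <- layerNormRows(lat, w$lnFcn$g, w$lnFcn$b)
  hdn <- gelu(hdn %*% w$fcn$W1 + rep(w$fcn$b1, each = nrow(hdn)))
  lat <- lat + hdn %*% w$fcn$W2 + rep(w$fcn$b2, each = nrow(lat))
  as.numeric(t(lat))                         # row-major flatten
}

#' Expand an embedding to a target length by bicubic interpolation
#'
#' The embedding is arranged row-major on a 2-D grid (32 x 64 for the
#' 2048-d default; otherwise the most square power-of-two-ish factorisation
#' with a 1:2 aspect), bicubic-resampled to a grid of at least `nTarget`
#' elements with the aspect preserved, flattened row-major and truncated to
#' exactly `nTarget`. Parameter-free and deterministic; reproduces
#' constants exactly and is the identity when `nTarget` equals the input
#' length.
#'
#' @param e numeric embedding.
#' @param nTarget output length (the video-embedding length N).
#' @return Numeric vector of length `nTarget`.
#' @export
bicubicExpand <- function(e, nTarget) {
  if (nTarget < 1L) pfStop("invalidArgument", "nTarget must be >= 1")
  L <- length(e)
  gh <- max(1L, floor(sqrt(L / 2)))
  while (L %% gh != 0L) gh <- gh - 1L
  gw <- L %/% gh
  if (gh * gw == nTarget && gh * gw == L) return(e)
  sc <- sqrt(nTarget / L)
  oh <- max(1L, ceiling(gh * sc)); ow <- max(1L, ceiling(gw * sc))
  while (oh * ow < nTarget) ow <- ow + 1L
  grid <- matrix(e, gh, gw, byrow = TRUE)
  out <- bicubicResize(grid, oh, ow)
  as.numeric(t(out))[seq_len(nTarget)]
}
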