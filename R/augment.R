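# Latent-space augmentations: the learned AugmNet encoder-decoder
# (training-only), Basic (polarity inversion + noise) and span Masking.

#' @title AugmNet: learned latent-space augmentation
#' @description A bottlenecked encoder-decoder (two fully connected layers
#'   each, ELU after every layer) that corrupts fused embeddings during
#'   training to regularise the downstream classifier; bit-identical
#'   passthrough at inference.
#' @slot inputDim embedding length N.
#' @slot weights named list of layer weights.
#' @exportClass AugmNet
setClass("AugmNet",
         representation(inputDim = "integer", weights = "list"))

setMethod("nParameters", "AugmNet",
          function(object) countWeights(object@weights))

#' Instantiate an AugmNet
#'
#' Layer widths follow `N -> encHidden -> bottleneck -> encHidden -> N`.
#' The defaults (36, 172) give 1.02 M parameters at the full embedding
#' length N = 13,800.
#'
#' @param inputDim embedding length N.
#' @param encHidden width of the outer encoder/decoder layers.
#' @param bottleneck width of the central code.
#' @param seed RNG seed.
#' @return An [AugmNet-class].
#' @export
augmNet <- function(inputDim = 13800L, encHidden = 36L, bottleneck = 172L,
                    seed = 1L) {
  w <- withSeed(seed, {
    list(enc1W = initMat(inputDim, encHidden), enc1B = numeric(encHidden),
         enc2W = initMat(encHidden, bottleneck), enc2B = numeric(bottleneck),
         dec1W = initMat(bottleneck, encHidden), dec1B = numeric(encHidden),
         dec2W = initMat(encHidden, inputDim), dec2B = numeric(inputDim))
  })
  methods::new("AugmNet", inputDim = as.integer(inputDim), weights = w)
}

#' AugmNet forward pass
#'
#' In training mode returns the transformed embedding
#' `P = decoder(encoder(e))` with ELU after each of the four layers; in
#' eval mode the module is inactive and returns `e` unchanged
#' (bit-identical).
#'
#' @param net an [AugmNet-class].
#' @param e numeric embedding of length `inputDim`.
#' @param mode `"eval"` or `"train"`.
#' @return Numeric embedding of the same length.
#' @export
augmNetForward <- function(net, e, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (length(e) != net@inputDim)
    pfStop("invalidArgument", "embedding length does not match the network")
  if (mode == "eval") return(e)
  w <- net@weights
  h <- eluAct(drop(e %*% w$enc1W) + w$enc1B)
  h <- eluAct(drop(h %*% w$enc2W) + w$enc2B)
  h <- eluAct(drop(h %*% w$dec1W) + w$dec1B)
  eluAct(drop(h %*% w$dec2W) + w$dec2B)
}

#' Basic augmentation: polarity inversion and noise insertion
#'
#' With probability `invertP` the embedding's polarity is inverted;
#' Gaussian noise with standard deviation `noiseSd * sd(e)` is then added.
#' With both knobs at zero this is the identity.
#'
#' @param e numeric embedding.
#' @param invertP inversion probability.
#' @param noiseSd noise scale as a fraction of the embedding's standard
#'   deviation.
#' @param seed RNG seed.
#' @return Augmented embedding.
#' @export
basicAugment <- function(e, invertP = 0.5, noiseSd = 0.1, seed = 1L) {
  if (noiseSd < 0) pfStop("invalidArgument", "noiseSd must be >= 0")
  withSeed(seed, {
    if (invertP > 0 && stats::runif(1) < invertP) e <- -e
    if (noiseSd > 0)
      e <- e + stats::rnorm(length(e), sd = noiseSd * stats::sd(e))
    e
  })
}

#' Masking augmentation: zero a random contiguous span
#'
#' One contiguous span whose length is drawn uniformly from 10--20% of the
#' embedding length is set to zero at a uniformly random start position;
#' spans that would run past the end are re-drawn (no wrapping).
#'
#' @param e numeric embedding of length >= 10.
#' @param seed RNG seed.
#' @return Masked embedding.
#' @export
maskAugment <- function(e, seed = 1L) {
  L <- length(e)
  if (L < 10L) pfStop("invalidArgument", "embedding must have length >= 10")
  withSeed(seed, {
    len <- sample(ceiling(0.1 * L):floor(0.2 * L), 1L)
    repeat {
      start <- sample.int(L, 1L)
      if (start + len - 1L <= L) break
    }
    e[start:(start + len - 1L)] <- 0
    e
  })
}
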