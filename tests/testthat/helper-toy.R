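# Reduced-size module configurations and fixture builders shared across the
# test files. The toy sizes keep every forward pass fast while exercising
# the same code paths as the full-size defaults.

toySpatialConfig <- function(embedDim = 20L) {
  spatialConfig(patchSize = 56L, subPatchSize = 14L, embedDim = embedDim,
                innerDim = 8L, innerHeads = 2L, outerHeads = 4L,
                depth = 1L, fcnInner = 16L, fcnOuter = 32L)
}

toyHrConfig <- function() {
  hrEncoderConfig(internalDim = 32L, nLatents = 4L, fourierBands = 4L,
                  fcnHidden = 64L)
}

toyTemporalConfig <- function(nClasses = 2L, dToken = 16L) {
  temporalConfig(internalDim = 16L, crossHeads = 1L, selfBlocks = 3L,
                 selfHeads = 4L, nLatents = 8L, nClasses = nClasses,
                 fourierBands = 4L, fcnHidden = 32L, dToken = dToken)
}

# two well-separated Gaussian clusters in N dimensions
separableEmbeddings <- function(n = 40L, N = 64L, shift = 2, seed = 1L) {
  withSeed(seed, {
    X <- matrix(rnorm(n * N), n)
    y <- rep(c("A", "B"), length.out = n)
    X[y == "B", 1:8] <- X[y == "B", 1:8] + shift
    list(X = X, y = y)
  })
}

randomImage <- function(size = 224L, seed = 1L) {
  withSeed(seed, array(runif(size * size * 3), c(size, size, 3L)))
}
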