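# Temporal classifier: tokenisation, forward pass, analytic gradients and
# trainability.

test_that("tokenisation slices the embedding into frame-width tokens", {
  tk <- tokenizeEmbedding(seq_len(13800), dToken = 100L)
  expect_identical(nrow(tk$tokens), 138L)
  expect_identical(tk$padded, 0L)
  tk2 <- tokenizeEmbedding(seq_len(200), dToken = 100L)
  expect_identical(nrow(tk2$tokens), 2L)
  # token i is the i-th contiguous slice
  e <- withSeed(1L, rnorm(350))
  tk3 <- tokenizeEmbedding(e, dToken = 100L)
  expect_identical(tk3$padded, 50L)
  expect_equal(tk3$tokens[2L, ], e[101:200])
  expect_equal(tk3$tokens[4L, ], c(e[301:350], numeric(50)))
  expect_identical(nrow(tk3$positions), 4L)
})

test_that("the classifier emits normalised class scores deterministically", {
  for (k in c(2L, 5L)) {
    mod <- temporalModule(toyTemporalConfig(nClasses = k), seed = k)
    e <- withSeed(2L, rnorm(160))
    pr <- temporalForward(mod, e)
    expect_length(pr@logits, k)
    expect_equal(sum(pr@probabilities), 1, tolerance = 1e-9)
    expect_identical(pr@logits, temporalForward(mod, e)@logits)
    expect_identical(pr@label, which.max(pr@logits))
  }
})

test_that("full-size classifier accepts the full-size fused embedding", {
  mod <- temporalModule(temporalConfig(), seed = 1L)
  e <- withSeed(3L, rnorm(13800))
  pr <- temporalForward(mod, e)
  expect_length(pr@logits, 5L)
})

test_that("analytic gradients agree with numerical differentiation", {
  cfg <- temporalConfig(internalDim = 8L, crossHeads = 1L, selfBlocks = 2L,
                        selfHeads = 2L, nLatents = 3L, nClasses = 3L,
                        fourierBands = 2L, fcnHidden = 10L, dToken = 5L)
  p <- temporalModule(cfg, seed = 3L)@weights
  e <- withSeed(9L, rnorm(23))            # exercises the padded path
  lossAt <- function(p, e) {
    crossEntropy(temporalForwardCache(p, cfg, e)$logits, 2L)$loss
  }
  fw <- temporalForwardCache(p, cfg, e)
  bw <- temporalBackward(p, cfg, fw$cache, crossEntropy(fw$logits, 2L)$dlogits)
  set.seed(4)
  for (nm in names(p)) {
    for (k in sample(length(p[[nm]]), min(2L, length(p[[nm]])))) {
      h <- 1e-5
      up <- p; up[[nm]][k] <- up[[nm]][k] + h
      dn <- p; dn[[nm]][k] <- dn[[nm]][k] - h
      num <- (lossAt(up, e) - lossAt(dn, e)) / (2 * h)
      expect_equal(bw$grads[[nm]][k], num, tolerance = 1e-3,
                   label = sprintf("grad of %s[%d]", nm, k))
    }
  }
  # input gradient (the path AugmNet trains through)
  for (k in c(1L, 12L, 23L)) {
    h <- 1e-5
    up <- e; up[k] <- up[k] + h
    dn <- e; dn[k] <- dn[k] - h
    expect_equal(bw$dInput[k], (lossAt(p, up) - lossAt(p, dn)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("a short fit steadily reduces the training loss", {
  d <- separableEmbeddings(n = 24L, N = 48L, seed = 5L)
  m <- fitPainClassifier(d$X, d$y, toyTemporalConfig(),
                         trainConfig(lr = 1e-3, warmupEpochs = 5L,
                                     epochs = 40L, seed = 2L))
  ma <- stats::filter(m@lossCurve, rep(1 / 10, 10), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(ma[length(ma)], ma[1L])
  expect_lt(m@lossCurve[40L], m@lossCurve[1L])
  # determinism: same seed, same final loss
  m2 <- fitPainClassifier(d$X, d$y, toyTemporalConfig(),
                          trainConfig(lr = 1e-3, warmupEpochs = 5L,
                                      epochs = 40L, seed = 2L))
  expect_identical(m@lossCurve, m2@lossCurve)
})

test_that("training refuses a label set that does not match the head", {
  d <- separableEmbeddings(n = 10L, N = 32L)
  expect_error(fitPainClassifier(d$X, d$y, toyTemporalConfig(nClasses = 5L)),
               class = "invalidDataset")
})

test_that("temporal attention maps are bounded rectangles over tokens", {
  mod <- temporalModule(toyTemporalConfig(), seed = 6L)
  e <- withSeed(7L, rnorm(160))           # 10 tokens
  mp <- temporalAttentionMap(mod, e, height = 16L)
  expect_identical(dim(mp), c(16L, 40L))  # width = 4 px per token
  expect_gte(min(mp), 0)
  expect_lte(max(mp), 1)
  # with position features silenced, identical tokens receive identical
  # attention and the map is flat
  mod@weights$fourW <- mod@weights$fourW * 0
  flat <- temporalAttentionMap(mod, rep(1, 160), height = 8L)
  expect_true(all(abs(flat - flat[1L, 1L]) < 1e-8))
})
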