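# Patch decomposition, attention algebra, TNT blocks, tile fusion and the
# concatenated video embedding.

test_that("patchify produces 196 patches of 16 sub-patches in raster order", {
  img <- randomImage(224L, seed = 1L)
  pc <- patchify(img, 16L, 4L)
  expect_identical(dim(pc$patches), c(196L, 16L, 16L, 3L))
  expect_identical(dim(pc$subPatches), c(196L, 16L, 4L, 4L, 3L))
  # raster order: patch (row 0, col 1) is the second patch
  expect_identical(pc$patches[2L, , , ], img[1:16, 17:32, ])
  # sub-patch (row 1, col 0) of patch 1 is sub index 5
  expect_identical(pc$subPatches[1L, 5L, , , ], img[5:8, 1:4, ])
  expect_error(patchify(randomImage(100L)), class = "invalidArgument")

  flat <- array(0.25, c(224, 224, 3))
  pcf <- patchify(flat)
  expect_true(all(pcf$patches == 0.25))
})

test_that("scaled dot-product attention matches the direct formula", {
  # single token: softmax of a scalar is 1, output = V row
  a1 <- scaledDotAttention(matrix(1.3, 1, 4), matrix(rnorm(4), 1),
                           matrix(5:8, 1))
  expect_equal(drop(a1$out), 5:8)
  # identical K rows: uniform weights, output = mean of V rows
  K <- matrix(rep(c(1, 2, 0.5, 0.7), each = 3), 3, 4)
  V <- matrix(withSeed(2L, rnorm(9)), 3)
  a2 <- scaledDotAttention(matrix(rnorm(4), 2, 4), K, V)
  expect_equal(a2$out[1L, ], colMeans(V))
  # random 3-token case against a brute-force evaluation
  Q <- matrix(withSeed(3L, rnorm(12)), 3)
  K <- matrix(withSeed(4L, rnorm(12)), 3)
  V <- matrix(withSeed(5L, rnorm(12)), 3)
  S <- Q %*% t(K) / sqrt(4)
  W <- t(apply(S, 1L, function(r) exp(r) / sum(exp(r))))
  a3 <- scaledDotAttention(Q, K, V)
  expect_equal(a3$weights, W, tolerance = 1e-12)
  expect_equal(a3$out, W %*% V, tolerance = 1e-12)
})

test_that("attention rows are stochastic at every head and block", {
  cfg <- toySpatialConfig()
  mod <- spatialModule(cfg, seed = 2L)
  out <- imageForward(mod, randomImage(224L, seed = 6L),
                      collectWeights = TRUE)
  aw <- attr(out, "attnWeights")
  for (blk in aw) {
    for (w in c(blk$inner, blk$outer))
      expect_true(all(abs(rowSums(w) - 1) < 1e-5))
  }
})

test_that("TNT blocks preserve shapes and reduce to plain attention when cut", {
  cfg <- toySpatialConfig()
  mod <- spatialModule(cfg, seed = 3L)
  img <- randomImage(224L, seed = 7L)
  pm <- patchMatrices(img, cfg@patchSize, cfg@subPatchSize)
  w <- mod@weights
  Y <- pm$Xsub %*% w$subEmbedW + rep(w$subEmbedB, each = nrow(pm$Xsub))
  Z <- rbind(w$clsToken,
             pm$Xpatch %*% w$patchEmbedW + rep(w$patchEmbedB, each = pm$n)) +
    w$posPatch
  res <- tntBlock(Z, Y, w$blocks[[1L]], cfg)
  expect_identical(dim(res$Z), dim(Z))
  expect_identical(dim(res$Y), dim(Y))

  # zeroed inner->outer projection: patch tokens evolve as a plain
  # transformer block, independent of the sub-patch stream
  bw <- w$blocks[[1L]]
  bw$projW <- bw$projW * 0
  bw$projB <- bw$projB * 0
  cut <- tntBlock(Z, Y, bw, cfg)
  plain <- preNormBlock(Z, bw$outerLn1, bw$outerAttn, bw$outerLn2,
                        bw$outerFcn, cfg@outerHeads)
  expect_equal(cut$Z, plain$tok, tolerance = 1e-12)
})

test_that("image encoding is deterministic with the configured width", {
  mod <- spatialModule(spatialConfig(), seed = 1L)
  img <- randomImage(224L, seed = 8L)
  v <- imageForward(mod, img)
  expect_length(v, 100L)
  expect_identical(v, imageForward(mod, img))
})

test_that("tile fusion follows D = d_full + c * sum(tiles)", {
  parts <- lapply(1:5, function(i) withSeed(10L + i, rnorm(20)))
  expect_equal(frameFuse(parts, c = 0)@D, parts[[1L]])
  same <- lapply(1:5, function(i) parts[[1L]])
  expect_equal(frameFuse(same, c = 1)@D, 5 * parts[[1L]])
  oracle <- parts[[1L]] + 0.1 * (parts[[2L]] + parts[[3L]] + parts[[4L]] +
                                   parts[[5L]])
  expect_equal(frameFuse(parts, c = 0.1)@D, oracle)
  # linearity in c
  c1 <- frameFuse(parts, c = 0.3)@D - parts[[1L]]
  c2 <- frameFuse(parts, c = 0.6)@D - parts[[1L]]
  expect_equal(2 * c1, c2, tolerance = 1e-12)
  expect_error(frameFuse(parts[1:4]), class = "invalidArgument")
})

test_that("video embedding concatenates frames block-wise", {
  cfg <- toySpatialConfig()
  mod <- spatialModule(cfg, seed = 4L)
  spec <- protocolSpec(windowS = 2, fps = 1.5, fs = 128, seed = 2L)
  frames <- synthSession("S001", "P4", spec)@frames
  ve <- videoForward(mod, frames)
  expect_identical(length(ve@vd), cfg@embedDim * length(frames))
  # permuting frames permutes the d-blocks
  perm <- c(3L, 1L, 2L)
  vp <- videoForward(mod, frames[perm])
  blocks <- function(v, d) split(v, rep(seq_len(length(v) / d), each = d))
  expect_equal(blocks(vp@vd, cfg@embedDim),
               setNames(blocks(ve@vd, cfg@embedDim)[perm],
                        seq_along(perm)))
  # single frame: VD equals the frame embedding
  v1 <- videoForward(mod, frames[1L])
  ts <- makeTileset(frames[[1L]])
  d1 <- frameFuse(lapply(c(list(ts@full), ts@tiles),
                         function(img) imageForward(mod, img)),
                  cfg@tileCoeff)@D
  expect_equal(v1@vd, d1)
  expect_error(videoForward(mod, list()), class = "invalidArgument")
})

test_that("spatial attention maps are normalised to the input size", {
  cfg <- toySpatialConfig()
  mod <- spatialModule(cfg, seed = 5L)
  img <- randomImage(224L, seed = 9L)
  mp <- spatialAttentionMap(mod, img)
  expect_identical(dim(mp), c(224L, 224L))
  expect_gte(min(mp), 0)
  expect_lte(max(mp), 1)
  # with position encodings silenced, a constant input gives equal patch
  # scores, hence a flat map
  mod@weights$posPatch <- mod@weights$posPatch * 0
  mod@weights$posSub <- mod@weights$posSub * 0
  flat <- spatialAttentionMap(mod, array(0.4, c(224, 224, 3)))
  expect_true(all(abs(flat - flat[1L, 1L]) < 1e-8))
})
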