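# Fusion, multi-task loss, training loop with warmup + cosine AdamW,
# leave-one-subject-out evaluation, metrics and the parameter/FLOP summary.

#' @title Training configuration
#' @slot optimizer optimiser name (`"adamw"`).
#' @slot lr base learning rate.
#' @slot lrSchedule schedule name (`"cosine"`, with linear warmup).
#' @slot weightDecay decoupled weight decay.
#' @slot warmupEpochs linear warmup length.
#' @slot batchSize minibatch size.
#' @slot epochs training epochs.
#' @slot seed RNG seed for shuffling, initialisation and augmentation.
#' @exportClass TrainConfig
setClass("TrainConfig",
         representation(optimizer = "character", lr = "numeric",
                        lrSchedule = "character", weightDecay = "numeric",
                        warmupEpochs = "integer", batchSize = "integer",
                        epochs = "integer", seed = "integer"),
         validity = function(object) {
           if (object@warmupEpochs >= object@epochs)
             return("warmupEpochs must be below epochs")
           TRUE
         })

#' Construct a TrainConfig
#'
#' Defaults follow the published training recipe: AdamW at 1e-4 with
#' cosine decay, weight decay 0.1, 50 warmup epochs, batch size 32, 500
#' epochs.
#'
#' @param optimizer,lr,lrSchedule,weightDecay,warmupEpochs,batchSize,epochs,seed
#'   see the class slots.
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(optimizer = "adamw", lr = 1e-4,
                        lrSchedule = "cosine", weightDecay = 0.1,
                        warmupEpochs = 50L, batchSize = 32L, epochs = 500L,
                        seed = 1L) {
  methods::new("TrainConfig", optimizer = optimizer, lr = lr,
               lrSchedule = lrSchedule, weightDecay = weightDecay,
               warmupEpochs = as.integer(warmupEpochs),
               batchSize = as.integer(batchSize),
               epochs = as.integer(epochs), seed = as.integer(seed))
}

#' Augmentation options for training
#' @param basic enable Basic (polarity inversion + noise).
#' @param basicInvertP,basicNoiseSd Basic's knobs.
#' @param mask enable span masking.
#' @param augmnet enable the learned AugmNet transformation.
#' @param prob per-sample application probability for Basic/Masking.
#' @return A named list of options.
#' @export
augmentOptions <- function(basic = FALSE, basicInvertP = 0.5,
                           basicNoiseSd = 0.1, mask = FALSE,
                           augmnet = FALSE, prob = 0.5) {
  list(basic = basic, basicInvertP = basicInvertP,
       basicNoiseSd = basicNoiseSd, mask = mask, augmnet = augmnet,
       prob = prob)
}

#' Fuse video and heart-rate embeddings by addition
#'
#' Element-wise sum of the concatenated video embedding `VD` and the
#' bicubic-expanded heart-rate embedding `Bh`; the expansion step exists
#' precisely so the two lengths agree.
#'
#' @param vd a [VideoEmbedding-class] or numeric vector.
#' @param bh numeric vector of the same length.
#' @return Numeric fused embedding.
#' @export
fuseEmbeddings <- function(vd, bh) {
  if (methods::is(vd, "VideoEmbedding")) vd <- vd@vd
  if (length(vd) != length(bh))
    pfStop("invalidArgument", "embedding lengths differ; expand first")
  vd + bh
}

#' Homoscedastic-uncertainty multi-task loss
#'
#' `L_total = sum_i [exp(-w_i) * L_i + w_i]` with learned per-task weights
#' `w`. Each task's loss is discounted by its learned uncertainty and the
#' `+ w_i` term penalises ignoring a task; the per-task stationary point is
#' `w_i* = log(L_i)`.
#'
#' @param losses numeric per-task losses (>= 0).
#' @param weights numeric learned weights, same length.
#' @return A list with `total` and `grad`, the gradient with respect to
#'   the weights.
#' @export
multitaskLoss <- function(losses, weights) {
  if (length(losses) != length(weights))
    pfStop("invalidArgument", "losses and weights must have equal length")
  if (any(losses < 0))
    pfStop("invalidArgument", "per-task losses must be non-negative")
  ew <- exp(-weights)
  list(total = sum(ew * losses + weights), grad = -ew * losses + 1)
}

#' Leave-one-subject-out splits
#'
#' One fold per subject: the test fold holds all of that subject's
#' sessions, the training fold the remainder; subjects never overlap.
#'
#' @param manifest data.frame with a `subject` column (one row per
#'   session).
#' @return List of folds, each with `testSubject`, `trainIdx`, `testIdx`
#'   row indices into the manifest.
#' @export
losoSplits <- function(manifest) {
  subjects <- unique(manifest$subject)
  if (length(subjects) < 2L)
    pfStop("invalidArgument", "LOSO needs at least 2 subjects")
  lapply(subjects, function(s) {
    test <- which(manifest$subject == s)
    list(testSubject = s, trainIdx = setdiff(seq_len(nrow(manifest)), test),
         testIdx = test)
  })
}

#' Compute the full session embedding for one modality
#'
#' Video path: tile decomposition and spatial encoding of every frame,
#' concatenated to `VD`. Heart-rate path: per-second heart rate, perceiver
#' encoding to 2048-d, bicubic expansion to length `nTarget`. Fused:
#' element-wise sum of the two.
#'
#' @param session a [SyntheticSession-class] (or any list-like with
#'   `frames` and `ecg`).
#' @param spatial a [SpatialModule-class].
#' @param hr an [HREncoder-class].
#' @param modality `"fused"`, `"video"` or `"hr"`.
#' @param nTarget embedding length for the heart-rate path when no video
#'   is present (defaults to `embedDim * n_frames`).
#' @return Numeric embedding.
#' @export
sessionEmbedding <- function(session, spatial, hr,
                             modality = c("fused", "video", "hr"),
                             nTarget = NULL) {
  modality <- match.arg(modality)
  vd <- NULL
  if (modality %in% c("fused", "video")) {
    vd <- videoForward(spatial, session@frames)
    if (is.null(nTarget)) nTarget <- length(vd@vd)
  }
  if (modality == "video") return(vd@vd)
  hrs <- hrPerSecond(session@ecg)
  eh <- hrEncode(hr, hrs)
  if (is.null(nTarget))
    pfStop("invalidArgument", "nTarget required for the hr modality")
  bh <- bicubicExpand(eh, nTarget)
  if (modality == "hr") return(bh)
  fuseEmbeddings(vd, bh)
}

#' @title Trained pain classifier
#' @slot temporal the trained [TemporalModule-class].
#' @slot augmnet the jointly trained [AugmNet-class], or `NULL` when
#'   disabled (inactive at inference either way).
#' @slot center,scale per-feature standardisation learned on the training
#'   embeddings.
#' @slot classes class labels in logit order.
#' @slot lossCurve per-epoch mean training loss.
#' @exportClass PainClassifier
setClass("PainClassifier",
         representation(temporal = "TemporalModule", augmnet = "ANY",
                        center = "numeric", scale = "numeric",
                        classes = "character", lossCurve = "numeric"))

crossEntropy <- function(logits, yIdx) {
  m <- max(logits)
  lse <- m + log(sum(exp(logits - m)))
  list(loss = lse - logits[yIdx],
       dlogits = exp(logits - lse) - (seq_along(logits) == yIdx))
}

#' Train the temporal classifier on session embeddings
#'
#' Cross-entropy objective optimised with AdamW under linear warmup and
#' cosine decay. Embeddings are standardised per feature on the training
#' set. Augmentations (Basic, Masking, AugmNet) are applied during
#' training only; AugmNet, when enabled, sits in the graph and is trained
#' jointly by the classification loss, its bottleneck forcing a learned
#' corruption of the embedding. Deterministic under `trainCfg@seed`.
#'
#' @param X numeric matrix, one session embedding per row.
#' @param labels factor or character vector of session labels.
#' @param cfg a [TemporalConfig-class] (its `nClasses` must match).
#' @param trainCfg a [TrainConfig-class].
#' @param augment an [augmentOptions()] list.
#' @return A [PainClassifier-class].
#' @export
fitPainClassifier <- function(X, labels, cfg = temporalConfig(),
                              trainCfg = trainConfig(),
                              augment = augmentOptions()) {
  labels <- as.factor(labels)
  classes <- levels(labels)
  if (length(classes) != cfg@nClasses)
    pfStop("invalidDataset", "nClasses does not match the label set")
  if (any(table(labels) == 0L))
    pfStop("invalidDataset", "every class must appear in the training set")
  y <- as.integer(labels)
  n <- nrow(X)

  center <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, `/`)

  tmod <- temporalModule(cfg, seed = subSeed(trainCfg@seed, 1L))
  anet <- if (augment$augmnet) {
    augmNet(ncol(X), seed = subSeed(trainCfg@seed, 2L))
  } else NULL

  params <- tmod@weights
  if (!is.null(anet))
    for (nm in names(anet@weights)) params[[paste0("a.", nm)]] <- anet@weights[[nm]]
  opt <- adamwInit(params)
  lossCurve <- numeric(trainCfg@epochs)
  aCount <- 0L

  for (ep in seq_len(trainCfg@epochs)) {
    lrEp <- trainCfg@lr * lrSchedule(ep, trainCfg@epochs, trainCfg@warmupEpochs)
    ord <- withSeed(subSeed(trainCfg@seed, 3L, ep), sample.int(n))
    epLoss <- 0
    for (bStart in seq(1L, n, by = trainCfg@batchSize)) {
      idx <- ord[bStart:min(bStart + trainCfg@batchSize - 1L, n)]
      grads <- NULL
      for (i in idx) {
        e <- Xs[i, ]
        aCount <- aCount + 1L
        aSeed <- subSeed(trainCfg@seed, 5L, aCount)
        if (augment$basic &&
            withSeed(subSeed(aSeed, 1L), stats::runif(1)) < augment$prob)
          e <- basicAugment(e, augment$basicInvertP, augment$basicNoiseSd,
                            seed = subSeed(aSeed, 2L))
        if (augment$mask &&
            withSeed(subSeed(aSeed, 3L), stats::runif(1)) < augment$prob)
          e <- maskAugment(e, seed = subSeed(aSeed, 4L))
        aCache <- NULL
        if (!is.null(anet)) {
          aCache <- augmNetForwardCache(params, e)
          e <- aCache$out
        }
        fw <- temporalForwardCache(params, cfg, e)
        ce <- crossEntropy(fw$logits, y[i])
        epLoss <- epLoss + ce$loss
        bw <- temporalBackward(params, cfg, fw$cache, ce$dlogits)
        gAll <- bw$grads
        if (!is.null(anet)) {
          ga <- augmNetBackward(params, aCache, bw$dInput)
          gAll <- c(gAll, ga)
        }
        grads <- if (is.null(grads)) gAll else {
          for (nm in names(gAll)) grads[[nm]] <- grads[[nm]] + gAll[[nm]]
          grads
        }
      }
      for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / length(idx)
      stepRes <- adamwStep(params, grads, opt, lrEp, trainCfg@weightDecay)
      params <- stepRes$params
      opt <- stepRes$state
    }
    lossCurve[ep] <- epLoss / n
  }

  tw <- params[!startsWith(names(params), "a.")]
  tmod@weights <- tw
  if (!is.null(anet)) {
    aw <- params[startsWith(names(params), "a.")]
    names(aw) <- sub("^a\\.", "", names(aw))
    anet@weights <- aw
  }
  methods::new("PainClassifier", temporal = tmod, augmnet = anet,
               center = center, scale = scl, classes = classes,
               lossCurve = lossCurve)
}

# AugmNet forward/backward on the flat "a."-prefixed parameter list
augmNetForwardCache <- function(p, e) {
  z1 <- drop(e %*% p$a.enc1W) + p$a.enc1B; h1 <- eluAct(z1)
  z2 <- drop(h1 %*% p$a.enc2W) + p$a.enc2B; h2 <- eluAct(z2)
  z3 <- drop(h2 %*% p$a.dec1W) + p$a.dec1B; h3 <- eluAct(z3)
  z4 <- drop(h3 %*% p$a.dec2W) + p$a.dec2B; out <- eluAct(z4)
  list(e = e, z1 = z1, h1 = h1, z2 = z2, h2 = h2, z3 = z3, h3 = h3,
       z4 = z4, out = out)
}

eluGrad <- function(z) ifelse(z > 0, 1, exp(z))

augmNetBackward <- function(p, cache, dOut) {
  g <- list()
  dz4 <- dOut * eluGrad(cache$z4)
  g$a.dec2W <- outer(cache$h3, dz4); g$a.dec2B <- dz4
  dz3 <- drop(p$a.dec2W %*% dz4) * eluGrad(cache$z3)
  g$a.dec1W <- outer(cache$h2, dz3); g$a.dec1B <- dz3
  dz2 <- drop(p$a.dec1W %*% dz3) * eluGrad(cache$z2)
  g$a.enc2W <- outer(cache$h1, dz2); g$a.enc2B <- dz2
  dz1 <- drop(p$a.enc2W %*% dz2) * eluGrad(cache$z1)
  g$a.enc1W <- outer(cache$e, dz1); g$a.enc1B <- dz1
  g
}

#' Predict classes for session embeddings
#' @param model a [PainClassifier-class].
#' @param X numeric matrix, one embedding per row.
#' @return A list with `labels` (character), `probabilities` (matrix) and
#'   `predictions` (list of [Prediction-class]).
#' @export
predictPain <- function(model, X) {
  Xs <- sweep(sweep(X, 2L, model@center), 2L, model@scale, `/`)
  preds <- lapply(seq_len(nrow(Xs)), function(i)
    temporalForward(model@temporal, Xs[i, ]))
  probs <- do.call(rbind, lapply(preds, function(p) p@probabilities))
  colnames(probs) <- model@classes
  list(labels = model@classes[vapply(preds, function(p) p@label, integer(1))],
       probabilities = probs, predictions = preds)
}

#' Pool predictions into a metrics report
#'
#' Builds the pooled confusion matrix over folds and computes accuracy plus
#' macro-averaged precision, recall and F1 (classes absent from the
#' denominator contribute 0).
#'
#' @param truth,predicted character/factor vectors (pooled over folds), or
#'   lists of per-fold vectors.
#' @param classes class labels fixing the matrix order.
#' @return A [MetricsReport-class].
#' @export
metricsReport <- function(truth, predicted, classes = NULL) {
  perFold <- list()
  if (is.list(truth)) {
    if (is.null(classes)) classes <- sort(unique(unlist(truth)))
    perFold <- Map(function(tr, pr) {
      table(factor(tr, classes), factor(pr, classes))
    }, truth, predicted)
    truth <- unlist(truth); predicted <- unlist(predicted)
  }
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, classes), factor(predicted, classes))
  cm <- unclass(as.matrix(cm))
  names(dimnames(cm)) <- c("truth", "predicted")
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  methods::new("MetricsReport", confusion = cm,
               accuracy = sum(tp) / sum(cm), precision = mean(prec),
               recall = mean(rec), f1 = mean(f1), perFold = perFold)
}

#' Leave-one-subject-out evaluation over precomputed embeddings
#'
#' For each fold: train a fresh classifier on all other subjects' sessions
#' and predict the held-out subject's. The binary task keeps only NP and
#' P4 sessions.
#'
#' @param X embedding matrix, one session per row.
#' @param labels session labels.
#' @param subjects session subject ids (defines the folds).
#' @param task `"mc"` (all five classes) or `"binary"` (NP vs P4).
#' @param cfg a [TemporalConfig-class]; `nClasses` is set from the task.
#' @param trainCfg a [TrainConfig-class].
#' @param augment an [augmentOptions()] list.
#' @return A [MetricsReport-class].
#' @export
losoEvaluate <- function(X, labels, subjects, task = c("mc", "binary"),
                         cfg = temporalConfig(), trainCfg = trainConfig(),
                         augment = augmentOptions()) {
  task <- match.arg(task)
  labels <- as.character(labels)
  keep <- if (task == "binary") labels %in% c("NP", "P4") else
    rep(TRUE, length(labels))
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  subjects <- subjects[keep]
  cfg@nClasses <- length(unique(labels))
  folds <- losoSplits(data.frame(subject = subjects))
  truths <- list(); preds <- list()
  for (k in seq_along(folds)) {
    f <- folds[[k]]
    model <- fitPainClassifier(X[f$trainIdx, , drop = FALSE],
                               labels[f$trainIdx], cfg, trainCfg, augment)
    pr <- predictPain(model, X[f$testIdx, , drop = FALSE])
    truths[[k]] <- labels[f$testIdx]
    preds[[k]] <- pr$labels
  }
  metricsReport(truths, preds, classes = sort(unique(labels)))
}

# analytic FLOP counts (2*m*n*k per matmul) for one forward pass
flopsSpatial <- function(cfg) {
  n <- nPatches(cfg); m <- nSubPatches(cfg)
  d <- cfg@embedDim; ci <- cfg@innerDim
  mm <- function(a, b, k) 2 * a * b * k
  embed <- mm(n * m, ci, 3 * cfg@subPatchSize^2) + mm(n, d, 3 * cfg@patchSize^2)
  inner <- mm(n * m, 3 * ci, ci) + n * (2 * mm(m, m, ci)) +
    mm(n * m, ci, ci) + mm(n * m, cfg@fcnInner, ci) + mm(n * m, ci, cfg@fcnInner)
  proj <- mm(n, d, m * ci)
  outer <- mm(n + 1, 3 * d, d) + 2 * mm(n + 1, n + 1, d) +
    mm(n + 1, d, d) + mm(n + 1, cfg@fcnOuter, d) + mm(n + 1, d, cfg@fcnOuter)
  embed + cfg@depth * (inner + proj + outer) + mm(1, d, d)
}

flopsHr <- function(cfg, theta = 5L) {
  D <- cfg@internalDim; L <- cfg@nLatents
  mm <- function(a, b, k) 2 * a * b * k
  mm(theta, D, 2 * cfg@fourierBands + 2) + mm(L, D, D) +
    2 * mm(theta, D, D) + 2 * mm(L, theta, D) + mm(L, D, D) +
    mm(L, cfg@fcnHidden, D) + mm(L, D, cfg@fcnHidden)
}

flopsTemporal <- function(cfg, nTokens = 138L) {
  d <- cfg@internalDim; L <- cfg@nLatents
  mm <- function(a, b, k) 2 * a * b * k
  tok <- mm(nTokens, d, cfg@dToken) + mm(nTokens, d, 2 * cfg@fourierBands + 1)
  cross <- mm(L, d, d) + 2 * mm(nTokens, d, d) + 2 * mm(L, nTokens, d) +
    mm(L, d, d) + mm(L, cfg@fcnHidden, d) + mm(L, d, cfg@fcnHidden)
  self <- mm(L, 3 * d, d) + 2 * mm(L, L, d) + mm(L, d, d) +
    mm(L, cfg@fcnHidden, d) + mm(L, d, cfg@fcnHidden)
  tok + cross + cfg@selfBlocks * self + mm(1, cfg@nClasses, d)
}

flopsAugmNet <- function(N = 13800L, a = 36L, b = 172L) {
  2 * (N * a + a * b + b * a + a * N)
}

#' Parameter and FLOP summary of the framework
#'
#' Instantiates the four modules and reports exact trainable-parameter
#' counts (millions, 2 decimals) and analytic FLOP estimates (Giga,
#' counting 2*m*n*k per matrix product) for one forward pass at the
#' default session shape. The inference total excludes AugmNet, which is
#' inactive outside training.
#'
#' @param spatialCfg,hrCfg,temporalCfg module configurations.
#' @param augmInputDim embedding length N for AugmNet.
#' @param frames frames per session (video-embedding tokens).
#' @param theta heart-rate vector length.
#' @return A [ModelSummary-class] with per-module rows plus `Total` and
#'   `Inference`.
#' @export
modelSummary <- function(spatialCfg = spatialConfig(),
                         hrCfg = hrEncoderConfig(),
                         temporalCfg = temporalConfig(),
                         augmInputDim = NULL, frames = 138L, theta = 5L) {
  if (is.null(augmInputDim))
    augmInputDim <- spatialCfg@embedDim * frames
  mods <- list(
    `Spatial-Module` = nParameters(spatialModule(spatialCfg, seed = 1L)),
    `Heart Rate Encoder` = nParameters(hrEncoder(hrCfg, seed = 1L)),
    `AugmNet` = nParameters(augmNet(augmInputDim, seed = 1L)),
    `Temporal-Module` = nParameters(temporalModule(temporalCfg, seed = 1L)))
  params <- unlist(mods)
  params <- c(params, Total = sum(params),
              Inference = sum(params) - params[["AugmNet"]])
  flops <- c(flopsSpatial(spatialCfg), flopsHr(hrCfg, theta),
             flopsAugmNet(augmInputDim),
             flopsTemporal(temporalCfg, frames))
  flops <- c(flops, sum(flops), sum(flops) - flops[3L])
  names(flops) <- names(params)
  methods::new("ModelSummary", paramsM = round(params / 1e6, 2),
               flopsG = round(flops / 1e9, 2), paramsRaw = params)
}
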