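# Shared numeric primitives for the transformer modules: deterministic RNG
# scoping, row-wise softmax / layer normalisation, scaled dot-product
# attention, Fourier position features and Keys bicubic resampling.

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library calls never perturb a caller's stream.
#'
#' @param seed integer seed (kept below 2^31 by callers).
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

# derive a reproducible sub-seed from a base seed and a few integer tags
subSeed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 2147483647
  for (t in tags) s <- (s * 48271 + as.double(t) + 1) %% 2147483647
  as.integer(s)
}

# classed condition constructor so callers can test specific failure modes
pfStop <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

softmaxRows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

layerNormRows <- function(x, gain, bias, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  sweep(xc / sqrt(v + eps), 2L, gain, `*`) + rep(bias, each = nrow(x))
}

gelu <- function(x) x * stats::pnorm(x)

eluAct <- function(x, alpha = 1) ifelse(x > 0, x, alpha * (exp(x) - 1))

initMat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V`, the basic attention operation used
#' by every encoder in the framework.
#'
#' @param Q,K,V query, key and value matrices; `Q` is `n_q x d_k`, `K` and
#'   `V` share row count.
#' @param dk key dimensionality used for scaling; defaults to `ncol(K)`.
#' @return A list with `out` (`n_q x ncol(V)`) and `weights`, the
#'   row-stochastic attention matrix.
#' @examples
#' a <- scaledDotAttention(matrix(0, 1, 4), matrix(rnorm(12), 3), diag(3))
#' rowSums(a$weights)  # 1
#' @export
scaledDotAttention <- function(Q, K, V, dk = ncol(K)) {
  if (ncol(Q) != ncol(K) || nrow(K) != nrow(V))
    pfStop("invalidArgument", "non-conformable attention inputs")
  A <- softmaxRows(Q %*% t(K) / sqrt(dk))
  list(out = A %*% V, weights = A)
}

# multi-head attention with separate q/k/v/out projections.
# qin: n_q x d queries source; ctx: n_k x d key/value source.
mhAttention <- function(qin, ctx, w, heads) {
  d <- ncol(w$Wq)
  dh <- d %/% heads
  Q <- qin %*% w$Wq + rep(w$bq, each = nrow(qin))
  K <- ctx %*% w$Wk + rep(w$bk, each = nrow(ctx))
  V <- ctx %*% w$Wv + rep(w$bv, each = nrow(ctx))
  out <- matrix(0, nrow(qin), d)
  weights <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    a <- scaledDotAttention(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                            V[, cols, drop = FALSE], dk = dh)
    out[, cols] <- a$out
    weights[[h]] <- a$weights
  }
  list(out = out %*% w$Wo + rep(w$bo, each = nrow(qin)), weights = weights)
}

mhAttentionInit <- function(d, sd = 0.02) {
  list(Wq = initMat(d, d, sd), bq = numeric(d),
       Wk = initMat(d, d, sd), bk = numeric(d),
       Wv = initMat(d, d, sd), bv = numeric(d),
       Wo = initMat(d, d, sd), bo = numeric(d))
}

#' Fourier position features
#'
#' Per-position sine/cosine features at `bands` frequencies log-spaced from 1
#' to the Nyquist frequency of the index axis, plus the raw normalised
#' coordinate, as used by the perceiver-style encoders in place of learned
#' position tables.
#'
#' @param length number of positions.
#' @param bands number of frequency bands.
#' @return A `length x (2 * bands + 1)` matrix `[x, sin(pi f x), cos(pi f x)]`
#'   with `x` in `[0, 1]`.
#' @examples
#' fourierPositions(5, 4)[1, ]  # position 0: sines 0, cosines 1
#' @export
fourierPositions <- function(length, bands) {
  if (length < 1L) pfStop("invalidArgument", "length must be >= 1")
  x <- if (length == 1L) 0 else (seq_len(length) - 1) / (length - 1)
  nyq <- max(length / 2, 1)
  f <- if (bands == 1L) nyq else exp(seq(log(1), log(nyq), length.out = bands))
  ang <- outer(x, pi * f)
  cbind(x, sin(ang), cos(ang), deparse.level = 0)
}

# Keys cubic convolution kernel, a = -0.5
cubicKernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

# dense row-resampling operator (nOut x nIn), half-pixel centres,
# edge-replicated taps; rows sum to 1 so constants are preserved.
bicubicWeights <- function(nIn, nOut) {
  W <- matrix(0, nOut, nIn)
  for (i in seq_len(nOut)) {
    src <- (i - 0.5) * nIn / nOut - 0.5      # 0-based source coordinate
    base <- floor(src)
    t <- src - base
    taps <- base + (-1:2)
    wts <- cubicKernel(t - (-1:2))
    taps <- pmin(pmax(taps, 0), nIn - 1) + 1L
    for (k in 1:4) W[i, taps[k]] <- W[i, taps[k]] + wts[k]
  }
  W / rowSums(W)
}

#' Bicubic resampling of a matrix or image array
#'
#' Separable cubic-convolution resampling (Keys kernel, `a = -0.5`,
#' half-pixel centres, edge replication). Preserves constants exactly and is
#' the identity when the output size equals the input size.
#'
#' @param x a numeric matrix or an `H x W x C` array.
#' @param outH,outW output height and width.
#' @return Resampled matrix or array of size `outH x outW (x C)`.
#' @export
bicubicResize <- function(x, outH, outW) {
  if (outH < 1L || outW < 1L) pfStop("invalidArgument", "bad output size")
  if (is.matrix(x)) {
    Wr <- bicubicWeights(nrow(x), outH)
    Wc <- bicubicWeights(ncol(x), outW)
    return(Wr %*% x %*% t(Wc))
  }
  if (length(dim(x)) == 3L) {
    Wr <- bicubicWeights(dim(x)[1L], outH)
    Wc <- bicubicWeights(dim(x)[2L], outW)
    out <- array(0, c(outH, outW, dim(x)[3L]))
    for (ch in seq_len(dim(x)[3L])) out[, , ch] <- Wr %*% x[, , ch] %*% t(Wc)
    return(out)
  }
  pfStop("invalidArgument", "x must be a matrix or H x W x C array")
}

# AdamW update; state holds first/second moments and step counter
adamwInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamwStep <- function(params, grads, state, lr, weightDecay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
    decay <- if (is.matrix(params[[nm]])) weightDecay else 0  # no decay on biases/gains
    params[[nm]] <- params[[nm]] - lr * (upd + decay * params[[nm]])
  }
  list(params = params, state = state)
}

# warmup + cosine decay multiplier for epoch e of E with warmup W
lrSchedule <- function(epoch, epochs, warmup) {
  if (warmup > 0 && epoch <= warmup) return(epoch / warmup)
  p <- (epoch - warmup) / max(epochs - warmup, 1L)
  0.5 * (1 + cos(pi * min(p, 1)))
}

nParamsList <- function(params) sum(vapply(params, length, integer(1)))
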