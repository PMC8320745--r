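# Compact NN engine: batched forward/backward for the conv backbone and
# dense heads, plus Adam. Batches are N x (C*H*W) matrices (see
# src/nn_kernels.cpp for the flat layout). All functions are deterministic
# given the RNG state; parameter lists are plain named lists of matrices and
# vectors so checkpoints are deep-copied by assignment.

backboneConfig <- function(backbone = c("tiny", "wide"), inChannels = 1L,
                           inSize = 32L) {
  backbone <- match.arg(backbone)
  channels <- switch(backbone, tiny = c(8L, 16L, 32L, 32L),
                     wide = c(16L, 32L, 64L, 64L))
  sizes <- inSize / 2^seq_along(channels)   # spatial side after each block
  stopUnless(all(sizes == floor(sizes)) && sizes[length(sizes)] >= 1,
             "input size must be divisible by 2^(number of blocks)")
  list(backbone = backbone, inChannels = inChannels, inSize = inSize,
       channels = channels, sizes = as.integer(sizes))
}

heInitMat <- function(nin, nout) {
  matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

backboneInit <- function(cfg) {
  params <- list()
  cin <- cfg$inChannels
  for (b in seq_along(cfg$channels)) {
    f <- cfg$channels[b]
    fanin <- cin * 9L
    params[[paste0("conv", b, "_W")]] <-
      matrix(rnorm(f * fanin, sd = sqrt(2 / fanin)), f, fanin)
    params[[paste0("conv", b, "_b")]] <- numeric(f)
    cin <- f
  }
  params
}

gapFwd <- function(X, C, hw) {
  out <- matrix(0, nrow(X), C)
  for (c in seq_len(C))
    out[, c] <- rowMeans(X[, ((c - 1L) * hw + 1L):(c * hw), drop = FALSE])
  out
}

gapBwd <- function(dY, C, hw) {
  dX <- matrix(0, nrow(dY), C * hw)
  for (c in seq_len(C))
    dX[, ((c - 1L) * hw + 1L):(c * hw)] <- dY[, c] / hw
  dX
}

# forward through the conv stack; returns the final pooled-GAP feature, the
# per-block GAP stage features, and (optionally) the caches for backward
backboneFwd <- function(params, X, cfg, train = FALSE) {
  nb <- length(cfg$channels)
  stages <- vector("list", nb)
  caches <- if (train) vector("list", nb) else NULL
  cur <- X
  C <- cfg$inChannels; S <- cfg$inSize
  for (b in seq_len(nb)) {
    f <- cfg$channels[b]
    W <- params[[paste0("conv", b, "_W")]]
    bb <- params[[paste0("conv", b, "_b")]]
    z <- .conv2d_fwd(cur, W, bb, C, S, S, 3L, 3L, 1L)
    mask <- z > 0
    r <- z * mask
    pl <- .maxpool2_fwd(r, f, S, S)
    So <- S %/% 2L
    if (train) caches[[b]] <- list(Xin = cur, mask = mask, idx = pl$idx,
                                   C = C, S = S, f = f, So = So)
    cur <- pl$Y
    stages[[b]] <- gapFwd(cur, f, So * So)
    C <- f; S <- So
  }
  list(feat = stages[[nb]], stages = stages, caches = caches,
       outC = C, outS = S)
}

# backward; dfeat is the gradient at the final GAP feature, dstages an
# optional list of gradients at each block's GAP stage feature
backboneBwd <- function(params, fwd, cfg, dfeat, dstages = NULL) {
  nb <- length(cfg$channels)
  grads <- list()
  addStage <- function(d_out, b) {
    if (!is.null(dstages) && !is.null(dstages[[b]])) {
      ca <- fwd$caches[[b]]
      d_out + gapBwd(dstages[[b]], ca$f, ca$So * ca$So)
    } else d_out
  }
  caN <- fwd$caches[[nb]]
  d_out <- gapBwd(dfeat, caN$f, caN$So * caN$So)
  d_out <- addStage(d_out, nb)
  for (b in nb:1) {
    ca <- fwd$caches[[b]]
    d_r <- .maxpool2_bwd(d_out, ca$idx, ca$f, ca$S, ca$S)
    d_z <- d_r * ca$mask
    bw <- .conv2d_bwd(ca$Xin, params[[paste0("conv", b, "_W")]], d_z,
                      ca$C, ca$S, ca$S, 3L, 3L, 1L)
    grads[[paste0("conv", b, "_W")]] <- bw$dW
    grads[[paste0("conv", b, "_b")]] <- bw$db
    if (b > 1L) d_out <- addStage(bw$dX, b - 1L)
  }
  grads
}

denseFwd <- function(X, W, b) sweep(X %*% W, 2L, b, "+")

denseBwd <- function(X, W, dY) {
  list(dW = crossprod(X, dY), db = colSums(dY), dX = tcrossprod(dY, W))
}

sigmoidFn <- function(x) 1 / (1 + exp(-x))

# elementwise clipped-linear activation h(x): 0 for x <= 0, x on (0,1), 1
# for x >= 1; gradient is the indicator of (0,1)
clipMask <- function(x) x > 0 & x < 1

softmaxRows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

addGrads <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}
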