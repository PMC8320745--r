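#' @include AllClasses.R nn-ops.R attributes.R
NULL

#' Clipped-linear activation
#'
#' h(x) = 0 for x <= 0, x for 0 < x < 1, 1 for x >= 1, applied elementwise;
#' the attribute heads use it so attribute outputs are probabilities in
#' \[0,1\]. Idempotent: h(h(x)) = h(x).
#'
#' @param x numeric scalar, vector, matrix or array.
#' @return same shape, values in \[0,1\].
#' @examples
#' clippedLinear(c(-1, 0.3, 2))
#' @export
clippedLinear <- function(x) clamp01(x)

#' Construct a multi-task category + attribute classifier
#'
#' A convolutional backbone feeding (i) a category head of two fully
#' connected layers (widths `catHidden`) and a K-way softmax output, and
#' (ii) one auxiliary attribute classifier per backbone stage response
#' (including the initial pooled response): each global-average-pools its
#' stage's feature map and applies a two-layer clipped-linear map (hidden
#' width `auxHidden`) to M values. A combiner classifier concatenates the
#' per-stage M-vectors and applies one more clipped-linear map, yielding the
#' final M attribute probabilities.
#'
#' @param K number of material categories.
#' @param M number of material attributes.
#' @param backbone `"tiny"` (test configuration) or `"wide"`.
#' @param catHidden widths of the two category-head layers (narrow-then-wide
#'   as configured; pass them swapped to reverse the order).
#' @param auxHidden hidden width H of the attribute heads.
#' @param patchSize input patch side length.
#' @param seed integer seed for initialization.
#' @return a [MacModel-class].
#' @export
macModel <- function(K, M = 4L, backbone = "tiny", catHidden = NULL,
                     auxHidden = 64L, patchSize = 32L, seed = 1L) {
  cfg <- backboneConfig(backbone, inChannels = 1L, inSize = patchSize)
  if (is.null(catHidden))
    catHidden <- if (backbone == "tiny") c(64L, 128L) else c(512L, 2048L)
  cfg$K <- as.integer(K); cfg$M <- as.integer(M)
  cfg$catHidden <- as.integer(catHidden); cfg$auxHidden <- as.integer(auxHidden)
  nb <- length(cfg$channels)
  params <- withSeed(seed, {
    p <- backboneInit(cfg)
    cLast <- cfg$channels[nb]
    p$cat1_W <- heInitMat(cLast, catHidden[1]); p$cat1_b <- numeric(catHidden[1])
    p$cat2_W <- heInitMat(catHidden[1], catHidden[2]); p$cat2_b <- numeric(catHidden[2])
    p$cat3_W <- heInitMat(catHidden[2], K); p$cat3_b <- numeric(K)
    for (s in seq_len(nb)) {
      p[[paste0("aux", s, "_1W")]] <- heInitMat(cfg$channels[s], auxHidden)
      p[[paste0("aux", s, "_1b")]] <- rep(0.25, auxHidden)
      p[[paste0("aux", s, "_2W")]] <- heInitMat(auxHidden, M)
      p[[paste0("aux", s, "_2b")]] <- rep(0.25, M)
    }
    p$comb1_W <- heInitMat(nb * M, auxHidden)
    p$comb1_b <- rep(0.25, auxHidden)
    p$comb2_W <- heInitMat(auxHidden, M)
    p$comb2_b <- rep(0.25, M)
    p
  })
  new("MacModel", params = params, config = cfg)
}

macFwd <- function(params, cfg, X, train = FALSE) {
  nb <- length(cfg$channels)
  bb <- backboneFwd(params, X, cfg, train = train)
  c1p <- denseFwd(bb$feat, params$cat1_W, params$cat1_b); c1 <- c1p * (c1p > 0)
  c2p <- denseFwd(c1, params$cat2_W, params$cat2_b); c2 <- c2p * (c2p > 0)
  logits <- denseFwd(c2, params$cat3_W, params$cat3_b)
  probs <- softmaxRows(logits)
  auxOut <- vector("list", nb)
  auxCache <- vector("list", nb)
  for (s in seq_len(nb)) {
    g <- bb$stages[[s]]
    a1p <- denseFwd(g, params[[paste0("aux", s, "_1W")]],
                    params[[paste0("aux", s, "_1b")]])
    a1 <- clippedLinear(a1p)
    a2p <- denseFwd(a1, params[[paste0("aux", s, "_2W")]],
                    params[[paste0("aux", s, "_2b")]])
    auxOut[[s]] <- clippedLinear(a2p)
    auxCache[[s]] <- list(g = g, a1p = a1p, a1 = a1, a2p = a2p)
  }
  concat <- do.call(cbind, auxOut)
  b1p <- denseFwd(concat, params$comb1_W, params$comb1_b)
  b1 <- clippedLinear(b1p)
  b2p <- denseFwd(b1, params$comb2_W, params$comb2_b)
  attrs <- clippedLinear(b2p)
  list(probs = probs, attrs = attrs, bb = bb, c1p = c1p, c1 = c1, c2p = c2p,
       c2 = c2, auxOut = auxOut, auxCache = auxCache, concat = concat,
       b1p = b1p, b1 = b1, b2p = b2p)
}

macBwd <- function(params, cfg, fwd, dlogits, dattrs) {
  nb <- length(cfg$channels)
  grads <- list()
  # category path
  b3 <- denseBwd(fwd$c2, params$cat3_W, dlogits)
  grads$cat3_W <- b3$dW; grads$cat3_b <- b3$db
  dc2 <- b3$dX * (fwd$c2p > 0)
  b2 <- denseBwd(fwd$c1, params$cat2_W, dc2)
  grads$cat2_W <- b2$dW; grads$cat2_b <- b2$db
  dc1 <- b2$dX * (fwd$c1p > 0)
  b1 <- denseBwd(fwd$bb$feat, params$cat1_W, dc1)
  grads$cat1_W <- b1$dW; grads$cat1_b <- b1$db
  dfeat <- b1$dX
  # attribute path: combiner
  db2p <- dattrs * clipMask(fwd$b2p)
  cb2 <- denseBwd(fwd$b1, params$comb2_W, db2p)
  grads$comb2_W <- cb2$dW; grads$comb2_b <- cb2$db
  db1p <- cb2$dX * clipMask(fwd$b1p)
  cb1 <- denseBwd(fwd$concat, params$comb1_W, db1p)
  grads$comb1_W <- cb1$dW; grads$comb1_b <- cb1$db
  M <- cfg$M
  dstages <- vector("list", nb)
  for (s in seq_len(nb)) {
    ca <- fwd$auxCache[[s]]
    dout <- cb1$dX[, ((s - 1L) * M + 1L):(s * M), drop = FALSE]
    da2p <- dout * clipMask(ca$a2p)
    a2 <- denseBwd(ca$a1, params[[paste0("aux", s, "_2W")]], da2p)
    grads[[paste0("aux", s, "_2W")]] <- a2$dW
    grads[[paste0("aux", s, "_2b")]] <- a2$db
    da1p <- a2$dX * clipMask(ca$a1p)
    a1 <- denseBwd(ca$g, params[[paste0("aux", s, "_1W")]], da1p)
    grads[[paste0("aux", s, "_1W")]] <- a1$dW
    grads[[paste0("aux", s, "_1b")]] <- a1$db
    dstages[[s]] <- a1$dX
  }
  addGrads(grads, backboneBwd(params, fwd$bb, cfg, dfeat, dstages))
}

#' Forward pass of the classifier
#'
#' @param model a [MacModel-class] or [MacFit-class].
#' @param x one patch (matrix or length-d vector) or a batch (N x d matrix)
#'   of flattened normalized patches.
#' @return list with `categoryScores` (N x K softmax probabilities) and
#'   `attributes` (N x M values in \[0,1\]); the predicted category is the
#'   argmax of the scores.
#' @export
macForward <- function(model, x) {
  if (is(model, "MacFit")) model <- model@model
  d <- model@config$inSize^2
  if (is.matrix(x) && nrow(x) == model@config$inSize &&
      ncol(x) == model@config$inSize)
    x <- matrix(as.vector(x), 1L)
  else if (is.null(dim(x))) x <- matrix(x, 1L)
  stopUnless(ncol(x) == d, "patch shape mismatch: expected flattened length ", d)
  fwd <- macFwd(model@params, model@config, x)
  list(categoryScores = fwd$probs, attributes = fwd$attrs)
}

#' Multi-task loss of the classifier
#'
#' The sum of three terms: (i) the negative log-likelihood of the softmax
#' category scores against the one-hot labels; (ii) `gamma1` times the KL
#' divergence, on the grid `P`, between the Beta(a, b) target and the
#' Gaussian KDE of the batch's attribute predictions; (iii) `gamma2` times
#' the sum over categories of the squared distance between the attribute
#' matrix row a_k and the mean attribute prediction over the batch samples
#' of category k (categories absent from the batch contribute 0).
#'
#' @param probs N x K matrix of softmax category scores.
#' @param attrs N x M matrix of attribute predictions in \[0,1\].
#' @param labels integer category indices (length N) or N x K one-hot matrix.
#' @param A an [AttributeMatrix-class] or K x M matrix.
#' @param gamma1 KL-divergence weight (default 1e-2).
#' @param gamma2 attribute-consistency weight (default 1).
#' @param a,b Beta target shape parameters.
#' @param P KL evaluation grid.
#' @param h KDE bandwidth.
#' @return scalar total loss with attribute `"components"` (nll, kl, attr).
#' @export
macLoss <- function(probs, attrs, labels, A, gamma1 = 1e-2, gamma2 = 1,
                    a = 0.5, b = 0.5, P = defaultEvalPoints(), h = 0.1) {
  stopUnless(nrow(probs) >= 1, "empty batch")
  Av <- if (is(A, "AttributeMatrix")) A@values else A
  K <- ncol(probs)
  y <- if (is.matrix(labels)) max.col(labels) else as.integer(labels)
  eps <- 1e-7
  nll <- -sum(log(pmax(probs[cbind(seq_len(nrow(probs)), y)], eps)))
  kl <- if (gamma1 > 0) klTermOn(attrs, P, h, a, b) else 0
  attrTerm <- 0
  if (gamma2 > 0) {
    for (k in seq_len(nrow(Av))) {
      sel <- y == k
      if (any(sel))
        attrTerm <- attrTerm +
          sum((Av[k, ] - colMeans(attrs[sel, , drop = FALSE]))^2)
    }
  }
  total <- nll + gamma1 * kl + gamma2 * attrTerm
  attr(total, "components") <- c(nll = nll, kl = kl, attr = attrTerm)
  total
}

# gradients of the (batch-mean-scaled) loss wrt logits and attribute outputs
macLossGrad <- function(fwd, y, Av, gamma1, gamma2, P, h, a = 0.5, b = 0.5) {
  n <- nrow(fwd$probs)
  Y <- matrix(0, n, ncol(fwd$probs)); Y[cbind(seq_len(n), y)] <- 1
  dlogits <- (fwd$probs - Y) / n
  dattrs <- matrix(0, n, ncol(fwd$attrs))
  if (gamma1 > 0) {
    av <- as.vector(fwd$attrs)
    bet <- betaDensity(P, a, b)
    Phi <- outer(av, P, function(x, p) dnorm(x - p, sd = h))
    q <- pmax(colMeans(Phi), 1e-12)
    dKL <- (Phi * outer(av, P, "-")) %*% (bet / q) / (h^2 * length(av))
    dattrs <- dattrs + gamma1 * matrix(dKL, n, ncol(fwd$attrs)) / n
  }
  if (gamma2 > 0) {
    for (k in seq_len(nrow(Av))) {
      sel <- y == k
      nk <- sum(sel)
      if (nk > 0) {
        mk <- colMeans(fwd$attrs[sel, , drop = FALSE])
        dattrs[sel, ] <- dattrs[sel, ] +
          matrix(2 * gamma2 * (mk - Av[k, ]) / nk, nk, ncol(fwd$attrs),
                 byrow = TRUE) / n
      }
    }
  }
  list(dlogits = dlogits, dattrs = dattrs)
}

batchMeanLoss <- function(fwd, y, Av, gamma1, gamma2, P, h) {
  as.numeric(macLoss(fwd$probs, fwd$attrs, y, Av, gamma1, gamma2,
                     P = P, h = h)) / length(y)
}

#' Train the multi-task classifier against a fixed attribute matrix
#'
#' Minimizes the three-term loss with Adam. The learning rate starts at
#' `lr0` and is divided by 10 after any epoch whose validation loss exceeds
#' the previous epoch's; the returned model is the checkpoint with the
#' lowest validation loss across epochs.
#'
#' @param dsTrain,dsVal disjoint [PatchSet-class] splits.
#' @param A the fixed [AttributeMatrix-class] (rows must match the dataset's
#'   categories; columns define M).
#' @param hyper list: `epochs` (15), `batch` (50), `lr0` (1e-4), `gamma1`
#'   (1e-2), `gamma2` (1), `backbone` ("tiny"), `P`, `h`.
#' @param seed integer seed.
#' @return a [MacFit-class].
#' @export
trainMACCNN <- function(dsTrain, dsVal, A, hyper = list(), seed = 1L) {
  hp <- utils::modifyList(list(epochs = 15L, batch = 50L, lr0 = 1e-4,
                               gamma1 = 1e-2, gamma2 = 1, backbone = "tiny",
                               P = defaultEvalPoints(), h = 0.1), hyper)
  cats <- categoryNames(dsTrain)
  Av <- if (is(A, "AttributeMatrix")) A@values else A
  stopUnless(nrow(Av) == length(cats),
             "attribute matrix rows must match the dataset's categories")
  seeds <- childSeeds(seed, 2L)
  model <- macModel(K = length(cats), M = ncol(Av), backbone = hp$backbone,
                    seed = seeds[1])
  params <- model@params; cfg <- model@config
  Xtr <- t(patchValues(dsTrain)); ytr <- patchCategories(dsTrain)
  Xva <- t(patchValues(dsVal)); yva <- patchCategories(dsVal)
  opt <- adamInit(params)
  lr <- hp$lr0
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_loss = numeric(),
                        val_acc = numeric())
  best <- list(loss = Inf)
  epochSeeds <- childSeeds(seeds[2], hp$epochs)
  n <- nrow(Xtr)
  for (ep in seq_len(hp$epochs)) {
    ord <- withSeed(epochSeeds[ep], sample.int(n))
    epLoss <- 0
    for (s in seq.int(1L, n, by = hp$batch)) {
      idx <- ord[s:min(n, s + hp$batch - 1L)]
      fwd <- macFwd(params, cfg, Xtr[idx, , drop = FALSE], train = TRUE)
      loss <- batchMeanLoss(fwd, ytr[idx], Av, hp$gamma1, hp$gamma2, hp$P, hp$h)
      if (!is.finite(loss))
        stop(sprintf("non-finite training loss at epoch %d (batch at %d)", ep, s),
             call. = FALSE)
      epLoss <- epLoss + loss * length(idx)
      g <- macLossGrad(fwd, ytr[idx], Av, hp$gamma1, hp$gamma2, hp$P, hp$h)
      grads <- macBwd(params, cfg, fwd, g$dlogits, g$dattrs)
      up <- adamStep(params, grads, opt, lr)
      params <- up$params; opt <- up$state
    }
    vf <- macFwd(params, cfg, Xva)
    valLoss <- batchMeanLoss(vf, yva, Av, hp$gamma1, hp$gamma2, hp$P, hp$h)
    valAcc <- mean(max.col(vf$probs) == yva)
    history <- rbind(history,
                     data.frame(epoch = ep, lr = lr, train_loss = epLoss / n,
                                val_loss = valLoss, val_acc = valAcc))
    if (valLoss < best$loss)
      best <- list(loss = valLoss, epoch = ep, params = params)
    if (ep > 1L && valLoss > history$val_loss[ep - 1L]) lr <- lr / 10
  }
  cfg$categoryNames <- cats
  new("MacFit",
      model = new("MacModel", params = best$params, config = cfg),
      history = history, bestEpoch = as.integer(best$epoch),
      bestValLoss = best$loss, seed = as.integer(seed))
}

#' Category accuracy and confusion matrix on a test set
#'
#' @param model a [MacModel-class] or [MacFit-class].
#' @param dsTest a nonempty [PatchSet-class].
#' @param batch forward batch size.
#' @return list with `accuracy` (fraction of argmax matches) and `confusion`
#'   (K x K matrix, rows = true category, columns = predicted).
#' @export
evaluateCategories <- function(model, dsTest, batch = 256L) {
  if (is(model, "MacFit")) model <- model@model
  stopUnless(ncol(dsTest) > 0, "empty test set")
  X <- t(patchValues(dsTest))
  y <- patchCategories(dsTest)
  cats <- categoryNames(dsTest)
  K <- length(cats)
  pred <- integer(nrow(X))
  for (s in seq.int(1L, nrow(X), by = batch)) {
    e <- min(nrow(X), s + batch - 1L)
    pred[s:e] <- max.col(macFwd(model@params, model@config,
                                X[s:e, , drop = FALSE])$probs)
  }
  conf <- matrix(0L, K, K, dimnames = list(true = cats, predicted = cats))
  for (i in seq_along(y)) conf[y[i], pred[i]] <- conf[y[i], pred[i]] + 1L
  list(accuracy = mean(pred == y), confusion = conf)
}

#' Per-patch predictions of the classifier
#'
#' @param model a [MacModel-class] or [MacFit-class].
#' @param ds a [PatchSet-class].
#' @param batch forward batch size.
#' @return data.frame with true category, predicted category and the M
#'   attribute values per patch.
#' @export
predictPatches <- function(model, ds, batch = 256L) {
  if (is(model, "MacFit")) model <- model@model
  X <- t(patchValues(ds))
  y <- patchCategories(ds)
  cats <- categoryNames(ds)
  n <- nrow(X); M <- model@config$M
  pred <- integer(n); attrs <- matrix(0, n, M)
  for (s in seq.int(1L, n, by = batch)) {
    e <- min(n, s + batch - 1L)
    fwd <- macFwd(model@params, model@config, X[s:e, , drop = FALSE])
    pred[s:e] <- max.col(fwd$probs)
    attrs[s:e, ] <- fwd$attrs
  }
  out <- data.frame(patch = seq_len(n), true_category = cats[y],
                    predicted_category = cats[pred])
  colnames(attrs) <- paste0("attribute_", seq_len(M) - 1L)
  cbind(out, attrs)
}
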