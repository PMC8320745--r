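#' @include AllClasses.R nn-ops.R
NULL

#' Construct a Siamese similarity model
#'
#' A weight-shared convolutional encoder pair with an order-invariant
#' comparison head: the two embeddings are combined by absolute elementwise
#' difference and passed through two fully connected layers and a sigmoid,
#' giving a same/different score in (0,1). The label convention is
#' y = 1 for a different-class pair, y = 0 for a same-class pair.
#'
#' @param backbone `"tiny"` (4-block encoder used throughout the tests) or
#'   `"wide"`.
#' @param embedDim embedding width.
#' @param headHidden hidden width of the comparison head.
#' @param patchSize input patch side length.
#' @param seed integer seed for the random initialization.
#' @return a [SimilarityModel-class].
#' @export
similarityModel <- function(backbone = "tiny", embedDim = 32L,
                            headHidden = 32L, patchSize = 32L, seed = 1L) {
  cfg <- backboneConfig(backbone, inChannels = 1L, inSize = patchSize)
  cfg$embedDim <- as.integer(embedDim)
  cfg$headHidden <- as.integer(headHidden)
  params <- withSeed(seed, {
    p <- backboneInit(cfg)
    cLast <- cfg$channels[length(cfg$channels)]
    p$emb_W <- heInitMat(cLast, embedDim); p$emb_b <- numeric(embedDim)
    p$head1_W <- heInitMat(embedDim, headHidden); p$head1_b <- numeric(headHidden)
    p$head2_W <- heInitMat(headHidden, 1L); p$head2_b <- numeric(1L)
    p
  })
  new("SimilarityModel", params = params, config = cfg)
}

encodeFwd <- function(params, cfg, X, train = FALSE) {
  bb <- backboneFwd(params, X, cfg, train = train)
  e <- denseFwd(bb$feat, params$emb_W, params$emb_b)
  list(e = e, bb = bb)
}

siameseFwd <- function(params, cfg, X1, X2, train = FALSE) {
  f1 <- encodeFwd(params, cfg, X1, train)
  f2 <- encodeFwd(params, cfg, X2, train)
  d <- abs(f1$e - f2$e)
  h_pre <- denseFwd(d, params$head1_W, params$head1_b)
  h <- h_pre * (h_pre > 0)
  o <- denseFwd(h, params$head2_W, params$head2_b)
  yhat <- sigmoidFn(o[, 1L])
  list(yhat = yhat, f1 = f1, f2 = f2, d = d, h_pre = h_pre, h = h)
}

siameseBwd <- function(params, cfg, fwd, dlogit) {
  grads <- list()
  do <- matrix(dlogit, ncol = 1L)
  b2 <- denseBwd(fwd$h, params$head2_W, do)
  grads$head2_W <- b2$dW; grads$head2_b <- b2$db
  dh <- b2$dX * (fwd$h_pre > 0)
  b1 <- denseBwd(fwd$d, params$head1_W, dh)
  grads$head1_W <- b1$dW; grads$head1_b <- b1$db
  sgn <- sign(fwd$f1$e - fwd$f2$e)
  de1 <- b1$dX * sgn
  de2 <- -de1
  for (side in 1:2) {
    f <- if (side == 1) fwd$f1 else fwd$f2
    de <- if (side == 1) de1 else de2
    be <- denseBwd(f$bb$feat, params$emb_W, de)
    grads <- addGrads(grads, list(emb_W = be$dW, emb_b = be$db))
    grads <- addGrads(grads, backboneBwd(params, f$bb, cfg, be$dX))
  }
  grads
}

#' Binary similarity decision for patch pairs
#'
#' Runs the Siamese network on one or more reference/comparison pairs and
#' returns the predicted probability that the pair is of *different*
#' categories, strictly inside (0,1). The decision is "different" when the
#' score is >= 0.5. Because the head consumes the absolute difference of the
#' two embeddings, swapping the pair leaves the score unchanged.
#'
#' @param model a [SimilarityModel-class] (or [DcnnFit-class]).
#' @param ref,cmp a single patch (matrix or length-d vector) or a batch
#'   (N x d matrix) of flattened patches in \[0,1\].
#' @return numeric vector of scores in (0,1).
#' @export
pairForward <- function(model, ref, cmp) {
  if (is(model, "DcnnFit")) model <- model@model
  asBatch <- function(x) {
    if (is.matrix(x) && nrow(x) == model@config$inSize &&
        ncol(x) == model@config$inSize)
      matrix(as.vector(x), 1L)
    else if (is.null(dim(x))) matrix(x, 1L)
    else as.matrix(x)
  }
  X1 <- asBatch(ref); X2 <- asBatch(cmp)
  d <- model@config$inSize^2
  stopUnless(ncol(X1) == d && ncol(X2) == d && nrow(X1) == nrow(X2),
             "patch shape mismatch: expected flattened length ", d)
  siameseFwd(model@params, model@config, X1, X2)$yhat
}

#' Cross-entropy loss of similarity decisions
#'
#' Mean of -(y log yhat + (1-y) log(1-yhat)); predictions are clamped to
#' \[1e-7, 1 - 1e-7\] before the logarithm.
#'
#' @param yhat predictions in (0,1).
#' @param y binary labels (1 = different classes).
#' @return scalar loss, >= 0.
#' @examples
#' dcnnLoss(0.5, 1)       # log(2)
#' @export
dcnnLoss <- function(yhat, y) {
  eps <- 1e-7
  yhat <- pmin(1 - eps, pmax(eps, yhat))
  mean(-(y * log(yhat) + (1 - y) * log(1 - yhat)))
}

#' Build a set of reference/comparison samples
#'
#' Each sample pairs one reference patch of class c with K comparison
#' patches, one per class in shuffled order; exactly one comparison (the one
#' of class c, always a different patch than the reference) carries label 0,
#' all others label 1. Reference classes are balanced across samples.
#'
#' @param ds a [PatchSet-class]; every class needs >= 2 patches.
#' @param nSamples number of samples.
#' @param seed integer seed.
#' @return data.frame with one row per pair: `sample`, `ref_idx`, `cmp_idx`
#'   (column indices into `ds`), `ref_class`, `cmp_class`, `label`.
#' @export
buildComparisonSet <- function(ds, nSamples, seed = 1L) {
  labs <- patchCategories(ds)
  K <- length(categoryNames(ds))
  byClass <- lapply(seq_len(K), function(k) which(labs == k))
  short <- which(vapply(byClass, length, integer(1)) < 2L)
  stopUnless(length(short) == 0,
             "classes with fewer than 2 patches: ",
             paste(categoryNames(ds)[short], collapse = ", "))
  withSeed(seed, {
    refClasses <- rep_len(sample.int(K), nSamples)
    rows <- vector("list", nSamples)
    for (s in seq_len(nSamples)) {
      rc <- refClasses[s]
      ref <- sample(byClass[[rc]], 1L)
      cmpClasses <- sample.int(K)
      cmp <- integer(K)
      for (j in seq_len(K)) {
        k <- cmpClasses[j]
        pool <- byClass[[k]]
        if (k == rc) pool <- setdiff(pool, ref)
        cmp[j] <- if (length(pool) == 1L) pool else sample(pool, 1L)
      }
      rows[[s]] <- data.frame(sample = s, ref_idx = ref, cmp_idx = cmp,
                              ref_class = rc, cmp_class = cmpClasses,
                              label = as.integer(cmpClasses != rc))
    }
    do.call(rbind, rows)
  })
}

evalPairs <- function(params, cfg, Xt, pairs, batch = 200L) {
  n <- nrow(pairs)
  yhat <- numeric(n)
  for (s in seq.int(1L, n, by = batch)) {
    e <- min(n, s + batch - 1L)
    yhat[s:e] <- siameseFwd(params, cfg, Xt[pairs$ref_idx[s:e], , drop = FALSE],
                            Xt[pairs$cmp_idx[s:e], , drop = FALSE])$yhat
  }
  yhat
}

#' Train the Siamese similarity network
#'
#' Minimizes the pairwise cross-entropy with Adam under a
#' best-validation-checkpoint regimen: after every epoch the validation loss
#' is computed and, whenever it improves on all previous epochs, the model
#' weights are saved together with the distance matrix built from the
#' validation decisions at that epoch.
#'
#' @param dsTrain,dsVal disjoint [PatchSet-class] splits.
#' @param hyper list of hyperparameters: `epochs` (default 15), `batch`
#'   (pairs per gradient step, default 50), `lr` (default 1e-3),
#'   `nTrainSamples` / `nValSamples` (comparison samples drawn from each
#'   split), `nDecisionSamples` (validation comparison samples used to build
#'   the distance matrix from the saved checkpoint; the per-class decision
#'   means carry sampling error of order 1/sqrt(n), so this is larger than
#'   `nValSamples`), `backbone`, `mode` (`"scalar"` or `"profile"` distance
#'   aggregation).
#' @param seed integer seed (initialization, pairing, shuffling).
#' @return a [DcnnFit-class].
#' @export
trainDCNN <- function(dsTrain, dsVal, hyper = list(), seed = 1L) {
  hp <- utils::modifyList(list(epochs = 15L, batch = 50L, lr = 1e-3,
                               nTrainSamples = 400L, nValSamples = 120L,
                               nDecisionSamples = 2000L,
                               backbone = "tiny", mode = "scalar"), hyper)
  seeds <- childSeeds(seed, 5L)
  model <- similarityModel(backbone = hp$backbone, seed = seeds[1])
  params <- model@params; cfg <- model@config
  cats <- categoryNames(dsTrain)

  trainPairs <- buildComparisonSet(dsTrain, hp$nTrainSamples, seeds[2])
  valPairs <- buildComparisonSet(dsVal, hp$nValSamples, seeds[3])
  Xtr <- t(patchValues(dsTrain))
  Xva <- t(patchValues(dsVal))

  opt <- adamInit(params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_acc = numeric())
  best <- list(loss = Inf)
  epochSeeds <- childSeeds(seeds[4], hp$epochs)
  n <- nrow(trainPairs)
  for (ep in seq_len(hp$epochs)) {
    ord <- withSeed(epochSeeds[ep], sample.int(n))
    epLoss <- 0
    for (s in seq.int(1L, n, by = hp$batch)) {
      idx <- ord[s:min(n, s + hp$batch - 1L)]
      X1 <- Xtr[trainPairs$ref_idx[idx], , drop = FALSE]
      X2 <- Xtr[trainPairs$cmp_idx[idx], , drop = FALSE]
      y <- trainPairs$label[idx]
      fwd <- siameseFwd(params, cfg, X1, X2, train = TRUE)
      loss <- dcnnLoss(fwd$yhat, y)
      if (!is.finite(loss))
        stop(sprintf("non-finite training loss at epoch %d (batch at %d)", ep, s),
             call. = FALSE)
      epLoss <- epLoss + loss * length(idx)
      grads <- siameseBwd(params, cfg, fwd, (fwd$yhat - y) / length(idx))
      up <- adamStep(params, grads, opt, hp$lr)
      params <- up$params; opt <- up$state
    }
    yv <- evalPairs(params, cfg, Xva, valPairs)
    valLoss <- dcnnLoss(yv, valPairs$label)
    valAcc <- mean((yv >= 0.5) == (valPairs$label == 1L))
    history <- rbind(history, data.frame(epoch = ep, train_loss = epLoss / n,
                                         val_loss = valLoss, val_acc = valAcc))
    if (valLoss < best$loss)
      best <- list(loss = valLoss, epoch = ep, params = params)
  }
  # decisions for the distance matrix: the saved best checkpoint applied to
  # a larger set of validation comparison samples
  decPairs <- buildComparisonSet(dsVal, hp$nDecisionSamples, seeds[5])
  yd <- evalPairs(best$params, cfg, Xva, decPairs)
  best$dlog <- data.frame(ref_class = decPairs$ref_class,
                          cmp_class = decPairs$cmp_class,
                          decision = as.integer(yd >= 0.5))
  D <- if (identical(hp$mode, "profile")) {
    buildProfileDistanceMatrix(best$dlog, cats)
  } else {
    buildDistanceMatrix(aggregateDecisions(best$dlog, cats), cats)
  }
  D@provenance <- list(mode = hp$mode, bestEpoch = best$epoch, seed = seed)
  new("DcnnFit",
      model = new("SimilarityModel", params = best$params, config = cfg),
      history = history, bestEpoch = as.integer(best$epoch),
      bestValLoss = best$loss, bestD = D, decisionLog = best$dlog,
      seed = as.integer(seed))
}

#' Per-category-pair similarity-decision accuracy
#'
#' Entry (i, j) is the fraction of correct same/different decisions among
#' pairs whose reference patch is of class i and comparison patch of class j.
#' Pairs of perceptually similar categories show lower accuracy. Cells with
#' no pairs are reported as NA.
#'
#' @param model a [SimilarityModel-class] or [DcnnFit-class].
#' @param dsTest a [PatchSet-class].
#' @param nSamples comparison samples to draw.
#' @param seed integer seed.
#' @return K x K matrix of accuracies in \[0,1\] (NA where empty).
#' @export
pairwiseAccuracyMatrix <- function(model, dsTest, nSamples = 200L, seed = 1L) {
  if (is(model, "DcnnFit")) model <- model@model
  cats <- categoryNames(dsTest)
  K <- length(cats)
  pairs <- buildComparisonSet(dsTest, nSamples, seed)
  Xt <- t(patchValues(dsTest))
  yhat <- evalPairs(model@params, model@config, Xt, pairs)
  ok <- (yhat >= 0.5) == (pairs$label == 1L)
  acc <- matrix(NA_real_, K, K, dimnames = list(cats, cats))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    sel <- pairs$ref_class == i & pairs$cmp_class == j
    if (any(sel)) acc[i, j] <- mean(ok[sel])
  }
  acc
}
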