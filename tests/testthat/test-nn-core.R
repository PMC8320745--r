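# gradient checks of the hand-written layers against central differences

test_that("convolution backward matches finite differences", {
  set.seed(11)
  N <- 2L; C <- 2L; H <- 6L; W <- 5L; F <- 3L
  X <- matrix(runif(N * C * H * W), N)
  Wt <- matrix(rnorm(F * C * 9), F)
  b <- rnorm(F)
  R <- matrix(rnorm(N * F * H * W), N)   # random cotangent
  lossW <- function(wv) {
    Y <- medmat:::.conv2d_fwd(X, matrix(wv, F), b, C, H, W, 3L, 3L, 1L)
    sum(Y * R)
  }
  lossX <- function(xv) {
    Y <- medmat:::.conv2d_fwd(matrix(xv, N), Wt, b, C, H, W, 3L, 3L, 1L)
    sum(Y * R)
  }
  bw <- medmat:::.conv2d_bwd(X, Wt, R, C, H, W, 3L, 3L, 1L)
  idx <- sample(length(Wt), 10)
  expect_equal(as.vector(bw$dW)[idx], numericalGrad(lossW, as.vector(Wt), idx),
               tolerance = 1e-6)
  idx <- sample(length(X), 10)
  expect_equal(as.vector(bw$dX)[idx], numericalGrad(lossX, as.vector(X), idx),
               tolerance = 1e-6)
  expect_equal(bw$db, as.vector(tapply(colSums(R), rep(1:F, each = H * W), sum)),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("max pooling routes gradients to the argmax", {
  set.seed(12)
  N <- 3L; C <- 2L; H <- 6L; W <- 6L
  X <- matrix(runif(N * C * H * W), N)
  pl <- medmat:::.maxpool2_fwd(X, C, H, W)
  R <- matrix(rnorm(length(pl$Y)), N)
  f <- function(xv) sum(medmat:::.maxpool2_fwd(matrix(xv, N), C, H, W)$Y * R)
  dX <- medmat:::.maxpool2_bwd(R, pl$idx, C, H, W)
  idx <- sample(length(X), 12)
  expect_equal(as.vector(dX)[idx], numericalGrad(f, as.vector(X), idx),
               tolerance = 1e-6)
})

test_that("the Siamese network gradient matches finite differences end to end", {
  set.seed(13)
  m <- similarityModel(patchSize = 16L, embedDim = 6L, headHidden = 5L, seed = 3)
  n <- 4L
  X1 <- matrix(runif(n * 256), n); X2 <- matrix(runif(n * 256), n)
  y <- c(0, 1, 1, 0)
  params <- m@params; cfg <- m@config
  fwd <- medmat:::siameseFwd(params, cfg, X1, X2, train = TRUE)
  grads <- medmat:::siameseBwd(params, cfg, fwd, (fwd$yhat - y) / n)
  lossAt <- function(p) {
    f <- medmat:::siameseFwd(p, cfg, X1, X2)
    dcnnLoss(f$yhat, y)
  }
  for (nm in c("conv1_W", "conv4_W", "emb_W", "head1_W", "head2_W", "head2_b")) {
    par <- params[[nm]]
    idx <- sample(length(par), min(4, length(par)))
    num <- vapply(idx, function(i) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + 1e-5
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - 1e-5
      (lossAt(p1) - lossAt(p2)) / 2e-5
    }, numeric(1))
    expect_equal(as.vector(grads[[nm]])[idx], num, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
})

test_that("the classifier gradient (all three loss terms) matches finite differences", {
  set.seed(14)
  m <- macModel(K = 3, M = 3, patchSize = 16L, auxHidden = 8L,
                catHidden = c(8L, 10L), seed = 5)
  n <- 5L
  X <- matrix(runif(n * 256), n)
  y <- c(1L, 2L, 3L, 1L, 2L)
  Av <- matrix(runif(9, 0.1, 0.9), 3, 3)
  P <- medmat:::defaultEvalPoints(); h <- 0.1
  params <- m@params; cfg <- m@config
  fwd <- medmat:::macFwd(params, cfg, X, train = TRUE)
  g <- medmat:::macLossGrad(fwd, y, Av, gamma1 = 0.05, gamma2 = 1, P, h)
  grads <- medmat:::macBwd(params, cfg, fwd, g$dlogits, g$dattrs)
  lossAt <- function(p) {
    f <- medmat:::macFwd(p, cfg, X)
    as.numeric(macLoss(f$probs, f$attrs, y, Av, gamma1 = 0.05, gamma2 = 1,
                       P = P, h = h)) / n
  }
  for (nm in c("conv1_W", "cat3_W", "aux2_1W", "comb2_W", "comb1_b")) {
    par <- params[[nm]]
    idx <- sample(length(par), min(4, length(par)))
    num <- vapply(idx, function(i) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + 1e-5
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - 1e-5
      (lossAt(p1) - lossAt(p2)) / 2e-5
    }, numeric(1))
    expect_equal(as.vector(grads[[nm]])[idx], num, tolerance = 1e-4,
                 label = paste("grad", nm))
  }
})

test_that("forward passes are deterministic", {
  m <- similarityModel(seed = 2)
  x <- matrix(runif(1024), 32)
  expect_identical(pairForward(m, x, x), pairForward(m, x, x))
  mm <- macModel(K = 4, M = 4, seed = 2)
  f1 <- macForward(mm, x); f2 <- macForward(mm, x)
  expect_identical(f1, f2)
})
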