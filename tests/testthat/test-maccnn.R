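test_that("clippedLinear is the piecewise identity clamp", {
  expect_identical(clippedLinear(c(-1, 0.3, 2)), c(0, 0.3, 1))
  x <- seq(-2, 3, length.out = 101)
  expect_identical(clippedLinear(clippedLinear(x)), clippedLinear(x))
  m <- matrix(c(-0.5, 0.2, 0.9, 1.4), 2)
  expect_identical(clippedLinear(m), matrix(c(0, 0.2, 0.9, 1), 2))
})

test_that("macLoss decomposes into NLL, KL and attribute-consistency terms", {
  probs <- rbind(c(0.97, 0.02, 0.01), c(0.01, 0.98, 0.01))
  attrs <- rbind(c(0.2, 0.8), c(0.6, 0.4))
  y <- c(1L, 2L)
  Av <- rbind(c(0.2, 0.8), c(0.6, 0.4), c(0.5, 0.5))
  # perfect certainty with both gammas off is (numerically) zero
  hot <- rbind(c(1, 0, 0), c(0, 1, 0))
  l0 <- macLoss(hot, attrs, y, Av, gamma1 = 0, gamma2 = 0)
  expect_lt(as.numeric(l0), 1e-6)
  # gamma2 term vanishes when batch attribute means equal the matrix rows
  l2 <- macLoss(probs, attrs, y, Av, gamma1 = 0, gamma2 = 1)
  comp <- attr(l2, "components")
  expect_equal(unname(comp["attr"]), 0, tolerance = 1e-12)
  # bare NLL decomposition holds to 1e-10
  lNll <- macLoss(probs, attrs, y, Av, gamma1 = 0, gamma2 = 0)
  expect_equal(as.numeric(lNll), -(log(0.97) + log(0.98)), tolerance = 1e-10)
})

test_that("a single-sample macLoss equals a hand-evaluated three-term sum", {
  probs <- matrix(c(0.7, 0.2, 0.1), 1)
  attrs <- matrix(c(0.3, 0.9), 1)
  Av <- rbind(c(0.5, 0.5), c(0.1, 0.9), c(0.9, 0.1))
  P <- medmat:::defaultEvalPoints(); h <- 0.1
  got <- macLoss(probs, attrs, 1L, Av, gamma1 = 0.3, gamma2 = 2, P = P, h = h)
  nll <- -log(0.7)
  bet <- dbeta(P, 0.5, 0.5)
  q <- vapply(P, function(p) mean(dnorm(p, mean = c(0.3, 0.9), sd = h)),
              numeric(1))
  kl <- sum(bet * log(bet / pmax(q, 1e-12)))
  att <- sum((Av[1, ] - c(0.3, 0.9))^2)
  expect_equal(as.numeric(got), nll + 0.3 * kl + 2 * att, tolerance = 1e-10)
  expect_error(macLoss(probs[0, , drop = FALSE], attrs[0, , drop = FALSE],
                       integer(0), Av), "empty")
})

test_that("attribute outputs always lie in the unit interval", {
  m <- macModel(K = 3, M = 5, seed = 4)
  set.seed(9)
  X <- matrix(runif(8 * 1024), 8)
  out <- macForward(m, X)
  expect_true(all(out$attributes >= 0 & out$attributes <= 1))
  expect_identical(dim(out$attributes), c(8L, 5L))
  expect_equal(rowSums(out$categoryScores), rep(1, 8), tolerance = 1e-9)
  expect_error(macForward(m, matrix(runif(100), 10)), "shape")
})

test_that("training honors the scheduler and checkpoint contracts deterministically", {
  ds <- makeToyPatchSet(K = 3, perClass = 14, seed = 51, spread = 0.08)
  spl <- splitDataset(ds, seed = 3)
  Av <- matrix(runif(9, 0.2, 0.8), 3, 3)
  # deliberately hot learning rate so validation loss fluctuates
  hp <- list(epochs = 5L, batch = 16L, lr0 = 0.02)
  fit <- trainMACCNN(spl$train, spl$val, Av, hp, seed = 6)
  h <- fit@history
  expect_identical(nrow(h), 5L)
  # the lr used in epoch e+1 is lr_e / 10 exactly when val loss rose at e
  for (e in 1:4) {
    if (e > 1 && h$val_loss[e] > h$val_loss[e - 1]) {
      expect_equal(h$lr[e + 1], h$lr[e] / 10, tolerance = 1e-15)
    } else if (e > 1) {
      expect_identical(h$lr[e + 1], h$lr[e])
    }
  }
  expect_equal(fit@bestValLoss, min(h$val_loss))
  expect_identical(h$val_loss[fit@bestEpoch], fit@bestValLoss)
  fit2 <- trainMACCNN(spl$train, spl$val, Av, hp, seed = 6)
  expect_identical(fit@history, fit2@history)
  # the returned model is really the best-epoch checkpoint: its validation
  # loss recomputes to bestValLoss
  vf <- medmat:::macFwd(fit@model@params, fit@model@config,
                        t(patchValues(spl$val)))
  vl <- medmat:::batchMeanLoss(vf, patchCategories(spl$val), Av, 1e-2, 1,
                               medmat:::defaultEvalPoints(), 0.1)
  expect_equal(vl, fit@bestValLoss, tolerance = 1e-12)
})

test_that("category evaluation conserves counts in the confusion matrix", {
  ds <- makeToyPatchSet(K = 3, perClass = 10, seed = 61)
  m <- macModel(K = 3, M = 4, seed = 2)
  ev <- evaluateCategories(m, ds)
  expect_identical(sum(ev$confusion), 30L)
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / 30)
  expect_true(all(rowSums(ev$confusion) == 10))
  expect_error(evaluateCategories(m, ds[, integer(0)]), "empty")
})
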