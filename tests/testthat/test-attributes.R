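test_that("the Beta target density has its closed form and symmetry", {
  expect_equal(betaDensity(0.5), 2 / pi, tolerance = 1e-12)
  expect_equal(betaDensity(0.25), betaDensity(0.75), tolerance = 1e-12)
  expect_equal(betaDensity(0.3), 1 / (pi * sqrt(0.3 * 0.7)), tolerance = 1e-12)
  expect_true(all(betaDensity(seq(0.1, 0.9, 0.1), a = 1, b = 1) == 1))
  expect_error(betaDensity(0), "strictly inside")
  expect_error(betaDensity(1), "strictly inside")
})

test_that("the entry KDE is a normalized equal-weight Gaussian mixture", {
  set.seed(3)
  for (h in c(0.05, 0.1, 0.3)) {
    A <- matrix(runif(12), 3, 4)
    grid <- seq(-5, 6, length.out = 4001)
    q <- kdeDensity(grid, A, h)
    integral <- sum((q[-1] + q[-length(q)]) / 2 * diff(grid))
    expect_equal(integral, 1, tolerance = 1e-4)
  }
  # collapsed mixture peaks at (2 pi h^2)^(-1/2)
  Ac <- matrix(0.4, 2, 3)
  expect_equal(kdeDensity(0.4, Ac, h = 0.1), 1 / sqrt(2 * pi * 0.01),
               tolerance = 1e-12)
  # two-component hand evaluation
  A2 <- matrix(c(0, 0, 1, 1), 2, 2)
  hand <- 0.5 * (dnorm(0.5, 0, 0.1) + dnorm(0.5, 1, 0.1))
  expect_equal(kdeDensity(0.5, A2, h = 0.1), hand, tolerance = 1e-12)
})

test_that("the objective vanishes on exact embeddings and doubles over ordered pairs", {
  d <- 0.6
  A <- rbind(c(0, 0), c(d / sqrt(2), d / sqrt(2)))
  D <- matrix(c(0, d, d, 0), 2)
  expect_equal(attributeObjective(A, D, gamma = 0), 0, tolerance = 1e-12)
  # all rows equal against off-diagonal x: ordered-pair convention gives 2x^2
  Ae <- matrix(0.5, 2, 3)
  x <- 0.4
  Dx <- matrix(c(0, x, x, 0), 2)
  expect_equal(attributeObjective(Ae, Dx, gamma = 0), 2 * x^2, tolerance = 1e-12)
})

test_that("the analytic objective gradient matches finite differences", {
  set.seed(7)
  K <- 4; M <- 3
  A <- matrix(runif(K * M, 0.15, 0.85), K, M)
  D <- as.matrix(dist(matrix(runif(K * 2), K)))
  P <- medmat:::defaultEvalPoints()
  g <- medmat:::attributeObjectiveGrad(A, D, gamma = 0.5, P = P, h = 0.1)
  f <- function(par) attributeObjective(matrix(par, K, M), D, gamma = 0.5,
                                        P = P, h = 0.1)
  idx <- sample(K * M, 8)
  expect_equal(as.vector(g)[idx], numericalGrad(f, as.vector(A), idx),
               tolerance = 1e-6)
})

test_that("optimization recovers an embeddable distance matrix at gamma = 0", {
  set.seed(5)
  K <- 5; M <- 3
  pts <- matrix(runif(K * M), K, M)
  D <- as.matrix(dist(pts))
  rownames(D) <- colnames(D) <- paste0("c", 1:K)
  A <- optimizeA(D, M = M, gamma = 0, seed = 4, restarts = 3)
  expect_lte(A@objectiveValue, 1e-4)
  # recovered pairwise distances match within 1e-2 RMS
  res <- as.matrix(dist(A@values)) - D
  expect_lte(sqrt(mean(res[upper.tri(res)]^2)), 1e-2)
  A2 <- optimizeA(D, M = M, gamma = 0, seed = 4, restarts = 3)
  expect_identical(A@values, A2@values)
})

test_that("a stronger gamma pulls the entry distribution toward the Beta target", {
  set.seed(6)
  D <- as.matrix(dist(matrix(runif(8), 4)))
  rownames(D) <- colnames(D) <- paste0("c", 1:4)
  P <- medmat:::defaultEvalPoints()
  kl <- vapply(c(0, 5), function(g) {
    A <- optimizeA(D, M = 4, gamma = g, seed = 9, restarts = 3)
    medmat:::klTermOn(A@values, P, h = 0.1)
  }, numeric(1))
  expect_lt(kl[2], kl[1])
})

test_that("with no distance signal the optimal entries are bimodal near 0 and 1", {
  D0 <- matrix(0, 3, 3)
  rownames(D0) <- colnames(D0) <- paste0("c", 1:3)
  A <- optimizeA(D0, M = 4, gamma = 1, seed = 2, restarts = 2)
  v <- as.vector(A@values)
  tails <- mean(v <= 0.2 | v >= 0.8)
  middle <- mean(v >= 0.4 & v <= 0.6)
  expect_gt(tails, middle)
})

test_that("attribute matrices round-trip through CSV plus JSON", {
  D <- buildDistanceMatrix(c(a = 0.2, b = 0.6, c = 0.4))
  A <- optimizeA(D, M = 3, gamma = 0.1, seed = 3, restarts = 2, maxit = 200)
  path <- file.path(withr::local_tempdir(), "A.csv")
  writeAttributeMatrix(A, path)
  back <- readAttributeMatrix(path)
  expect_equal(as.matrix(back), as.matrix(A), tolerance = 1e-12)
  expect_equal(back@objectiveValue, A@objectiveValue, tolerance = 1e-12)
  expect_identical(back@bandwidth, A@bandwidth)
})
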