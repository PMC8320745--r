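#' @include AllClasses.R utils.R
NULL

defaultEvalPoints <- function() seq(0.005, 0.995, length.out = 101L)

#' Beta target density
#'
#' Density of the Beta(a, b) target distribution; the default a = b = 0.5
#' (arcsine) distribution encodes the prior that attributes are mostly
#' strongly present or strongly absent, equal to 1 / (pi * sqrt(p (1 - p))).
#'
#' @param p evaluation points strictly inside (0, 1).
#' @param a,b shape parameters, > 0.
#' @return density values.
#' @examples
#' betaDensity(0.5)      # 2 / pi
#' @export
betaDensity <- function(p, a = 0.5, b = 0.5) {
  stopUnless(all(p > 0 & p < 1),
             "evaluation points must lie strictly inside (0, 1)")
  stopUnless(a > 0 && b > 0, "shape parameters must be positive")
  dbeta(p, a, b)
}

#' Gaussian kernel density estimate of a matrix's entries
#'
#' Places a Gaussian kernel of bandwidth h on every entry of A with equal
#' weight 1/(KM): q(p; A) = (1/KM) sum_km (2 pi h^2)^(-1/2)
#' exp(-(a_km - p)^2 / (2 h^2)). As a mixture of normalized Gaussians it
#' integrates to 1 over the real line.
#'
#' @param p evaluation point(s).
#' @param A an [AttributeMatrix-class] or numeric matrix/vector of entries.
#' @param h bandwidth (> 0); taken from the AttributeMatrix when omitted.
#' @return density values, same length as `p`.
#' @export
kdeDensity <- function(p, A, h = NULL) {
  if (is(A, "AttributeMatrix")) {
    if (is.null(h)) h <- A@bandwidth
    A <- A@values
  }
  stopUnless(!is.null(h) && h > 0, "bandwidth h must be > 0")
  a <- as.vector(A)
  vapply(p, function(pp) mean(dnorm(pp, mean = a, sd = h)), numeric(1))
}

# KL(beta || q) estimated on the grid P: sum_p beta(p) log(beta(p) / q(p))
klTermOn <- function(entries, P, h, a = 0.5, b = 0.5, eps = 1e-12) {
  bet <- betaDensity(P, a, b)
  q <- pmax(kdeDensity(P, entries, h), eps)
  sum(bet * log(bet / q))
}

#' Objective of the category-attribute matrix
#'
#' The sum over ordered pairs k != k' of (||a_k - a_k'|| - D_kk')^2 (rows of
#' A embed the perceptual distances) plus gamma times the KL divergence,
#' evaluated on the grid `P`, between the Beta(a, b) target and the Gaussian
#' KDE of A's entries. The KDE is clamped to 1e-12 before the logarithm.
#'
#' @param A numeric K x M matrix with entries in \[0,1\]
#'   (or an [AttributeMatrix-class]).
#' @param D a [DistanceMatrix-class] or K x K matrix.
#' @param gamma KL term weight, >= 0.
#' @param P evaluation grid in (0,1); default 101 equispaced points in
#'   \[0.005, 0.995\].
#' @param h KDE bandwidth.
#' @param a,b Beta target shape parameters.
#' @return scalar objective value.
#' @export
attributeObjective <- function(A, D, gamma = 0.1, P = defaultEvalPoints(),
                               h = 0.1, a = 0.5, b = 0.5) {
  if (is(A, "AttributeMatrix")) A <- A@values
  if (is(D, "DistanceMatrix")) D <- D@values
  stopUnless(nrow(A) == nrow(D), "A and D disagree on the number of categories")
  dd <- as.matrix(dist(A))
  distTerm <- sum((dd - D)^2)   # ordered pairs; diagonal contributes zero
  klTerm <- if (gamma > 0) klTermOn(A, P, h, a, b) else 0
  distTerm + gamma * klTerm
}

# analytic gradient of attributeObjective with respect to the entries of A
attributeObjectiveGrad <- function(A, D, gamma, P, h, a = 0.5, b = 0.5,
                                   eps = 1e-12) {
  K <- nrow(A); M <- ncol(A)
  dd <- as.matrix(dist(A))
  G <- matrix(0, K, M)
  for (k in seq_len(K)) {
    diffs <- sweep(-A[-k, , drop = FALSE], 2, -A[k, ])  # a_k - a_k'
    nr <- dd[k, -k]
    r <- nr - D[k, -k]
    w <- ifelse(nr > 0, 4 * r / nr, 0)  # both orderings of each pair
    G[k, ] <- colSums(diffs * w)
  }
  if (gamma > 0) {
    bet <- betaDensity(P, a, b)
    av <- as.vector(A)
    # Phi[e, p] = dnorm(a_e - P_p, sd = h)
    Phi <- outer(av, P, function(x, p) dnorm(x - p, sd = h))
    q <- pmax(colMeans(Phi), eps)
    # d/da_e of -sum_p bet log q = sum_p (bet/q) * Phi * (a_e - p) / h^2 / (KM)
    coef <- bet / q
    dKL <- (Phi * outer(av, P, "-")) %*% coef / (h^2 * K * M)
    G <- G + gamma * matrix(dKL, K, M)
  }
  G
}

#' Optimize the category-attribute matrix
#'
#' Box-constrained quasi-Newton (L-BFGS-B) minimization of
#' [attributeObjective()] over A in \[0,1\]^(K x M), run from `restarts`
#' seeded random initializations (entries i.i.d. uniform on \[0.1, 0.9\]);
#' the best final iterate is returned. The optimized matrix is held constant
#' downstream as the attribute target of the classifier loss.
#'
#' @param D a [DistanceMatrix-class] (or K x K matrix with category names).
#' @param M number of attributes (>= 2).
#' @param gamma KL term weight.
#' @param seed integer seed.
#' @param restarts number of random initializations.
#' @param h KDE bandwidth.
#' @param P KL evaluation grid.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @return an [AttributeMatrix-class] with `objectiveValue` equal to
#'   [attributeObjective()] at the returned matrix.
#' @export
optimizeA <- function(D, M = 4L, gamma = 0.1, seed = 1L, restarts = 5L,
                      h = 0.1, P = defaultEvalPoints(), maxit = 1000L) {
  cats <- if (is(D, "DistanceMatrix")) D@categoryNames else rownames(D)
  Dm <- if (is(D, "DistanceMatrix")) D@values else unname(as.matrix(D))
  K <- nrow(Dm)
  stopUnless(M >= 2, "at least M = 2 attributes are required")
  if (is.null(cats)) cats <- paste0("cat_", seq_len(K))
  fn <- function(par) attributeObjective(matrix(par, K, M), Dm, gamma, P, h)
  gr <- function(par) as.vector(
    attributeObjectiveGrad(matrix(par, K, M), Dm, gamma, P, h))
  seeds <- childSeeds(seed, restarts)
  best <- NULL
  anyConverged <- FALSE
  for (r in seq_len(restarts)) {
    init <- withSeed(seeds[r], runif(K * M, 0.1, 0.9))
    fit <- optim(init, fn, gr, method = "L-BFGS-B", lower = 0, upper = 1,
                 control = list(maxit = maxit, factr = 1e4))
    if (fit$convergence == 0) anyConverged <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!anyConverged)
    warning("L-BFGS-B did not converge in any restart; returning best iterate",
            call. = FALSE)
  Av <- matrix(clamp01(best$par), K, M)
  new("AttributeMatrix", values = Av, categoryNames = cats, gamma = gamma,
      bandwidth = h, evalPoints = P,
      objectiveValue = attributeObjective(Av, Dm, gamma, P, h),
      seed = as.integer(seed))
}

#' Write / read an attribute matrix as CSV plus JSON metadata
#'
#' Rows are categories, columns `attribute_0 .. attribute_{M-1}`; the JSON
#' sidecar (`<path>.json`) records M, gamma, bandwidth, the evaluation-grid
#' range, the objective value and the seed.
#'
#' @param A an [AttributeMatrix-class].
#' @param path CSV path.
#' @return `writeAttributeMatrix`: invisibly, `path`;
#'   `readAttributeMatrix`: an [AttributeMatrix-class].
#' @export
writeAttributeMatrix <- function(A, path) {
  write.csv(as.matrix(A), path, row.names = TRUE)
  meta <- list(M = ncol(A@values), gamma = A@gamma, bandwidth = A@bandwidth,
               evalPoints = list(min = min(A@evalPoints),
                                 max = max(A@evalPoints),
                                 n = length(A@evalPoints)),
               objectiveValue = A@objectiveValue, seed = A@seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeAttributeMatrix
#' @export
readAttributeMatrix <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  cats <- rownames(m)
  dimnames(m) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("AttributeMatrix", values = m, categoryNames = cats,
      gamma = meta$gamma, bandwidth = meta$bandwidth,
      evalPoints = seq(meta$evalPoints$min, meta$evalPoints$max,
                       length.out = meta$evalPoints$n),
      objectiveValue = meta$objectiveValue, seed = as.integer(meta$seed))
}
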