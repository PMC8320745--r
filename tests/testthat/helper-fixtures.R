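# shared fixtures; everything is generated in code, no stored data

# A labeled patch set built directly (class-k patches are Gaussian noise
# around a class-specific brightness), bypassing image extraction so model
# tests are independent of the patch module.
makeToyPatchSet <- function(K = 3, perClass = 20, patchSize = 32, seed = 1,
                            spread = 0.04) {
  d <- patchSize^2
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    n <- K * perClass
    base <- seq(0.2, 0.8, length.out = K)
    vals <- matrix(0, d, n)
    cat <- integer(n)
    for (k in seq_len(K)) {
      idx <- ((k - 1) * perClass + 1):(k * perClass)
      vals[, idx] <- matrix(base[k] + rnorm(d * perClass, sd = spread),
                            d, perClass)
      cat[idx] <- k
    }
    vals[vals < 0] <- 0; vals[vals > 1] <- 1
    cd <- S4Vectors::DataFrame(
      image_id = sprintf("toy%03d", seq_len(n)), x = seq_len(n), y = 1L,
      category = cat, avgBrightness = colMeans(vals), maskFraction = 0)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(values = vals), colData = cd,
      metadata = list(categoryNames = paste0("class_", seq_len(K)),
                      patchSize = patchSize, split = NA_character_))
    new("PatchSet", se)
  })
}

# Independent brute-force re-application of the patch categorization rules
# at every grid point of an image; deliberately written from the rule
# definitions, not via the package's categorizeRegion().
oracleEnumerate <- function(img, constraints, spacing = 8L, size = 32L) {
  px <- img@pixels; msk <- img@mask
  H <- nrow(px); W <- ncol(px)
  rows <- list()
  for (x in seq.int(1L, W - size + 1L, by = spacing)) {
    for (y in seq.int(1L, H - size + 1L, by = spacing)) {
      p <- px[y:(y + size - 1L), x:(x + size - 1L)]
      bbar <- sum(p) / length(p)
      mf <- if (is.null(msk)) 0 else sum(msk[y:(y + size - 1L), x:(x + size - 1L)] != 0) / (size * size)
      lab <- NA_character_
      if (bbar < constraints@bNull) {
        lab <- img@bindings$null
      } else if (bbar >= constraints@bMin && bbar <= constraints@bMax) {
        tol <- constraints@maskTolerance
        if (mf >= 1 - tol && !is.na(img@bindings$expert)) lab <- img@bindings$expert
        else if (mf <= tol) lab <- img@bindings$naive
      }
      if (!is.na(lab))
        rows[[length(rows) + 1L]] <- data.frame(image_id = img@id, x = x,
                                                y = y, category = lab)
    }
  }
  do.call(rbind, rows)
}

numericalGrad <- function(f, par, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    p1 <- par; p1[i] <- p1[i] + eps
    p2 <- par; p2[i] <- p2[i] - eps
    (f(p1) - f(p2)) / (2 * eps)
  }, numeric(1))
}
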