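#' @include AllClasses.R utils.R
NULL

#' Create brightness constraints
#'
#' @param bMin,bMax brightness window for non-null patches.
#' @param bNull brightness below which a patch is null-category.
#' @param maskTolerance the mask tolerance T in (0, 0.5): expert patches need
#'   mask coverage >= 1 - T, naive patches <= T; coverage strictly inside
#'   (T, 1 - T) straddles the mask boundary and is rejected.
#' @return a [BrightnessConstraints-class].
#' @export
brightnessConstraints <- function(bMin = 0.1, bMax = 0.95, bNull = 0.05,
                                  maskTolerance = 0.05) {
  new("BrightnessConstraints", bMin = bMin, bMax = bMax, bNull = bNull,
      maskTolerance = maskTolerance)
}

#' Normalize a raw image to \[0,1\]
#'
#' Min-max normalizes the raw values; a negative (an image where bright
#' encodes dark) is inverted after normalization. A constant-valued image is
#' emitted as all zeros with a warning.
#'
#' @param raw numeric or integer matrix.
#' @param isNegative invert after normalization.
#' @param id image identifier.
#' @param mask optional binary matrix of the expert region.
#' @param modalityTag free-form tag.
#' @param bindings named list: category names emitted by the `null`, `naive`
#'   and `expert` rules for this image (`expert` may be NA).
#' @return a [SourceImage-class].
#' @examples
#' img <- normalizeImage(matrix(c(0L, 128L, 255L), 1), id = "toy")
#' range(img@pixels)
#' @export
normalizeImage <- function(raw, isNegative = FALSE, id = "img",
                           mask = NULL, modalityTag = "unknown",
                           bindings = list(null = "null", naive = "naive",
                                           expert = NA_character_)) {
  stopUnless(length(raw) > 0, "empty image")
  raw <- as.matrix(raw)
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    warning("constant-valued image; emitting all-zero pixels", call. = FALSE)
    px <- matrix(0, nrow(raw), ncol(raw))
  } else {
    px <- (raw - rng[1]) / (rng[2] - rng[1])
    if (isNegative) px <- 1 - px
  }
  new("SourceImage", pixels = px, mask = mask, modalityTag = modalityTag,
      negative = isNegative, id = id, bindings = bindings)
}

#' Average brightness of a region
#'
#' The sum of the region's normalized values divided by the number of values.
#'
#' @param region numeric matrix or vector.
#' @return the mean, a scalar.
#' @export
averageBrightness <- function(region) {
  stopUnless(length(region) > 0, "empty region")
  mean(region)
}

#' Mask coverage fraction of a region
#'
#' Fraction of mask-positive pixels in the candidate patch's source region;
#' an absent mask counts as 0 by convention.
#'
#' @param regionMask binary matrix (same shape as the patch), or NULL.
#' @return scalar in \[0,1\].
#' @export
maskFraction <- function(regionMask) {
  if (is.null(regionMask)) return(0)
  mean(regionMask != 0)
}

#' Categorize a candidate patch region
#'
#' Applies the categorization rules in order: (1) average brightness below
#' `bNull` puts the patch in the null category regardless of the mask or the
#' brightness window; (2) brightness outside \[`bMin`, `bMax`\] rejects it;
#' (3) mask coverage >= 1 - T assigns the image's expert category, coverage
#' <= T its naive category, and anything in between straddles the mask
#' boundary and is rejected.
#'
#' @param patch numeric matrix of normalized values.
#' @param constraints a [BrightnessConstraints-class].
#' @param bindings named list (`null`, `naive`, `expert`) of category names.
#' @param regionMask binary matrix aligned with `patch`, or NULL.
#' @return the assigned category name, or `NA_character_` for a rejection.
#' @export
categorizeRegion <- function(patch, constraints, bindings, regionMask = NULL) {
  b <- averageBrightness(patch)
  if (b < constraints@bNull) return(bindings$null)
  if (b < constraints@bMin || b > constraints@bMax) return(NA_character_)
  mf <- maskFraction(regionMask)
  tol <- constraints@maskTolerance
  if (mf >= 1 - tol) {
    if (is.na(bindings$expert)) return(NA_character_)
    return(bindings$expert)
  }
  if (mf <= tol) return(bindings$naive)
  NA_character_
}

# evaluate all grid points of one image; returns a data.frame of candidates
# (x, y are the 1-based top-left pixel; the patch extends patchSize pixels
# rightward and downward)
enumerateCandidates <- function(img, constraints, gridSpacing, patchSize) {
  H <- nrow(img@pixels); W <- ncol(img@pixels)
  if (H < patchSize || W < patchSize)
    return(data.frame(image_id = character(), x = integer(), y = integer(),
                      category = character(), avgBrightness = numeric(),
                      maskFraction = numeric()))
  xs <- seq.int(1L, W - patchSize + 1L, by = gridSpacing)
  ys <- seq.int(1L, H - patchSize + 1L, by = gridSpacing)
  grid <- expand.grid(y = ys, x = xs)    # column-major order: y fastest
  n <- nrow(grid)
  cat <- character(n); ab <- numeric(n); mf <- numeric(n)
  for (i in seq_len(n)) {
    y <- grid$y[i]; x <- grid$x[i]
    p <- img@pixels[y:(y + patchSize - 1L), x:(x + patchSize - 1L)]
    m <- if (is.null(img@mask)) NULL
         else img@mask[y:(y + patchSize - 1L), x:(x + patchSize - 1L)]
    ab[i] <- mean(p)
    mf[i] <- maskFraction(m)
    cat[i] <- categorizeRegion(p, constraints, img@bindings, m)
  }
  data.frame(image_id = img@id, x = grid$x, y = grid$y, category = cat,
             avgBrightness = ab, maskFraction = mf,
             stringsAsFactors = FALSE)
}

buildPatchSet <- function(images, picks, categories, patchSize, split = NA_character_) {
  n <- nrow(picks)
  vals <- matrix(0, patchSize * patchSize, n)
  byId <- stats::setNames(images, vapply(images, function(i) i@id, character(1)))
  for (i in seq_len(n)) {
    img <- byId[[picks$image_id[i]]]
    y <- picks$y[i]; x <- picks$x[i]
    vals[, i] <- as.vector(img@pixels[y:(y + patchSize - 1L),
                                      x:(x + patchSize - 1L)])
  }
  cd <- S4Vectors::DataFrame(
    image_id = picks$image_id, x = picks$x, y = picks$y,
    category = match(picks$category, categories),
    avgBrightness = picks$avgBrightness, maskFraction = picks$maskFraction)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = vals), colData = cd,
    metadata = list(categoryNames = categories, patchSize = patchSize,
                    split = split))
  new("PatchSet", se)
}

#' Select and categorize unique patches from a set of images
#'
#' Walks the grid of candidate points (spaced `gridSpacing` pixels apart,
#' patch extending `patchSize` pixels below and to the right of each point),
#' applies [categorizeRegion()] at every point, and samples accepted patches
#' round-robin across categories so the emitted set is as class-balanced as
#' the eligible pool allows. Every emitted patch originates from a unique
#' (image, x, y).
#'
#' @param images list of [SourceImage-class].
#' @param constraints a [BrightnessConstraints-class].
#' @param nTarget total number of patches wanted; `Inf` enumerates the whole
#'   eligible grid ("exhaustive" mode).
#' @param gridSpacing grid spacing p in pixels.
#' @param patchSize patch side length (default 32).
#' @param seed integer seed controlling sampling order.
#' @param categories category names defining the index order; every category
#'   must be eligible somewhere or a configuration error is raised.
#' @return a [PatchSet-class]. If the eligible grid is exhausted before
#'   `nTarget`, the partial set is returned with a warning.
#' @export
generatePatches <- function(images, constraints, nTarget, gridSpacing = 8L,
                            patchSize = 32L, seed = 1L, categories = NULL) {
  stopUnless(gridSpacing >= 1, "gridSpacing must be >= 1")
  cand <- do.call(rbind, lapply(images, enumerateCandidates,
                                constraints = constraints,
                                gridSpacing = gridSpacing,
                                patchSize = patchSize))
  cand <- cand[!is.na(cand$category), , drop = FALSE]
  if (is.null(categories)) categories <- sort(unique(cand$category))
  missing <- setdiff(categories, unique(cand$category))
  stopUnless(length(missing) == 0,
             "no eligible patches for category: ", paste(missing, collapse = ", "))
  extra <- setdiff(unique(cand$category), categories)
  if (length(extra)) cand <- cand[cand$category %in% categories, , drop = FALSE]

  if (is.finite(nTarget)) {
    picks <- withSeed(seed, {
      pools <- lapply(categories, function(cc) {
        rows <- which(cand$category == cc)
        rows[sample.int(length(rows))]
      })
      chosen <- integer(0)
      ptr <- rep(1L, length(pools))
      total <- 0L
      repeat {
        advanced <- FALSE
        for (k in seq_along(pools)) {
          if (total >= nTarget) break
          if (ptr[k] <= length(pools[[k]])) {
            chosen <- c(chosen, pools[[k]][ptr[k]])
            ptr[k] <- ptr[k] + 1L
            total <- total + 1L
            advanced <- TRUE
          }
        }
        if (total >= nTarget || !advanced) break
      }
      cand[chosen, , drop = FALSE]
    })
    if (nrow(picks) < nTarget)
      warning(sprintf("eligible grid exhausted: %d of %d patches emitted",
                      nrow(picks), nTarget), call. = FALSE)
  } else {
    picks <- cand
  }
  buildPatchSet(images, picks, categories, patchSize)
}

#' Split a patch set into train / validation / test subsets
#'
#' Per-category stratified split: within each category the patches are
#' shuffled with `seed` and allocated to the three subsets by `fractions`
#' (largest-remainder rounding), so the subsets are disjoint and exhaustive.
#'
#' @param ds a [PatchSet-class].
#' @param fractions length-3 nonnegative vector summing to 1
#'   (default 0.6 / 0.2 / 0.2).
#' @param seed integer seed.
#' @return named list of PatchSets: `train`, `val`, `test`.
#' @export
splitDataset <- function(ds, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopUnless(length(fractions) == 3 && all(fractions >= 0) &&
               abs(sum(fractions) - 1) < 1e-9,
             "fractions must be three nonnegative values summing to 1")
  labs <- patchCategories(ds)
  counts <- table(labs)
  if (any(counts < 3) && all(fractions > 0))
    stop("every category needs at least 3 patches to stratify", call. = FALSE)
  assign3 <- function(n) {
    base <- floor(fractions * n)
    rem <- n - sum(base)
    if (rem > 0) {
      frac <- fractions * n - base
      ord <- order(frac, decreasing = TRUE)
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
    }
    rep.int(c("train", "val", "test"), base)
  }
  member <- withSeed(seed, {
    out <- character(length(labs))
    for (k in unique(labs)) {
      idx <- which(labs == k)
      idx <- idx[sample.int(length(idx))]
      out[idx] <- assign3(length(idx))
    }
    out
  })
  subsetSplit <- function(which) {
    sel <- member == which
    se <- ds[, sel]
    S4Vectors::metadata(se)$split <- which
    new("PatchSet", se)
  }
  list(train = subsetSplit("train"), val = subsetSplit("val"),
       test = subsetSplit("test"))
}

#' Write a patch manifest CSV
#'
#' One row per patch: image id, x, y, category name, average brightness and
#' mask fraction, plus the split label when the set carries one.
#'
#' @param ds a [PatchSet-class].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writePatchManifest <- function(ds, path) {
  info <- as.data.frame(patchInfo(ds))
  info$category <- categoryNames(ds)[info$category]
  info$split <- S4Vectors::metadata(ds)$split
  write.csv(info, path, row.names = FALSE)
  invisible(path)
}
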