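#' @include AllClasses.R utils.R
NULL

#' Create a texture specification
#'
#' @param name category label (unique within a generation config).
#' @param baseBrightness mean brightness of the textured region, in \[0,1\].
#' @param noiseScale fluctuation amplitude (standard deviation), >= 0.
#' @param blurRadius Gaussian blur sigma in pixels; sets the spatial scale
#'   of the texture (0 = per-pixel noise).
#' @param pattern `"speckle"` (blurred value-noise renormalized to
#'   `noiseScale`, the spongy look), `"smooth"` (noise whose amplitude the
#'   blur damps) or `"blob"` (bright chi-square bumps).
#' @return a [TextureSpec-class].
#' @examples
#' textureSpec("bone_like", 0.55, 0.12, 1, "speckle")
#' @export
textureSpec <- function(name, baseBrightness, noiseScale = 0,
                        blurRadius = 0, pattern = "speckle") {
  new("TextureSpec", name = name, baseBrightness = baseBrightness,
      noiseScale = noiseScale, blurRadius = blurRadius, pattern = pattern)
}

#' Describe the region geometry of a synthetic scene
#'
#' A layout places named rectangular regions on a `width` x `height` canvas.
#' Every pixel not covered by a rectangle belongs to `background`, so the
#' regions always cover the canvas; overlapping rectangles are a
#' configuration error. Coordinates are 1-based and inclusive.
#'
#' @param width,height canvas size in pixels.
#' @param regions list of `list(spec = <name>, x0, y0, x1, y1)` rectangles.
#' @param background name of the spec filling uncovered pixels.
#' @param maskRegion name of the spec whose region is emitted as the expert
#'   mask, or NA for no mask.
#' @return a layout list consumed by [generateScene()].
#' @export
sceneLayout <- function(width, height, regions = list(),
                        background, maskRegion = NA_character_) {
  stopUnless(width >= 1 && height >= 1, "canvas must be at least 1x1")
  for (r in regions) {
    stopUnless(all(c("spec", "x0", "y0", "x1", "y1") %in% names(r)),
               "each region needs spec, x0, y0, x1, y1")
    stopUnless(r$x0 >= 1 && r$y0 >= 1 && r$x1 <= width && r$y1 <= height &&
               r$x0 <= r$x1 && r$y0 <= r$y1,
               "region rectangle out of canvas bounds")
  }
  list(width = as.integer(width), height = as.integer(height),
       regions = regions, background = background, maskRegion = maskRegion)
}

# full-canvas texture field for one spec; deterministic given the RNG state
textureField <- function(spec, height, width) {
  if (spec@noiseScale == 0) return(matrix(spec@baseBrightness, height, width))
  z <- matrix(rnorm(height * width), height, width)
  blur <- function(m) {
    if (spec@blurRadius > 0)
      as.matrix(EBImage::imageData(EBImage::gblur(m, sigma = spec@blurRadius)))
    else m
  }
  tex <- switch(spec@pattern,
    smooth = spec@baseBrightness + blur(spec@noiseScale * z),
    speckle = {
      f <- blur(z)
      s <- sd(as.vector(f))
      if (s > 0) f <- f / s
      spec@baseBrightness + spec@noiseScale * f
    },
    blob = {
      f <- blur(z)
      s <- sd(as.vector(f))
      if (s > 0) f <- f / s
      v <- f^2 - 1               # centered chi-square bumps
      sv <- sd(as.vector(v))
      if (sv > 0) v <- v / sv
      spec@baseBrightness + spec@noiseScale * v
    })
  clamp01(tex)
}

#' Generate a synthetic radiography-like scene
#'
#' Composes one procedural texture per [TextureSpec-class] onto the canvas
#' described by `layout`. Identical `(specs, layout, seed)` give bit-identical
#' scenes; each region's pixel mean stays within 0.05 of its spec's
#' `baseBrightness`.
#'
#' @param specs list of [TextureSpec-class]; names must be unique and include
#'   every name referenced by the layout.
#' @param layout a [sceneLayout()].
#' @param seed integer seed.
#' @return a [SyntheticScene-class].
#' @examples
#' sp <- list(textureSpec("background", 0.02, 0.005, 0, "smooth"),
#'            textureSpec("tissue", 0.55, 0.1, 1, "speckle"))
#' ly <- sceneLayout(64, 64, list(list(spec = "tissue", x0 = 17, y0 = 17,
#'                                     x1 = 48, y1 = 48)),
#'                   background = "background")
#' sc <- generateScene(sp, ly, seed = 7)
#' @export
generateScene <- function(specs, layout, seed) {
  stopUnless(length(specs) >= 2, "at least two texture specs are required")
  nm <- vapply(specs, function(s) s@name, character(1))
  stopUnless(!anyDuplicated(nm), "texture spec names must be unique")
  stopUnless(layout$background %in% nm, "layout background spec not found")
  H <- layout$height; W <- layout$width
  regionMap <- matrix(match(layout$background, nm), H, W)
  covered <- matrix(FALSE, H, W)
  for (r in layout$regions) {
    idx <- match(r$spec, nm)
    stopUnless(!is.na(idx), sprintf("layout references unknown spec '%s'", r$spec))
    rows <- r$y0:r$y1; cols <- r$x0:r$x1
    stopUnless(!any(covered[rows, cols]), "layout regions overlap")
    covered[rows, cols] <- TRUE
    regionMap[rows, cols] <- idx
  }
  img <- withSeed(seed, {
    out <- matrix(0, H, W)
    for (i in seq_along(specs)) {
      sel <- regionMap == i
      if (!any(sel)) next
      out[sel] <- textureField(specs[[i]], H, W)[sel]
    }
    out
  })
  expertIdx <- NA_integer_
  mask <- NULL
  if (!is.na(layout$maskRegion)) {
    expertIdx <- match(layout$maskRegion, nm)
    stopUnless(!is.na(expertIdx), "maskRegion spec not found")
    mask <- (regionMap == expertIdx) * 1L
    storage.mode(mask) <- "integer"
  }
  new("SyntheticScene", image = img, mask = mask, regionMap = regionMap,
      categoryNames = nm, expertIndex = expertIdx, seed = as.integer(seed))
}

#' Generate a ladder of increasingly dissimilar texture categories
#'
#' Returns one full-canvas scene per category, with texture parameters spaced
#' so that the ground-truth perceptual ordering from category 1 is
#' dist(1,2) < dist(1,3) < ... < dist(1,n): brightness and blur radius both
#' step by an amount proportional to `similarityGap`.
#'
#' @param nCategories number of categories (>= 3).
#' @param similarityGap spacing of the ladder, in (0, 1).
#' @param seed integer seed.
#' @param size canvas side length in pixels.
#' @return list of [SyntheticScene-class], one per category.
#' @export
generateSimilarityLadder <- function(nCategories, similarityGap, seed,
                                     size = 128) {
  stopUnless(nCategories >= 3, "at least 3 categories are required")
  stopUnless(similarityGap > 0 && similarityGap < 1,
             "similarityGap must lie strictly in (0, 1)")
  steps <- (seq_len(nCategories) - 1) / (nCategories - 1)
  specs <- lapply(seq_len(nCategories), function(i) {
    textureSpec(sprintf("rung_%d", i - 1L),
                baseBrightness = 0.3 + 0.5 * similarityGap * steps[i],
                noiseScale = 0.1,
                blurRadius = 0.5 + 2.5 * similarityGap * steps[i],
                pattern = "speckle")
  })
  seeds <- childSeeds(seed, nCategories)
  lapply(seq_len(nCategories), function(i) {
    ly <- sceneLayout(size, size, list(), background = specs[[i]]@name)
    sc <- generateScene(list(specs[[i]], textureSpec("unused_", 0.5)),
                        ly, seeds[i])
    # single-texture canvas: relabel to the full ladder category list
    new("SyntheticScene", image = sc@image, mask = NULL,
        regionMap = matrix(i, size, size),
        categoryNames = vapply(specs, function(s) s@name, character(1)),
        expertIndex = NA_integer_, seed = as.integer(seeds[i]))
  })
}

#' Ladder texture parameter distances
#'
#' Euclidean distance in (brightness, blur-radius) parameter space between
#' the first ladder rung and every other rung, under the spacing used by
#' [generateSimilarityLadder()]; strictly increasing along the ladder.
#'
#' @param nCategories,similarityGap the ladder parameters.
#' @return numeric vector of length `nCategories - 1`.
#' @export
ladderParameterDistances <- function(nCategories, similarityGap) {
  steps <- (seq_len(nCategories) - 1) / (nCategories - 1)
  sqrt((0.5 * similarityGap * steps)^2 + (2.5 * similarityGap * steps)^2)[-1]
}

#' Convert a synthetic scene to a SourceImage
#'
#' Attaches the category bindings used by patch categorization. The scene's
#' image is already normalized, so no rescaling is applied.
#'
#' @param scene a [SyntheticScene-class].
#' @param id image identifier.
#' @param naive name of the naive category for this image.
#' @param null name of the null (background) category.
#' @param modalityTag free-form tag.
#' @return a [SourceImage-class].
#' @export
sceneToSourceImage <- function(scene, id, naive, null = "background",
                               modalityTag = "synthetic") {
  expert <- if (is.na(scene@expertIndex)) NA_character_
            else scene@categoryNames[scene@expertIndex]
  new("SourceImage", pixels = scene@image, mask = scene@mask,
      modalityTag = modalityTag, negative = FALSE, id = id,
      bindings = list(null = null, naive = naive, expert = expert))
}

#' Default texture specifications of the synthetic material study
#'
#' Four categories emulating the composite radiography setting: a dark
#' background (null), two perceptually similar mid-brightness tissue textures
#' that differ only in speckle scale (the confusable pair), and a brighter,
#' smoother lesion texture that stands in for the expert-masked category.
#'
#' @return named list of [TextureSpec-class].
#' @export
studyTextureSpecs <- function() {
  list(
    background = textureSpec("background", 0.02, 0.005, 0,   "smooth"),
    bone_like  = textureSpec("bone_like",  0.55, 0.12,  2.0, "speckle"),
    brain_like = textureSpec("brain_like", 0.63, 0.12,  2.0, "speckle"),
    lesion     = textureSpec("lesion",     0.70, 0.08,  3.0, "blob"))
}

#' Default brightness constraints of the synthetic material study
#'
#' The brightness window is set to reject patches that straddle the dark
#' background and a tissue region (their mixed average brightness falls below
#' `bMin`), and the mask tolerance follows the small-T convention.
#'
#' @return a [BrightnessConstraints-class].
#' @export
studyConstraints <- function() {
  brightnessConstraints(bMin = 0.35, bMax = 0.95, bNull = 0.05,
                        maskTolerance = 0.05)
}

#' Generate the study's synthetic source images
#'
#' Two image modalities mirror the composite dataset design: modality A
#' images contain the `bone_like` texture on a dark background (naive
#' category, no mask); modality B images contain the `brain_like` texture
#' with an expert-masked `lesion` region inside it.
#'
#' @param nA number of modality-A images.
#' @param nB number of modality-B images.
#' @param size canvas side length in pixels.
#' @param seed integer seed.
#' @return list of [SourceImage-class].
#' @export
generateStudyImages <- function(nA = 6, nB = 12, size = 256, seed = 1) {
  sp <- studyTextureSpecs()
  specs <- unname(sp)
  m <- round(size * c(0.19, 0.81))      # tissue square, border >= window
  q <- round(size * c(0.375, 0.625))    # lesion square inside it
  layA <- sceneLayout(size, size,
    list(list(spec = "bone_like", x0 = m[1], y0 = m[1], x1 = m[2], y1 = m[2])),
    background = "background")
  # the lesion square sits inside the brain_like square; regions must be
  # disjoint, so the brain region is expressed as a frame of four rectangles
  layB <- sceneLayout(size, size,
    list(list(spec = "brain_like", x0 = m[1], y0 = m[1], x1 = m[2], y1 = q[1] - 1),
         list(spec = "brain_like", x0 = m[1], y0 = q[2] + 1, x1 = m[2], y1 = m[2]),
         list(spec = "brain_like", x0 = m[1], y0 = q[1], x1 = q[1] - 1, y1 = q[2]),
         list(spec = "brain_like", x0 = q[2] + 1, y0 = q[1], x1 = m[2], y1 = q[2]),
         list(spec = "lesion", x0 = q[1], y0 = q[1], x1 = q[2], y1 = q[2])),
    background = "background", maskRegion = "lesion")
  seeds <- childSeeds(seed, nA + nB)
  imgs <- vector("list", nA + nB)
  for (i in seq_len(nA)) {
    sc <- generateScene(specs, layA, seeds[i])
    imgs[[i]] <- sceneToSourceImage(sc, sprintf("A%02d", i), naive = "bone_like",
                                    modalityTag = "synthetic_xray_like")
  }
  for (i in seq_len(nB)) {
    sc <- generateScene(specs, layB, seeds[nA + i])
    imgs[[nA + i]] <- sceneToSourceImage(sc, sprintf("B%02d", i),
                                         naive = "brain_like",
                                         modalityTag = "synthetic_mri_like")
  }
  imgs
}

#' Study category names in canonical order
#' @return character vector (null, naive A, naive B, expert).
#' @export
studyCategories <- function() c("background", "bone_like", "brain_like", "lesion")

#' Write a scene to PNG files with a JSON sidecar
#'
#' Writes `<stem>.png` (image), `<stem>_mask.png` (if the scene has a mask)
#' and `<stem>.json` recording the seed and category names.
#'
#' @param scene a [SyntheticScene-class].
#' @param stem output path without extension.
#' @return invisibly, the paths written.
#' @export
writeScene <- function(scene, stem) {
  paths <- paste0(stem, ".png")
  png::writePNG(scene@image, paths)
  if (!is.null(scene@mask)) {
    mp <- paste0(stem, "_mask.png")
    png::writePNG(scene@mask * 1.0, mp)
    paths <- c(paths, mp)
  }
  jp <- paste0(stem, ".json")
  jsonlite::write_json(list(seed = scene@seed,
                            categoryNames = scene@categoryNames,
                            expertIndex = scene@expertIndex),
                       jp, auto_unbox = TRUE, null = "null")
  invisible(c(paths, jp))
}
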