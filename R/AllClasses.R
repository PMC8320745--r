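#' @include utils.R
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' TextureSpec: parameters of one procedural texture
#'
#' Describes one material texture for the synthetic scene generator: a base
#' brightness in \[0,1\], a noise amplitude, a Gaussian blur radius (pixels)
#' that sets the texture's spatial scale, and a pattern family.
#'
#' @slot name category label, unique within a generation config.
#' @slot baseBrightness mean brightness of the region, in \[0,1\].
#' @slot noiseScale standard deviation of the texture fluctuation, >= 0.
#' @slot blurRadius Gaussian blur sigma in pixels, >= 0.
#' @slot pattern one of `"speckle"`, `"smooth"`, `"blob"`.
#' @export
setClass("TextureSpec",
  slots = c(name = "character", baseBrightness = "numeric",
            noiseScale = "numeric", blurRadius = "numeric",
            pattern = "character"))

setValidity("TextureSpec", function(object) {
  msg <- NULL
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  b <- object@baseBrightness; s <- object@noiseScale
  if (length(b) != 1L || b < 0 || b > 1)
    msg <- c(msg, "'baseBrightness' must lie in [0, 1]")
  if (length(s) != 1L || s < 0)
    msg <- c(msg, "'noiseScale' must be >= 0")
  if (length(b) == 1L && length(s) == 1L && (b - 3 * s < -1e-9 || b + 3 * s > 1 + 1e-9))
    msg <- c(msg, "baseBrightness +/- 3*noiseScale must stay clippable to [0, 1]")
  if (length(object@blurRadius) != 1L || object@blurRadius < 0)
    msg <- c(msg, "'blurRadius' must be >= 0")
  if (!object@pattern %in% c("speckle", "smooth", "blob"))
    msg <- c(msg, "'pattern' must be one of speckle, smooth, blob")
  if (is.null(msg)) TRUE else msg
})

#' SyntheticScene: one generated image with ground truth
#'
#' A generated grayscale raster together with the ground-truth region map
#' (category index per pixel, 1-based into `categoryNames`) and an optional
#' binary expert mask. Image, mask and region map share dimensions; the mask
#' is nonzero exactly where the region map equals the expert-category index.
#'
#' @slot image numeric matrix in \[0,1\].
#' @slot mask binary matrix or NULL.
#' @slot regionMap integer matrix of category indices.
#' @slot categoryNames character vector naming the region indices.
#' @slot expertIndex index of the masked category, or NA.
#' @slot seed integer seed the scene was generated from.
#' @export
setClass("SyntheticScene",
  slots = c(image = "matrix", mask = "matrixOrNULL", regionMap = "matrix",
            categoryNames = "character", expertIndex = "integer",
            seed = "integer"))

setValidity("SyntheticScene", function(object) {
  msg <- NULL
  d <- dim(object@image)
  if (!identical(dim(object@regionMap), d))
    msg <- c(msg, "image and regionMap dimensions differ")
  if (!is.null(object@mask)) {
    if (!identical(dim(object@mask), d))
      msg <- c(msg, "mask dimensions differ from image")
    else if (!is.na(object@expertIndex) &&
             !all((object@mask != 0) == (object@regionMap == object@expertIndex)))
      msg <- c(msg, "mask must be nonzero exactly on the expert-category region")
  }
  if (any(object@image < 0 | object@image > 1))
    msg <- c(msg, "image values must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' SourceImage: a normalized input image with category bindings
#'
#' A grayscale raster normalized to \[0,1\], with an optional expert mask and
#' the category bindings used by patch categorization: which category name the
#' null (dark background), naive (bright-window, maskless) and expert (inside
#' mask) rules emit for this image.
#'
#' @slot pixels numeric matrix in \[0,1\].
#' @slot mask binary matrix or NULL.
#' @slot modalityTag free-form string describing the image source.
#' @slot negative whether the raw image was a negative (inverted on input).
#' @slot id image identifier, unique within a dataset.
#' @slot bindings named list with elements `null`, `naive`, `expert`
#'   (character or NA).
#' @export
setClass("SourceImage",
  slots = c(pixels = "matrix", mask = "matrixOrNULL", modalityTag = "character",
            negative = "logical", id = "character", bindings = "list"))

setValidity("SourceImage", function(object) {
  msg <- NULL
  if (any(object@pixels < -1e-12 | object@pixels > 1 + 1e-12))
    msg <- c(msg, "pixels must be normalized to [0, 1]")
  if (!is.null(object@mask) && !identical(dim(object@mask), dim(object@pixels)))
    msg <- c(msg, "mask dimensions must equal pixel dimensions")
  need <- c("null", "naive", "expert")
  if (!all(need %in% names(object@bindings)))
    msg <- c(msg, "bindings must name 'null', 'naive' and 'expert' categories")
  if (is.null(msg)) TRUE else msg
})

#' BrightnessConstraints: patch categorization thresholds
#'
#' Run-time thresholds of the patch categorization rules: a patch whose
#' average brightness falls below `bNull` is a null-category patch; otherwise
#' its brightness must lie in \[`bMin`, `bMax`\] and its mask coverage decides
#' expert (>= 1 - T) versus naive (<= T) membership, with coverage strictly
#' between T and 1 - T rejected as boundary-straddling.
#'
#' @slot bMin minimum average brightness for non-null patches.
#' @slot bMax maximum average brightness for non-null patches.
#' @slot bNull brightness below which a patch is null-category.
#' @slot maskTolerance the tolerance T in (0, 0.5).
#' @export
setClass("BrightnessConstraints",
  slots = c(bMin = "numeric", bMax = "numeric", bNull = "numeric",
            maskTolerance = "numeric"))

setValidity("BrightnessConstraints", function(object) {
  msg <- NULL
  v <- c(object@bMin, object@bMax, object@bNull, object@maskTolerance)
  if (length(v) != 4L || any(v < 0 | v > 1))
    msg <- c(msg, "all constraint values must be scalars in [0, 1]")
  else {
    if (object@bMin > object@bMax) msg <- c(msg, "bMin must be <= bMax")
    t <- object@maskTolerance
    if (t <= 0 || t >= 0.5)
      msg <- c(msg, "maskTolerance must satisfy 0 < T < 0.5 so expert and naive rules are exclusive")
  }
  if (is.null(msg)) TRUE else msg
})

#' PatchSet: a labeled set of image patches
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single `"values"`
#' assay holds one flattened patch per column (length `patchSize^2`, values in
#' \[0,1\]) and whose `colData` records provenance: `image_id`, `x`, `y`
#' (1-based top-left pixel of the patch), `category` (integer index into
#' `categoryNames(x)`), `avgBrightness` and `maskFraction`.
#'
#' @export
setClass("PatchSet", contains = "SummarizedExperiment")

setValidity("PatchSet", function(object) {
  msg <- NULL
  cd <- SummarizedExperiment::colData(object)
  need <- c("image_id", "x", "y", "category", "avgBrightness", "maskFraction")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'values' is required")
  cn <- S4Vectors::metadata(object)$categoryNames
  if (is.null(cn)) msg <- c(msg, "metadata$categoryNames is required")
  else if (ncol(object) > 0 && any(cd$category < 1 | cd$category > length(cn)))
    msg <- c(msg, "category indices out of range")
  if (ncol(object) > 0) {
    key <- paste(cd$image_id, cd$x, cd$y)
    if (anyDuplicated(key)) msg <- c(msg, "patch origins (image_id, x, y) must be unique")
  }
  if (is.null(msg)) TRUE else msg
})

#' DistanceMatrix: perceptual distances between categories
#'
#' Symmetric K x K matrix of perceptual distances between material
#' categories, derived from aggregated same/different similarity decisions.
#' Entries are nonnegative with a zero diagonal.
#'
#' @slot values K x K numeric matrix.
#' @slot categoryNames category labels, length K.
#' @slot provenance free-form list (checkpoint id, dataset id, mode).
#' @export
setClass("DistanceMatrix",
  slots = c(values = "matrix", categoryNames = "character",
            provenance = "list"))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  msg <- NULL
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  else {
    if (length(object@categoryNames) != nrow(v))
      msg <- c(msg, "categoryNames length must match matrix dimension")
    if (max(abs(v - t(v))) > 1e-9) msg <- c(msg, "matrix must be symmetric")
    if (any(abs(diag(v)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
    if (any(v < -1e-12)) msg <- c(msg, "entries must be nonnegative")
  }
  if (is.null(msg)) TRUE else msg
})

#' AttributeMatrix: category-conditional attribute probabilities
#'
#' K x M matrix whose row k is category k's probability vector over M
#' machine-discovered attributes; entries lie in \[0,1\]. Carries the
#' optimization settings it was produced under.
#'
#' @slot values K x M numeric matrix in \[0,1\].
#' @slot categoryNames category labels, length K.
#' @slot gamma weight of the KL term in the objective.
#' @slot bandwidth Gaussian KDE bandwidth h.
#' @slot evalPoints KL evaluation grid P, a vector in (0, 1).
#' @slot objectiveValue objective at the returned matrix.
#' @slot seed integer seed of the optimization run.
#' @export
setClass("AttributeMatrix",
  slots = c(values = "matrix", categoryNames = "character", gamma = "numeric",
            bandwidth = "numeric", evalPoints = "numeric",
            objectiveValue = "numeric", seed = "integer"))

setValidity("AttributeMatrix", function(object) {
  msg <- NULL
  v <- object@values
  if (ncol(v) < 2) msg <- c(msg, "at least M = 2 attributes are required")
  if (any(v < -1e-9 | v > 1 + 1e-9)) msg <- c(msg, "entries must lie in [0, 1]")
  if (length(object@categoryNames) != nrow(v))
    msg <- c(msg, "categoryNames length must match row count")
  if (object@bandwidth <= 0) msg <- c(msg, "bandwidth must be > 0")
  if (any(object@evalPoints <= 0 | object@evalPoints >= 1))
    msg <- c(msg, "evalPoints must lie strictly inside (0, 1)")
  if (is.null(msg)) TRUE else msg
})

#' SimilarityModel: Siamese patch-pair comparison network
#'
#' Two weight-shared convolutional encoders whose embeddings are compared by
#' an order-invariant head (absolute elementwise difference followed by fully
#' connected layers and a sigmoid), producing a same/different score in (0,1).
#' Weight sharing is structural: one parameter set encodes both branches.
#'
#' @slot params named list of parameter arrays.
#' @slot config architecture configuration list.
#' @export
setClass("SimilarityModel", slots = c(params = "list", config = "list"))

#' MacModel: multi-task category + attribute classifier
#'
#' A convolutional backbone with (i) a K-way category head of two fully
#' connected layers, and (ii) one auxiliary attribute classifier per backbone
#' stage response (including the initial pooled response), each a two-layer
#' clipped-linear map to M values, merged by a combiner classifier into the
#' final M-vector of attribute probabilities in \[0,1\].
#'
#' @slot params named list of parameter arrays.
#' @slot config architecture configuration list (includes K, M).
#' @export
setClass("MacModel", slots = c(params = "list", config = "list"))

#' DcnnFit: trained similarity network with its optimal distance matrix
#'
#' Training state of the Siamese similarity network: the best-validation-loss
#' checkpoint, the per-epoch history, the validation decision log at the best
#' epoch, and the distance matrix built from it.
#'
#' @slot model the best-checkpoint [SimilarityModel-class].
#' @slot history data.frame (epoch, train_loss, val_loss, val_acc).
#' @slot bestEpoch epoch of the saved checkpoint.
#' @slot bestValLoss minimum validation loss across epochs.
#' @slot bestD [DistanceMatrix-class] from the best epoch's validation decisions.
#' @slot decisionLog data.frame of validation decisions at the best epoch.
#' @slot seed integer.
#' @export
setClass("DcnnFit",
  slots = c(model = "SimilarityModel", history = "data.frame",
            bestEpoch = "integer", bestValLoss = "numeric",
            bestD = "DistanceMatrix", decisionLog = "data.frame",
            seed = "integer"))

#' MacFit: trained multi-task classifier
#'
#' @slot model the best-checkpoint [MacModel-class].
#' @slot history data.frame (epoch, lr, train_loss, val_loss, val_acc).
#' @slot bestEpoch epoch of the saved checkpoint.
#' @slot bestValLoss minimum validation loss across epochs.
#' @slot seed integer.
#' @export
setClass("MacFit",
  slots = c(model = "MacModel", history = "data.frame", bestEpoch = "integer",
            bestValLoss = "numeric", seed = "integer"))

#' MaterialMap: sliding-window category and attribute maps
#'
#' Whole-image inference output: cell (i, j) of the maps corresponds to the
#' 32x32 window whose top-left pixel is at 1-based image position
#' (x = (j-1)*stride + 1, y = (i-1)*stride + 1). `categoryMap` holds argmax
#' category indices; `attributeMaps` is an H' x W' x M array in \[0,1\].
#'
#' @slot categoryMap integer matrix.
#' @slot attributeMaps 3-d numeric array.
#' @slot window window side length (pixels).
#' @slot stride window stride (pixels).
#' @slot categoryNames category labels.
#' @export
setClass("MaterialMap",
  slots = c(categoryMap = "matrix", attributeMaps = "array",
            window = "integer", stride = "integer",
            categoryNames = "character"))

setValidity("MaterialMap", function(object) {
  msg <- NULL
  if (!identical(dim(object@categoryMap), dim(object@attributeMaps)[1:2]))
    msg <- c(msg, "categoryMap and attributeMaps grid dimensions differ")
  a <- object@attributeMaps
  if (any(a < -1e-9 | a > 1 + 1e-9)) msg <- c(msg, "attribute values must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})
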