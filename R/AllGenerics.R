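#' @include AllClasses.R
NULL

#' Category labels of an object
#'
#' @param x a PatchSet, DistanceMatrix, AttributeMatrix, SyntheticScene or
#'   MaterialMap.
#' @return character vector of category names.
#' @export
setGeneric("categoryNames", function(x) standardGeneric("categoryNames"))

#' @rdname categoryNames
#' @export
setMethod("categoryNames", "PatchSet",
          function(x) S4Vectors::metadata(x)$categoryNames)
#' @rdname categoryNames
#' @export
setMethod("categoryNames", "DistanceMatrix", function(x) x@categoryNames)
#' @rdname categoryNames
#' @export
setMethod("categoryNames", "AttributeMatrix", function(x) x@categoryNames)
#' @rdname categoryNames
#' @export
setMethod("categoryNames", "SyntheticScene", function(x) x@categoryNames)
#' @rdname categoryNames
#' @export
setMethod("categoryNames", "MaterialMap", function(x) x@categoryNames)

#' Patch values matrix
#'
#' The flattened patch matrix of a [PatchSet-class]: one column per patch,
#' `patchSize^2` rows, values in \[0,1\]. Columns are `as.vector()` of the
#' patch matrix (column-major).
#'
#' @param x a PatchSet.
#' @return numeric matrix.
#' @export
patchValues <- function(x) SummarizedExperiment::assay(x, "values")

#' Per-patch provenance table
#'
#' @param x a PatchSet.
#' @return the `colData` DataFrame (image_id, x, y, category, avgBrightness,
#'   maskFraction).
#' @export
patchInfo <- function(x) SummarizedExperiment::colData(x)

#' Integer category labels of a PatchSet
#'
#' @param x a PatchSet.
#' @return integer vector of 1-based category indices.
#' @export
patchCategories <- function(x) as.integer(patchInfo(x)$category)

#' Extract the distance matrix with category dimnames
#' @param x a [DistanceMatrix-class].
#' @param ... ignored.
#' @return K x K numeric matrix.
#' @export
as.matrix.DistanceMatrix <- function(x, ...) {
  m <- x@values
  dimnames(m) <- list(x@categoryNames, x@categoryNames)
  m
}

#' Extract the K x M attribute matrix with dimnames
#' @param x an [AttributeMatrix-class].
#' @param ... ignored.
#' @return K x M numeric matrix.
#' @export
as.matrix.AttributeMatrix <- function(x, ...) {
  m <- x@values
  dimnames(m) <- list(x@categoryNames,
                      paste0("attribute_", seq_len(ncol(m)) - 1L))
  m
}

setMethod("show", "TextureSpec", function(object) {
  cat(sprintf("TextureSpec '%s': pattern=%s, base=%.3f, noise=%.3f, blur=%.2f\n",
              object@name, object@pattern, object@baseBrightness,
              object@noiseScale, object@blurRadius))
})

setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@image)
  cat(sprintf("SyntheticScene %dx%d, %d categor%s (%s)%s, seed %d\n",
              d[1], d[2], length(object@categoryNames),
              if (length(object@categoryNames) == 1) "y" else "ies",
              paste(object@categoryNames, collapse = ", "),
              if (is.null(object@mask)) "" else ", with expert mask",
              object@seed))
})

setMethod("show", "SourceImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SourceImage '%s' (%s) %dx%d%s; bindings: null=%s naive=%s expert=%s\n",
              object@id, object@modalityTag, d[1], d[2],
              if (is.null(object@mask)) "" else " +mask",
              object@bindings$null, object@bindings$naive,
              ifelse(is.na(object@bindings$expert), "-", object@bindings$expert)))
})

setMethod("show", "BrightnessConstraints", function(object) {
  cat(sprintf("BrightnessConstraints: bNull=%.3f, window=[%.3f, %.3f], T=%.3f\n",
              object@bNull, object@bMin, object@bMax, object@maskTolerance))
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix over %d categories (%s mode)\n",
              nrow(object@values),
              if (is.null(object@provenance$mode)) "scalar" else object@provenance$mode))
  print(round(as.matrix(object), 4))
})

setMethod("show", "AttributeMatrix", function(object) {
  cat(sprintf("AttributeMatrix %d x %d (gamma=%g, h=%g, objective=%.4f)\n",
              nrow(object@values), ncol(object@values), object@gamma,
              object@bandwidth, object@objectiveValue))
  print(round(as.matrix(object), 3))
})

setMethod("show", "SimilarityModel", function(object) {
  cat(sprintf("SimilarityModel: '%s' backbone (%s channels), embedding %d, %d parameters\n",
              object@config$backbone, paste(object@config$channels, collapse = "-"),
              object@config$embedDim, nParams(object@params)))
})

setMethod("show", "MacModel", function(object) {
  cat(sprintf("MacModel: '%s' backbone, K=%d categories, M=%d attributes, %d aux heads, %d parameters\n",
              object@config$backbone, object@config$K, object@config$M,
              length(object@config$channels), nParams(object@params)))
})

setMethod("show", "DcnnFit", function(object) {
  cat(sprintf("DcnnFit: best epoch %d of %d, val loss %.4f, val pair accuracy %.3f\n",
              object@bestEpoch, nrow(object@history), object@bestValLoss,
              object@history$val_acc[object@bestEpoch]))
})

setMethod("show", "MacFit", function(object) {
  cat(sprintf("MacFit: best epoch %d of %d, val loss %.4f, val accuracy %.3f\n",
              object@bestEpoch, nrow(object@history), object@bestValLoss,
              object@history$val_acc[object@bestEpoch]))
})

setMethod("show", "MaterialMap", function(object) {
  d <- dim(object@categoryMap)
  cat(sprintf("MaterialMap %dx%d cells (window %d, stride %d), %d attribute maps\n",
              d[1], d[2], object@window, object@stride,
              dim(object@attributeMaps)[3]))
})

nParams <- function(params) sum(vapply(params, length, integer(1)))
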