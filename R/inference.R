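#' @include AllClasses.R maccnn.R
NULL

#' Sliding-window material map of a whole image
#'
#' Applies the classifier to every `window` x `window` patch on a stride-
#' `stride` grid. Map cell (i, j) holds the argmax category and the M
#' attribute values of the window whose top-left pixel is at 1-based image
#' position (x = (j-1)*stride + 1, y = (i-1)*stride + 1); the map is
#' floor((H - window)/stride) + 1 rows by floor((W - window)/stride) + 1
#' columns. Deterministic: a cell equals [macForward()] on the manually
#' extracted window.
#'
#' @param model a [MacModel-class] or [MacFit-class].
#' @param image a [SourceImage-class], [SyntheticScene-class] or numeric
#'   matrix in \[0,1\]; both dimensions must be >= `window`.
#' @param window window side length (default 32).
#' @param stride window stride in pixels (default 4).
#' @param categories category names for the map (taken from the model's
#'   training record when available).
#' @param batch forward batch size.
#' @return a [MaterialMap-class].
#' @export
slidingWindowMap <- function(model, image, window = 32L, stride = 4L,
                             categories = NULL, batch = 512L) {
  if (is(model, "MacFit")) model <- model@model
  px <- if (is(image, "SourceImage")) image@pixels
        else if (is(image, "SyntheticScene")) image@image
        else as.matrix(image)
  H <- nrow(px); W <- ncol(px)
  stopUnless(H >= window && W >= window,
             "image must be at least window x window pixels")
  if (is.null(categories))
    categories <- model@config$categoryNames %||%
      paste0("cat_", seq_len(model@config$K))
  nr <- (H - window) %/% stride + 1L
  nc <- (W - window) %/% stride + 1L
  M <- model@config$M
  catMap <- matrix(NA_integer_, nr, nc)
  attrMaps <- array(0, dim = c(nr, nc, M))
  cells <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  for (s in seq.int(1L, nrow(cells), by = batch)) {
    e <- min(nrow(cells), s + batch - 1L)
    blk <- cells[s:e, , drop = FALSE]
    X <- matrix(0, nrow(blk), window * window)
    for (r in seq_len(nrow(blk))) {
      y0 <- (blk$i[r] - 1L) * stride + 1L
      x0 <- (blk$j[r] - 1L) * stride + 1L
      X[r, ] <- as.vector(px[y0:(y0 + window - 1L), x0:(x0 + window - 1L)])
    }
    fwd <- macFwd(model@params, model@config, X)
    pred <- max.col(fwd$probs)
    for (r in seq_len(nrow(blk))) {
      catMap[blk$i[r], blk$j[r]] <- pred[r]
      attrMaps[blk$i[r], blk$j[r], ] <- fwd$attrs[r, ]
    }
  }
  new("MaterialMap", categoryMap = catMap, attributeMaps = attrMaps,
      window = as.integer(window), stride = as.integer(stride),
      categoryNames = categories)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson correlation between true categories and attribute predictions
#'
#' Entry (k, m) is the Pearson correlation, across patches, between the
#' binary indicator of true category k and predicted attribute m. Attributes
#' with zero variance yield NA entries (reported missing, with a warning).
#' The matrix is invariant to patch order.
#'
#' @param attrs N x M matrix of attribute predictions.
#' @param labels integer category indices (length N) or N x K one-hot matrix.
#' @param categories category names (optional row names).
#' @return K x M matrix of correlations in \[-1, 1\] (NA where undefined).
#' @export
categoryAttributeCorrelation <- function(attrs, labels, categories = NULL) {
  y <- if (is.matrix(labels)) max.col(labels) else as.integer(labels)
  stopUnless(length(y) == nrow(attrs) && nrow(attrs) >= 2,
             "need >= 2 samples with matching labels")
  K <- max(y)
  stopUnless(all(seq_len(K) %in% y), "each category must be present")
  M <- ncol(attrs)
  out <- matrix(NA_real_, K, M)
  dead <- apply(attrs, 2L, sd) == 0
  if (any(dead))
    warning("zero-variance attributes reported as missing: ",
            paste(which(dead) - 1L, collapse = ", "), call. = FALSE)
  for (k in seq_len(K)) {
    ind <- as.numeric(y == k)
    for (m in seq_len(M))
      if (!dead[m]) out[k, m] <- cor(ind, attrs[, m])
  }
  rownames(out) <- categories %||% paste0("cat_", seq_len(K))
  colnames(out) <- paste0("attribute_", seq_len(M) - 1L)
  out
}

#' Two-dimensional embedding and silhouette of a labeled feature set
#'
#' Embeds the feature vectors into two dimensions (classical metric
#' multidimensional scaling on Euclidean distances, deterministic) and
#' scores the category separation on the embedding with the mean silhouette
#' width. Used to compare how well the learned attribute predictions
#' separate categories relative to the raw 1024-dimensional patch features.
#'
#' @param features N x d numeric matrix.
#' @param labels integer category indices, >= 2 distinct values.
#' @return list with `embedding` (N x 2 matrix) and `silhouette` (mean
#'   silhouette width in \[-1, 1\]).
#' @export
embeddingSeparation <- function(features, labels) {
  labels <- as.integer(labels)
  stopUnless(length(unique(labels)) >= 2,
             "at least two categories are required")
  d <- dist(features)
  stopUnless(any(d > 0), "all feature vectors are identical; separation undefined")
  emb <- cmdscale(d, k = 2L)
  sil <- cluster::silhouette(labels, dist(emb))
  list(embedding = emb, silhouette = mean(sil[, "sil_width"]))
}

#' Write a material map as CSV files (plus optional grayscale PNGs)
#'
#' Writes `<stem>_category.csv` with the cell category indices and one
#' `<stem>_attribute_<m>.csv` per attribute map; with `png = TRUE` also
#' writes each attribute map (and the category map scaled to \[0,1\]) as a
#' grayscale PNG.
#'
#' @param map a [MaterialMap-class].
#' @param stem output path stem.
#' @param png also write PNG renderings.
#' @return invisibly, the paths written.
#' @export
writeMaterialMap <- function(map, stem, png = FALSE) {
  paths <- paste0(stem, "_category.csv")
  write.csv(map@categoryMap, paths, row.names = FALSE)
  M <- dim(map@attributeMaps)[3]
  for (m in seq_len(M)) {
    p <- sprintf("%s_attribute_%d.csv", stem, m - 1L)
    write.csv(map@attributeMaps[, , m], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (png) {
    K <- length(map@categoryNames)
    p <- paste0(stem, "_category.png")
    png::writePNG((map@categoryMap - 1) / max(1L, K - 1L), p)
    paths <- c(paths, p)
    for (m in seq_len(M)) {
      p <- sprintf("%s_attribute_%d.png", stem, m - 1L)
      png::writePNG(map@attributeMaps[, , m], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
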