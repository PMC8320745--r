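#' @include AllClasses.R
NULL

#' Aggregate similarity decisions into a per-category mean-decision vector
#'
#' Entry k is the mean of the binary decisions (1 = judged different) over
#' all logged pairs whose comparison patch is of class k.
#'
#' @param log data.frame with columns `ref_class`, `cmp_class`, `decision`.
#' @param categories category names (their order defines the indexing).
#' @return numeric K-vector in \[0,1\], named by category.
#' @export
aggregateDecisions <- function(log, categories) {
  K <- length(categories)
  p <- numeric(K)
  for (k in seq_len(K)) {
    sel <- log$cmp_class == k
    stopUnless(any(sel), "no decisions with comparison class '", categories[k], "'")
    p[k] <- mean(log$decision[sel])
  }
  names(p) <- categories
  p
}

#' Build the perceptual distance matrix from a mean-decision vector
#'
#' Entry (k, k') is the L2 norm of the difference of the scalar entries
#' p_k and p_k', i.e. |p_k - p_k'|; the matrix is symmetric with a zero
#' diagonal and entries in \[0,1\].
#'
#' @param p numeric K-vector of mean decisions in \[0,1\].
#' @param categories category names (defaults to `names(p)`).
#' @return a [DistanceMatrix-class].
#' @examples
#' buildDistanceMatrix(c(a = 0.1, b = 0.9, c = 0.5))
#' @export
buildDistanceMatrix <- function(p, categories = names(p)) {
  stopUnless(all(p >= 0 & p <= 1), "entries of p must lie in [0, 1]")
  if (is.null(categories)) categories <- paste0("cat_", seq_along(p))
  D <- abs(outer(p, p, "-"))
  dimnames(D) <- NULL
  new("DistanceMatrix", values = D, categoryNames = categories,
      provenance = list(mode = "scalar"))
}

#' Build a distance matrix from per-reference-class decision profiles
#'
#' Variant aggregation that keeps the reference-class information: each
#' class r gets a profile vector p(r) whose entry k is the mean decision
#' against comparison class k, and the distance between classes is the L2
#' norm between their profiles. Requires decisions for every
#' reference x comparison class cell.
#'
#' @param log data.frame with columns `ref_class`, `cmp_class`, `decision`.
#' @param categories category names.
#' @return a [DistanceMatrix-class].
#' @export
buildProfileDistanceMatrix <- function(log, categories) {
  K <- length(categories)
  P <- matrix(NA_real_, K, K)
  for (r in seq_len(K)) for (k in seq_len(K)) {
    sel <- log$ref_class == r & log$cmp_class == k
    stopUnless(any(sel),
               sprintf("no decisions for reference '%s' vs comparison '%s'",
                       categories[r], categories[k]))
    P[r, k] <- mean(log$decision[sel])
  }
  D <- as.matrix(dist(P))
  dimnames(D) <- NULL
  new("DistanceMatrix", values = D, categoryNames = categories,
      provenance = list(mode = "profile"))
}

#' Write / read a distance matrix as CSV
#'
#' The CSV carries category names as header row and first column; a JSON
#' sidecar (`<path>.json`) records the provenance list.
#'
#' @param D a [DistanceMatrix-class].
#' @param path CSV path.
#' @return `writeDistanceMatrix`: invisibly, `path`;
#'   `readDistanceMatrix`: a [DistanceMatrix-class].
#' @export
writeDistanceMatrix <- function(D, path) {
  write.csv(as.matrix(D), path, row.names = TRUE)
  jsonlite::write_json(D@provenance, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  cats <- rownames(m)
  dimnames(m) <- NULL
  prov <- list()
  jp <- paste0(path, ".json")
  if (file.exists(jp)) prov <- jsonlite::read_json(jp, simplifyVector = TRUE)
  new("DistanceMatrix", values = m, categoryNames = cats,
      provenance = as.list(prov))
}
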