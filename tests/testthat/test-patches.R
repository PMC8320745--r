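test_that("normalizeImage min-max scales, inverts negatives, and flags constants", {
  img <- normalizeImage(matrix(c(0L, 128L, 255L), 1), id = "a")
  expect_equal(as.vector(img@pixels), c(0, 128 / 255, 1))
  neg <- normalizeImage(matrix(c(0L, 255L), 1), isNegative = TRUE, id = "b")
  expect_equal(as.vector(neg@pixels), c(1, 0))
  expect_warning(flat <- normalizeImage(matrix(0L, 4, 4), id = "c"), "constant")
  expect_true(all(flat@pixels == 0))
})

test_that("averageBrightness is the arithmetic mean of the region", {
  expect_equal(averageBrightness(matrix(0.5, 8, 8)), 0.5)
  expect_equal(averageBrightness(matrix(c(0, 0.2, 0.4, 1.0), 2)), 0.4)
  expect_equal(averageBrightness(matrix(1, 3, 3)), 1)
  expect_error(averageBrightness(numeric(0)), "empty")
})

test_that("maskFraction counts positive pixels, absent mask counts as zero", {
  expect_equal(maskFraction(matrix(1L, 32, 32)), 1)
  m <- matrix(0L, 4, 4); m[1:12] <- 1L
  expect_equal(maskFraction(m), 0.75)
  expect_equal(maskFraction(NULL), 0)
})

test_that("categorizeRegion applies null, window and mask-tolerance rules", {
  cons <- brightnessConstraints(bMin = 0.1, bMax = 0.9, bNull = 0.05,
                                maskTolerance = 0.05)
  bind <- list(null = "bg", naive = "tissue", expert = "tumor")
  mk <- function(frac) { m <- matrix(0L, 32, 32); m[seq_len(round(frac * 1024))] <- 1L; m }
  # dark region is null regardless of anything else
  expect_identical(categorizeRegion(matrix(0.01, 32, 32), cons, bind), "bg")
  # high mask coverage within the window is the expert category
  expect_identical(categorizeRegion(matrix(0.5, 32, 32), cons, bind, mk(0.97)),
                   "tumor")
  # boundary-straddling coverage is rejected
  expect_identical(categorizeRegion(matrix(0.5, 32, 32), cons, bind, mk(0.5)),
                   NA_character_)
  # brightness outside the window is rejected even with no mask overlap
  expect_identical(categorizeRegion(matrix(0.95, 32, 32), cons, bind, mk(0)),
                   NA_character_)
  # no mask at all follows the naive rule
  expect_identical(categorizeRegion(matrix(0.5, 32, 32), cons, bind), "tissue")
})

test_that("the null rule dominates the brightness window", {
  cons <- brightnessConstraints(bMin = 0.1, bMax = 0.9, bNull = 0.3,
                                maskTolerance = 0.05)
  bind <- list(null = "bg", naive = "tissue", expert = NA_character_)
  # 0.2 is inside [bMin, bMax] but below bNull: null wins
  expect_identical(categorizeRegion(matrix(0.2, 32, 32), cons, bind), "bg")
})

test_that("constraints enforce expert/naive exclusivity at load", {
  expect_error(brightnessConstraints(maskTolerance = 0.6), "T < 0.5")
  expect_error(brightnessConstraints(bMin = 0.8, bMax = 0.2), "bMin")
})

test_that("exhaustive patch generation equals the brute-force oracle", {
  imgs <- generateStudyImages(nA = 1, nB = 1, size = 192, seed = 42)
  cons <- studyConstraints()
  ps <- generatePatches(imgs, cons, nTarget = Inf, gridSpacing = 8L,
                        seed = 1, categories = studyCategories())
  got <- as.data.frame(patchInfo(ps))
  got$category <- categoryNames(ps)[got$category]
  oracle <- do.call(rbind, lapply(imgs, oracleEnumerate, constraints = cons))
  keyG <- sort(paste(got$image_id, got$x, got$y, got$category))
  keyO <- sort(paste(oracle$image_id, oracle$x, oracle$y, oracle$category))
  expect_identical(keyG, keyO)
  # stored values and brightness agree with the source pixels
  v <- patchValues(ps)
  expect_true(all(abs(colMeans(v) - got$avgBrightness) < 1e-9))
})

test_that("the grid-exhausted path returns the oracle-sized partial set", {
  imgs <- generateStudyImages(nA = 1, nB = 0, size = 192, seed = 9)
  cons <- studyConstraints()
  oracle <- do.call(rbind, lapply(imgs, oracleEnumerate, constraints = cons))
  cats <- c("background", "bone_like")
  expect_warning(
    ps <- generatePatches(imgs, cons, nTarget = 1e6, gridSpacing = 8L,
                          seed = 1, categories = cats),
    "exhausted")
  expect_identical(ncol(ps), nrow(oracle))
})

test_that("patch sampling is deterministic and unique by origin", {
  imgs <- generateStudyImages(nA = 1, nB = 1, size = 192, seed = 4)
  cons <- studyConstraints()
  a <- generatePatches(imgs, cons, nTarget = 60, seed = 5,
                       categories = studyCategories())
  b <- generatePatches(imgs, cons, nTarget = 60, seed = 5,
                       categories = studyCategories())
  expect_identical(as.data.frame(patchInfo(a)), as.data.frame(patchInfo(b)))
  key <- with(as.data.frame(patchInfo(a)), paste(image_id, x, y))
  expect_false(anyDuplicated(key) > 0)
})

test_that("a category missing everywhere is a configuration error", {
  imgs <- generateStudyImages(nA = 1, nB = 0, size = 192, seed = 4)
  expect_error(generatePatches(imgs, studyConstraints(), nTarget = 10,
                               seed = 1, categories = studyCategories()),
               "lesion")
})

test_that("splits are stratified, disjoint, exhaustive and seeded", {
  ds <- makeToyPatchSet(K = 3, perClass = 100, seed = 2)
  spl <- splitDataset(ds, c(0.6, 0.2, 0.2), seed = 7)
  for (k in 1:3) {
    expect_identical(sum(patchCategories(spl$train) == k), 60L)
    expect_identical(sum(patchCategories(spl$val) == k), 20L)
    expect_identical(sum(patchCategories(spl$test) == k), 20L)
  }
  keys <- lapply(spl, function(s) paste(patchInfo(s)$image_id,
                                        patchInfo(s)$x, patchInfo(s)$y))
  expect_length(unique(unlist(keys)), ncol(ds))
  expect_identical(length(intersect(keys$train, keys$val)), 0L)
  spl2 <- splitDataset(ds, c(0.6, 0.2, 0.2), seed = 7)
  expect_identical(keys$train, paste(patchInfo(spl2$train)$image_id,
                                     patchInfo(spl2$train)$x,
                                     patchInfo(spl2$train)$y))
  allTrain <- splitDataset(ds, c(1, 0, 0), seed = 1)
  expect_identical(ncol(allTrain$train), ncol(ds))
  expect_identical(ncol(allTrain$val), 0L)
  tiny <- makeToyPatchSet(K = 2, perClass = 2, seed = 1)
  expect_error(splitDataset(tiny, seed = 1), "at least 3")
})

test_that("patch manifests round-trip through CSV", {
  ds <- makeToyPatchSet(K = 2, perClass = 5, seed = 3)
  path <- file.path(withr::local_tempdir(), "manifest.csv")
  writePatchManifest(ds, path)
  back <- read.csv(path)
  expect_identical(nrow(back), 10L)
  expect_true(all(back$category %in% c("class_1", "class_2")))
})
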