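twoSpecScene <- function(seed = 7) {
  sp <- list(textureSpec("background", 0.02, 0.005, 0, "smooth"),
             textureSpec("tissue", 0.55, 0.1, 1, "speckle"))
  ly <- sceneLayout(128, 128,
                    list(list(spec = "tissue", x0 = 33, y0 = 33,
                              x1 = 96, y1 = 96)),
                    background = "background")
  generateScene(sp, ly, seed)
}

test_that("generated scenes hit their target region brightness", {
  sc <- twoSpecScene(7)
  expect_lt(mean(sc@image[sc@regionMap == 1]), 0.1)
  bt <- mean(sc@image[sc@regionMap == 2])
  expect_gte(bt, 0.5); expect_lte(bt, 0.6)
  # a study spec keeps its region mean within 0.05 of its base brightness
  specs <- studyTextureSpecs()
  scB <- generateScene(unname(specs),
                       sceneLayout(128, 128,
                                   list(list(spec = "brain_like", x0 = 25, y0 = 25,
                                             x1 = 104, y1 = 104)),
                                   background = "background"),
                       seed = 11)
  expect_lt(abs(mean(scB@image[scB@regionMap == 3]) -
                  specs$brain_like@baseBrightness), 0.05)
  expect_lt(abs(mean(scB@image[scB@regionMap == 1]) - 0.02), 0.05)
})

test_that("scene generation is a pure function of (specs, layout, seed)", {
  a <- twoSpecScene(7); b <- twoSpecScene(7); c <- twoSpecScene(8)
  expect_identical(a@image, b@image)
  expect_identical(a@regionMap, b@regionMap)
  expect_false(identical(a@image, c@image))
})

test_that("zero noise and zero blur give exactly the base brightness", {
  sp <- list(textureSpec("bg", 0.1, 0, 0, "smooth"),
             textureSpec("flat", 0.4, 0, 0, "smooth"))
  ly <- sceneLayout(32, 32, list(list(spec = "flat", x0 = 9, y0 = 9,
                                      x1 = 24, y1 = 24)), background = "bg")
  sc <- generateScene(sp, ly, 1)
  expect_true(all(sc@image[sc@regionMap == 2] == 0.4))
  expect_true(all(sc@image[sc@regionMap == 1] == 0.1))
})

test_that("overlapping layout regions are a configuration error", {
  sp <- list(textureSpec("bg", 0.1, 0, 0, "smooth"),
             textureSpec("a", 0.4, 0, 0, "smooth"),
             textureSpec("b", 0.6, 0, 0, "smooth"))
  ly <- sceneLayout(64, 64,
                    list(list(spec = "a", x0 = 1, y0 = 1, x1 = 40, y1 = 40),
                         list(spec = "b", x0 = 30, y0 = 30, x1 = 64, y1 = 64)),
                    background = "bg")
  expect_error(generateScene(sp, ly, 1), "overlap")
})

test_that("texture spec invariants are enforced", {
  expect_error(textureSpec("x", 0.95, 0.1), "clippable")
  expect_error(textureSpec("x", 0.5, -0.1), "noiseScale")
  expect_error(textureSpec("x", 0.5, 0.1, pattern = "stripes"), "pattern")
  sp <- list(textureSpec("dup", 0.2), textureSpec("dup", 0.4))
  expect_error(generateScene(sp, sceneLayout(16, 16, list(), background = "dup"), 1),
               "unique")
})

test_that("the similarity ladder is ordered and validated", {
  expect_error(generateSimilarityLadder(2, 0.3, 1), "3 categories")
  expect_error(generateSimilarityLadder(3, 0, 1), "similarityGap")
  d <- ladderParameterDistances(5, 0.3)
  expect_true(all(diff(d) > 0))
  scenes <- generateSimilarityLadder(4, 0.2, seed = 2, size = 64)
  expect_length(scenes, 4)
  labels <- sort(unique(vapply(scenes, function(s) s@regionMap[1, 1], integer(1))))
  expect_identical(labels, 1:4)
  # brightness increases along the ladder as constructed
  means <- vapply(scenes, function(s) mean(s@image), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("masks align exactly with the expert region", {
  imgs <- generateStudyImages(nA = 0, nB = 1, size = 128, seed = 5)
  img <- imgs[[1]]
  expect_false(is.null(img@mask))
  expect_identical(dim(img@mask), dim(img@pixels))
  expect_identical(img@bindings$expert, "lesion")
})

test_that("scenes round-trip to PNG with a JSON sidecar", {
  sc <- generateScene(unname(studyTextureSpecs()),
                      sceneLayout(64, 64,
                                  list(list(spec = "lesion", x0 = 17, y0 = 17,
                                            x1 = 48, y1 = 48)),
                                  background = "background",
                                  maskRegion = "lesion"),
                      seed = 4)
  stem <- file.path(withr::local_tempdir(), "scene")
  paths <- writeScene(sc, stem)
  expect_true(all(file.exists(paths)))
  back <- png::readPNG(paste0(stem, ".png"))
  expect_lt(max(abs(back - sc@image)), 1 / 255)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_identical(meta$categoryNames, sc@categoryNames)
})
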