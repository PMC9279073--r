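# Raster I/O, dataset splits, patch extraction, augmentation and stitching.

test_that("image/mask pairs round-trip through PNG with midpoint binarization", {
  dir <- withr::local_tempdir()
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  mask255 <- matrix(sample(c(0, 1), 32 * 32, replace = TRUE), 32, 32)
  png::writePNG(img, file.path(dir, "img.png"))
  png::writePNG(mask255, file.path(dir, "mask.png"))  # values {0, 255} on disk
  pair <- load_image_pair(file.path(dir, "img.png"), file.path(dir, "mask.png"))
  expect_s3_class(pair, "image_pair")
  expect_equal(dim(pair$image), c(32, 32, 3))
  expect_true(all(pair$mask %in% c(0, 1)))
  expect_equal(pair$mask, mask255)
  expect_lt(max(abs(pair$image - img)), 1 / 255)
  # grayscale images are replicated to three channels
  png::writePNG(matrix(runif(32 * 32), 32), file.path(dir, "gray.png"))
  pg <- load_image_pair(file.path(dir, "gray.png"), file.path(dir, "mask.png"))
  expect_equal(pg$image[, , 1], pg$image[, , 3])
  # size mismatch is rejected
  png::writePNG(matrix(0, 16, 16), file.path(dir, "small.png"))
  expect_error(load_image_pair(file.path(dir, "img.png"),
                               file.path(dir, "small.png")), "32x32.*16x16")
})

test_that("PGM/PPM and GIF rasters load", {
  dir <- withr::local_tempdir()
  # ascii PGM written by hand
  writeLines(c("P2", "3 2", "255", "0 128 255", "255 128 0"),
             file.path(dir, "t.pgm"))
  g <- vesselnet:::read_raster(file.path(dir, "t.pgm"))
  expect_equal(dim(g), c(2, 3))
  expect_equal(g[1, ], c(0, 128, 255) / 255)
  # GIF written through the Python imaging library on PATH
  png::writePNG(array(runif(24 * 24 * 3), c(24, 24, 3)),
                file.path(dir, "src.png"))
  st <- system2("python", c("-c", shQuote(sprintf(
    "from PIL import Image; Image.open(r'%s').convert('RGB').save(r'%s')",
    file.path(dir, "src.png"), file.path(dir, "t.gif")))))
  expect_identical(st, 0L)
  gf <- vesselnet:::read_raster(file.path(dir, "t.gif"))
  expect_equal(dim(gf)[1:2], c(24, 24))
})

test_that("benchmark dataset splits follow the stated divisions", {
  stare <- sprintf("im%04d", 1:20)
  sp <- split_dataset("STARE", sample(stare))   # order-independent
  expect_equal(sp$train, sort(stare)[1:10])
  expect_equal(sp$test, sort(stare)[11:20])
  drive <- sprintf("%02d_g", 1:40)
  dv <- split_dataset("DRIVE", drive)
  expect_length(dv$train, 20)
  expect_length(dv$test, 20)
  expect_equal(dv$test, sort(drive)[1:20])      # official: 1-20 test
  expect_error(split_dataset("STARE", stare[1:19]), "20 ids")
  expect_error(split_dataset("DRIVE", drive[1:39]), "40 ids")
})

test_that("patch extraction covers the grid and is seeded-reproducible", {
  pair <- small_phantom(seed = 2, size = 128)
  # degenerate tiling: one patch at the origin
  one <- extract_patches(
    structure(list(image = pair$image[1:64, 1:64, , drop = FALSE],
                   mask = pair$mask[1:64, 1:64], fov = NULL,
                   source_id = "crop"), class = "image_pair"),
    size = 64, strategy = "grid", stride = 64)
  expect_length(one$patches, 1)
  expect_equal(c(one$patches[[1]]$row, one$patches[[1]]$col), c(0, 0))
  # 128x128 at stride 64: a 2x2 lattice
  four <- extract_patches(pair, size = 64, strategy = "grid", stride = 64)
  expect_length(four$patches, 4)
  # random strategy: same seed, same origins
  r1 <- extract_patches(pair, size = 64, strategy = "random", n = 10, seed = 5)
  r2 <- extract_patches(pair, size = 64, strategy = "random", n = 10, seed = 5)
  expect_identical(lapply(r1$patches, `[`, c("row", "col")),
                   lapply(r2$patches, `[`, c("row", "col")))
  # image and mask patches cut from identical coordinates
  p1 <- r1$patches[[1]]
  expect_equal(p1$image[, , 1],
               pair$image[p1$row + 1:64, p1$col + 1:64, 1])
  expect_equal(p1$mask, pair$mask[p1$row + 1:64, p1$col + 1:64])
  expect_error(extract_patches(pair, size = 256), "smaller")
})

test_that("random patches respect the field-of-view coverage filter", {
  pair <- small_phantom(seed = 3, size = 128)
  ps <- extract_patches(pair, size = 64, strategy = "random", n = 30,
                        seed = 7, min_fov = 0.5)
  covs <- vapply(ps$patches, function(p)
    mean(pair$fov[p$row + 1:64, p$col + 1:64]), numeric(1))
  expect_true(all(covs >= 0.5))
})

test_that("augmentations are exact pixel permutations with group structure", {
  pair <- small_phantom(seed = 4)
  patch <- extract_patches(pair, size = 64, strategy = "grid",
                           stride = 64)$patches[[1]]
  # involutions and the rotation cycle
  expect_equal(augment(augment(patch, "hflip"), "hflip"), patch)
  expect_equal(augment(augment(patch, "vflip"), "vflip"), patch)
  r <- patch
  for (i in 1:4) r <- augment(r, "rot90")
  expect_equal(r, patch)
  expect_equal(augment(patch, c("rot90", "rot90")), augment(patch, "rot180"))
  # flips/rotations permute pixels: the histogram is untouched
  for (op in c("hflip", "vflip", "rot90", "rot180", "rot270")) {
    a <- augment(patch, op)
    expect_equal(sort(as.vector(a$image)), sort(as.vector(patch$image)))
    expect_true(all(a$mask %in% c(0, 1)))
  }
  # translation loses shifted-out foreground, never creates any
  tr <- augment(patch, "translate", shift = c(2, 3))
  expect_lte(sum(tr$mask), sum(patch$mask))
  expect_true(all(tr$mask %in% c(0, 1)))
  # seeded random shift reproduces
  t1 <- augment(patch, "translate", seed = 11)
  t2 <- augment(patch, "translate", seed = 11)
  expect_identical(t1, t2)
  expect_error(augment(patch, "zoom"), "unknown augmentation")
})

test_that("stitching averages overlaps and flags uncovered pixels", {
  # single full tile: identity
  m <- matrix(runif(64 * 64), 64, 64)
  st <- stitch_predictions(list(list(prob = m, row = 0, col = 0)), c(64, 64))
  expect_equal(st$prob, m)
  # two fully overlapping constant tiles average
  st2 <- stitch_predictions(list(list(prob = matrix(0.2, 8, 8), row = 0, col = 0),
                                 list(prob = matrix(0.8, 8, 8), row = 0, col = 0)),
                            c(8, 8))
  expect_true(all(st2$prob == 0.5))
  # random tiling against the accumulate/count oracle
  set.seed(12)
  tiles <- lapply(1:6, function(i)
    list(prob = matrix(runif(16), 4, 4),
         row = sample(0:8, 1), col = sample(0:8, 1)))
  got <- stitch_predictions(tiles, c(12, 12))
  expect_equal(got$prob, oracle_stitch(tiles, c(12, 12)))
  expect_true(anyNA(got$prob) == any(got$coverage == 0))
  expect_error(stitch_predictions(list(list(prob = matrix(0, 8, 8),
                                            row = 10, col = 0)), c(12, 12)),
               "exceeds")
})

test_that("binarization is strictly greater-than the threshold", {
  expect_true(all(binarize(matrix(0.5, 3, 3)) == 0))
  expect_true(all(binarize(matrix(0.6, 3, 3)) == 1))
  set.seed(13)
  p <- matrix(runif(100), 10, 10)
  expect_equal(binarize(p, 0.3), 1 * (p > 0.3))
  expect_error(binarize(matrix(1.5, 2, 2)), "\\[0,1\\]")
})

test_that("grid tiling plus identity prediction stitches back the mask", {
  pair <- small_phantom(seed = 6, size = 128)
  ps <- extract_patches(pair, size = 64, strategy = "grid", stride = 32)
  tiles <- lapply(ps$patches, function(p)
    list(prob = p$mask, row = p$row, col = p$col))
  st <- stitch_predictions(tiles, dim(pair$mask))
  expect_true(all(st$coverage >= 1))
  expect_equal(st$prob, pair$mask)
})
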