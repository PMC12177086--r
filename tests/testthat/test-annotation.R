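test_that("annotation I/O round-trips and rejects unsupported dialects", {
  tri <- structure(list(label = "tumor",
                        points = cbind(x = c(5, 20.5, 12), y = c(5, 8, 22.25)),
                        imageSize = c(32L, 32L)), class = "PolygonAnnotation")
  f <- tempfile(fileext = ".json")
  writeAnnotation(tri, f, imagePath = "img.png")
  back <- readAnnotation(f)
  expect_identical(nrow(back$points), 3L)
  expect_equal(back$points, tri$points, ignore_attr = TRUE)
  expect_identical(back$label, "tumor")

  # unsupported shape_type
  obj <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  obj$shapes[[1]]$shape_type <- "rectangle"
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, f2, auto_unbox = TRUE)
  expect_error(readAnnotation(f2), "shape_type")

  # missing required keys are named
  obj2 <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  obj2$imageHeight <- NULL
  f3 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj2, f3, auto_unbox = TRUE)
  expect_error(readAnnotation(f3), "imageHeight")
})

test_that("annotation round trip is stable over generated cohorts", {
  toy <- cachedToyCohort()
  for (i in seq_len(min(20, nrow(toy$manifest)))) {
    ann <- readAnnotation(file.path(toy$dir, toy$manifest$annotation_path[i]))
    f <- tempfile(fileext = ".json")
    writeAnnotation(ann, f)
    again <- readAnnotation(f)
    expect_identical(again$points, ann$points)
  }
})

test_that("rasterization matches the exhaustive point-in-polygon oracle", {
  sq <- cbind(x = c(10, 20, 20, 10), y = c(10, 10, 20, 20))
  got <- rasterizePolygon(sq, c(30, 30))
  expect_identical(got, rasterOracle(sq, c(30, 30)))
  expect_identical(sum(got), 121L)  # inclusive 11x11 centre grid

  set.seed(5)
  for (rep in 1:5) {
    n <- sample(3:7, 1)
    pts <- cbind(x = runif(n, 2, 26), y = runif(n, 2, 26))
    expect_identical(rasterizePolygon(pts, c(28, 28)),
                     rasterOracle(pts, c(28, 28)),
                     label = sprintf("random polygon %d", rep))
  }
})

test_that("polygons partially outside the frame are clipped", {
  pts <- cbind(x = c(-10, 5, 5, -10), y = c(2, 2, 8, 8))
  m <- rasterizePolygon(pts, c(12, 12))
  expect_identical(dim(m), c(12L, 12L))
  expect_true(all(m[, 7:12] == 0))
  expect_true(sum(m) > 0)
})

test_that("degenerate polygons give an empty mask with a warning", {
  line <- cbind(x = c(1, 5, 9), y = c(1, 5, 9))
  expect_warning(m <- rasterizePolygon(line, c(12, 12)), "degenerate")
  expect_identical(sum(m), 0L)
})

test_that("triangle area agrees with 2x supersampled rasterization within 5%", {
  tri <- cbind(x = c(4.2, 25.7, 13.1), y = c(5.1, 9.3, 24.8))
  a1 <- sum(rasterizePolygon(tri, c(30, 30)))
  a2 <- sum(rasterizePolygon(tri * 2, c(60, 60))) / 4
  expect_lt(abs(a1 - a2) / a2, 0.05)
})

test_that("eval preprocessing is a deterministic resize", {
  img <- matrix(runif(300 * 400), 300, 400)
  msk <- matrix(0L, 300, 400); msk[100:180, 150:260] <- 1L
  out1 <- preprocessView(img, msk, "eval", targetSize = 512)
  out2 <- preprocessView(img, msk, "eval", targetSize = 512)
  expect_identical(dim(out1$image), c(512L, 512L))
  expect_identical(dim(out1$mask), c(512L, 512L))
  expect_identical(out1, out2)
  expect_true(all(out1$mask %in% c(0L, 1L)))
})

test_that("train preprocessing draws scales in [0.8, 1.25] and flip is a mirror", {
  img <- matrix(runif(64 * 64), 64, 64)
  msk <- matrix(0L, 64, 64); msk[20:40, 25:45] <- 1L
  set.seed(11)
  for (i in 1:20) {
    # the drawn scale is observable through the pre-crop size when < target
    out <- preprocessView(img, msk, "train", targetSize = 64)
    expect_identical(dim(out$image), c(64L, 64L))
  }
  # flip forced on equals mirrored flip-off pipeline
  set.seed(42)
  a <- preprocessView(img, msk, "train", targetSize = 64, flipProb = 1)
  set.seed(42)
  b <- preprocessView(img, msk, "train", targetSize = 64, flipProb = 0)
  expect_equal(a$image, b$image[, 64:1])
  expect_equal(a$mask, b$mask[, 64:1])
  expect_error(preprocessView(img, msk, "bogus"), "arg")
})

test_that("admission-time split follows the floor rule and partitions patients", {
  mk <- function(n) data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                               admission_index = sample(seq_len(n)))
  r10 <- splitByAdmission(mk(10), 0.8)
  expect_identical(sum(r10$split == "train"), 8L)
  late <- r10$patient_id[order(r10$admission_index, decreasing = TRUE)][1:2]
  expect_setequal(r10$patient_id[r10$split == "internal_test"], late)

  expect_true(all(splitByAdmission(mk(7), 1.0)$split == "train"))

  rBig <- splitByAdmission(mk(1417), 0.8)
  expect_identical(sum(rBig$split == "train"), 1133L)
  expect_identical(sum(rBig$split == "internal_test"), 284L)

  dup <- data.frame(patient_id = c("A", "B"), admission_index = c(3, 3))
  expect_error(splitByAdmission(dup, 0.8), "unique")
})

test_that("geometric transforms commute with rasterization", {
  set.seed(8)
  for (i in 1:50) {
    # flips are exact at any scale
    les <- LesionSpec("tumor", c(32, 32), sort(runif(2, 8, 18), decreasing = TRUE),
                      rotation = runif(1, 0, pi), irregularity = runif(1, 0, 0.15),
                      lobes = sample(3:7, 1), phase = runif(1, 0, 2 * pi))
    pts <- lesionPolygon(les, 256)
    m <- rasterizePolygon(pts, c(64, 64))
    fpts <- cbind(x = 63 - pts[, 1], y = pts[, 2])
    fm <- rasterizePolygon(fpts, c(64, 64))
    iouF <- sum(fm & m[, 64:1]) / sum(fm | m[, 64:1])
    expect_gte(iouF, 0.98)
    # 2x upscale vs nearest-resize of the mask agrees up to boundary pixels;
    # masks large enough that the boundary band is a small area fraction
    lesL <- LesionSpec("tumor", c(88, 88), sort(runif(2, 34, 60), decreasing = TRUE),
                       rotation = runif(1, 0, pi), irregularity = runif(1, 0, 0.12),
                       lobes = sample(3:7, 1), phase = runif(1, 0, 2 * pi))
    ptsL <- lesionPolygon(lesL, 512)
    mL <- rasterizePolygon(ptsL, c(176, 176))
    spts <- (ptsL + 0.5) * 2 - 0.5
    sm <- rasterizePolygon(spts, c(352, 352))
    rm <- 1L * (axilnet:::resizeGrid(mL, 352, 352, "none") > 0.5)
    iouS <- sum(sm & rm) / sum(sm | rm)
    expect_gte(iouS, 0.98)
  }
})
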