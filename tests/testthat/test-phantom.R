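test_that("cohort simulation is deterministic and respects the label rule", {
  spec <- CohortSpec(nPatients = 12, seed = 77, imageSize = 64)
  a <- simulateCohort(spec)
  b <- simulateCohort(spec)
  expect_identical(
    lapply(patients(a), function(p) p@views[[1]]$image),
    lapply(patients(b), function(p) p@views[[1]]$image))
  expect_identical(alnStatus(a), alnStatus(b))
  thr <- 1 - spec@prevalence
  for (p in patients(a)) {
    expect_identical(p@alnStatus, as.integer(p@metastaticScore > thr))
    vt <- vapply(p@views, function(v) v$viewType, character(1))
    expect_gte(sum(vt == "tumor"), 1L)
  }
})

test_that("prevalence 0 yields an all-negative cohort; labels follow Bernoulli(prevalence)", {
  z <- simulateCohort(CohortSpec(nPatients = 10, prevalence = 0, seed = 4,
                                 imageSize = 64))
  expect_identical(alnStatus(z), rep(0L, 10))
  # label-only draw at the training-cohort scale: positive count inside the
  # central 99% binomial interval around n * prevalence
  big <- simulateCohort(CohortSpec(nPatients = 1144, prevalence = 0.642,
                                   seed = 7), render = FALSE)
  npos <- sum(alnStatus(big))
  lim <- qbinom(c(0.005, 0.995), 1144, 0.642)
  expect_gte(npos, lim[1])
  expect_lte(npos, lim[2])
})

test_that("node-view visibility follows the status-conditional probabilities", {
  coh <- simulateCohort(CohortSpec(nPatients = 200, prevalence = 0.5,
                                   pNodeVisiblePos = 1, pNodeVisibleNeg = 0,
                                   seed = 9), render = FALSE)
  for (p in patients(coh)) {
    vt <- vapply(p@views, function(v) v$viewType, character(1))
    if (p@alnStatus == 1) expect_gte(sum(vt == "node"), 1L)
    else expect_identical(sum(vt == "node"), 0L)
  }
})

test_that("invalid cohort specifications name the offending field", {
  expect_error(CohortSpec(prevalence = 1.4), "prevalence")
  expect_error(CohortSpec(tumorViewsRange = c(0, 2)), "tumorViewsRange")
  expect_error(CohortSpec(pNodeVisiblePos = -0.1), "pNodeVisiblePos")
  expect_error(EffectParams(roundnessShift = -1), "roundnessShift")
  expect_error(NoiseParams(lesionContrast = 2), "lesionContrast")
})

test_that("renderer contrast model matches its stated expectations", {
  set.seed(31)
  # zero lesion contrast: interior indistinguishable from background
  nz <- NoiseParams(lesionContrast = 0, hilumContrast = 0,
                    backgroundMean = 0.5, speckleScale = 0.25)
  les <- LesionSpec("tumor", c(48, 48), c(16, 10))
  diffs <- replicate(20, {
    rv <- renderView(les, nz, 96)
    mean(rv$image[rv$mask == 1]) - mean(rv$image[rv$mask == 0])
  })
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-3)

  # hilum brightening: gap between hilum disc and surrounding node ring is
  # hilumContrast * backgroundMean under the multiplicative model
  nh <- NoiseParams(lesionContrast = 0.5, hilumContrast = 0.3,
                    backgroundMean = 0.5, speckleScale = 0.2)
  nodeLes <- LesionSpec("node", c(48, 48), c(18, 14), hilumPresent = TRUE)
  gaps <- replicate(20, {
    rv <- renderView(nodeLes, nh, 96)
    ring <- rv$mask == 1 & rv$hilum == 0
    mean(rv$image[rv$hilum == 1]) - mean(rv$image[ring])
  })
  expect_lt(abs(mean(gaps) - 0.3 * 0.5), 0.02)
})

test_that("unperturbed ellipse mask area matches pi*a*b within 2%", {
  les <- LesionSpec("tumor", c(48, 48), c(40, 20))
  mask <- rasterizePolygon(lesionPolygon(les, 720), c(96, 96))
  expect_lt(abs(sum(mask) - pi * 40 * 20) / (pi * 40 * 20), 0.02)
})

test_that("lesions leaving the frame raise a geometry error", {
  les <- LesionSpec("tumor", c(5, 48), c(16, 10))
  expect_error(renderView(les, NoiseParams(), 96), "geometry")
})

test_that("mask polygonization round-trips and hugs the boundary", {
  # filled square
  sq <- matrix(0L, 12, 12); sq[4:9, 4:9] <- 1L
  p <- polygonizeMask(sq)
  back <- rasterizePolygon(p, c(12, 12))
  expect_gte(sum(sq & back) / sum(sq | back), 0.95)
  # empty and multi-component masks are errors
  expect_error(polygonizeMask(matrix(0L, 8, 8)), "empty")
  two <- matrix(0L, 20, 20); two[2:5, 2:5] <- 1L; two[14:18, 14:18] <- 1L
  expect_error(polygonizeMask(two), "components")
  # ellipse: enough vertices, all within 1 px of true boundary pixels
  les <- LesionSpec("node", c(24, 24), c(14, 9))
  mask <- rasterizePolygon(lesionPolygon(les, 720), c(48, 48))
  poly <- polygonizeMask(mask)
  expect_gte(nrow(poly$points), 8)
  edge <- which(mask == 1 & (EBImage::erode(mask, EBImage::makeBrush(3, "box")) == 0),
                arr.ind = TRUE)
  bx <- edge[, 2] - 1; by <- edge[, 1] - 1
  dists <- apply(poly$points, 1, function(v) min(sqrt((v[1] - bx)^2 + (v[2] - by)^2)))
  expect_lte(max(dists), 1)
  back2 <- rasterizePolygon(poly, c(48, 48))
  expect_gte(sum(mask & back2) / sum(mask | back2), 0.95)
})

test_that("null effects make image statistics uninformative; a planted hilum gap separates node views", {
  # null: mean-intensity classifier over 500 views has AUC ~ 0.5
  nullSpec <- CohortSpec(nPatients = 170, prevalence = 0.5,
                         tumorViewsRange = c(1, 2), nodeViewsRange = c(1, 2),
                         pNodeVisiblePos = 0.7, pNodeVisibleNeg = 0.7,
                         effect = nullEffect(), seed = 21, imageSize = 64)
  coh <- simulateCohort(nullSpec)
  stats <- c(); labs <- c()
  for (p in patients(coh)) for (v in p@views) {
    stats <- c(stats, mean(v$image)); labs <- c(labs, p@alnStatus)
  }
  stats <- stats[seq_len(min(500, length(stats)))]
  labs <- labs[seq_len(length(stats))]
  expect_lt(abs(rocAuc(stats, labs) - 0.5), 0.05)

  # planted: hilum-disc-brighter-than-ring detector on node views
  plantSpec <- CohortSpec(nPatients = 160, prevalence = 0.5,
                          nodeViewsRange = c(1, 1), pNodeVisiblePos = 1,
                          pNodeVisibleNeg = 1,
                          effect = EffectParams(hilumLossGap = 0.9),
                          seed = 22, imageSize = 64)
  pc <- simulateCohort(plantSpec)
  det <- c(); labs2 <- c()
  for (p in patients(pc)) for (v in p@views) {
    if (v$viewType != "node") next
    hil <- axilnet:::hilumMask(v$lesion, 64)
    ring <- v$mask == 1 & hil == 0
    det <- c(det, mean(v$image[hil == 1]) - mean(v$image[ring]))
    labs2 <- c(labs2, p@alnStatus)
  }
  det <- det[seq_len(min(200, length(det)))]
  labs2 <- labs2[seq_len(length(det))]
  # negative nodes keep the bright hilum, so the detector scores them higher
  expect_gte(rocAuc(-det, labs2), 0.9)
})
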