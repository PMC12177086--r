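test_that("mask decoder emits contract-conforming shapes and probabilities", {
  set.seed(10)
  m <- mtlModel(list(imageSize = 64L,
                     backbone = list(name = "tinyconv", channels = 16L),
                     decoder = list(depth = 2L, heads = 2L, segChannels = 8L)))
  x <- array(runif(64 * 64 * 3), c(64, 64, 1, 3))
  out <- mtlForward(m, x)
  expect_identical(dim(out$z), c(4L, 4L, 16L, 3L))        # stride 16
  expect_identical(dim(out$s), c(16L, 16L, 8L, 3L))       # 1/4 scale
  expect_identical(dim(out$ySegHat), c(64L, 64L, 3L))     # input resolution
  expect_true(all(out$ySegHat > 0 & out$ySegHat < 1))
  expect_true(all(out$yMcls > 0 & out$yMcls < 1))
  expect_true(all(out$yCls > 0 & out$yCls < 1))
})

test_that("zeroed token feed-forward output collapses the mask to sigmoid(0)", {
  set.seed(11)
  m <- mtlModel(list(imageSize = 32L,
                     backbone = list(name = "tinyconv", channels = 8L),
                     decoder = list(depth = 1L, heads = 2L, segChannels = 4L)))
  m@params[["dec.tokmlp.W2"]][] <- 0
  m@params[["dec.tokmlp.b2"]][] <- 0
  out <- mtlForward(m, matrix(runif(32 * 32), 32, 32))
  expect_equal(as.vector(out$ySegHat), rep(0.5, 32 * 32), tolerance = 1e-12)
})

test_that("segmentation-as-attention gating annihilates, passes through, and averages correctly", {
  set.seed(12)
  z <- array(rnorm(6 * 6 * 5 * 2), c(6, 6, 5, 2))
  s <- array(rnorm(24 * 24 * 3 * 2), c(24, 24, 3, 2))
  zeroA <- array(0, c(96, 96, 2)); oneA <- array(1, c(96, 96, 2))
  g0 <- gateFeatures(z, s, zeroA)
  expect_true(all(g0$zm == 0) && all(g0$zc == 0))
  g1 <- gateFeatures(z, s, oneA)
  expect_equal(g1$zm, s); expect_equal(g1$zc, z)

  # half-plane indicator: gated spatial mean equals direct masked averaging
  att <- array(0, c(96, 96, 2)); att[, 1:48, ] <- 1
  g <- gateFeatures(z, s, att)
  for (b in 1:2) for (ch in 1:5) {
    direct <- sum(z[, 1:3, ch, b]) / 36   # half-plane pools to columns 1:3 of 6
    expect_equal(mean(g$zc[, , ch, b]), direct, tolerance = 1e-12)
  }
})

test_that("classification heads are exactly pool-then-linear", {
  set.seed(13)
  hp <- list(Wm = matrix(rnorm(3)), bm = 0.2, Wc = matrix(rnorm(5)), bc = -0.4)
  # constant feature maps: logit = <w, c> + b exactly
  cm <- c(0.5, -1, 2); cc <- c(1, 2, -0.5, 0.25, 3)
  zm <- array(rep(cm, each = 16), c(4, 4, 3, 1))
  zc <- array(rep(cc, each = 16), c(4, 4, 5, 1))
  got <- classifyHeads(zm, zc, hp)
  expect_equal(got$yMcls, axilnet:::sigmoid(sum(hp$Wm * cm) + hp$bm),
               tolerance = 1e-12)
  expect_equal(got$yCls, axilnet:::sigmoid(sum(hp$Wc * cc) + hp$bc),
               tolerance = 1e-12)
  # zero features: sigmoid(bias)
  z0 <- classifyHeads(zm * 0, zc * 0, hp)
  expect_equal(z0$yCls, axilnet:::sigmoid(hp$bc), tolerance = 1e-12)
  # random features: equals hand-computed pool-then-linear
  zr <- array(rnorm(4 * 4 * 5 * 2), c(4, 4, 5, 2))
  gr <- classifyHeads(zm, zr, hp)
  for (b in 1:2) {
    pooled <- vapply(1:5, function(ch) mean(zr[, , ch, b]), numeric(1))
    expect_equal(gr$yCls[b], axilnet:::sigmoid(sum(pooled * hp$Wc) + hp$bc),
                 tolerance = 1e-12)
  }
})

test_that("pseudo-labels broadcast the patient label to every image", {
  expect_identical(makePseudoLabels(1, list("a", "b", "c")), c(1L, 1L, 1L))
  expect_identical(makePseudoLabels(0, list("a", "b")), c(0L, 0L))
  expect_identical(makePseudoLabels(1, list()), integer(0))
  expect_error(makePseudoLabels(2, list("a")))
})

test_that("multi-task loss components are BCE and sum exactly", {
  out <- list(ySegHat = matrix(0.5, 4, 4), yMcls = 0.5, yCls = 0.5)
  tg <- list(ySeg = matrix(1, 4, 4), yMcls = 1, yCls = 1)
  lb <- mtlLoss(out, tg)
  expect_equal(lb$l_seg, log(2), tolerance = 1e-12)
  expect_equal(lb$l_mcls, log(2), tolerance = 1e-12)
  expect_equal(lb$total, 3 * log(2), tolerance = 1e-12)

  perf <- list(ySegHat = matrix(1 - 1e-9, 4, 4), yMcls = 1 - 1e-9,
               yCls = 1 - 1e-9)
  expect_lt(mtlLoss(perf, tg)$total, 1e-6)

  set.seed(3)
  ro <- list(ySegHat = matrix(runif(16), 4, 4), yMcls = runif(2),
             yCls = runif(2))
  rt <- list(ySeg = matrix(rbinom(16, 1, 0.5), 4, 4), yMcls = c(0, 1),
             yCls = c(1, 1))
  w <- c(0.7, 1.3, 2)
  lb2 <- mtlLoss(ro, rt, w)
  expect_equal(lb2$total,
               w[1] * lb2$l_seg + w[2] * lb2$l_mcls + w[3] * lb2$l_cls,
               tolerance = 1e-12)
  expect_equal(lb2$l_mcls,
               mean(-rt$yMcls * log(ro$yMcls) -
                      (1 - rt$yMcls) * log(1 - ro$yMcls)), tolerance = 1e-9)
  bad <- list(ySegHat = matrix(0.5, 3, 3), yMcls = 0.5, yCls = 0.5)
  expect_error(mtlLoss(bad, tg), "shape")
})

test_that("a brief overfit run on one fixed image pair collapses the segmentation BCE by >= 90%", {
  set.seed(21)
  m <- mtlModel(list(imageSize = 64L,
                     backbone = list(name = "tinyconv", channels = 16L),
                     decoder = list(depth = 2L, heads = 2L, segChannels = 8L)))
  img <- matrix(runif(64 * 64, 0.3, 0.7), 64, 64)
  msk <- matrix(0L, 64, 64); msk[17:48, 17:48] <- 1L
  img[msk == 1] <- img[msk == 1] * 0.4
  x <- array(img, c(64, 64, 1, 1))
  tg <- list(ySeg = array(msk, c(64, 64, 1)), yMcls = 0, yCls = 1)
  st <- axilnet:::adamwInit(m@params)
  first <- NULL
  for (i in 1:100) {
    sp <- axilnet:::mtlStep(m, st, x, tg, lr = 2e-2)
    m <- sp$model; st <- sp$state
    if (i == 1) first <- sp$loss$l_seg
  }
  final <- mtlLoss(mtlForward(m, x), tg)$l_seg
  expect_lt(final, 0.1 * first)
})

test_that("with near-binary attention, pixels far outside the lesion cannot move the ALN head", {
  set.seed(22)
  m <- mtlModel(list(imageSize = 96L,
                     backbone = list(name = "tinyconv", channels = 16L),
                     decoder = list(depth = 1L, heads = 2L, segChannels = 8L)))
  les <- LesionSpec("tumor", c(28, 28), c(12, 9))
  rv <- renderView(les, NoiseParams(), 96)
  x1 <- rv$image
  x2 <- x1
  x2[70:96, 70:96] <- runif(27 * 27)     # perturb a far corner (> receptive field away)
  att <- array(0, c(96, 96, 1)); att[rv$mask == 1] <- 1
  hp <- list(Wm = m@params[["head.mcls.W"]], bm = m@params[["head.mcls.b"]],
             Wc = m@params[["head.cls.W"]], bc = m@params[["head.cls.b"]])
  yOf <- function(img) {
    out <- mtlForward(m, img)
    g <- gateFeatures(out$z, out$s, att)
    classifyHeads(g$zm, g$zc, hp)$yCls
  }
  expect_lt(abs(yOf(x1) - yOf(x2)), 0.05)
})
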