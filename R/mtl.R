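## ---------------------------------------------------------------------------
## Stage 1: image-level multi-task network.
##
## backbone -> feature map z (stride 16)
## mask decoder (two two-way attention blocks + 2 transposed convolutions)
##   -> segmentation feature s (1/4 scale) and an enhanced mask token
## segmentation head: sigmoid(<mlp(token), s>) per location, upsampled
## segmentation-as-attention: y_seg_hat gates s -> z_m and z -> z_c
## two pool-then-linear heads: lesion type from z_m, image-level ALN from z_c
## All three losses are BCE; gradients flow through the attention map.
## ---------------------------------------------------------------------------

mtlDefaults <- function() {
  list(imageSize = 96L,
       backbone = list(name = "tinyconv", channels = 32L),
       decoder = list(depth = 2L, heads = 2L, segChannels = 8L),
       loss = list(weights = c(seg = 1, mcls = 1, cls = 1)),
       epsilon = 1e-7,
       tokenDim = 256L)
}

#' Stage-1 multi-task model
#'
#' @slot params flat named list of parameter arrays.
#' @slot config resolved configuration list.
#' @exportClass MtlModel
setClass("MtlModel", representation(params = "list", config = "list"))

#' @rdname modelConfig
#' @export
setMethod("modelConfig", "MtlModel", function(object) object@config)

#' @rdname modelConfig
#' @export
setMethod("nParameters", "MtlModel", function(object)
  sum(vapply(object@params, length, numeric(1))))

setMethod("show", "MtlModel", function(object) {
  cat(sprintf("MtlModel: %s backbone (C=%d), decoder depth %d, %d parameters\n",
              object@config$backbone$name, object@config$backbone$channels,
              object@config$decoder$depth, nParameters(object)))
})

#' Construct a stage-1 multi-task model
#'
#' Initializes the backbone, the SAM-style mask decoder (learnable mask
#' token, two-way attention blocks, two 2x stride-2 transposed convolutions)
#' and the two pool-then-linear classification heads. Weights are drawn from
#' the current RNG stream.
#'
#' @param config optional list overriding entries of the default
#'   configuration (`imageSize`, `backbone`, `decoder`, `loss`, `epsilon`).
#' @return an [MtlModel-class].
#' @export
mtlModel <- function(config = list()) {
  cfg <- modifyList(mtlDefaults(), config)
  C <- as.integer(cfg$backbone$channels)
  C1 <- max(4L, C %/% 2L)
  C2 <- as.integer(cfg$decoder$segChannels)
  p <- list()
  bp <- backboneInit(cfg$backbone$name, C)
  names(bp) <- paste0("bb.", names(bp))
  p <- c(p, bp)
  p[["dec.token"]] <- rnorm(C, sd = 0.5)
  for (i in seq_len(cfg$decoder$depth)) {
    pre <- sprintf("dec.blk%d", i)
    blk <- list(sa = mhaInit(C), ln1 = lnInit(C),
                ca = mhaInit(C), ln2 = lnInit(C),
                mlp = mlpInit(C, 2L * C, C), ln3 = lnInit(C),
                ia = mhaInit(C), ln4 = lnInit(C))
    bf <- flattenParams(blk)
    names(bf) <- paste0(pre, ".", names(bf))
    p <- c(p, bf)
  }
  fin <- flattenParams(list(fa = mhaInit(C), ln5 = lnInit(C),
                            tokmlp = mlpInit(C, C, C2),
                            convt1 = convTInit(C, C1),
                            convt2 = convTInit(C1, C2)))
  names(fin) <- paste0("dec.", names(fin))
  p <- c(p, fin)
  hd <- flattenParams(list(mcls = list(W = matrix(rnorm(C2, sd = sqrt(1 / C2))),
                                       b = 0),
                           cls = list(W = matrix(rnorm(C, sd = sqrt(1 / C))),
                                      b = 0)))
  names(hd) <- paste0("head.", names(hd))
  p <- c(p, hd)
  new("MtlModel", params = p, config = cfg)
}

## one two-way attention block (token t [1,C], image X [P,C])
decBlockFwd <- function(t, X, params, pre, heads) {
  sp <- function(nm) subParams(params, paste0(pre, ".", nm))
  sa <- mhaFwd(t, t, sp("sa"), heads)
  t1 <- t + sa$out
  l1 <- lnFwd(t1, params[[paste0(pre, ".ln1.g")]], params[[paste0(pre, ".ln1.b")]])
  ca <- mhaFwd(l1$out, X, sp("ca"), heads)
  t2 <- l1$out + ca$out
  l2 <- lnFwd(t2, params[[paste0(pre, ".ln2.g")]], params[[paste0(pre, ".ln2.b")]])
  ml <- mlpFwd(l2$out, sp("mlp"))
  t3 <- l2$out + ml$out
  l3 <- lnFwd(t3, params[[paste0(pre, ".ln3.g")]], params[[paste0(pre, ".ln3.b")]])
  ia <- mhaFwd(X, l3$out, sp("ia"), heads)
  X2 <- X + ia$out
  l4 <- lnFwd(X2, params[[paste0(pre, ".ln4.g")]], params[[paste0(pre, ".ln4.b")]])
  list(t = l3$out, X = l4$out,
       cache = list(sa = sa, l1 = l1, ca = ca, l2 = l2, ml = ml, l3 = l3,
                    ia = ia, l4 = l4))
}

decBlockBwd <- function(dt_out, dX_out, cache, params, pre, heads, env) {
  sp <- function(nm) subParams(params, paste0(pre, ".", nm))
  g4 <- lnBwd(dX_out, cache$l4$cache)
  gradAdd(env, paste0(pre, ".ln4"), list(g = g4$dg, b = g4$db))
  dX2 <- g4$dx
  a4 <- mhaBwd(dX2, cache$ia$cache, sp("ia"))
  gradAdd(env, paste0(pre, ".ia"), a4$grads)
  dX_in <- dX2 + a4$dxq
  dl3 <- dt_out + a4$dxkv
  g3 <- lnBwd(dl3, cache$l3$cache)
  gradAdd(env, paste0(pre, ".ln3"), list(g = g3$dg, b = g3$db))
  dt3 <- g3$dx
  mb <- mlpBwd(dt3, cache$ml$cache, sp("mlp"))
  gradAdd(env, paste0(pre, ".mlp"), mb$grads)
  dl2 <- dt3 + mb$dx
  g2 <- lnBwd(dl2, cache$l2$cache)
  gradAdd(env, paste0(pre, ".ln2"), list(g = g2$dg, b = g2$db))
  dt2 <- g2$dx
  a2 <- mhaBwd(dt2, cache$ca$cache, sp("ca"))
  gradAdd(env, paste0(pre, ".ca"), a2$grads)
  dX_in <- dX_in + a2$dxkv
  dl1 <- dt2 + a2$dxq
  g1 <- lnBwd(dl1, cache$l1$cache)
  gradAdd(env, paste0(pre, ".ln1"), list(g = g1$dg, b = g1$db))
  dt1 <- g1$dx
  a1 <- mhaBwd(dt1, cache$sa$cache, sp("sa"))
  gradAdd(env, paste0(pre, ".sa"), a1$grads)
  dt_in <- dt1 + a1$dxq + a1$dxkv
  list(dt = dt_in, dX = dX_in)
}

#' Forward pass of the stage-1 multi-task network
#'
#' @param model an [MtlModel-class].
#' @param x image batch, array `[H, W, 1, B]` (or a single `[H, W]` matrix).
#' @param withCache keep intermediate caches for a backward pass.
#' @return list with `z` (backbone features), `s` (segmentation feature at
#'   1/4 scale), `ySegHat` (`[H, W, B]` probability maps), `zm`, `zc` (gated
#'   features), `yMcls`, `yCls` (per-image probabilities), plus caches when
#'   requested.
#' @export
mtlForward <- function(model, x, withCache = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  p <- model@params; cfg <- model@config
  H <- dim(x)[1]; W <- dim(x)[2]; B <- dim(x)[4]
  heads <- cfg$decoder$heads; depth <- cfg$decoder$depth
  C <- cfg$backbone$channels
  bb <- backboneFwd(cfg$backbone$name, subParams(p, "bb"), x)
  z <- bb$z
  h <- dim(z)[1]; w <- dim(z)[2]; P <- h * w
  tok0 <- matrix(p[["dec.token"]], 1, C)
  items <- vector("list", B)
  XF <- array(0, c(h, w, C, B))
  hvecs <- matrix(0, B, cfg$decoder$segChannels)
  for (b in seq_len(B)) {
    X <- matrix(z[, , , b], P, C)
    t <- tok0
    blocks <- vector("list", depth)
    for (i in seq_len(depth)) {
      bf <- decBlockFwd(t, X, p, sprintf("dec.blk%d", i), heads)
      blocks[[i]] <- bf$cache
      t <- bf$t; X <- bf$X
    }
    fa <- mhaFwd(t, X, subParams(p, "dec.fa"), heads)
    tf <- t + fa$out
    l5 <- lnFwd(tf, p[["dec.ln5.g"]], p[["dec.ln5.b"]])
    tm <- mlpFwd(l5$out, subParams(p, "dec.tokmlp"))
    hvecs[b, ] <- tm$out
    XF[, , , b] <- array(X, c(h, w, C))
    items[[b]] <- list(blocks = blocks, fa = fa, l5 = l5, tm = tm, X = X)
  }
  ct1 <- convTFwd(XF, p[["dec.convt1.W"]], p[["dec.convt1.b"]])
  a1 <- relu(ct1$out)
  ct2 <- convTFwd(a1, p[["dec.convt2.W"]], p[["dec.convt2.b"]])
  s <- relu(ct2$out)                                  # [4h, 4w, C2, B]
  h4 <- dim(s)[1]; P4 <- h4 * dim(s)[2]; C2 <- dim(s)[3]
  p24 <- array(0, c(h4, dim(s)[2], B))
  for (b in seq_len(B)) {
    logits <- matrix(s[, , , b], P4, C2) %*% hvecs[b, ]
    p24[, , b] <- sigmoid(array(logits, c(h4, dim(s)[2])))
  }
  U <- bilinearMatrix(H, h4)
  ySeg <- sepApply(U, p24)                            # [H, W, B]
  gated <- gateFeatures(z, s, ySeg)
  heads_out <- classifyHeads(gated$zm, gated$zc,
                             list(Wm = p[["head.mcls.W"]], bm = p[["head.mcls.b"]],
                                  Wc = p[["head.cls.W"]], bc = p[["head.cls.b"]]))
  out <- list(z = z, s = s, ySegHat = ySeg, p24 = p24,
              zm = gated$zm, zc = gated$zc,
              yMcls = heads_out$yMcls, yCls = heads_out$yCls,
              gm = heads_out$gm, gc = heads_out$gc, hvecs = hvecs)
  if (withCache)
    out$cache <- list(bb = bb$cache, items = items, ct1 = ct1, a1pre = ct1$out,
                      ct2 = ct2, spre = ct2$out, U = U, dims = dim(x))
  out
}

#' Gate feature maps with the predicted segmentation map
#'
#' The segmentation probability map is area-average pooled to each feature
#' map's resolution and multiplied elementwise (broadcast over channels):
#' `z_m = s * pool(ySegHat)` and `z_c = z * pool(ySegHat)`. An all-zero map
#' annihilates both features; an all-one map passes them through unchanged.
#'
#' @param z backbone feature map `[h, w, C, B]` (or `[h, w, C]`).
#' @param s segmentation feature map `[4h, 4w, C', B]` (or 3-D).
#' @param ySegHat segmentation probability map `[H, W, B]` (or a matrix).
#' @return list with gated `zm`, `zc` and the pooled attention maps `a4`,
#'   `a16`.
#' @export
gateFeatures <- function(z, s, ySegHat) {
  if (length(dim(z)) == 3) z <- array(z, c(dim(z), 1L))
  if (length(dim(s)) == 3) s <- array(s, c(dim(s), 1L))
  if (is.matrix(ySegHat)) ySegHat <- array(ySegHat, c(dim(ySegHat), 1L))
  H <- dim(ySegHat)[1]
  a4 <- sepApply(poolMatrix(dim(s)[1], H), ySegHat)
  a16 <- sepApply(poolMatrix(dim(z)[1], H), ySegHat)
  gate <- function(f, a) {
    fp <- aperm(f, c(1, 2, 4, 3))                     # [h, w, B, C]
    aperm(array(as.vector(fp) * as.vector(a), dim(fp)), c(1, 2, 4, 3))
  }
  list(zm = gate(s, a4), zc = gate(z, a16), a4 = a4, a16 = a16)
}

#' Pool-then-linear classification heads
#'
#' Each head applies global average pooling over space followed by a 1x1
#' convolution (a linear map over channels) and a sigmoid. The lesion-type
#' head reads the mask feature `z_m`; the image-level ALN head reads the
#' lesion feature `z_c`.
#'
#' @param zm,zc gated feature maps (`[h, w, C, B]` or 3-D single image).
#' @param headParams list with `Wm`, `bm`, `Wc`, `bc`.
#' @return list with probabilities `yMcls`, `yCls` and the pooled features
#'   `gm`, `gc`.
#' @export
classifyHeads <- function(zm, zc, headParams) {
  if (length(dim(zm)) == 3) zm <- array(zm, c(dim(zm), 1L))
  if (length(dim(zc)) == 3) zc <- array(zc, c(dim(zc), 1L))
  gm <- gapPool(zm)                                   # [B, C']
  gc <- gapPool(zc)                                   # [B, C]
  list(yMcls = as.vector(sigmoid(gm %*% headParams$Wm + headParams$bm)),
       yCls = as.vector(sigmoid(gc %*% headParams$Wc + headParams$bc)),
       gm = gm, gc = gc)
}

#' Broadcast the patient label to all of its images
#'
#' The image-level metastasis targets are pseudo-labels: every view of a
#' patient inherits the patient-level ALN label (noise from mislabelled
#' tumor views of positive patients is absorbed by the MIL stage).
#'
#' @param patientLabel 0 or 1.
#' @param imageList list (or vector) of the patient's images.
#' @return integer vector of per-image labels.
#' @export
makePseudoLabels <- function(patientLabel, imageList) {
  stopifnot(patientLabel %in% c(0, 1))
  rep(as.integer(patientLabel), length(imageList))
}

#' Multi-task loss bundle
#'
#' `l_seg` is the mean pixelwise BCE between the predicted and ground-truth
#' masks, `l_mcls` the BCE of the lesion-type head against the node
#' indicator, `l_cls` the BCE of the image-level head against the broadcast
#' pseudo-labels; `total` is their weighted sum.
#'
#' @param outputs list with `ySegHat`, `yMcls`, `yCls` (as from
#'   [mtlForward]).
#' @param targets list with `ySeg` (`[H, W, B]` or matrix), `yMcls` (1 =
#'   node), `yCls`.
#' @param weights length-3 weights `(seg, mcls, cls)`.
#' @param eps BCE clamping constant.
#' @return list with `l_seg`, `l_mcls`, `l_cls`, `total`.
#' @export
mtlLoss <- function(outputs, targets, weights = c(1, 1, 1), eps = 1e-7) {
  ySeg <- targets$ySeg
  if (is.matrix(ySeg) && length(dim(outputs$ySegHat)) == 3)
    ySeg <- array(ySeg, dim(outputs$ySegHat))
  if (!all(dim(outputs$ySegHat) == dim(ySeg)))
    stopf("segmentation target shape %s does not match output shape %s",
          paste(dim(ySeg), collapse = "x"),
          paste(dim(outputs$ySegHat), collapse = "x"))
  l_seg <- mean(bceLoss(outputs$ySegHat, ySeg, eps))
  l_mcls <- mean(bceLoss(outputs$yMcls, targets$yMcls, eps))
  l_cls <- mean(bceLoss(outputs$yCls, targets$yCls, eps))
  list(l_seg = l_seg, l_mcls = l_mcls, l_cls = l_cls,
       total = weights[1] * l_seg + weights[2] * l_mcls + weights[3] * l_cls)
}

## full backward pass; returns flat gradient list aligned with model@params
mtlBackward <- function(model, out, targets) {
  p <- model@params; cfg <- model@config
  w <- cfg$loss$weights; eps <- cfg$epsilon
  cache <- out$cache
  dims <- cache$dims; H <- dims[1]; B <- dims[4]
  z <- out$z; s <- out$s
  h <- dim(z)[1]; C <- dim(z)[3]
  h4 <- dim(s)[1]; C2 <- dim(s)[3]
  P <- h * h; P4 <- h4 * h4
  env <- new.env(); env$g <- list()

  ySeg <- targets$ySeg
  if (is.matrix(ySeg)) ySeg <- array(ySeg, dim(out$ySegHat))
  pS <- pmin(pmax(out$ySegHat, eps), 1 - eps)
  dy96 <- w[1] * (pS - ySeg) / (pS * (1 - pS)) / (H * H * B)

  ## heads
  pm <- pmin(pmax(out$yMcls, eps), 1 - eps)
  dlm <- matrix(w[2] * (pm - targets$yMcls) / B, ncol = 1)
  gradAdd(env, "head.mcls", list(W = t(out$gm) %*% dlm, b = sum(dlm)))
  dgm <- dlm %*% t(p[["head.mcls.W"]])                # [B, C2]
  pc <- pmin(pmax(out$yCls, eps), 1 - eps)
  dlc <- matrix(w[3] * (pc - targets$yCls) / B, ncol = 1)
  gradAdd(env, "head.cls", list(W = t(out$gc) %*% dlc, b = sum(dlc)))
  dgc <- dlc %*% t(p[["head.cls.W"]])                 # [B, C]

  ## GAP backward: spread over spatial positions
  dzm <- aperm(array(rep(t(dgm) / P4, each = P4), c(h4, h4, C2, B)), c(1, 2, 3, 4))
  dzc <- aperm(array(rep(t(dgc) / P, each = P), c(h, h, C, B)), c(1, 2, 3, 4))

  ## gating backward
  gated <- gateFeatures(z, s, out$ySegHat)
  ds <- array(0, dim(s)); dz <- array(0, dim(z))
  expand <- function(a, C_) aperm(array(rep(as.vector(a), times = C_),
                                        c(dim(a)[1], dim(a)[2], dim(a)[3], C_)),
                                  c(1, 2, 4, 3))
  ds <- ds + dzm * expand(gated$a4, C2)
  dz <- dz + dzc * expand(gated$a16, C)
  dA4 <- channelSum(dzm * s)                          # [4h, 4w, B]
  dA16 <- channelSum(dzc * z)
  dy96 <- dy96 + sepApply(t(poolMatrix(h4, H)), dA4) +
    sepApply(t(poolMatrix(h, H)), dA16)

  ## through the upsample and the dot-product segmentation head
  dp24 <- sepApply(t(cache$U), dy96)
  dlog24 <- dp24 * out$p24 * (1 - out$p24)
  dhv <- matrix(0, B, C2)
  for (b in seq_len(B)) {
    v <- as.vector(dlog24[, , b])
    sm <- matrix(s[, , , b], P4, C2)
    ds[, , , b] <- ds[, , , b] + array(v %*% t(out$hvecs[b, ]), c(h4, h4, C2))
    dhv[b, ] <- t(sm) %*% v
  }

  ## transposed-convolution chain
  ds <- reluBwd(ds, cache$spre)
  b2 <- convTBwd(ds, cache$ct2$cache, p[["dec.convt2.W"]])
  gradAdd(env, "dec.convt2", list(W = b2$dW, b = b2$db))
  da1 <- reluBwd(b2$dx, cache$a1pre)
  b1 <- convTBwd(da1, cache$ct1$cache, p[["dec.convt1.W"]])
  gradAdd(env, "dec.convt1", list(W = b1$dW, b = b1$db))
  dXF <- b1$dx                                        # [h, w, C, B]

  ## per-item decoder backward
  heads_n <- cfg$decoder$heads; depth <- cfg$decoder$depth
  dtok0 <- numeric(C)
  for (b in seq_len(B)) {
    it <- cache$items[[b]]
    tb <- mlpBwd(matrix(dhv[b, ], 1, C2), it$tm$cache, subParams(p, "dec.tokmlp"))
    gradAdd(env, "dec.tokmlp", tb$grads)
    g5 <- lnBwd(tb$dx, it$l5$cache)
    gradAdd(env, "dec.ln5", list(g = g5$dg, b = g5$db))
    dtf <- g5$dx
    fb <- mhaBwd(dtf, it$fa$cache, subParams(p, "dec.fa"))
    gradAdd(env, "dec.fa", fb$grads)
    dt <- dtf + fb$dxq
    dX <- matrix(dXF[, , , b], P, C) + fb$dxkv
    for (i in rev(seq_len(depth))) {
      bb <- decBlockBwd(dt, dX, it$blocks[[i]], p, sprintf("dec.blk%d", i),
                        heads_n, env)
      dt <- bb$dt; dX <- bb$dX
    }
    dtok0 <- dtok0 + as.vector(dt)
    dz[, , , b] <- dz[, , , b] + array(dX, c(h, h, C))
  }
  gradAdd(env, "dec", list(token = dtok0))

  bbg <- backboneBwd(cfg$backbone$name, subParams(p, "bb"), dz, cache$bb)
  names(bbg) <- paste0("bb.", names(bbg))
  c(env$g, bbg)
}

## single optimization step; returns updated model, state and loss bundle
mtlStep <- function(model, optState, x, targets, lr, weight_decay = 0.01) {
  out <- mtlForward(model, x, withCache = TRUE)
  lb <- mtlLoss(out, targets, model@config$loss$weights, model@config$epsilon)
  grads <- mtlBackward(model, out, targets)
  up <- adamwStep(model@params, grads, optState, lr,
                  weight_decay = weight_decay)
  model@params <- up$params
  list(model = model, state = up$state, loss = lb)
}
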