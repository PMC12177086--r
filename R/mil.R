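## ---------------------------------------------------------------------------
## Stage 2: patient-level multi-instance learning.
##
## Each image contributes a 256-d token: a linear projection of the global
## average pool of its gated lesion feature z_c (stage-1 weights frozen).
## A learnable CLS token is prepended to the patient's variable-size bag and
## a small pre-LN transformer encoder (no positional embeddings -- bag order
## is clinically meaningless) lets the CLS token attend to every valid
## instance. An MLP on the final CLS embedding predicts the patient-level
## ALN probability. Padded slots are excluded from attention, so padded and
## unpadded forwards agree exactly.
## ---------------------------------------------------------------------------

milDefaults <- function() {
  list(tokenDim = 256L, depth = 2L, heads = 4L, mlpHidden = 64L,
       inputChannels = 32L, epsilon = 1e-7)
}

#' Stage-2 multi-instance model
#'
#' @slot params flat named list of parameter arrays.
#' @slot config resolved configuration list.
#' @exportClass MilModel
setClass("MilModel", representation(params = "list", config = "list"))

#' @rdname modelConfig
#' @export
setMethod("modelConfig", "MilModel", function(object) object@config)
#' @rdname modelConfig
#' @export
setMethod("nParameters", "MilModel", function(object)
  sum(vapply(object@params, length, numeric(1))))

setMethod("show", "MilModel", function(object) {
  cat(sprintf("MilModel: d=%d, depth %d, %d heads, %d parameters\n",
              object@config$tokenDim, object@config$depth,
              object@config$heads, nParameters(object)))
})

#' Construct a stage-2 multi-instance model
#'
#' @param config list overriding the defaults (`tokenDim` 256, `depth` 2,
#'   `heads` 4, `mlpHidden` 64, `inputChannels` = stage-1 feature channels).
#' @return a [MilModel-class]. Weights (including the randomly initialized
#'   CLS token) are drawn from the current RNG stream.
#' @export
milModel <- function(config = list()) {
  cfg <- modifyList(milDefaults(), config)
  d <- as.integer(cfg$tokenDim)
  p <- list()
  pr <- flattenParams(list(proj = linearInit(cfg$inputChannels, d,
                                             scale = sqrt(1 / cfg$inputChannels))))
  p <- c(p, pr)
  p[["cls"]] <- rnorm(d, sd = 0.02)
  ## learned view-type embeddings (row 1 tumor, row 2 node) added to tokens;
  ## the acquiring view of each image is known metadata carried by the bag
  p[["typeEmb"]] <- matrix(rnorm(2 * d, sd = 0.1), 2, d)
  for (i in seq_len(cfg$depth)) {
    pre <- sprintf("enc%d", i)
    blk <- flattenParams(list(ln1 = lnInit(d), attn = mhaInit(d),
                              ln2 = lnInit(d), mlp = mlpInit(d, 2L * d, d)))
    names(blk) <- paste0(pre, ".", names(blk))
    p <- c(p, blk)
  }
  fin <- flattenParams(list(lnf = lnInit(d),
                            head = mlpInit(d, cfg$mlpHidden, 1L)))
  p <- c(p, fin)
  new("MilModel", params = p, config = cfg)
}

#' Extract a patient-level image token from the gated lesion feature
#'
#' Global average pooling over the spatial grid of `z_c` followed by a
#' learned linear projection to the token dimension.
#'
#' @param zc gated lesion feature `[h, w, C]` (or `[h, w, C, B]`).
#' @param model a [MilModel-class] (holds the projection).
#' @return a token vector (or `[B, d]` matrix).
#' @export
extractToken <- function(zc, model) {
  if (length(dim(zc)) == 3) zc <- array(zc, c(dim(zc), 1L))
  if (dim(zc)[3] != model@config$inputChannels)
    stopf("channel mismatch: feature has %d channels, projection expects %d",
          dim(zc)[3], model@config$inputChannels)
  g <- gapPool(zc)                                    # [B, C]
  tok <- linearFwd(g, model@params[["proj.W"]], model@params[["proj.b"]])
  if (nrow(tok) == 1L) as.vector(tok) else tok
}

typeIndex <- function(viewTypes) ifelse(viewTypes == "node", 2L, 1L)

## forward over one bag: tokens [n, d] already projected, valid logical [n],
## viewTypes optional character vector ("tumor"/"node") adding type embeddings
milEncode <- function(params, cfg, tokens, valid = NULL, viewTypes = NULL) {
  n <- nrow(tokens)
  if (n == 0L) stopf("empty bag: at least one instance token is required")
  if (!is.null(viewTypes))
    tokens <- tokens + params[["typeEmb"]][typeIndex(viewTypes), , drop = FALSE]
  if (is.null(valid)) valid <- rep(TRUE, n)
  X <- rbind(matrix(params[["cls"]], 1), tokens)
  validX <- c(TRUE, valid)
  caches <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    pre <- sprintf("enc%d", i)
    l1 <- lnFwd(X, params[[paste0(pre, ".ln1.g")]], params[[paste0(pre, ".ln1.b")]])
    at <- mhaFwd(l1$out, l1$out, subParams(params, paste0(pre, ".attn")),
                 cfg$heads, valid = validX)
    X2 <- X + at$out
    l2 <- lnFwd(X2, params[[paste0(pre, ".ln2.g")]], params[[paste0(pre, ".ln2.b")]])
    ml <- mlpFwd(l2$out, subParams(params, paste0(pre, ".mlp")))
    X3 <- X2 + ml$out
    caches[[i]] <- list(l1 = l1, at = at, X2 = X2, l2 = l2, ml = ml)
    X <- X3
  }
  lf <- lnFwd(X[1, , drop = FALSE], params[["lnf.g"]], params[["lnf.b"]])
  hd <- mlpFwd(lf$out, subParams(params, "head"))
  prob <- as.vector(sigmoid(hd$out))
  list(prob = prob, cache = list(blocks = caches, lf = lf, hd = hd,
                                 n = n, validX = validX))
}

milEncodeBwd <- function(params, cfg, dlogit, cache, env) {
  d <- cfg$tokenDim
  hb <- mlpBwd(matrix(dlogit, 1, 1), cache$hd$cache, subParams(params, "head"))
  gradAdd(env, "head", hb$grads)
  gf <- lnBwd(hb$dx, cache$lf$cache)
  gradAdd(env, "lnf", list(g = gf$dg, b = gf$db))
  dX <- matrix(0, cache$n + 1L, d)
  dX[1, ] <- gf$dx
  for (i in rev(seq_len(cfg$depth))) {
    pre <- sprintf("enc%d", i)
    cb <- cache$blocks[[i]]
    mb <- mlpBwd(dX, cb$ml$cache, subParams(params, paste0(pre, ".mlp")))
    gradAdd(env, paste0(pre, ".mlp"), mb$grads)
    g2 <- lnBwd(mb$dx, cb$l2$cache)
    gradAdd(env, paste0(pre, ".ln2"), list(g = g2$dg, b = g2$db))
    dX2 <- dX + g2$dx
    ab <- mhaBwd(dX2, cb$at$cache, subParams(params, paste0(pre, ".attn")))
    gradAdd(env, paste0(pre, ".attn"), ab$grads)
    g1 <- lnBwd(ab$dxq + ab$dxkv, cb$l1$cache)
    gradAdd(env, paste0(pre, ".ln1"), list(g = g1$dg, b = g1$db))
    dX <- dX2 + g1$dx
  }
  gradAdd(env, "", list(cls = as.vector(dX[1, ])))
  dX[-1, , drop = FALSE]                              # gradient into tokens
}

#' Patient-level probability for one bag of image tokens
#'
#' @param bag either a `[n, d]` matrix of already-projected tokens, or a
#'   `[n, C]` matrix of pooled stage-1 features (detected by column count
#'   and projected internally).
#' @param model a [MilModel-class].
#' @param valid optional logical vector flagging real (non-padded) slots;
#'   padded slots are excluded from attention and do not influence the
#'   output.
#' @param viewTypes optional character vector (`"tumor"`/`"node"`) of the
#'   acquiring view per instance; when supplied, a learned view-type
#'   embedding is added to each token before encoding.
#' @return probability in (0, 1).
#' @export
forwardBag <- function(bag, model, valid = NULL, viewTypes = NULL) {
  cfg <- model@config
  if (is.null(dim(bag))) bag <- matrix(bag, 1)
  if (nrow(bag) == 0L) stopf("empty bag: at least one instance is required")
  if (ncol(bag) == cfg$inputChannels && cfg$inputChannels != cfg$tokenDim)
    bag <- linearFwd(bag, model@params[["proj.W"]], model@params[["proj.b"]])
  else if (ncol(bag) != cfg$tokenDim)
    stopf("bag has %d columns; expected token dim %d or feature dim %d",
          ncol(bag), cfg$tokenDim, cfg$inputChannels)
  milEncode(model@params, cfg, bag, valid, viewTypes)$prob
}

#' BCE loss of the multi-instance classifier
#'
#' @param probability predicted patient-level probability (vectorized).
#' @param label 0/1 patient label(s).
#' @param eps clamping constant.
#' @return mean BCE.
#' @export
milLoss <- function(probability, label, eps = 1e-7) {
  stopifnot(all(label %in% c(0, 1)))
  mean(bceLoss(probability, label, eps))
}

## one AdamW step over a batch of bags (list of [n_i, C] pooled features,
## each optionally paired with its view types)
milStep <- function(model, optState, bags, labels, lr, weight_decay = 0.01,
                    viewTypes = NULL) {
  cfg <- model@config
  env <- new.env(); env$g <- list()
  probs <- numeric(length(bags))
  B <- length(bags)
  for (i in seq_len(B)) {
    feats <- bags[[i]]
    vt <- if (is.null(viewTypes)) NULL else viewTypes[[i]]
    toks <- linearFwd(feats, model@params[["proj.W"]], model@params[["proj.b"]])
    fw <- milEncode(model@params, cfg, toks, viewTypes = vt)
    probs[i] <- fw$prob
    pc <- pmin(pmax(fw$prob, cfg$epsilon), 1 - cfg$epsilon)
    dlogit <- (pc - labels[i]) / B
    dtok <- milEncodeBwd(model@params, cfg, dlogit, fw$cache, env)
    if (!is.null(vt)) {
      dEmb <- matrix(0, 2, cfg$tokenDim)
      ti <- typeIndex(vt)
      for (k in seq_along(ti)) dEmb[ti[k], ] <- dEmb[ti[k], ] + dtok[k, ]
      gradAdd(env, "", list(typeEmb = dEmb))
    }
    pb <- linearBwd(dtok, feats, model@params[["proj.W"]])
    gradAdd(env, "proj", list(W = pb$dW, b = pb$db))
  }
  loss <- milLoss(probs, labels, cfg$epsilon)
  up <- adamwStep(model@params, env$g, optState, lr, weight_decay = weight_decay)
  model@params <- up$params
  list(model = model, state = up$state, loss = loss, probs = probs)
}
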