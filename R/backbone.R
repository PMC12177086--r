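## ---------------------------------------------------------------------------
## Backbone contract: a backbone maps a [H, W, 1, B] image batch to a feature
## map z of shape [H/stride, W/stride, C, B] with stride fixed at 16. Two
## tiny reference backbones are provided (a 4-stage convolutional net and a
## patch-embedding attention net); full-scale production architectures can be
## attached through the same registry without changing any downstream code.
## ---------------------------------------------------------------------------

.planCache <- new.env(parent = emptyenv())

getConvPlan <- function(H, W, Cin, k, stride, pad, B) {
  key <- paste(H, W, Cin, k, stride, pad, B, sep = "_")
  if (is.null(.planCache[[key]]))
    .planCache[[key]] <- convPlan(H, W, Cin, k, stride, pad, B)
  .planCache[[key]]
}

BACKBONE_STRIDE <- 16L

#' Initialize backbone parameters
#'
#' @param name `"tinyconv"` (4-stage strided convolutional net) or
#'   `"tinyattn"` (16x16 patch embedding followed by a transformer encoder
#'   block).
#' @param channels output channel count C.
#' @return flat named parameter list.
#' @export
backboneInit <- function(name = c("tinyconv", "tinyattn"), channels = 32L) {
  name <- match.arg(name)
  C <- as.integer(channels)
  if (name == "tinyconv") {
    ch <- c(1L, max(8L, C %/% 4L), max(8L, C %/% 2L), C, C)
    p <- list()
    for (i in 1:4)
      p[[paste0("conv", i)]] <- convInit(ch[i], ch[i + 1], 3L)
    flattenParams(p)
  } else {
    p <- list(embed = convInit(1L, C, 16L),
              ln1 = lnInit(C), attn = mhaInit(C),
              ln2 = lnInit(C), mlp = mlpInit(C, 2L * C, C))
    flattenParams(p)
  }
}

backboneChannels <- function(name, channels) as.integer(channels)

backboneFwd <- function(name, params, x) {
  d <- dim(x); H <- d[1]; W <- d[2]; B <- d[4]
  if (name == "tinyconv") {
    caches <- vector("list", 4)
    cur <- x
    for (i in 1:4) {
      p <- subParams(params, paste0("conv", i))
      plan <- getConvPlan(dim(cur)[1], dim(cur)[2], dim(cur)[3], 3L, 2L, 1L, B)
      cf <- convFwd(cur, p$W, p$b, plan)
      caches[[i]] <- list(cache = cf$cache, pre = cf$out)
      cur <- relu(cf$out)
      caches[[i]]$out <- cur
    }
    list(z = cur, cache = list(x = x, layers = caches))
  } else {
    p_embed <- subParams(params, "embed")
    plan <- getConvPlan(H, W, 1L, 16L, 16L, 0L, B)
    emb <- convFwd(x, p_embed$W, p_embed$b, plan)
    z0 <- emb$out                                   # [h, w, C, B]
    h <- dim(z0)[1]; w <- dim(z0)[2]; C <- dim(z0)[3]
    P <- h * w
    items <- vector("list", B)
    out <- array(0, dim(z0))
    for (b in seq_len(B)) {
      X <- matrix(z0[, , , b], P, C)
      l1 <- lnFwd(X, params[["ln1.g"]], params[["ln1.b"]])
      at <- mhaFwd(l1$out, l1$out, subParams(params, "attn"), heads = 2L)
      X2 <- X + at$out
      l2 <- lnFwd(X2, params[["ln2.g"]], params[["ln2.b"]])
      ml <- mlpFwd(l2$out, subParams(params, "mlp"))
      X3 <- X2 + ml$out
      out[, , , b] <- array(X3, c(h, w, C))
      items[[b]] <- list(X = X, l1 = l1, at = at, X2 = X2, l2 = l2, ml = ml)
    }
    list(z = out, cache = list(embed = emb$cache, items = items,
                               dims = c(h, w, C, B)))
  }
}

backboneBwd <- function(name, params, dz, cache) {
  env <- new.env(); env$g <- list()
  if (name == "tinyconv") {
    cur <- dz
    for (i in 4:1) {
      cl <- cache$layers[[i]]
      cur <- reluBwd(cur, cl$pre)
      p <- subParams(params, paste0("conv", i))
      bk <- convBwd(cur, cl$cache, p$W, needDx = i > 1L)
      gradAdd(env, paste0("conv", i), list(W = bk$dW, b = bk$db))
      cur <- bk$dx
    }
    env$g
  } else {
    dm <- cache$dims; h <- dm[1]; w <- dm[2]; C <- dm[3]; B <- dm[4]
    P <- h * w
    dz0 <- array(0, c(h, w, C, B))
    p_attn <- subParams(params, "attn")
    p_mlp <- subParams(params, "mlp")
    for (b in seq_len(B)) {
      it <- cache$items[[b]]
      dX3 <- matrix(dz[, , , b], P, C)
      mb <- mlpBwd(dX3, it$ml$cache, p_mlp)
      gradAdd(env, "mlp", mb$grads)
      l2b <- lnBwd(mb$dx, it$l2$cache)
      gradAdd(env, "ln2", list(g = l2b$dg, b = l2b$db))
      dX2 <- dX3 + l2b$dx
      ab <- mhaBwd(dX2, it$at$cache, p_attn)
      gradAdd(env, "attn", ab$grads)
      l1b <- lnBwd(ab$dxq + ab$dxkv, it$l1$cache)
      gradAdd(env, "ln1", list(g = l1b$dg, b = l1b$db))
      dX <- dX2 + l1b$dx
      dz0[, , , b] <- array(dX, c(h, w, C))
    }
    p_embed <- subParams(params, "embed")
    eb <- convBwd(dz0, cache$embed, p_embed$W, needDx = FALSE)
    gradAdd(env, "embed", list(W = eb$dW, b = eb$db))
    env$g
  }
}
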