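## ---------------------------------------------------------------------------
## Minimal batched neural-network primitives.
##
## No deep-learning runtime is assumed: every layer is a pure function with an
## explicit, hand-derived backward pass, built on BLAS matrix products.
## Tensors are base-R arrays in [H, W, C, B] layout (column-major, H fastest);
## token sets are [n, d] matrices processed per bag. Parameters live in flat
## named lists of arrays so the optimizer and gradient checks can treat them
## uniformly.
## ---------------------------------------------------------------------------

relu <- function(x) { x[x < 0] <- 0; x }
reluBwd <- function(dy, x) { dy[x <= 0] <- 0; dy }

## ---- dense layer ----------------------------------------------------------

linearInit <- function(din, dout, scale = sqrt(2 / din)) {
  list(W = matrix(rnorm(din * dout, sd = scale), din, dout),
       b = numeric(dout))
}

linearFwd <- function(x, W, b) sweep(x %*% W, 2, b, "+")

linearBwd <- function(dy, x, W) {
  list(dx = dy %*% t(W), dW = t(x) %*% dy, db = colSums(dy))
}

## ---- strided 2-D convolution via precomputed gather (im2col) --------------

## A conv "plan" caches the gather indices for a fixed input geometry so the
## per-step cost is one indexed read plus one GEMM.
convPlan <- function(H, W, Cin, k, stride, pad, B) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  r0 <- rep(seq(1L, by = stride, length.out = Ho), times = Wo)
  c0 <- rep(seq(1L, by = stride, length.out = Wo), each = Ho)
  taps <- expand.grid(dy = 0:(k - 1), dx = 0:(k - 1), cc = 0:(Cin - 1))
  K <- nrow(taps)
  idx <- matrix(0L, Ho * Wo, K)
  for (j in seq_len(K)) {
    idx[, j] <- (r0 + taps$dy[j]) +
      Hp * (c0 + taps$dx[j] - 1L) + Hp * Wp * taps$cc[j]
  }
  per <- Hp * Wp * Cin
  bidx <- idx[rep(seq_len(Ho * Wo), B), , drop = FALSE] +
    rep((0:(B - 1)) * per, each = Ho * Wo)
  bidx <- as.vector(bidx)
  ## inverse gather for the backward scatter-add: for each padded-input cell,
  ## the (fixed, precomputed) set of im2col positions that read it
  nIn <- per * B
  cnt <- tabulate(bidx, nbins = nIn)
  maxUse <- max(cnt)
  o <- order(bidx)
  G <- matrix(length(bidx) + 1L, nIn, maxUse)
  G[cbind(bidx[o], sequence(cnt[cnt > 0]))] <- o
  list(H = H, W = W, Cin = Cin, k = k, stride = stride, pad = pad, B = B,
       Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, K = K,
       bidx = bidx, nrow = Ho * Wo * B, G = G, nIn = nIn, maxUse = maxUse)
}

convInit <- function(Cin, Cout, k) {
  list(W = matrix(rnorm(k * k * Cin * Cout, sd = sqrt(2 / (k * k * Cin))),
                  k * k * Cin, Cout),
       b = numeric(Cout))
}

convFwd <- function(x, W, b, plan) {
  B <- dim(x)[4]
  stopifnot(B == plan$B)
  if (plan$pad > 0) {
    xp <- array(0, c(plan$Hp, plan$Wp, plan$Cin, B))
    xp[plan$pad + seq_len(plan$H), plan$pad + seq_len(plan$W), , ] <- x
  } else xp <- x
  m <- matrix(xp[plan$bidx], plan$nrow, plan$K)
  y <- sweep(m %*% W, 2, b, "+")
  Cout <- ncol(W)
  ya <- aperm(array(y, c(plan$Ho, plan$Wo, B, Cout)), c(1, 2, 4, 3))
  list(out = ya, cache = list(m = m, plan = plan))
}

convBwd <- function(dy, cache, W, needDx = TRUE) {
  plan <- cache$plan
  B <- dim(dy)[4]; Cout <- ncol(W)
  dmat <- matrix(aperm(dy, c(1, 2, 4, 3)), plan$nrow, Cout)
  dW <- t(cache$m) %*% dmat
  db <- colSums(dmat)
  if (!needDx) return(list(dx = NULL, dW = dW, db = db))
  dm <- dmat %*% t(W)
  dmv <- c(as.vector(dm), 0)
  acc <- .rowSums(dmv[plan$G], plan$nIn, plan$maxUse)
  dxp <- array(acc, c(plan$Hp, plan$Wp, plan$Cin, B))
  dx <- if (plan$pad > 0)
    dxp[plan$pad + seq_len(plan$H), plan$pad + seq_len(plan$W), , , drop = FALSE]
  else dxp
  list(dx = dx, dW = dW, db = db)
}

## ---- 2x2 stride-2 transposed convolution (non-overlapping upscale) --------

convTInit <- function(Cin, Cout) {
  list(W = matrix(rnorm(Cin * Cout * 4, sd = sqrt(2 / Cin)), Cin, Cout * 4),
       b = numeric(Cout))
}

convTFwd <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]; B <- d[4]
  Cout <- ncol(W) / 4
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), H * Wd * B, Cin)
  y <- xm %*% W                                  # [HWB, Cout*4]
  ya <- array(y, c(H, Wd, B, Cout, 2, 2))
  out <- array(0, c(2 * H, 2 * Wd, B, Cout))
  ro <- seq(1, 2 * H, 2); co <- seq(1, 2 * Wd, 2)
  for (dy_ in 1:2) for (dx_ in 1:2)
    out[ro + dy_ - 1, co + dx_ - 1, , ] <- ya[, , , , dy_, dx_]
  out <- sweep(out, 4, b, "+")
  list(out = aperm(out, c(1, 2, 4, 3)), cache = list(xm = xm, dims = d))
}

convTBwd <- function(dy, cache, W) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]; Cin <- d[3]; B <- d[4]
  Cout <- ncol(W) / 4
  dyp <- aperm(dy, c(1, 2, 4, 3))                # [2H, 2W, B, Cout]
  db <- colSums(matrix(dyp, ncol = Cout))
  dya <- array(0, c(H, Wd, B, Cout, 2, 2))
  ro <- seq(1, 2 * H, 2); co <- seq(1, 2 * Wd, 2)
  for (dy_ in 1:2) for (dx_ in 1:2)
    dya[, , , , dy_, dx_] <- dyp[ro + dy_ - 1, co + dx_ - 1, , ]
  dmat <- matrix(dya, H * Wd * B, Cout * 4)
  dW <- t(cache$xm) %*% dmat
  dxm <- dmat %*% t(W)
  dx <- aperm(array(dxm, c(H, Wd, B, Cin)), c(1, 2, 4, 3))
  list(dx = dx, dW = dW, db = db)
}

## ---- layer normalization over the feature dimension -----------------------

lnInit <- function(d) list(g = rep(1, d), b = numeric(d))

lnFwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"),
       cache = list(xhat = xhat, inv = inv, g = g))
}

lnBwd <- function(dy, cache) {
  xhat <- cache$xhat; inv <- cache$inv; g <- cache$g
  d <- ncol(xhat)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, "*")
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

## ---- multi-head attention -------------------------------------------------

mhaInit <- function(d, scale = sqrt(1 / d)) {
  list(Wq = matrix(rnorm(d * d, sd = scale), d, d), bq = numeric(d),
       Wk = matrix(rnorm(d * d, sd = scale), d, d), bk = numeric(d),
       Wv = matrix(rnorm(d * d, sd = scale), d, d), bv = numeric(d),
       Wo = matrix(rnorm(d * d, sd = scale), d, d), bo = numeric(d))
}

## xq [nq, d] attends to xkv [nkv, d]; `valid` is a logical key mask.
mhaFwd <- function(xq, xkv, p, heads, valid = NULL) {
  d <- ncol(xq); dh <- d / heads
  Q <- linearFwd(xq, p$Wq, p$bq)
  K <- linearFwd(xkv, p$Wk, p$bk)
  V <- linearFwd(xkv, p$Wv, p$bv)
  nq <- nrow(xq); nk <- nrow(xkv)
  O <- matrix(0, nq, d)
  A_list <- vector("list", heads)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dh)
    if (!is.null(valid)) S[, !valid] <- -1e30
    S <- S - apply(S, 1, max)
    E <- exp(S)
    A <- E / rowSums(E)
    A_list[[h]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  out <- linearFwd(O, p$Wo, p$bo)
  list(out = out,
       cache = list(xq = xq, xkv = xkv, Q = Q, K = K, V = V, O = O,
                    A = A_list, heads = heads, dh = dh))
}

mhaBwd <- function(dy, cache, p) {
  xq <- cache$xq; xkv <- cache$xkv
  heads <- cache$heads; dh <- cache$dh
  lo <- linearBwd(dy, cache$O, p$Wo)
  dO <- lo$dx
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dV[, cols] <- t(A) %*% dOh
    dA <- dOh %*% t(cache$V[, cols, drop = FALSE])
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- (dS %*% cache$K[, cols, drop = FALSE]) / sqrt(dh)
    dK[, cols] <- (t(dS) %*% cache$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  gq <- linearBwd(dQ, xq, p$Wq)
  gk <- linearBwd(dK, xkv, p$Wk)
  gv <- linearBwd(dV, xkv, p$Wv)
  list(dxq = gq$dx, dxkv = gk$dx + gv$dx,
       grads = list(Wq = gq$dW, bq = gq$db, Wk = gk$dW, bk = gk$db,
                    Wv = gv$dW, bv = gv$db, Wo = lo$dW, bo = lo$db))
}

## ---- two-layer MLP --------------------------------------------------------

mlpInit <- function(din, dhid, dout) {
  c(stats::setNames(linearInit(din, dhid), c("W1", "b1")),
    stats::setNames(linearInit(dhid, dout), c("W2", "b2")))
}

mlpFwd <- function(x, p) {
  h1 <- linearFwd(x, p$W1, p$b1)
  a1 <- relu(h1)
  out <- linearFwd(a1, p$W2, p$b2)
  list(out = out, cache = list(x = x, h1 = h1, a1 = a1))
}

mlpBwd <- function(dy, cache, p) {
  l2 <- linearBwd(dy, cache$a1, p$W2)
  da1 <- reluBwd(l2$dx, cache$h1)
  l1 <- linearBwd(da1, cache$x, p$W1)
  list(dx = l1$dx,
       grads = list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db))
}

## ---- flat parameter lists -------------------------------------------------

## Prefixes nested layer parameter lists into a flat named list,
## e.g. flattenParams(list(conv1 = list(W = ..., b = ...))) ->
## list("conv1.W" = ..., "conv1.b" = ...).
flattenParams <- function(nested, prefix = "") {
  out <- list()
  for (nm in names(nested)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    x <- nested[[nm]]
    if (is.list(x)) out <- c(out, flattenParams(x, key))
    else out[[key]] <- x
  }
  out
}

## pull sub-list "prefix.*" out of a flat list, dropping the prefix
subParams <- function(flat, prefix) {
  pre <- paste0(prefix, ".")
  keys <- names(flat)[startsWith(names(flat), pre)]
  stats::setNames(flat[keys], substring(keys, nchar(pre) + 1))
}

## add gradients under a prefix into an accumulator environment
gradAdd <- function(env, prefix, grads) {
  for (nm in names(grads)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.null(env$g[[key]])) env$g[[key]] <- grads[[nm]]
    else env$g[[key]] <- env$g[[key]] + grads[[nm]]
  }
}

zeroLike <- function(params) lapply(params, function(p) p * 0)

## ---- AdamW ----------------------------------------------------------------

adamwInit <- function(params) {
  list(m = zeroLike(params), v = zeroLike(params), t = 0L)
}

adamwStep <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0.01) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] -
      lr * (mhat / (sqrt(vhat) + eps) + weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}
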