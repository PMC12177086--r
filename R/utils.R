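#' @importFrom stats rnorm runif rbinom rgamma sd quantile plogis qlogis
#' @importFrom utils head tail modifyList
NULL

## numerically safe sigmoid / BCE ------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binary cross-entropy with epsilon clamping
#'
#' Elementwise \eqn{-y \log p - (1-y)\log(1-p)} with probabilities clamped to
#' \eqn{[\epsilon, 1-\epsilon]} so the loss stays finite at saturated
#' predictions.
#'
#' @param p predicted probabilities (any numeric array).
#' @param y targets in `[0, 1]`, same shape as `p`.
#' @param eps clamping constant (default `1e-7`).
#' @return elementwise loss, same shape as `p`.
#' @export
bceLoss <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

## gradient of mean BCE wrt the pre-sigmoid logit is (p - y) / n; wrt p it is
## (p - y) / (p (1 - p) n). We mostly backprop through logits directly.
bceGradLogit <- function(p, y) (p - y)

## seeded sub-streams --------------------------------------------------------

## Runs `expr` under a temporary RNG state seeded by `seed`, restoring the
## caller's stream afterwards. Used to derive per-patient counter substreams
## so cohorts are reproducible regardless of generation order.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## counter-derived substream seed, kept inside 32-bit signed range
substreamSeed <- function(master, counter) {
  as.integer((as.numeric(master) * 48271 + as.numeric(counter) * 16807) %%
               2147483629L)
}

## FNV-1a hash of a deparsed object; used for checkpoint/config compatibility
configHash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

## interpolation / pooling operators as matrices -----------------------------

## Row-stochastic bilinear interpolation matrix mapping a length-`from` axis
## to length-`to`, with half-pixel centre alignment (align_corners = FALSE).
bilinearMatrix <- function(to, from) {
  M <- matrix(0, to, from)
  if (from == 1L) { M[, 1] <- 1; return(M) }
  scale <- from / to
  for (i in seq_len(to)) {
    src <- (i - 0.5) * scale - 0.5
    lo <- floor(src)
    w <- src - lo
    lo <- max(0, min(from - 1, lo)); hi <- max(0, min(from - 1, lo + 1))
    M[i, lo + 1] <- M[i, lo + 1] + (1 - w)
    M[i, hi + 1] <- M[i, hi + 1] + w
  }
  M
}

## Nearest-neighbour interpolation matrix with the same half-pixel centre
## alignment as bilinearMatrix.
nearestMatrix <- function(to, from) {
  M <- matrix(0, to, from)
  src <- floor((seq_len(to) - 0.5) * from / to)
  src <- pmin(pmax(src, 0), from - 1)
  M[cbind(seq_len(to), src + 1)] <- 1
  M
}

## Area-average pooling matrix from length `from` to `to` (from = k * to).
poolMatrix <- function(to, from) {
  stopifnot(from %% to == 0)
  k <- from / to
  M <- matrix(0, to, from)
  for (i in seq_len(to)) M[i, ((i - 1) * k + 1):(i * k)] <- 1 / k
  M
}

## apply separable operator M (to x from) to the two leading dims of an
## [H, W, C, B] array (or [H, W, B] when C absent)
sepApply <- function(M, x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; rest <- prod(d[-(1:2)])
  y <- M %*% matrix(x, H, W * rest)              # rows
  Hn <- nrow(M)
  y <- array(y, c(Hn, W, rest))
  y <- aperm(y, c(2, 1, 3))
  y <- M %*% matrix(y, W, Hn * rest)
  y <- array(y, c(nrow(M), Hn, rest))
  y <- aperm(y, c(2, 1, 3))
  array(y, c(Hn, nrow(M), d[-(1:2)]))
}

## global average pool over space: [h, w, C, B] -> [B, C]
gapPool <- function(x) {
  d <- dim(x)
  t(matrix(.colMeans(matrix(x, d[1] * d[2], d[3] * d[4]),
                     d[1] * d[2], d[3] * d[4]), d[3], d[4]))
}

## sum over the channel dimension: [h, w, C, B] -> [h, w, B]
channelSum <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  m <- aperm(array(x, c(hw, d[3], d[4])), c(2, 1, 3))
  array(.colSums(matrix(m, d[3], hw * d[4]), d[3], hw * d[4]),
        c(d[1], d[2], d[4]))
}

## ---------------------------------------------------------------------------

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
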