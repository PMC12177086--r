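# Independent oracles kept deliberately separate from the implementation
# code paths they validate.

# crossing-number point-in-polygon (with on-edge => inside), one point at a
# time; used to brute-force rasterization over all pixel centres
pipOracle <- function(px, py, pts) {
  n <- nrow(pts)
  x1 <- pts[, 1]; y1 <- pts[, 2]
  x2 <- pts[c(2:n, 1), 1]; y2 <- pts[c(2:n, 1), 2]
  # on-segment check
  for (e in seq_len(n)) {
    dx <- x2[e] - x1[e]; dy <- y2[e] - y1[e]
    cross <- (px - x1[e]) * dy - (py - y1[e]) * dx
    if (abs(cross) < 1e-9) {
      if (px >= min(x1[e], x2[e]) - 1e-9 && px <= max(x1[e], x2[e]) + 1e-9 &&
          py >= min(y1[e], y2[e]) - 1e-9 && py <= max(y1[e], y2[e]) + 1e-9)
        return(TRUE)
    }
  }
  inside <- FALSE
  for (e in seq_len(n)) {
    if ((y1[e] <= py) != (y2[e] <= py)) {
      xc <- x1[e] + (py - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
      if (px < xc) inside <- !inside
    }
  }
  inside
}

rasterOracle <- function(pts, size) {
  H <- size[1]; W <- size[2]
  m <- matrix(0L, H, W)
  for (yy in 0:(H - 1)) for (xx in 0:(W - 1))
    if (pipOracle(xx, yy, pts)) m[yy + 1, xx + 1] <- 1L
  m
}

# exhaustive pairwise AUC (ties count one half)
aucOracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# numeric gradient of a scalar function of one model parameter entry
numGrad <- function(lossFn, model, name, j, eps = 1e-5) {
  mp <- model; mp@params[[name]][j] <- mp@params[[name]][j] + eps
  mn <- model; mn@params[[name]][j] <- mn@params[[name]][j] - eps
  (lossFn(mp) - lossFn(mn)) / (2 * eps)
}

# small rendered cohort written to a temp dir, cached per session
cachedToyCohort <- local({
  store <- new.env()
  function(n = 12, seed = 402, imageSize = 64) {
    key <- paste(n, seed, imageSize, sep = "_")
    if (is.null(store[[key]])) {
      coh <- simulateCohort(CohortSpec(nPatients = n, imageSize = imageSize,
                                       seed = seed))
      dir <- file.path(tempdir(), paste0("toycoh_", key))
      mf <- writeCohort(coh, dir, force = TRUE)
      store[[key]] <- list(cohort = coh, dir = dir, manifest = mf)
    }
    store[[key]]
  }
})
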