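## ---------------------------------------------------------------------------
## Class activation mapping for the pool-then-linear classification heads.
##
## Because each head is exactly global-average-pooling followed by a 1x1
## convolution, the CAM is exact: the channelwise weighted sum of the head's
## input feature map, whose spatial mean equals the class logit minus the
## bias. Maps are rectified before per-image min-max normalization (negative
## evidence is not displayed).
## ---------------------------------------------------------------------------

#' Class activation map of a pool-then-linear head
#'
#' @param featureMap the head's input feature map `[h, w, C]` (for the ALN
#'   head this is the gated lesion feature `z_c`).
#' @param weights length-`C` 1x1-convolution weights of the head.
#' @param class `1` (positive class, weights as-is) or `0` (negative class,
#'   negated weights).
#' @param targetSize side of the upsampled output map; `NULL` keeps the
#'   feature resolution.
#' @return a `Heatmap`: list with `map` (normalized to `[0, 1]`), `raw`
#'   (pre-normalization weighted sum at feature resolution), `class`,
#'   `rawRange` (pre-normalization min/max after upsampling and
#'   rectification) and `degenerate` (TRUE for a flat map).
#' @export
computeCam <- function(featureMap, weights, class = 1L, targetSize = NULL) {
  if (!class %in% c(0L, 1L))
    stopf("class index out of range: %s (expected 0 or 1)", class)
  if (length(dim(featureMap)) != 3 || dim(featureMap)[3] != length(weights))
    stopf("feature map [h, w, C] with C = length(weights) required")
  w <- if (class == 1L) as.numeric(weights) else -as.numeric(weights)
  h <- dim(featureMap)[1]
  raw <- matrix(matrix(featureMap, h * dim(featureMap)[2]) %*% w,
                h, dim(featureMap)[2])
  up <- if (is.null(targetSize)) raw
        else sepApply(bilinearMatrix(targetSize, h), raw)
  rect <- pmax(up, 0)
  rng <- range(rect)
  degenerate <- (rng[2] - rng[1]) < .Machine$double.eps
  map <- if (degenerate) rect * 0
         else (rect - rng[1]) / (rng[2] - rng[1])
  structure(list(map = map, raw = raw, class = class, rawRange = rng,
                 degenerate = degenerate), class = "Heatmap")
}

#' @export
print.Heatmap <- function(x, ...) {
  cat(sprintf("Heatmap (%dx%d, class %d)%s\n", nrow(x$map), ncol(x$map),
              x$class, if (x$degenerate) " [degenerate: flat]" else ""))
  invisible(x)
}

#' CAM of the image-level ALN head for one image
#'
#' Runs the stage-1 forward pass and applies [computeCam] to the gated
#' lesion feature with the ALN head's weights.
#'
#' @param model trained [MtlModel-class].
#' @param image matrix at the model's input size.
#' @param class 1 = positive ALN evidence (default).
#' @return a `Heatmap` at input-image resolution, plus the image-level
#'   probability as attribute `"probability"`.
#' @export
camForImage <- function(model, image, class = 1L) {
  out <- mtlForward(model, image)
  hm <- computeCam(array(out$zc[, , , 1], dim(out$zc)[1:3]),
                   as.vector(model@params[["head.cls.W"]]), class = class,
                   targetSize = nrow(image))
  attr(hm, "probability") <- out$yCls[1]
  hm
}

#' Fraction of heatmap mass inside the lesion
#'
#' `sum(heatmap * mask) / sum(heatmap)`; quantifies whether the model's
#' evidence concentrates in the annotated lesion rather than background.
#' Undefined (returned as `NA`) for an all-zero heatmap.
#'
#' @param heatmap a `Heatmap` or a nonnegative matrix.
#' @param mask binary ground-truth mask of identical shape.
#' @return fraction in `[0, 1]`, or `NA`.
#' @export
lesionMassFraction <- function(heatmap, mask) {
  hm <- if (inherits(heatmap, "Heatmap")) heatmap$map else heatmap
  if (!all(dim(hm) == dim(mask))) stopf("heatmap and mask shapes differ")
  tot <- sum(hm)
  if (tot <= 0) return(NA_real_)
  sum(hm * (mask > 0.5)) / tot
}

## simple blue->red colormap for overlays
jetColor <- function(v) {
  r <- clamp01(1.5 - abs(4 * v - 3))
  g <- clamp01(1.5 - abs(4 * v - 2))
  b <- clamp01(1.5 - abs(4 * v - 1))
  list(r = r, g = g, b = b)
}

#' Write a heatmap overlay PNG
#'
#' Blends the grayscale image with the colorized heatmap.
#'
#' @param image grayscale matrix in `[0, 1]`.
#' @param heatmap a `Heatmap` (or matrix in `[0, 1]`) of identical shape.
#' @param path output PNG path.
#' @param alpha heatmap opacity.
#' @return `path`, invisibly.
#' @export
camOverlay <- function(image, heatmap, path, alpha = 0.45) {
  hm <- if (inherits(heatmap, "Heatmap")) heatmap$map else heatmap
  stopifnot(all(dim(hm) == dim(image)))
  cols <- jetColor(hm)
  blend <- function(ch) (1 - alpha) * image + alpha * ch
  rgb <- array(0, c(ncol(image), nrow(image), 3))
  rgb[, , 1] <- t(blend(cols$r))
  rgb[, , 2] <- t(blend(cols$g))
  rgb[, , 3] <- t(blend(cols$b))
  EBImage::writeImage(EBImage::Image(clamp01(rgb), colormode = "Color"),
                      path, type = "png", bits.per.sample = 8L)
  invisible(path)
}
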