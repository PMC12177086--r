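## ---------------------------------------------------------------------------
## Annotation and manifest I/O, polygon rasterization, preprocessing.
##
## Pixel convention: 0-based coordinates, x to the right, y down; a pixel
## (x, y) is foreground iff its centre lies inside or on the polygon by the
## even-odd rule. This matches the LabelMe annotation dialect.
## ---------------------------------------------------------------------------

#' Read a LabelMe-dialect polygon annotation
#'
#' Supported keys: `version`, `imagePath`, `imageHeight`, `imageWidth`,
#' `shapes` with exactly one polygon shape carrying `label` and `points`.
#'
#' @param path JSON file path.
#' @return a `PolygonAnnotation` (list with `label`, `points`, `imageSize`).
#' @export
readAnnotation <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  for (key in c("imageHeight", "imageWidth", "shapes"))
    if (is.null(obj[[key]]))
      stopf("annotation format error: missing field '%s' in %s", key, path)
  sh <- obj$shapes
  if (is.data.frame(sh)) sh <- split(sh, seq_len(nrow(sh)))
  if (length(sh) != 1)
    stopf("annotation format error: expected exactly one shape, found %d",
          length(sh))
  s <- sh[[1]]
  st <- if (is.data.frame(s)) s$shape_type[[1]] else s$shape_type
  if (is.null(st) || !identical(as.character(st), "polygon"))
    stopf("annotation format error: unsupported shape_type '%s'",
          as.character(st %||% "<missing>"))
  lab <- if (is.data.frame(s)) s$label[[1]] else s$label
  pts <- if (is.data.frame(s)) s$points[[1]] else s$points
  pts <- matrix(as.numeric(as.matrix(pts)), ncol = 2,
                dimnames = list(NULL, c("x", "y")))
  if (nrow(pts) < 3)
    stopf("annotation format error: field 'points' needs >= 3 vertices")
  if (any(!is.finite(pts)))
    stopf("annotation format error: non-finite coordinates in 'points'")
  structure(list(label = as.character(lab), points = pts,
                 imageSize = c(obj$imageHeight, obj$imageWidth)),
            class = "PolygonAnnotation")
}

#' Write a LabelMe-dialect polygon annotation
#'
#' @param poly a `PolygonAnnotation`.
#' @param path output JSON path.
#' @param imagePath value stored under the `imagePath` key.
#' @return `path`, invisibly.
#' @export
writeAnnotation <- function(poly, path, imagePath = "") {
  obj <- list(
    version = "5.0.1",
    imagePath = imagePath,
    imageHeight = poly$imageSize[1],
    imageWidth = poly$imageSize[2],
    shapes = list(list(
      label = poly$label,
      points = lapply(seq_len(nrow(poly$points)),
                      function(i) as.numeric(poly$points[i, ])),
      shape_type = "polygon")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rasterize a polygon to a binary mask
#'
#' Scanline even-odd fill on pixel centres: a pixel is foreground iff its
#' centre lies inside or on the polygon. Pixels outside the frame are
#' clipped; a degenerate (zero-area) polygon yields an empty mask with a
#' warning.
#'
#' @param poly a `PolygonAnnotation`, or an n x 2 matrix of (x, y) vertices.
#' @param size `(height, width)`; defaults to the annotation's `imageSize`.
#' @return binary matrix of dimension `size` (rows = y).
#' @export
rasterizePolygon <- function(poly, size = NULL) {
  if (inherits(poly, "PolygonAnnotation")) {
    pts <- poly$points
    if (is.null(size)) size <- poly$imageSize
  } else pts <- poly
  if (is.null(size)) stopf("mask size required when passing raw vertices")
  H <- as.integer(size[1]); W <- as.integer(size[2])
  mask <- matrix(0L, H, W)
  n <- nrow(pts)
  if (n < 3) { warning("degenerate polygon: fewer than 3 vertices"); return(mask) }
  x1 <- pts[, 1]; y1 <- pts[, 2]
  x2 <- pts[c(2:n, 1), 1]; y2 <- pts[c(2:n, 1), 2]
  area2 <- abs(sum(x1 * y2 - x2 * y1))
  if (area2 < 1e-9) {
    warning("degenerate polygon: zero area")
    return(mask)
  }
  eps <- 1e-9
  crossings <- vector("list", H)
  for (e in seq_len(n)) {
    if (y1[e] == y2[e]) next
    ylo <- min(y1[e], y2[e]); yhi <- max(y1[e], y2[e])
    rows <- seq.int(max(0L, ceiling(ylo - eps)), min(H - 1L, floor(yhi)))
    rows <- rows[rows >= ylo - eps & rows < yhi - eps]   # half-open [ylo, yhi)
    if (!length(rows)) next
    xc <- x1[e] + (rows - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
    for (i in seq_along(rows)) {
      r <- rows[i] + 1L
      crossings[[r]] <- c(crossings[[r]], xc[i])
    }
  }
  for (r in seq_len(H)) {
    xs <- crossings[[r]]
    if (is.null(xs) || length(xs) < 2) next
    xs <- sort(xs)
    for (j in seq(1, length(xs) - 1, by = 2)) {
      lo <- max(0L, ceiling(xs[j] - eps))
      hi <- min(W - 1L, floor(xs[j + 1] + eps))
      if (lo <= hi) mask[r, (lo:hi) + 1L] <- 1L
    }
  }
  ## pixels whose centre lies exactly on an edge count as foreground
  for (e in seq_len(n)) {
    if (y1[e] == y2[e]) {
      yy <- y1[e]
      if (abs(yy - round(yy)) < eps && round(yy) >= 0 && round(yy) <= H - 1) {
        lo <- max(0L, ceiling(min(x1[e], x2[e]) - eps))
        hi <- min(W - 1L, floor(max(x1[e], x2[e]) + eps))
        if (lo <= hi) mask[round(yy) + 1L, (lo:hi) + 1L] <- 1L
      }
    } else {
      ylo <- min(y1[e], y2[e]); yhi <- max(y1[e], y2[e])
      rows <- seq.int(max(0L, ceiling(ylo - eps)), min(H - 1L, floor(yhi + eps)))
      if (!length(rows)) next
      xc <- x1[e] + (rows - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
      hit <- abs(xc - round(xc)) < 1e-7 & round(xc) >= 0 & round(xc) <= W - 1
      if (any(hit))
        mask[cbind(rows[hit] + 1L, round(xc[hit]) + 1L)] <- 1L
    }
  }
  mask
}

## ---------------------------------------------------------------------------
## Manifests and splits
## ---------------------------------------------------------------------------

manifestColumns <- c("patient_id", "admission_index", "image_path",
                     "annotation_path", "view_type", "aln_status", "split")

#' Read / write a cohort manifest (tab-separated)
#'
#' @param path TSV path.
#' @return `readManifest`: the manifest data.frame.
#' @export
readManifest <- function(path) {
  mf <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifestColumns, names(mf))
  if (length(missing))
    stopf("manifest format error: missing column(s) %s",
          paste(missing, collapse = ", "))
  mf
}

#' @rdname readManifest
#' @param manifest a manifest data.frame.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assign chronological train / internal-test splits
#'
#' Patients are sorted by `admission_index`; the first
#' `floor(ratio * n_patients)` go to `train`, the rest to `internal_test`.
#' The split is per patient, so no patient straddles the two splits.
#'
#' @param records manifest data.frame with `patient_id` and
#'   `admission_index` columns.
#' @param ratio train fraction in `[0, 1]`.
#' @return the records with the `split` column filled.
#' @export
splitByAdmission <- function(records, ratio = 0.8) {
  adm <- unique(records[, c("patient_id", "admission_index")])
  if (anyDuplicated(adm$patient_id) || anyDuplicated(adm$admission_index))
    stopf("admission_index must be unique per patient")
  adm <- adm[order(adm$admission_index), ]
  nTrain <- floor(ratio * nrow(adm))
  trainIds <- adm$patient_id[seq_len(nTrain)]
  records$split <- ifelse(records$patient_id %in% trainIds,
                          "train", "internal_test")
  records
}

## ---------------------------------------------------------------------------
## Preprocessing / augmentation
## ---------------------------------------------------------------------------

## Separable resize with explicit half-pixel centre alignment: output pixel
## centre (i + 0.5) maps to input coordinate (i + 0.5) * from/to - 0.5.
## Bilinear for images, nearest neighbour for masks. Interpolation matrices
## are cached per geometry.
.resizeCache <- new.env(parent = emptyenv())

resizeGrid <- function(m, h, w, filter = c("bilinear", "none")) {
  filter <- match.arg(filter)
  mk <- function(to, from) {
    key <- paste(filter, to, from)
    if (is.null(.resizeCache[[key]]))
      .resizeCache[[key]] <- if (filter == "bilinear") bilinearMatrix(to, from)
                             else nearestMatrix(to, from)
    .resizeCache[[key]]
  }
  mk(h, nrow(m)) %*% m %*% t(mk(w, ncol(m)))
}

#' Preprocess an image/mask pair
#'
#' Eval mode deterministically resizes to `targetSize`. Train mode applies
#' the standard online augmentation: the resize scale is jittered uniformly in
#' `[0.8, 1.25]`, followed by a fixed-size random crop (zero-padded when the
#' scaled image is smaller than the target) and a horizontal flip with
#' probability `flipProb`. The identical geometric transform is applied to
#' image (bilinear) and mask (nearest neighbour).
#'
#' @param image numeric matrix (rows = y).
#' @param mask binary matrix of identical shape.
#' @param mode `"train"` or `"eval"`.
#' @param targetSize output side in pixels.
#' @param scaleRange scale-jitter interval for train mode.
#' @param flipProb horizontal flip probability in train mode.
#' @return list with transformed `image` and `mask`, both
#'   `targetSize x targetSize`. Train mode consumes the current RNG stream.
#' @export
preprocessView <- function(image, mask, mode = c("eval", "train"),
                           targetSize = 96L, scaleRange = c(0.8, 1.25),
                           flipProb = 0.5) {
  mode <- match.arg(mode)
  stopifnot(all(dim(image) == dim(mask)))
  t <- as.integer(targetSize)
  if (mode == "eval") {
    return(list(image = resizeGrid(image, t, t, "bilinear"),
                mask = 1L * (resizeGrid(mask, t, t, "none") > 0.5)))
  }
  sc <- runif(1, scaleRange[1], scaleRange[2])
  s <- max(8L, as.integer(round(t * sc)))
  img <- resizeGrid(image, s, s, "bilinear")
  msk <- 1L * (resizeGrid(mask, s, s, "none") > 0.5)
  if (s >= t) {
    oy <- sample.int(s - t + 1L, 1L) - 1L
    ox <- sample.int(s - t + 1L, 1L) - 1L
    img <- img[(oy + 1):(oy + t), (ox + 1):(ox + t)]
    msk <- msk[(oy + 1):(oy + t), (ox + 1):(ox + t)]
  } else {
    canvasI <- matrix(0, t, t); canvasM <- matrix(0L, t, t)
    oy <- sample.int(t - s + 1L, 1L) - 1L
    ox <- sample.int(t - s + 1L, 1L) - 1L
    canvasI[(oy + 1):(oy + s), (ox + 1):(ox + s)] <- img
    canvasM[(oy + 1):(oy + s), (ox + 1):(ox + s)] <- msk
    img <- canvasI; msk <- canvasM
  }
  if (runif(1) < flipProb) {
    img <- img[, ncol(img):1]
    msk <- msk[, ncol(msk):1]
  }
  list(image = img, mask = msk)
}

#' Load every view referenced by a manifest into memory
#'
#' Reads each image PNG and rasterizes its polygon annotation.
#'
#' @param manifest manifest data.frame (or a split subset of one).
#' @param root cohort root directory.
#' @return list of views: `image`, `mask`, `viewType`, `patientId`,
#'   `alnStatus`, `split`.
#' @export
loadCohortViews <- function(manifest, root) {
  lapply(seq_len(nrow(manifest)), function(i) {
    ip <- file.path(root, manifest$image_path[i])
    ap <- file.path(root, manifest$annotation_path[i])
    if (!file.exists(ip)) stopf("manifest refers to missing image '%s'", ip)
    img <- t(EBImage::imageData(EBImage::readImage(ip)))
    ann <- readAnnotation(ap)
    list(image = img, mask = rasterizePolygon(ann),
         viewType = manifest$view_type[i],
         patientId = manifest$patient_id[i],
         alnStatus = manifest$aln_status[i], split = manifest$split[i])
  })
}
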