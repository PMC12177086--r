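## ---------------------------------------------------------------------------
## Synthetic speckle-phantom cohort generator.
##
## Emulates the statistical structure the two-stage framework assumes: each
## patient contributes a bag of M >= 1 primary-tumor views and N >= 0
## lymph-node views, one hypoechoic lesion per view on a speckled background,
## with node features (hilum loss, roundness, border irregularity) and a weak
## tumor-view signal tied to a latent metastasis score.
## ---------------------------------------------------------------------------

## boundary radius of the (possibly perturbed) lesion at angles theta
lesionRadius <- function(lesion, theta) {
  a <- lesion@semiAxes[1]; b <- lesion@semiAxes[2]
  psi <- theta - lesion@rotation
  base <- a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
  base * (1 + lesion@irregularity * sin(lesion@lobes * theta + lesion@phase))
}

#' Analytic boundary polygon of a lesion
#'
#' Samples the perturbed-ellipse boundary at `n` angles.
#'
#' @param lesion a [LesionSpec-class].
#' @param n number of vertices.
#' @return `n x 2` matrix of 0-based (x, y) vertices.
#' @export
lesionPolygon <- function(lesion, n = 180L) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- lesionRadius(lesion, theta)
  cbind(x = lesion@center[1] + r * cos(theta),
        y = lesion@center[2] + r * sin(theta))
}

## binary mask of the hilum region: the lesion ellipse scaled by `scale`
hilumMask <- function(lesion, size, scale = 0.4) {
  inner <- LesionSpec("node", lesion@center, lesion@semiAxes * scale,
                      rotation = lesion@rotation)
  rasterizePolygon(lesionPolygon(inner), c(size, size))
}

#' Render one phantom view
#'
#' Draws a multiplicative gamma speckle field (unit mean, dispersion
#' `speckleScale`), smooths it with a Gaussian kernel, multiplies by the
#' constant background profile, darkens the lesion interior by
#' `lesionContrast`, brightens the hilum disc (node views with a preserved
#' hilum) by `hilumContrast` relative to background, and clips to `[0, 1]`.
#'
#' @param lesion a [LesionSpec-class]; must lie fully inside the frame.
#' @param noise a [NoiseParams-class].
#' @param size square image side in pixels.
#' @return list with `image` (matrix in `[0,1]`, rows = y), `mask` (binary
#'   matrix of the rasterized perturbed ellipse) and `hilum` (binary matrix,
#'   or NULL when absent). Consumes the current RNG stream.
#' @export
renderView <- function(lesion, noise, size) {
  stopifnot(is(lesion, "LesionSpec"), is(noise, "NoiseParams"))
  maxr <- max(lesionRadius(lesion, seq(0, 2 * pi, length.out = 256)))
  cx <- lesion@center[1]; cy <- lesion@center[2]
  if (cx - maxr < 0 || cy - maxr < 0 || cx + maxr > size - 1 ||
      cy + maxr > size - 1)
    stopf("geometry error: lesion leaves the %dx%d frame", size, size)

  shape <- if (noise@speckleScale > 0) 1 / noise@speckleScale^2 else Inf
  speckle <- if (is.finite(shape))
    matrix(rgamma(size * size, shape = shape, scale = 1 / shape), size, size)
  else matrix(1, size, size)
  if (noise@smoothingRadius > 0)
    speckle <- EBImage::gblur(speckle, sigma = noise@smoothingRadius)

  mask <- rasterizePolygon(lesionPolygon(lesion), c(size, size))
  hil <- NULL
  mult <- 1 - noise@lesionContrast * mask
  if (lesion@lesionType == "node" && lesion@hilumPresent) {
    hil <- hilumMask(lesion, size)
    mult <- mult + noise@hilumContrast * hil
  }
  img <- clamp01(speckle * noise@backgroundMean * mult)
  list(image = img, mask = mask, hilum = hil)
}

## draw a lesion spec for one view; positive status shifts the parameters
drawLesion <- function(viewType, status, effect, size) {
  S <- size
  if (viewType == "tumor") {
    a <- runif(1, 0.13, 0.19) * S * (1 + 0.5 * effect@tumorSignalShift * status)
    ratio <- runif(1, 0.45, 0.75)
    irr <- runif(1, 0.04, 0.10) + effect@tumorSignalShift * status * 0.6
    hil <- FALSE
  } else {
    a <- runif(1, 0.11, 0.17) * S
    ratio <- min(0.95, runif(1, 0.45, 0.65) + effect@roundnessShift * status)
    irr <- runif(1, 0.02, 0.07) + effect@irregularityShift * status
    hil <- runif(1) < (0.95 - effect@hilumLossGap * status)
  }
  b <- max(3, a * ratio)
  a <- max(a, b)
  rot <- runif(1, 0, pi)
  lobes <- sample(3:7, 1)
  phase <- runif(1, 0, 2 * pi)
  maxr <- a * (1 + irr) + 2
  if (2 * maxr > S - 6) { a <- a * (S - 6) / (2 * maxr); b <- max(2, a * ratio) }
  maxr <- a * (1 + irr) + 2
  cx <- runif(1, maxr + 1, S - 2 - maxr)
  cy <- runif(1, maxr + 1, S - 2 - maxr)
  LesionSpec(viewType, c(cx, cy), c(a, b), rotation = rot,
             irregularity = irr, lobes = lobes, phase = phase,
             hilumPresent = hil)
}

simulateOnePatient <- function(i, spec, render) {
  eff <- spec@effect
  thr <- if (is.na(eff@labelThreshold)) 1 - spec@prevalence
         else eff@labelThreshold
  withSeed(substreamSeed(spec@seed, i), {
    score <- runif(1)
    status <- as.integer(score > thr)
    nTumor <- sample(spec@tumorViewsRange[1]:spec@tumorViewsRange[2], 1)
    pvis <- if (status == 1) spec@pNodeVisiblePos else spec@pNodeVisibleNeg
    visible <- runif(1) < pvis
    nNode <- if (visible)
      sample(max(1L, spec@nodeViewsRange[1]):max(1L, spec@nodeViewsRange[2]), 1)
    else 0L
    types <- c(rep("tumor", nTumor), rep("node", nNode))
    views <- if (render) lapply(types, function(vt) {
      lesion <- drawLesion(vt, status, eff, spec@imageSize)
      rv <- renderView(lesion, spec@noise, spec@imageSize)
      list(image = rv$image, mask = rv$mask, hilum = rv$hilum,
           lesion = lesion, viewType = vt)
    }) else lapply(types, function(vt) list(viewType = vt))
    new("PhantomPatient", patientId = sprintf("P%05d", i),
        admissionIndex = i, alnStatus = status, metastaticScore = score,
        views = views)
  })
}

#' Simulate a phantom cohort
#'
#' Draws `nPatients` patients with Bernoulli(`prevalence`) ALN labels (via a
#' latent uniform metastasis score thresholded at `1 - prevalence`), assigns
#' view counts and node visibility, and renders every view. Each patient uses
#' a counter-derived RNG substream, so the same spec and seed reproduce the
#' cohort byte-for-byte regardless of generation order.
#'
#' @param spec a [CohortSpec-class].
#' @param render if `FALSE`, draw labels and view types but skip image
#'   rendering (cheap label-level simulations).
#' @return a [PhantomCohort-class].
#' @examples
#' coh <- simulateCohort(CohortSpec(nPatients = 3, seed = 1))
#' alnStatus(coh)
#' @export
simulateCohort <- function(spec, render = TRUE) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  validObject(spec@effect)
  validObject(spec@noise)
  pts <- lapply(seq_len(spec@nPatients), simulateOnePatient,
                spec = spec, render = render)
  new("PhantomCohort", patients = pts, spec = spec)
}

#' Trace the boundary of a single-component binary mask as a polygon
#'
#' Extracts the 0.5-level contour of the mask (crack boundary, lying half a
#' pixel outside the foreground pixel centres), so that re-rasterizing the
#' polygon with the pixel-centre even-odd rule recovers the mask almost
#' exactly (IoU >= 0.95 by contract, typically 1.0).
#'
#' @param mask binary matrix (rows = y).
#' @return a `PolygonAnnotation` list with fields `label`, `points`
#'   (n x 2 matrix of 0-based x/y vertices) and `imageSize` `(height, width)`.
#' @param label lesion-type label stored in the annotation.
#' @export
polygonizeMask <- function(mask, label = "lesion") {
  if (sum(mask) == 0) stopf("cannot polygonize an empty mask")
  comp <- EBImage::bwlabel(mask)
  if (max(comp) > 1L)
    stopf("mask has %d connected components; expected exactly one", max(comp))
  H <- nrow(mask); W <- ncol(mask)
  padded <- matrix(0, H + 2, W + 2)
  padded[2:(H + 1), 2:(W + 1)] <- mask
  ## contourLines wants z[i, j] at (x[i], y[j]); our mask is [y, x]
  cl <- grDevices::contourLines(x = seq(-1, W) , y = seq(-1, H),
                                z = t(padded), levels = 0.5)
  if (length(cl) == 0) stopf("cannot polygonize an empty mask")
  lens <- vapply(cl, function(c_) length(c_$x), numeric(1))
  ring <- cl[[which.max(lens)]]
  pts <- cbind(x = ring$x, y = ring$y)
  if (all(pts[1, ] == pts[nrow(pts), ])) pts <- pts[-nrow(pts), , drop = FALSE]
  structure(list(label = label, points = pts, imageSize = c(H, W)),
            class = "PolygonAnnotation")
}

#' @export
print.PolygonAnnotation <- function(x, ...) {
  cat(sprintf("PolygonAnnotation '%s': %d vertices in a %dx%d frame\n",
              x$label, nrow(x$points), x$imageSize[1], x$imageSize[2]))
  invisible(x)
}

## ---------------------------------------------------------------------------
## On-disk cohort layout: PNG images + LabelMe-dialect JSON + TSV manifest
## ---------------------------------------------------------------------------

#' Build the manifest table of a cohort
#'
#' One row per view with columns `patient_id`, `admission_index`,
#' `image_path`, `annotation_path`, `view_type`, `aln_status` and `split`
#' (assigned chronologically by [splitByAdmission]).
#'
#' @param cohort a [PhantomCohort-class].
#' @param ratio train fraction for the admission-ordered split.
#' @return a data.frame manifest.
#' @export
cohortManifest <- function(cohort, ratio = 0.8) {
  rows <- list()
  for (p in cohort@patients) {
    for (j in seq_along(p@views)) {
      v <- p@views[[j]]
      stem <- sprintf("%s_v%02d_%s", p@patientId, j, v$viewType)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p@patientId, admission_index = p@admissionIndex,
        image_path = file.path("images", paste0(stem, ".png")),
        annotation_path = file.path("annotations", paste0(stem, ".json")),
        view_type = v$viewType, aln_status = p@alnStatus,
        split = NA_character_, stringsAsFactors = FALSE)
    }
  }
  mf <- do.call(rbind, rows)
  splitByAdmission(mf, ratio)
}

#' Write a rendered cohort to disk
#'
#' Writes 8-bit grayscale PNGs, LabelMe-dialect JSON annotations (polygons
#' traced from the ground-truth masks) and a tab-separated manifest.
#'
#' @param cohort a rendered [PhantomCohort-class].
#' @param dir output directory (created if needed).
#' @param ratio train fraction passed to [cohortManifest].
#' @param force overwrite a non-empty directory.
#' @return the manifest, invisibly.
#' @export
writeCohort <- function(cohort, dir, ratio = 0.8, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force)
    stopf("output directory '%s' is not empty (use force = TRUE)", dir)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), recursive = TRUE,
             showWarnings = FALSE)
  mf <- cohortManifest(cohort, ratio)
  k <- 1L
  for (p in cohort@patients) {
    for (v in p@views) {
      img_path <- file.path(dir, mf$image_path[k])
      ann_path <- file.path(dir, mf$annotation_path[k])
      EBImage::writeImage(EBImage::Image(t(v$image)), img_path,
                          type = "png", bits.per.sample = 8L)
      poly <- polygonizeMask(v$mask, label = v$viewType)
      writeAnnotation(poly, ann_path, imagePath = basename(img_path))
      k <- k + 1L
    }
  }
  writeManifest(mf, file.path(dir, "manifest.tsv"))
  invisible(mf)
}
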