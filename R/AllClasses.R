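#' @import methods
NULL

## ---------------------------------------------------------------------------
## Central S4 data objects
## ---------------------------------------------------------------------------

#' Noise model for the speckle phantom renderer
#'
#' Parameters of the multiplicative-speckle image model: a constant
#' background intensity profile is multiplied by a gamma-distributed speckle
#' field (unit mean, dispersion `speckleScale`) smoothed with a Gaussian
#' kernel, then modulated inside the lesion and hilum regions and clipped to
#' `[0, 1]`.
#'
#' @slot backgroundMean mean background intensity in `[0, 1]`.
#' @slot speckleScale standard deviation of the multiplicative speckle field
#'   before smoothing (gamma with unit mean).
#' @slot smoothingRadius Gaussian smoothing sigma in pixels (0 disables).
#' @slot lesionContrast fractional intensity drop inside the lesion; 0 makes
#'   the lesion indistinguishable from background in expectation.
#' @slot hilumContrast fractional intensity rise (relative to background) in
#'   the fatty-hilum disc of a lymph-node view.
#' @exportClass NoiseParams
setClass("NoiseParams",
  representation(backgroundMean = "numeric", speckleScale = "numeric",
                 smoothingRadius = "numeric", lesionContrast = "numeric",
                 hilumContrast = "numeric"),
  validity = function(object) {
    for (f in c("backgroundMean", "speckleScale", "smoothingRadius",
                "lesionContrast", "hilumContrast")) {
      v <- slot(object, f)
      if (length(v) != 1 || !is.finite(v) || v < 0)
        return(sprintf("field '%s' must be a single nonnegative number", f))
    }
    if (object@backgroundMean > 1) return("field 'backgroundMean' must be <= 1")
    if (object@lesionContrast > 1) return("field 'lesionContrast' must be <= 1")
    TRUE
  })

#' @rdname NoiseParams-class
#' @param backgroundMean,speckleScale,smoothingRadius,lesionContrast,hilumContrast
#'   see slot documentation.
#' @return a validated `NoiseParams` object.
#' @export
NoiseParams <- function(backgroundMean = 0.5, speckleScale = 0.3,
                        smoothingRadius = 1.2, lesionContrast = 0.55,
                        hilumContrast = 0.35) {
  new("NoiseParams", backgroundMean = backgroundMean,
      speckleScale = speckleScale, smoothingRadius = smoothingRadius,
      lesionContrast = lesionContrast, hilumContrast = hilumContrast)
}

#' Effect sizes tying phantom image features to the latent metastasis status
#'
#' Encodes the sonographic signs of nodal metastasis as parameter shifts
#' applied to views of ALN-positive patients: loss of the fatty hilum,
#' rounder node shape, more irregular borders, and a weaker size/irregularity
#' signal in the primary-tumor views. Setting every shift to 0 renders the
#' images statistically independent of the patient label.
#'
#' @slot hilumLossGap drop in hilum-presence probability for positive nodes
#'   (baseline presence probability is 0.95).
#' @slot roundnessShift increase of the node axis ratio b/a for positives.
#' @slot irregularityShift added radial-perturbation amplitude for positive
#'   lesions.
#' @slot tumorSignalShift size/irregularity shift of primary-tumor lesions of
#'   positive patients (the weak tumor-view correlate).
#' @slot labelThreshold cutoff on the latent metastasis score; `NA` means
#'   "derive from the cohort prevalence" (threshold `1 - prevalence` on a
#'   uniform latent score).
#' @exportClass EffectParams
setClass("EffectParams",
  representation(hilumLossGap = "numeric", roundnessShift = "numeric",
                 irregularityShift = "numeric", tumorSignalShift = "numeric",
                 labelThreshold = "numeric"),
  validity = function(object) {
    for (f in c("hilumLossGap", "roundnessShift", "irregularityShift",
                "tumorSignalShift")) {
      v <- slot(object, f)
      if (length(v) != 1 || !is.finite(v) || v < 0)
        return(sprintf("field '%s' must be a single nonnegative shift", f))
    }
    if (object@hilumLossGap > 0.95)
      return("field 'hilumLossGap' must be <= 0.95 (baseline presence 0.95)")
    TRUE
  })

#' @rdname EffectParams-class
#' @param hilumLossGap,roundnessShift,irregularityShift,tumorSignalShift,labelThreshold
#'   see slot documentation.
#' @return a validated `EffectParams` object.
#' @export
EffectParams <- function(hilumLossGap = 0.9, roundnessShift = 0.3,
                         irregularityShift = 0.12, tumorSignalShift = 0.15,
                         labelThreshold = NA_real_) {
  new("EffectParams", hilumLossGap = hilumLossGap,
      roundnessShift = roundnessShift, irregularityShift = irregularityShift,
      tumorSignalShift = tumorSignalShift, labelThreshold = labelThreshold)
}

#' Null-effect parameters
#'
#' Convenience constructor with every status-linked shift set to zero, so
#' rendered views are statistically independent of the patient label.
#' @return an `EffectParams` object with all shifts 0.
#' @export
nullEffect <- function() EffectParams(hilumLossGap = 0, roundnessShift = 0,
                                      irregularityShift = 0,
                                      tumorSignalShift = 0)

#' Specification of a synthetic phantom cohort
#'
#' Describes one reproducible cohort draw: the number of patients, the ALN
#' metastasis prevalence, per-patient view-count ranges, the probability that
#' a node view is visible given the status, and the effect/noise models.
#' The same spec and seed always regenerate a byte-identical cohort.
#'
#' @slot nPatients number of patients.
#' @slot prevalence probability of ALN-positive status.
#' @slot imageSize square image side in pixels.
#' @slot tumorViewsRange integer range (min >= 1) of tumor views per patient.
#' @slot nodeViewsRange integer range (min >= 0) of node views when the node
#'   is visible.
#' @slot pNodeVisiblePos,pNodeVisibleNeg probability that at least one node
#'   view exists given positive / negative status.
#' @slot effect an [EffectParams-class] object.
#' @slot noise a [NoiseParams-class] object.
#' @slot seed master RNG seed; per-patient substreams are derived by counter.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nPatients = "integer", prevalence = "numeric",
                 imageSize = "integer", tumorViewsRange = "integer",
                 nodeViewsRange = "integer", pNodeVisiblePos = "numeric",
                 pNodeVisibleNeg = "numeric", effect = "EffectParams",
                 noise = "NoiseParams", seed = "integer"),
  validity = function(object) {
    if (object@nPatients < 1L) return("field 'nPatients' must be >= 1")
    if (object@prevalence < 0 || object@prevalence > 1)
      return("field 'prevalence' must lie in [0, 1]")
    if (object@imageSize < 32L) return("field 'imageSize' must be >= 32")
    if (length(object@tumorViewsRange) != 2 || object@tumorViewsRange[1] < 1L ||
        diff(object@tumorViewsRange) < 0)
      return("field 'tumorViewsRange' must be an interval with min >= 1")
    if (length(object@nodeViewsRange) != 2 || object@nodeViewsRange[1] < 0L ||
        diff(object@nodeViewsRange) < 0)
      return("field 'nodeViewsRange' must be an interval with min >= 0")
    for (f in c("pNodeVisiblePos", "pNodeVisibleNeg")) {
      v <- slot(object, f)
      if (v < 0 || v > 1)
        return(sprintf("field '%s' must lie in [0, 1]", f))
    }
    TRUE
  })

#' @rdname CohortSpec-class
#' @param nPatients,prevalence,imageSize,tumorViewsRange,nodeViewsRange see
#'   slot documentation.
#' @param pNodeVisiblePos,pNodeVisibleNeg node-view visibility probabilities.
#' @param effect,noise effect and noise parameter objects.
#' @param seed master seed.
#' @return a validated `CohortSpec` object.
#' @export
CohortSpec <- function(nPatients = 100, prevalence = 0.642, imageSize = 96,
                       tumorViewsRange = c(1, 3), nodeViewsRange = c(1, 2),
                       pNodeVisiblePos = 0.9, pNodeVisibleNeg = 0.6,
                       effect = EffectParams(), noise = NoiseParams(),
                       seed = 1L) {
  new("CohortSpec", nPatients = as.integer(nPatients),
      prevalence = as.numeric(prevalence), imageSize = as.integer(imageSize),
      tumorViewsRange = as.integer(tumorViewsRange),
      nodeViewsRange = as.integer(nodeViewsRange),
      pNodeVisiblePos = pNodeVisiblePos, pNodeVisibleNeg = pNodeVisibleNeg,
      effect = effect, noise = noise, seed = as.integer(seed))
}

#' One lesion to be rendered into a view
#'
#' An ellipse with semi-axes `a >= b`, rotated by `rotation`, whose boundary
#' radius is perturbed as \eqn{r(\theta) = r_0(\theta)\,(1 + \iota
#' \sin(k\theta + \phi))} with amplitude `irregularity` and integer lobe
#' count `k` in 3..7.
#'
#' @slot lesionType `"tumor"` or `"node"`.
#' @slot center (x, y) centre in 0-based pixel coordinates.
#' @slot semiAxes (a, b) semi-axes in pixels, `a >= b > 0`.
#' @slot rotation radians.
#' @slot irregularity radial perturbation amplitude.
#' @slot lobes integer perturbation frequency k.
#' @slot phase perturbation phase.
#' @slot hilumPresent logical; nodes only.
#' @exportClass LesionSpec
setClass("LesionSpec",
  representation(lesionType = "character", center = "numeric",
                 semiAxes = "numeric", rotation = "numeric",
                 irregularity = "numeric", lobes = "integer",
                 phase = "numeric", hilumPresent = "logical"),
  validity = function(object) {
    if (!object@lesionType %in% c("tumor", "node"))
      return("lesionType must be 'tumor' or 'node'")
    if (object@semiAxes[1] < object@semiAxes[2] || object@semiAxes[2] <= 0)
      return("semiAxes must satisfy a >= b > 0")
    TRUE
  })

#' @rdname LesionSpec-class
#' @param lesionType,center,semiAxes,rotation,irregularity,lobes,phase,hilumPresent
#'   see slot documentation.
#' @return a validated `LesionSpec` object.
#' @export
LesionSpec <- function(lesionType, center, semiAxes, rotation = 0,
                       irregularity = 0, lobes = 4L, phase = 0,
                       hilumPresent = FALSE) {
  new("LesionSpec", lesionType = lesionType, center = as.numeric(center),
      semiAxes = as.numeric(semiAxes), rotation = rotation,
      irregularity = irregularity, lobes = as.integer(lobes), phase = phase,
      hilumPresent = hilumPresent)
}

#' A synthetic patient: label, latent score and bag of rendered views
#'
#' @slot patientId identifier.
#' @slot admissionIndex integer ordering used for chronological splits.
#' @slot alnStatus 0/1 patient-level ALN label; equals
#'   `metastaticScore > labelThreshold` by construction.
#' @slot metastaticScore latent uniform metastasis score.
#' @slot views list of views; each view is a list with elements `image`
#'   (matrix, rows = y), `mask` (binary matrix), `hilum` (binary matrix or
#'   NULL), `lesion` (a [LesionSpec-class]) and `viewType`.
#' @exportClass PhantomPatient
setClass("PhantomPatient",
  representation(patientId = "character", admissionIndex = "integer",
                 alnStatus = "integer", metastaticScore = "numeric",
                 views = "list"))

#' A simulated cohort of phantom patients
#'
#' @slot patients list of [PhantomPatient-class] objects.
#' @slot spec the generating [CohortSpec-class].
#' @exportClass PhantomCohort
setClass("PhantomCohort",
  representation(patients = "list", spec = "CohortSpec"))

## ---- accessors ------------------------------------------------------------

#' @describeIn PhantomCohort-class list of patients.
#' @param object a `PhantomCohort`.
#' @export
setGeneric("patients", function(object) standardGeneric("patients"))
#' @rdname PhantomCohort-class
#' @export
setMethod("patients", "PhantomCohort", function(object) object@patients)

#' @describeIn PhantomCohort-class per-patient 0/1 ALN labels.
#' @export
setGeneric("alnStatus", function(object) standardGeneric("alnStatus"))
#' @rdname PhantomCohort-class
#' @export
setMethod("alnStatus", "PhantomCohort", function(object)
  vapply(object@patients, function(p) p@alnStatus, integer(1)))

#' @describeIn PhantomCohort-class the generating specification.
#' @export
setGeneric("cohortSpec", function(object) standardGeneric("cohortSpec"))
#' @rdname PhantomCohort-class
#' @export
setMethod("cohortSpec", "PhantomCohort", function(object) object@spec)

setMethod("show", "PhantomCohort", function(object) {
  st <- alnStatus(object)
  nv <- vapply(object@patients, function(p) length(p@views), integer(1))
  cat(sprintf(
    "PhantomCohort: %d patients (%.1f%% ALN-positive), %d views, %dx%d px\n",
    length(object@patients), 100 * mean(st), sum(nv),
    object@spec@imageSize, object@spec@imageSize))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: n=%d, prevalence=%.3f, image %dx%d, seed=%d\n",
    object@nPatients, object@prevalence, object@imageSize, object@imageSize,
    object@seed))
})

#' Model accessors
#'
#' `modelConfig` returns the resolved configuration list of a model object;
#' `nParameters` its total parameter count.
#'
#' @param object a model object (`MtlModel` or `MilModel`).
#' @return `modelConfig`: a list; `nParameters`: an integer-valued numeric.
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' @rdname modelConfig
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))

setMethod("show", "PhantomPatient", function(object) {
  vt <- vapply(object@views, function(v) v$viewType, character(1))
  cat(sprintf("PhantomPatient %s: ALN=%d, %d tumor + %d node view(s)\n",
              object@patientId, object@alnStatus,
              sum(vt == "tumor"), sum(vt == "node")))
})
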