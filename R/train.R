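## ---------------------------------------------------------------------------
## Config-driven, seeded training and inference for both stages.
##
## The "paper" profile carries the full clinical-scale reference
## hyperparameters (512x512 inputs,
## AdamW at 6e-5, 16 images per MTL step for 10k iterations, 4 patients per
## MIL step for 100 epochs, 256-d tokens). The "desk" profile is a
## first-class scaled-down configuration for CPU-only runs: <= 128 px
## images, <= 2000 iterations and ~10^5 parameters, with a learning rate
## suited to the tiny models. The optimizer has no learning-rate schedule
## (none is specified); a hook is available via `lrSchedule`.
## ---------------------------------------------------------------------------

#' Build a training configuration
#'
#' @param stage `"mtl"` (image-level multi-task stage) or `"mil"`
#'   (patient-level multi-instance stage).
#' @param profile `"paper"` (full clinical-scale hyperparameters) or `"desk"`
#'   (CPU-scale).
#' @param ... overrides of individual fields.
#' @return a list with class `"trainConfig"`: fields `stage`, `profile`,
#'   `optimizer`, `learning_rate`, `weight_decay`, `mtl_batch_images`,
#'   `mtl_iterations`, `mil_patients_per_step`, `mil_epochs`, `image_size`,
#'   `seed`, `augment` (online MTL augmentation; disable for memorization
#'   or debugging runs), `model` (architecture overrides), `view_filter`,
#'   `lrSchedule`.
#' @export
trainConfig <- function(stage = c("mtl", "mil"), profile = c("paper", "desk"),
                        ...) {
  stage <- match.arg(stage)
  profile <- match.arg(profile)
  cfg <- list(stage = stage, profile = profile, optimizer = "adamw",
              learning_rate = 6e-5, weight_decay = 0.01,
              mtl_batch_images = 16L, mtl_iterations = 10000L,
              mil_patients_per_step = 4L, mil_epochs = 100L,
              image_size = 512L, seed = 1L, augment = TRUE,
              model = list(), view_filter = "all", lrSchedule = NULL)
  if (profile == "desk") {
    cfg$image_size <- 96L
    cfg$mtl_iterations <- 1200L
    cfg$mtl_batch_images <- 8L
    cfg$mil_epochs <- 20L
    cfg$learning_rate <- if (stage == "mtl") 3e-3 else 1e-3
    cfg$model <- list(backbone = list(name = "tinyconv", channels = 32L),
                      decoder = list(depth = 2L, heads = 2L, segChannels = 8L),
                      tokenDim = 64L, depth = 2L, heads = 4L, mlpHidden = 32L)
  }
  ov <- list(...)
  if (length(ov)) cfg <- modifyList(cfg, ov)
  if (cfg$profile == "desk") {
    if (cfg$image_size > 128L)
      stopf("desk profile caps image_size at 128 (got %d)", cfg$image_size)
    if (cfg$mtl_iterations > 2000L)
      stopf("desk profile caps mtl_iterations at 2000 (got %d)",
            cfg$mtl_iterations)
  }
  structure(cfg, class = "trainConfig")
}

#' @export
print.trainConfig <- function(x, ...) {
  cat(sprintf("trainConfig [%s, %s]: lr=%g, image %d px, seed %d\n",
              x$stage, x$profile, x$learning_rate, x$image_size, x$seed))
  invisible(x)
}

## checkpoints are runtime artifacts (lists with a config hash)
saveCheckpoint <- function(model, path, extra = list()) {
  obj <- c(list(class = class(model), params = model@params,
                config = model@config, hash = configHash(model@config)),
           extra)
  saveRDS(obj, path)
  invisible(path)
}

loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  model <- new(obj$class, params = obj$params, config = obj$config)
  attr(model, "extra") <- obj[setdiff(names(obj),
                                      c("class", "params", "config"))]
  obj$model <- model
  obj
}

## assemble one MTL batch from in-memory views
mtlBatch <- function(views, idx, size, augment = TRUE) {
  B <- length(idx)
  x <- array(0, c(size, size, 1L, B))
  ySeg <- array(0, c(size, size, B))
  yMcls <- numeric(B); yCls <- numeric(B)
  for (j in seq_along(idx)) {
    v <- views[[idx[j]]]
    pp <- preprocessView(v$image, v$mask,
                         mode = if (augment) "train" else "eval",
                         targetSize = size)
    x[, , 1L, j] <- pp$image
    ySeg[, , j] <- pp$mask
    yMcls[j] <- as.numeric(v$viewType == "node")
    yCls[j] <- makePseudoLabels(v$alnStatus, list(1))  # broadcast patient label
  }
  list(x = x, targets = list(ySeg = ySeg, yMcls = yMcls, yCls = yCls))
}

## frozen stage-1 pass over views -> pooled z_c features [n, C]
stage1Features <- function(model, views, batch = 16L) {
  size <- model@config$imageSize
  n <- length(views)
  C <- model@config$backbone$channels
  feats <- matrix(0, n, C)
  segProbs <- vector("list", n)
  imgProbs <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(n, i + batch - 1L)
    idx <- i:j
    real <- length(idx)
    pad <- c(idx, rep(idx[1], batch - real))          # fixed-size batch
    bt <- mtlBatch(views, pad, size, augment = FALSE)
    out <- mtlForward(model, bt$x)
    gc <- gapPool(out$zc)                             # [batch, C]
    feats[idx, ] <- gc[seq_len(real), , drop = FALSE]
    for (k in seq_len(real)) segProbs[[idx[k]]] <- out$ySegHat[, , k]
    imgProbs[idx] <- out$yCls[seq_len(real)]
    i <- j + 1L
  }
  list(features = feats, segProbs = segProbs, imgProbs = imgProbs)
}

## group per-view features into per-patient bags
buildBags <- function(views, features, viewFilter = "all") {
  keep <- if (viewFilter == "tumor")
    vapply(views, function(v) v$viewType == "tumor", logical(1))
  else rep(TRUE, length(views))
  ids <- vapply(views, function(v) v$patientId, character(1))
  labs <- vapply(views, function(v) as.numeric(v$alnStatus), numeric(1))
  vts <- vapply(views, function(v) v$viewType, character(1))
  out <- list()
  for (pid in unique(ids)) {
    sel <- which(ids == pid & keep)
    if (!length(sel)) sel <- which(ids == pid)[1]     # never drop a patient
    out[[pid]] <- list(features = features[sel, , drop = FALSE],
                       viewTypes = vts[sel],
                       label = labs[ids == pid][1])
  }
  out
}

#' Train one stage of the framework
#'
#' Runs the seeded optimization loop for the requested stage over the
#' `train` split of the manifest: stage `mtl` draws augmented image batches
#' and optimizes the joint segmentation / lesion-type / image-level loss;
#' stage `mil` freezes the stage-1 model, extracts one pooled lesion-feature
#' token per image, and optimizes the bag-level transformer. All randomness
#' (weight init, batch order, augmentation) derives from `config$seed`, so
#' identical configs reproduce identical loss trajectories.
#'
#' @param config a [trainConfig].
#' @param manifest cohort manifest data.frame.
#' @param root cohort root directory.
#' @param stage1 for stage `"mil"`: the trained [MtlModel-class] (or a
#'   checkpoint path).
#' @param verbose print progress.
#' @param features optional precomputed stage-1 feature matrix for the train
#'   views (as returned by [extractFeatures]); avoids re-running the frozen
#'   stage-1 pass when several MIL variants share one stage-1 model.
#' @param views optional preloaded train-split view list (as produced
#'   internally from the manifest); avoids re-reading the cohort from disk.
#' @return list with `model`, `metrics` (per-step loss log) and, for MIL,
#'   the `stage1Hash` recorded for checkpoint compatibility.
#' @export
trainStage <- function(config, manifest, root, stage1 = NULL, verbose = FALSE,
                       features = NULL, views = NULL) {
  stopifnot(inherits(config, "trainConfig"))
  if (is.null(views))
    views <- loadCohortViews(manifest[manifest$split == "train", , drop = FALSE],
                             root)
  set.seed(config$seed)
  lrOf <- function(step, base) {
    if (is.null(config$lrSchedule)) base else config$lrSchedule(step, base)
  }
  if (config$stage == "mtl") {
    mcfg <- modifyList(list(imageSize = config$image_size), config$model)
    mcfg$tokenDim <- NULL; mcfg$depth <- NULL
    mcfg$heads <- NULL; mcfg$mlpHidden <- NULL
    model <- mtlModel(mcfg)
    state <- adamwInit(model@params)
    log <- vector("list", config$mtl_iterations)
    for (it in seq_len(config$mtl_iterations)) {
      idx <- sample.int(length(views), config$mtl_batch_images,
                        replace = length(views) < config$mtl_batch_images)
      bt <- mtlBatch(views, idx, config$image_size, augment = config$augment)
      st <- mtlStep(model, state, bt$x, bt$targets,
                    lr = lrOf(it, config$learning_rate),
                    weight_decay = config$weight_decay)
      model <- st$model; state <- st$state
      log[[it]] <- data.frame(step = it, l_seg = st$loss$l_seg,
                              l_mcls = st$loss$l_mcls, l_cls = st$loss$l_cls,
                              total = st$loss$total)
      if (verbose && it %% 50 == 0)
        message(sprintf("mtl step %d: total %.4f (seg %.4f mcls %.4f cls %.4f)",
                        it, st$loss$total, st$loss$l_seg, st$loss$l_mcls,
                        st$loss$l_cls))
    }
    return(list(model = model, metrics = do.call(rbind, log)))
  }
  ## ---- MIL stage -----------------------------------------------------------
  if (is.null(stage1))
    stopf("stage 'mil' requires the trained stage-1 model (stage1 argument)")
  if (is.character(stage1)) stage1 <- loadCheckpoint(stage1)$model
  featMat <- if (is.null(features)) stage1Features(stage1, views)$features
             else features
  bags <- buildBags(views, featMat, config$view_filter)
  milCfg <- config$model
  milCfg <- milCfg[names(milCfg) %in%
                     c("tokenDim", "depth", "heads", "mlpHidden")]
  milCfg$inputChannels <- stage1@config$backbone$channels
  model <- milModel(milCfg)
  state <- adamwInit(model@params)
  ids <- names(bags)
  perStep <- config$mil_patients_per_step
  log <- list()
  step <- 0L
  for (ep in seq_len(config$mil_epochs)) {
    ord <- sample(ids)
    i <- 1L
    while (i <= length(ord)) {
      sel <- ord[i:min(length(ord), i + perStep - 1L)]
      st <- milStep(model, state,
                    lapply(bags[sel], `[[`, "features"),
                    vapply(bags[sel], `[[`, numeric(1), "label"),
                    lr = lrOf(step + 1L, config$learning_rate),
                    weight_decay = config$weight_decay,
                    viewTypes = lapply(bags[sel], `[[`, "viewTypes"))
      model <- st$model; state <- st$state
      step <- step + 1L
      log[[step]] <- data.frame(step = step, epoch = ep, loss = st$loss)
      i <- i + perStep
    }
    if (verbose && ep %% 10 == 0)
      message(sprintf("mil epoch %d: loss %.4f", ep, st$loss))
  }
  list(model = model, metrics = do.call(rbind, log),
       stage1Hash = configHash(stage1@config))
}

#' Frozen stage-1 features for a manifest subset
#'
#' Runs the frozen stage-1 model over the views of the given split and
#' returns the pooled lesion-feature matrix used for MIL tokens.
#'
#' @param stage1 trained [MtlModel-class].
#' @param manifest,root cohort manifest and root directory.
#' @param split split name (`NULL` = all rows).
#' @param views optional preloaded view list (skips the manifest read).
#' @return list with `views`, `features` (`[n, C]` pooled lesion features),
#'   `segProbs` (per-view segmentation probability maps) and `imgProbs`
#'   (per-view image-level metastasis probabilities).
#' @export
extractFeatures <- function(stage1, manifest = NULL, root = NULL,
                            split = "train", views = NULL) {
  if (is.null(views)) {
    mf <- if (is.null(split)) manifest
          else manifest[manifest$split == split, , drop = FALSE]
    views <- loadCohortViews(mf, root)
  }
  sf <- stage1Features(stage1, views)
  list(views = views, features = sf$features, segProbs = sf$segProbs,
       imgProbs = sf$imgProbs)
}

#' Segmentation and image-level metrics from extracted features
#'
#' @param featureCache result of [extractFeatures] for the split of interest.
#' @param imageSize the stage-1 input size used for ground-truth resizing.
#' @return list with foreground `miou` and image-level `auc`.
#' @export
stage1MetricsFromFeatures <- function(featureCache, imageSize) {
  gts <- lapply(featureCache$views, function(v)
    preprocessView(v$image, v$mask, "eval", imageSize)$mask)
  labs <- vapply(featureCache$views, function(v) as.numeric(v$alnStatus),
                 numeric(1))
  list(miou = meanIoU(featureCache$segProbs, gts),
       auc = rocAuc(featureCache$imgProbs, labs))
}

#' Patient-level predictions from a trained two-stage model
#'
#' Extracts frozen stage-1 tokens for every view in the manifest, groups
#' them into per-patient bags, and applies the MIL transformer. Patients
#' without node views are predicted from their tumor views alone. Inference
#' is deterministic.
#'
#' @param stage1 trained [MtlModel-class] (or checkpoint path).
#' @param mil trained [MilModel-class] (or checkpoint path).
#' @param manifest cohort manifest.
#' @param root cohort root directory.
#' @param splits which splits to score (default: all present).
#' @param stage1Hash optional hash recorded at MIL training time; a mismatch
#'   with `stage1`'s config is an error (incompatible checkpoints).
#' @param viewFilter `"all"` or `"tumor"` (single-view ablation).
#' @param featureCache optional precomputed `list(views, features)` from
#'   [extractFeatures] for the requested splits.
#' @return data.frame with `patient_id`, `probability`, `label`, `split`.
#' @export
predictPatients <- function(stage1, mil, manifest, root, splits = NULL,
                            stage1Hash = NULL, viewFilter = "all",
                            featureCache = NULL) {
  if (is.character(stage1)) stage1 <- loadCheckpoint(stage1)$model
  if (is.character(mil)) {
    ck <- loadCheckpoint(mil)
    mil <- ck$model
    if (is.null(stage1Hash)) stage1Hash <- attr(mil, "extra")$stage1Hash
  }
  if (!is.null(stage1Hash) && !identical(stage1Hash, configHash(stage1@config)))
    stopf("incompatible checkpoints: MIL model was trained on a different stage-1 configuration")
  if (is.null(splits)) splits <- unique(manifest$split)
  if (is.null(featureCache)) {
    mf <- manifest[manifest$split %in% splits, , drop = FALSE]
    views <- loadCohortViews(mf, root)
    featMat <- stage1Features(stage1, views)$features
  } else {
    views <- featureCache$views
    featMat <- featureCache$features
  }
  bags <- buildBags(views, featMat, viewFilter)
  ids <- vapply(views, function(v) v$patientId, character(1))
  rows <- lapply(names(bags), function(pid) {
    i <- which(ids == pid)[1]
    data.frame(patient_id = pid,
               probability = forwardBag(bags[[pid]]$features, mil,
                                        viewTypes = bags[[pid]]$viewTypes),
               label = bags[[pid]]$label,
               split = views[[i]]$split, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Segmentation quality of a stage-1 model on a manifest split
#'
#' @param stage1 trained [MtlModel-class].
#' @param manifest,root cohort manifest and root.
#' @param split which split to evaluate.
#' @return list with `miou` (foreground mean IoU at 0.5) and image-level
#'   classification `auc`.
#' @export
evaluateStage1 <- function(stage1, manifest, root, split = "internal_test") {
  mf <- manifest[manifest$split == split, , drop = FALSE]
  views <- loadCohortViews(mf, root)
  feats <- stage1Features(stage1, views)
  size <- stage1@config$imageSize
  gts <- lapply(views, function(v)
    preprocessView(v$image, v$mask, "eval", size)$mask)
  labs <- vapply(views, function(v) as.numeric(v$alnStatus), numeric(1))
  list(miou = meanIoU(feats$segProbs, gts),
       auc = rocAuc(feats$imgProbs, labs))
}
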