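## ---------------------------------------------------------------------------
## Diagnostic-accuracy statistics: rank-based AUC, paired DeLong tests,
## threshold metrics, precision-recall, decision curve analysis, mean IoU,
## chi-square cohort comparisons and the clinical logistic baseline.
## ---------------------------------------------------------------------------

checkScores <- function(scores, labels) {
  if (length(scores) != length(labels))
    stopf("scores and labels must have equal length")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  if (length(unique(labels)) < 2)
    stopf("both classes must be present")
  invisible(TRUE)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator: the probability that a random
#' positive scores above a random negative, with ties counting one half.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 outcomes.
#' @return AUC in `[0, 1]`.
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  checkScores(scores, labels)
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## ROC curve points over all thresholds (for plotting / reports)
rocCurve <- function(scores, labels) {
  checkScores(scores, labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- t(vapply(th, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & labels == 0) / sum(labels == 0),
      tpr = sum(pred & labels == 1) / sum(labels == 1))
  }, numeric(2)))
  data.frame(threshold = th, fpr = pts[, 1], tpr = pts[, 2])
}

#' Confusion-matrix summary at a probability threshold
#'
#' Cases with `score >= threshold` are called positive. Derived rates
#' satisfy the identities `mistake_rate = 1 - specificity` (false positive
#' rate) and `omission_rate = 1 - sensitivity` (false negative rate);
#' `F1 = 2 PPV sens / (PPV + sens)`.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 outcomes.
#' @param threshold operating point in (0, 1); 0.5 by default.
#' @return list with counts `TP`, `FP`, `TN`, `FN` and fractions
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`, `f1`,
#'   `mistake_rate`, `omission_rate`.
#' @export
confusionAt <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    stopf("scores and labels must have equal length")
  pred <- scores >= threshold
  TP <- sum(pred & labels == 1); FP <- sum(pred & labels == 0)
  TN <- sum(!pred & labels == 0); FN <- sum(!pred & labels == 1)
  sens <- TP / (TP + FN); spec <- TN / (TN + FP)
  ppv <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  npv <- if (TN + FN > 0) TN / (TN + FN) else NA_real_
  f1 <- if (!is.na(ppv) && (ppv + sens) > 0) 2 * ppv * sens / (ppv + sens)
        else NA_real_
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       accuracy = (TP + TN) / length(labels),
       sensitivity = sens, specificity = spec, ppv = ppv, npv = npv, f1 = f1,
       mistake_rate = 1 - spec, omission_rate = 1 - sens)
}

## structural components of the AUC (one value per case)
delongComponents <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean(psi(pos, y)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired DeLong test for two correlated AUCs
#'
#' DeLong's structural-components estimator of the variance of the AUC
#' difference for two models scored on the same cases, with
#' `z = dAUC / SE` referred to the standard normal. When the two score
#' vectors are identical the difference is exactly 0 and `p = 1`.
#'
#' @param scoresA,scoresB predictions of the two models on the same cases.
#' @param labels shared 0/1 outcomes.
#' @return list with `aucA`, `aucB`, `varA`, `varB`, `covAB`, `z` and the
#'   two-sided `p`.
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  if (length(scoresA) != length(scoresB))
    stopf("paired test requires score vectors on the same cases")
  checkScores(scoresA, labels)
  ca <- delongComponents(scoresA, labels)
  cb <- delongComponents(scoresB, labels)
  m <- length(ca$v10); n <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / m + s01 / n
  varDiff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  dAuc <- ca$auc - cb$auc
  if (varDiff <= .Machine$double.eps) {
    z <- if (abs(dAuc) < .Machine$double.eps^0.5) 0 else sign(dAuc) * Inf
  } else z <- dAuc / sqrt(varDiff)
  list(aucA = ca$auc, aucB = cb$auc,
       varA = S[1, 1], varB = S[2, 2], covAB = S[1, 2],
       z = z, p = if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z)))
}

#' Variance and confidence interval of a single AUC (DeLong)
#'
#' @param scores,labels as in [rocAuc].
#' @param level confidence level.
#' @return list with `auc`, `var`, `lower`, `upper`.
#' @export
delongCI <- function(scores, labels, level = 0.95) {
  checkScores(scores, labels)
  cc <- delongComponents(scores, labels)
  v <- stats::var(cc$v10) / length(cc$v10) + stats::var(cc$v01) / length(cc$v01)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = cc$auc, var = v,
       lower = max(0, cc$auc - zq * sqrt(v)),
       upper = min(1, cc$auc + zq * sqrt(v)))
}

#' Precision-recall curve and average precision
#'
#' A stepwise curve over all observed score thresholds; average precision is
#' the step integral \eqn{\sum_i (R_i - R_{i-1}) P_i}.
#'
#' @param scores,labels as in [rocAuc] (positives must be present).
#' @return list with `points` (threshold, recall, precision) and `ap`.
#' @export
prCurve <- function(scores, labels) {
  if (sum(labels == 1) == 0) stopf("positives must be present")
  th <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(th, function(t) {
    pred <- scores >= t
    TP <- sum(pred & labels == 1)
    c(recall = TP / sum(labels == 1),
      precision = if (sum(pred) > 0) TP / sum(pred) else 1)
  }, numeric(2)))
  rec <- pts[, 1]; prec <- pts[, 2]
  ap <- sum(diff(c(0, rec)) * prec)
  list(points = data.frame(threshold = th, recall = rec, precision = prec),
       ap = ap)
}

#' Decision curve analysis
#'
#' Net benefit of treating according to `score >= pt` at each threshold
#' probability `pt`: `NB = TP/n - (FP/n) pt/(1-pt)`, compared with treating
#' everyone and treating no one. The treat-all curve crosses zero exactly at
#' `pt = prevalence`.
#'
#' @param scores,labels as in [rocAuc].
#' @param thresholds grid of threshold probabilities, strictly inside (0,1).
#' @return data.frame with columns `threshold`, `nb_model`, `nb_all`,
#'   `nb_none`.
#' @export
dca <- function(scores, labels, thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stopf("thresholds must lie strictly inside (0, 1)")
  n <- length(labels)
  prev <- mean(labels == 1)
  out <- t(vapply(thresholds, function(pt) {
    pred <- scores >= pt
    TP <- sum(pred & labels == 1); FP <- sum(pred & labels == 0)
    w <- pt / (1 - pt)
    c(nb_model = TP / n - (FP / n) * w,
      nb_all = prev - (1 - prev) * w)
  }, numeric(2)))
  data.frame(threshold = thresholds, nb_model = out[, 1], nb_all = out[, 2],
             nb_none = 0)
}

#' Mean intersection-over-union of predicted masks
#'
#' Per-image foreground IoU at the given probability threshold, averaged
#' over images; a pair with empty union counts as IoU 1. With
#' `classes = "both"` the background IoU is averaged in as well
#' (two-class mIoU).
#'
#' @param pred list of predicted probability maps (or binary masks).
#' @param gt list of ground-truth binary masks, matched to `pred`.
#' @param threshold probability cutoff.
#' @param classes `"foreground"` (default) or `"both"`.
#' @return mean IoU in `[0, 1]`.
#' @export
meanIoU <- function(pred, gt, threshold = 0.5, classes = c("foreground", "both")) {
  classes <- match.arg(classes)
  if (length(pred) != length(gt)) stopf("pred and gt must be matched lists")
  ious <- vapply(seq_along(pred), function(i) {
    p <- pred[[i]] >= threshold; g <- gt[[i]] > 0.5
    if (!all(dim(p) == dim(g))) stopf("mask shape mismatch at pair %d", i)
    fg <- if (sum(p | g) == 0) 1 else sum(p & g) / sum(p | g)
    if (classes == "foreground") return(fg)
    bg <- if (sum(!p | !g) == 0) 1 else sum(!p & !g) / sum(!p | !g)
    (fg + bg) / 2
  }, numeric(1))
  mean(ious)
}

#' Pearson chi-square test on a contingency table
#'
#' `sum((O - E)^2 / E)` with `df = (r-1)(c-1)` and an upper-tail p-value;
#' no continuity correction by default (a Yates-corrected variant is
#' available by flag for 2x2 tables).
#'
#' @param table matrix of nonnegative integer counts.
#' @param correct apply the Yates continuity correction (2x2 only).
#' @return list with `statistic`, `df`, `p`.
#' @export
chiSquareTest <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("contingency table has an all-zero row or column")
  res <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Fit the clinical logistic baseline (BI-RADS + clinical T stage)
#'
#' Maximum-likelihood logistic regression of the ALN label on one-hot coded
#' ultrasound BI-RADS grade (reference 4A) and clinical T stage (reference
#' T1). Complete separation is detected and flagged; a finite
#' ridge-stabilized fit is then returned.
#'
#' @param records data.frame with columns `birads` (4A/4B/4C/5), `t_stage`
#'   (T1..T4) and `label` (0/1).
#' @return list with `coefficients`, the fitted `glm` (or ridge fallback
#'   description), per-case `fitted` probabilities, `separation` flag and a
#'   `predict(newdata)` closure.
#' @export
fitClinicalModel <- function(records) {
  stopifnot(all(c("birads", "t_stage", "label") %in% names(records)))
  records$birads <- factor(records$birads, levels = c("4A", "4B", "4C", "5"))
  records$t_stage <- factor(records$t_stage, levels = paste0("T", 1:4))
  records <- droplevels(records)
  if (nlevels(records$birads) < 2 || nlevels(records$t_stage) < 2)
    stopf("at least 2 observed levels per covariate are required")
  fit <- suppressWarnings(stats::glm(label ~ birads + t_stage,
                                     family = stats::binomial(), data = records))
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)
  if (sep) {
    warning("complete separation detected; returning ridge-stabilized fit")
    X <- stats::model.matrix(~ birads + t_stage, records)
    y <- records$label
    beta <- ridgeLogistic(X, y, lambda = 1)
    coefs <- stats::setNames(as.vector(beta), colnames(X))
    fitted <- as.vector(sigmoid(X %*% beta))
    predictFun <- function(newdata) {
      newdata$birads <- factor(newdata$birads, levels = levels(records$birads))
      newdata$t_stage <- factor(newdata$t_stage, levels = levels(records$t_stage))
      Xn <- stats::model.matrix(~ birads + t_stage, newdata)
      as.vector(sigmoid(Xn %*% beta))
    }
    return(list(coefficients = coefs, se = rep(NA_real_, length(coefs)),
                fitted = fitted, separation = TRUE, predict = predictFun))
  }
  predictFun <- function(newdata) {
    newdata$birads <- factor(newdata$birads, levels = levels(records$birads))
    newdata$t_stage <- factor(newdata$t_stage, levels = levels(records$t_stage))
    as.vector(stats::predict(fit, newdata = newdata, type = "response"))
  }
  list(coefficients = stats::coef(fit),
       se = summary(fit)$coefficients[, "Std. Error"],
       fitted = as.vector(stats::fitted(fit)),
       separation = FALSE, predict = predictFun, glm = fit)
}

## simple IRLS ridge-penalized logistic regression (separation fallback)
ridgeLogistic <- function(X, y, lambda = 1, iters = 50) {
  beta <- numeric(ncol(X))
  for (i in seq_len(iters)) {
    eta <- as.vector(X %*% beta)
    mu <- sigmoid(eta)
    Wd <- mu * (1 - mu)
    H <- t(X) %*% (X * Wd) + diag(lambda, ncol(X))
    g <- t(X) %*% (y - mu) - lambda * beta
    beta <- beta + solve(H, g)
  }
  beta
}

#' Simulate clinical records with known covariate log-odds
#'
#' Draws BI-RADS grades and T stages from fixed marginal frequencies and the
#' label from a logistic model with the supplied coefficients; used to check
#' parameter recovery of [fitClinicalModel].
#'
#' @param n number of records.
#' @param intercept,biradsCoef,tStageCoef true log-odds (coefficients for
#'   levels 4B, 4C, 5 and T2, T3, T4 relative to the references).
#' @return data.frame with `birads`, `t_stage`, `label` plus the true
#'   coefficients as an attribute.
#' @export
simulateClinicalRecords <- function(n, intercept = -0.5,
                                    biradsCoef = c(0.5, 1.0, 1.6),
                                    tStageCoef = c(0.4, 0.9, 1.3)) {
  bl <- c("4A", "4B", "4C", "5"); tl <- paste0("T", 1:4)
  birads <- sample(bl, n, replace = TRUE, prob = c(0.08, 0.2, 0.38, 0.34))
  tst <- sample(tl, n, replace = TRUE, prob = c(0.31, 0.6, 0.06, 0.03))
  eta <- intercept +
    c(0, biradsCoef)[match(birads, bl)] + c(0, tStageCoef)[match(tst, tl)]
  label <- rbinom(n, 1, sigmoid(eta))
  out <- data.frame(birads = birads, t_stage = tst, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- c(intercept, biradsCoef, tStageCoef)
  out
}

## ---------------------------------------------------------------------------
## EvalReport
## ---------------------------------------------------------------------------

#' Per-cohort evaluation report
#'
#' @slot metrics data.frame with one row per model and split: AUC with
#'   DeLong CI plus threshold metrics (accuracy, sensitivity, specificity,
#'   PPV, NPV, F1).
#' @slot comparisons data.frame of pairwise DeLong tests per split.
#' @slot curves list of ROC / PR / DCA curves per model and split.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(metrics = "data.frame", comparisons = "data.frame",
                 curves = "list"))

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  print(object@metrics, digits = 3, row.names = FALSE)
  if (nrow(object@comparisons)) {
    cat("DeLong comparisons:\n")
    print(object@comparisons, digits = 3, row.names = FALSE)
  }
})

#' Build an evaluation report from patient-level scores
#'
#' @param scores data.frame with columns `model`, `split`, `patient_id`,
#'   `probability`, `label`.
#' @param threshold operating point for the threshold metrics.
#' @return an [EvalReport-class].
#' @export
evalReport <- function(scores, threshold = 0.5) {
  stopifnot(all(c("model", "split", "probability", "label") %in% names(scores)))
  metrics <- list(); comparisons <- list(); curves <- list()
  for (sp in unique(scores$split)) {
    sub <- scores[scores$split == sp, ]
    models <- unique(sub$model)
    for (m in models) {
      sm <- sub[sub$model == m, ]
      ci <- delongCI(sm$probability, sm$label)
      cf <- confusionAt(sm$probability, sm$label, threshold)
      metrics[[length(metrics) + 1L]] <- data.frame(
        model = m, split = sp, n = nrow(sm),
        auc = ci$auc, auc_lower = ci$lower, auc_upper = ci$upper,
        accuracy = cf$accuracy, sensitivity = cf$sensitivity,
        specificity = cf$specificity, ppv = cf$ppv, npv = cf$npv, f1 = cf$f1)
      curves[[paste(m, sp, sep = "|")]] <- list(
        roc = rocCurve(sm$probability, sm$label),
        pr = prCurve(sm$probability, sm$label)$points,
        dca = dca(sm$probability, sm$label))
    }
    if (length(models) > 1) {
      for (i in seq_len(length(models) - 1)) for (j in (i + 1):length(models)) {
        a <- sub[sub$model == models[i], ]; b <- sub[sub$model == models[j], ]
        a <- a[order(a$patient_id), ]; b <- b[order(b$patient_id), ]
        if (!identical(a$patient_id, b$patient_id)) next
        dl <- delongTest(a$probability, b$probability, a$label)
        comparisons[[length(comparisons) + 1L]] <- data.frame(
          split = sp, modelA = models[i], modelB = models[j],
          aucA = dl$aucA, aucB = dl$aucB, z = dl$z, p = dl$p)
      }
    }
  }
  new("EvalReport",
      metrics = do.call(rbind, metrics),
      comparisons = if (length(comparisons)) do.call(rbind, comparisons)
                    else data.frame(),
      curves = curves)
}

#' Write an evaluation report to a directory
#'
#' Emits `metrics.tsv`, `comparisons.tsv`, per-model curve tables and (when
#' a PNG device is available) ROC/PR/DCA plots.
#'
#' @param report an [EvalReport-class].
#' @param dir output directory.
#' @param plots attempt PNG plots.
#' @return `dir`, invisibly.
#' @export
writeEvalReport <- function(report, dir, plots = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report@metrics, file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(report@comparisons))
    utils::write.table(report@comparisons, file.path(dir, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report@curves)) {
    safe <- gsub("[^A-Za-z0-9_]", "_", nm)
    for (ct in names(report@curves[[nm]]))
      utils::write.table(report@curves[[nm]][[ct]],
                         file.path(dir, sprintf("curve_%s_%s.tsv", safe, ct)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (plots) {
    ok <- tryCatch({
      grDevices::png(file.path(dir, "roc.png"), width = 600, height = 600)
      graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "FPR",
                     ylab = "TPR", main = "ROC")
      graphics::abline(0, 1, lty = 2, col = "grey")
      i <- 1
      for (nm in names(report@curves)) {
        cv <- report@curves[[nm]]$roc
        graphics::lines(cv$fpr, cv$tpr, col = i); i <- i + 1
      }
      graphics::legend("bottomright", legend = names(report@curves),
                       col = seq_along(report@curves), lty = 1, cex = 0.7)
      grDevices.off <- grDevices::dev.off()
      TRUE
    }, error = function(e) FALSE)
    if (!ok) message("PNG device unavailable; curve plots skipped")
  }
  invisible(dir)
}
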