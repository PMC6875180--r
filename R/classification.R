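# Linear maximum-margin classification under repeated stratified k-fold
# cross-validation, the accuracy-vs-feature-count sweep, and the nested
# 70/30 hold-out protocol with a C grid.  SVMs are fitted with the LIBSVM
# wrapper in e1071 (linear kernel, stopping tolerance 1e-3).

#' Classification rates from a confusion table
#'
#' Patients are the positive class: sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP).
#'
#' @param predictions,labels factors (or coercible) with levels
#'   `control`/`patient`.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`;
#'   a rate is `NA` with a warning when its class is absent from `labels`.
#' @export
confusionRates <- function(predictions, labels) {
  lv <- c("control", "patient")
  pr <- factor(as.character(predictions), levels = lv)
  tr <- factor(as.character(labels), levels = lv)
  acc <- mean(pr == tr)
  npos <- sum(tr == "patient"); nneg <- sum(tr == "control")
  sens <- if (npos > 0) sum(pr == "patient" & tr == "patient") / npos else {
    warning("no positive (patient) cases; sensitivity undefined"); NA_real_
  }
  spec <- if (nneg > 0) sum(pr == "control" & tr == "control") / nneg else {
    warning("no negative (control) cases; specificity undefined"); NA_real_
  }
  c(accuracy = acc, sensitivity = sens, specificity = spec)
}

# Standardize with training-fold statistics only (no leakage); constant
# columns are centred and left unscaled.
scale_train_apply <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(train = sweep(sweep(train, 2L, mu), 2L, sd, "/"),
       test = sweep(sweep(test, 2L, mu), 2L, sd, "/"))
}

fit_linear_svm <- function(x, y, cost = 1, tolerance = 1e-3) {
  e1071::svm(x = x, y = y, kernel = "linear", cost = cost, scale = FALSE,
             tolerance = tolerance)
}

# Stratified fold ids 1..k; re-drawn (with a warning) if any training fold
# would contain a single class.
stratified_folds <- function(y, k, maxTries = 20L) {
  n <- length(y)
  for (try in seq_len(maxTries)) {
    fold <- integer(n)
    for (cls in levels(y)) {
      i <- which(y == cls)
      fold[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    trainOk <- vapply(seq_len(k), function(f)
      length(unique(y[fold != f])) == 2L, TRUE)
    if (all(trainOk)) return(fold)
    warning("single-class training fold; re-drawing fold assignment")
  }
  stop("could not build usable folds; too few subjects per class?")
}

#' Repeated stratified k-fold cross-validation of a linear SVM
#'
#' Per repeat, subjects are split into k stratified folds; each fold in turn
#' is held out, the model is trained on the rest and evaluated on the
#' held-out fold.  Features are standardized with training-fold statistics
#' only.  Test predictions are pooled within a repeat to compute accuracy,
#' sensitivity and specificity; training accuracy is averaged over folds.
#'
#' @param x subjects x features numeric matrix, or an
#'   [AUCFeatureTable-class] (then `y` defaults to its group labels).
#' @param y factor with levels `control`/`patient`.
#' @param features optional column indices to restrict `x` to.
#' @param k folds (default 10).
#' @param repeats repetitions of the whole CV (default 100).
#' @param cost SVM penalty C (LIBSVM default 1).
#' @param tolerance SVM stopping tolerance.
#' @param stratified stratify folds by group?
#' @param seed RNG seed; the full result is a pure function of
#'   (data, config, seed).
#' @return A list of class `CVResult`: mean `accuracy`, `sensitivity`,
#'   `specificity`, `trainAccuracy`, per-repeat data frame `perRepeat`, and
#'   the `config` echo.
#' @export
repeatedKFold <- function(x, y = NULL, features = NULL, k = 10, repeats = 100,
                          cost = 1, tolerance = 1e-3, stratified = TRUE,
                          seed = 1) {
  if (is(x, "AUCFeatureTable")) {
    if (is.null(y)) y <- SummarizedExperiment::colData(x)$group
    x <- t(SummarizedExperiment::assay(x, "auc"))
  }
  x <- as.matrix(x)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  y <- factor(as.character(y), levels = c("control", "patient"))
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  if (min(table(y)) < 2L) stop("need >= 2 subjects per class")
  k <- min(k, length(y))
  per <- matrix(NA_real_, repeats, 4L)
  with_rng(seed, {
    for (r in seq_len(repeats)) {
      fold <- if (stratified) stratified_folds(y, k) else
        sample(rep_len(seq_len(k), length(y)))
      pred <- factor(rep(NA_character_, length(y)),
                     levels = c("control", "patient"))
      trainAcc <- numeric(k)
      for (f in seq_len(k)) {
        te <- fold == f
        sc <- scale_train_apply(x[!te, , drop = FALSE], x[te, , drop = FALSE])
        fit <- fit_linear_svm(sc$train, y[!te], cost, tolerance)
        pred[te] <- predict(fit, sc$test)
        trainAcc[f] <- mean(predict(fit, sc$train) == y[!te])
      }
      per[r, 1:3] <- confusionRates(pred, y)
      per[r, 4L] <- mean(trainAcc)
    }
  })
  colnames(per) <- c("accuracy", "sensitivity", "specificity",
                     "trainAccuracy")
  structure(list(
    accuracy = mean(per[, 1L]), sensitivity = mean(per[, 2L]),
    specificity = mean(per[, 3L]), trainAccuracy = mean(per[, 4L]),
    perRepeat = as.data.frame(per),
    config = list(k = k, repeats = repeats, cost = cost,
                  tolerance = tolerance, stratified = stratified,
                  seed = seed, nFeatures = ncol(x))
  ), class = "CVResult")
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf(
    "CVResult (%d-fold x %d repeats, %d features)\n  accuracy %.3f | sensitivity %.3f | specificity %.3f | train %.3f\n",
    x$config$k, x$config$repeats, x$config$nFeatures,
    x$accuracy, x$sensitivity, x$specificity, x$trainAccuracy))
  invisible(x)
}

#' Accuracy as a function of the number of P-ranked features
#'
#' Features are added in ascending raw-P order in blocks of `step`; each
#' prefix subset is evaluated with [repeatedKFold()].
#'
#' @param table an [AUCFeatureTable-class].
#' @param screen result of [screenFeatures()] on the same table.
#' @param step block size for growing the subset (default 3).
#' @param repeats CV repeats per subset (default 5; the sweep refits many
#'   models, so fewer repeats than the headline CV are used).
#' @param k folds.
#' @param maxFeatures optional cap on the sweep length.
#' @param cost,seed see [repeatedKFold()].
#' @return Data frame with columns `nFeatures`, `accuracy`, `pThreshold`
#'   (largest raw P included); attribute `argmax` gives the row index of the
#'   accuracy peak.
#' @export
accuracyVsFeatureCount <- function(table, screen, step = 3, repeats = 5,
                                   k = 10, maxFeatures = NULL, cost = 1,
                                   seed = 1) {
  if (nrow(screen) == 0L) stop("empty screen")
  if (step <= 0) stop("step must be positive")
  ord <- order(screen$p, screen$feature)
  nf <- nrow(screen)
  if (!is.null(maxFeatures)) nf <- min(nf, maxFeatures)
  sizes <- as.integer(unique(c(seq(min(step, nf), nf, by = step), nf)))
  acc <- numeric(length(sizes))
  pthr <- numeric(length(sizes))
  x <- t(SummarizedExperiment::assay(table, "auc"))
  y <- SummarizedExperiment::colData(table)$group
  for (i in seq_along(sizes)) {
    fs <- screen$feature[ord][seq_len(sizes[i])]
    cv <- repeatedKFold(x, y, features = fs, k = k, repeats = repeats,
                        cost = cost, seed = substream_seed(seed, i))
    acc[i] <- cv$accuracy
    pthr[i] <- screen$p[ord][sizes[i]]
  }
  out <- data.frame(nFeatures = sizes, accuracy = acc, pThreshold = pthr)
  attr(out, "argmax") <- which.max(acc)
  out
}

#' Nested 70/30 hold-out protocol with inner C selection
#'
#' Per repeat: a stratified 70/30 split; on the 70% an inner k-fold CV picks
#' the penalty C from `cGrid` (`2^c`, `c = -5..5` by default) maximising
#' inner accuracy; the chosen model, refitted on the full 70%, is evaluated
#' on the untouched 30%.  A linear regression of test accuracy on validation
#' (inner-CV) accuracy summarises how well internal validation predicts
#' held-out performance.
#'
#' @param table an [AUCFeatureTable-class] or subjects x features matrix.
#' @param y group factor (defaults to the table's labels).
#' @param features optional feature indices.
#' @param ratio training fraction (default 0.7).
#' @param repeats number of random splits (default 100).
#' @param cGrid candidate penalties (default `2^(-5:5)`).
#' @param innerK inner CV folds (default 10).
#' @param seed RNG seed.
#' @return List with `perRepeat` (validation/test accuracy and chosen C per
#'   repeat) and `regression` (slope, adjusted R-squared, two-sided slope P).
#' @export
nestedHoldoutProtocol <- function(table, y = NULL, features = NULL,
                                  ratio = 0.7, repeats = 100,
                                  cGrid = 2^(-5:5), innerK = 10, seed = 1) {
  if (!length(cGrid)) stop("cGrid must be nonempty")
  if (is(table, "AUCFeatureTable")) {
    if (is.null(y)) y <- SummarizedExperiment::colData(table)$group
    x <- t(SummarizedExperiment::assay(table, "auc"))
  } else x <- as.matrix(table)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  y <- factor(as.character(y), levels = c("control", "patient"))
  val <- te <- cs <- numeric(repeats)
  with_rng(seed, {
    for (r in seq_len(repeats)) {
      repeat {
        tr <- unlist(lapply(levels(y), function(cl) {
          i <- which(y == cl)
          sample(i, max(1L, round(ratio * length(i))))
        }))
        if (length(unique(y[tr])) == 2L && length(unique(y[-tr])) == 2L) break
      }
      xtr <- x[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
      kk <- min(innerK, length(ytr))
      fold <- stratified_folds(ytr, kk)
      innerAcc <- vapply(cGrid, function(C) {
        ok <- logical(length(ytr))
        for (f in seq_len(kk)) {
          hold <- fold == f
          sc <- scale_train_apply(xtr[!hold, , drop = FALSE],
                                  xtr[hold, , drop = FALSE])
          fit <- fit_linear_svm(sc$train, ytr[!hold], C)
          ok[hold] <- predict(fit, sc$test) == ytr[hold]
        }
        mean(ok)
      }, 0)
      best <- which.max(innerAcc)  # ties -> smallest C
      sc <- scale_train_apply(xtr, x[-tr, , drop = FALSE])
      fit <- fit_linear_svm(sc$train, ytr, cGrid[best])
      val[r] <- innerAcc[best]
      te[r] <- mean(predict(fit, sc$test) == y[-tr])
      cs[r] <- cGrid[best]
    }
  })
  regression <- if (stats::sd(val) > 0 && stats::sd(te) > 0 && repeats >= 3) {
    reg <- summary(stats::lm(te ~ val))
    list(slope = unname(stats::coef(reg)[2L, 1L]),
         adjR2 = reg$adj.r.squared,
         p = unname(stats::coef(reg)[2L, 4L]))
  } else {
    list(slope = NA_real_, adjR2 = NA_real_, p = NA_real_)
  }
  list(perRepeat = data.frame(validation = val, test = te, C = cs),
       regression = regression)
}
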