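#' L2-regularised logistic regression
#'
#' Fits the linear logistic model p(y = 1 | x) = sigmoid(x'w + b) by
#' penalised maximum likelihood: the summed logistic loss plus a unit-
#' strength ridge penalty 0.5 * ||w||^2 on the coefficients (never the
#' intercept), minimised with the quasi-Newton L-BFGS-B optimiser using the
#' analytic gradient. The fit is deterministic — no random initialisation.
#'
#' @param x numeric matrix (samples x selected descriptors), no missing
#'   values; column names become coefficient names.
#' @param labels binary 0/1 vector with both classes present.
#' @param lambda ridge strength (default 1).
#' @param maxit iteration cap (default 1000); non-convergence is an error
#'   carrying the iteration count.
#' @param tol projected-gradient tolerance (default 1e-4).
#' @param threshold decision threshold on the probability (default 0.5).
#' @return object of class `psgkm_lr`: list with `coefficients` (named),
#'   `intercept`, `descriptor_names`, `threshold`, `lambda`,
#'   `convergence` (optim counts).
#' @export
fit_lr <- function(x, labels, lambda = 1, maxit = 1000L, tol = 1e-4,
                   threshold = 0.5) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (anyNA(x) || anyNA(labels)) stop("missing values not allowed")
  if (length(unique(labels)) < 2L) stop("labels must contain both classes")
  if (min(table(labels)) < 2L) stop("need >= 2 samples per class")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  t_ <- ifelse(labels == 1L, 1, -1)
  p <- ncol(x)
  obj <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    z <- drop(x %*% w) + b
    # log(1 + exp(-t z)) computed stably
    m <- -t_ * z
    0.5 * lambda * sum(w^2) + sum(ifelse(m > 0, m + log1p(exp(-m)), log1p(exp(m))))
  }
  grad <- function(par) {
    w <- par[seq_len(p)]; b <- par[p + 1L]
    z <- drop(x %*% w) + b
    s <- stats::plogis(-t_ * z)       # sigma(-t z)
    r <- -t_ * s
    c(lambda * w + drop(crossprod(x, r)), sum(r))
  }
  fit <- stats::optim(rep(0, p + 1L), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit, pgtol = tol,
                                     factr = 1e3, lmm = 20L))
  if (fit$convergence == 1L)
    stop(sprintf("logistic fit did not converge within %d iterations", maxit))
  w <- fit$par[seq_len(p)]
  names(w) <- colnames(x)
  structure(list(coefficients = w, intercept = fit$par[p + 1L],
                 descriptor_names = colnames(x), threshold = threshold,
                 lambda = lambda, convergence = fit$counts),
            class = "psgkm_lr")
}

#' @export
coef.psgkm_lr <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Predict probabilities and binary calls
#'
#' @param object a fitted `psgkm_lr`.
#' @param x numeric matrix whose columns match the model's descriptor
#'   names in order.
#' @param ... unused.
#' @return data.frame with `probability` (in (0,1)) and `call`
#'   (1 iff probability >= threshold).
#' @export
predict.psgkm_lr <- function(object, x, ...) {
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && !is.null(object$descriptor_names)) {
    mism <- which(colnames(x) != object$descriptor_names)
    if (length(mism))
      stop("descriptor mismatch at column ", mism[1L], ": got '",
           colnames(x)[mism[1L]], "', expected '",
           object$descriptor_names[mism[1L]], "'")
  }
  z <- drop(x %*% object$coefficients) + object$intercept
  prob <- stats::plogis(z)
  data.frame(probability = prob,
             call = as.integer(prob >= object$threshold))
}

#' Confusion-matrix performance metrics
#'
#' Computes TP/TN/FP/FN and the derived metrics: accuracy, precision,
#' sensitivity (recall) and specificity as percentages; F1 as the harmonic
#' mean of fractional precision and recall; and the Matthews correlation
#' coefficient. Undefined ratios (zero denominators) are reported as 0 and
#' recorded in the `undefined` field.
#'
#' @param labels binary truth vector.
#' @param calls binary predicted calls of the same length.
#' @return object of class `psgkm_metrics`.
#' @export
confusion_metrics <- function(labels, calls) {
  labels <- as.integer(labels); calls <- as.integer(calls)
  if (length(labels) != length(calls) || length(labels) == 0L)
    stop("labels and calls must be non-empty and of equal length")
  tp <- sum(labels == 1L & calls == 1L)
  tn <- sum(labels == 0L & calls == 0L)
  fp <- sum(labels == 0L & calls == 1L)
  fn <- sum(labels == 1L & calls == 0L)
  undefined <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) { undefined <<- c(undefined, what); return(0) }
    num / den
  }
  prec <- ratio(tp, tp + fp, "precision")
  sens <- ratio(tp, tp + fn, "sensitivity")
  spec <- ratio(tn, tn + fp, "specificity")
  f1 <- if (prec + sens == 0) { undefined <- c(undefined, "f1"); 0 } else
    2 * prec * sens / (prec + sens)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) { undefined <- c(undefined, "mcc"); 0 } else
    (tp * tn - fp * fn) / mcc_den
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
                 precision = 100 * prec, sensitivity = 100 * sens,
                 specificity = 100 * spec, f1 = f1, mcc = mcc,
                 undefined = undefined),
            class = "psgkm_metrics")
}

#' @export
print.psgkm_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.1f%%  precision %.1f%%  sensitivity %.1f%%  specificity %.1f%%  F1 %.3f  MCC %.3f\n",
    x$accuracy, x$precision, x$sensitivity, x$specificity, x$f1, x$mcc))
  cat(sprintf("  (TP %d, TN %d, FP %d, FN %d)\n", x$TP, x$TN, x$FP, x$FN))
  if (length(x$undefined))
    cat("  undefined (reported as 0):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC and precision-recall curves with areas
#'
#' Sweeps the decision threshold over the unique scores, computing the ROC
#' curve (FPR, TPR) with auROC by the trapezoid rule — equal to the
#' Mann-Whitney rank statistic U/(P*N) with ties counted half — and the
#' precision-recall curve with auPR by step-wise interpolation (the
#' average-precision convention: sum of precision at each threshold times
#' the recall increment).
#'
#' @param labels binary truth vector containing both classes.
#' @param probabilities numeric scores, higher = more positive.
#' @return list with `roc_points` (data.frame fpr/tpr), `auroc`,
#'   `pr_points` (data.frame recall/precision), `aupr`.
#' @export
curves_and_areas <- function(labels, probabilities) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(probabilities))
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L) stop("both classes must be present")
  ord <- order(probabilities, decreasing = TRUE)
  lab_ord <- labels[ord]
  cum_tp <- cumsum(lab_ord == 1L)
  cum_fp <- cumsum(lab_ord == 0L)
  # last index of each distinct score block
  keep <- c(diff(probabilities[ord]) != 0, TRUE)
  tp <- cum_tp[keep]; fp <- cum_fp[keep]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / P
  precision <- tp / (tp + fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr),
       auroc = auroc,
       pr_points = data.frame(recall = recall, precision = precision),
       aupr = aupr)
}

#' Stratified fold assignment
#'
#' @param labels binary labels.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return integer fold id per sample, class proportions preserved to
#'   within one sample per fold.
#' @keywords internal
stratified_folds <- function(labels, folds, seed) {
  if (folds == length(labels)) return(seq_along(labels))  # leave-one-out
  if (min(table(labels)) < folds)
    stop("smallest class has fewer samples than folds")
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
    assign
  })
}

#' Repeated stratified cross-validation with in-fold selection
#'
#' The evaluation protocol: the data are split into `folds` stratified
#' folds; for each fold, mode-wise feature selection ([groupwise_select()])
#' and the logistic fit ([fit_lr()]) are trained on the remaining folds
#' only, and the held-out fold is scored. The whole procedure is repeated
#' `repeats` times with fresh fold assignments, and metrics are reported
#' per fold, per repeat (pooled over that repeat's held-out predictions),
#' and as mean/sd across repeats. Selection inside the loop guarantees the
#' validation folds never influence feature choice.
#'
#' @param dataset labeled [psgkm_dataset()].
#' @param folds number of folds (default 5).
#' @param repeats number of repetitions (default 10).
#' @param k descriptors per mode group (default 100).
#' @param seed integer seed driving fold assignment and forest seeds.
#' @param num_trees,mtry forwarded to the per-mode rankers.
#' @param features optional pre-computed `psgkm_features` for `dataset`
#'   (encoding is per-sequence, so sharing it across folds leaks nothing).
#' @return object of class `psgkm_cv`: list with `per_fold` (data.frame),
#'   `per_repeat` (data.frame incl. auroc/aupr pooled per repeat),
#'   `summary` (mean/sd across repeats), `selections` (list of
#'   `psgkm_selection`, one per fold x repeat), `folds`, `repeats`, `k`,
#'   `seed`.
#' @export
cross_validate <- function(dataset, folds = 5L, repeats = 10L, k = 100L,
                           seed = 1L, num_trees = 100L, mtry = NULL,
                           features = NULL) {
  stopifnot(inherits(dataset, "psgkm_dataset"))
  if (is.null(dataset$labels) || anyNA(dataset$labels))
    stop("cross_validate needs complete labels")
  if (folds < 2L) stop("folds must be >= 2")
  if (is.null(features)) features <- encode_dataset(dataset)
  labels <- dataset$labels
  n <- length(labels)
  per_fold <- list(); per_repeat <- list(); selections <- list()
  metric_names <- c("accuracy", "precision", "sensitivity", "specificity",
                    "f1", "mcc")
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(labels, folds, seed = as.integer(seed) + 1000L * r)
    prob <- numeric(n); call <- integer(n)
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f); te <- which(fold_id == f)
      sub <- features
      sub$x <- features$x[tr, , drop = FALSE]
      sub$labels <- labels[tr]
      sub$sample_ids <- features$sample_ids[tr]
      sel <- groupwise_select(sub, k = k,
                              seed = as.integer(seed) + 1000L * r + 10L * f,
                              num_trees = num_trees, mtry = mtry)
      cols <- sel$selected$index
      xtr <- as.matrix(features$x[tr, cols, drop = FALSE])
      xte <- as.matrix(features$x[te, cols, drop = FALSE])
      model <- fit_lr(xtr, labels[tr])
      pr <- predict(model, xte)
      prob[te] <- pr$probability; call[te] <- pr$call
      m <- confusion_metrics(labels[te], pr$call)
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        repeat. = r, fold = f, n_test = length(te),
        accuracy = m$accuracy, precision = m$precision,
        sensitivity = m$sensitivity, specificity = m$specificity,
        f1 = m$f1, mcc = m$mcc)
      selections[[length(selections) + 1L]] <- sel
    }
    m <- confusion_metrics(labels, call)
    cur <- curves_and_areas(labels, prob)
    per_repeat[[r]] <- data.frame(
      repeat. = r, accuracy = m$accuracy, precision = m$precision,
      sensitivity = m$sensitivity, specificity = m$specificity,
      f1 = m$f1, mcc = m$mcc, auroc = cur$auroc, aupr = cur$aupr)
  }
  per_fold <- do.call(rbind, per_fold)
  per_repeat <- do.call(rbind, per_repeat)
  cols <- c(metric_names, "auroc", "aupr")
  summ <- data.frame(metric = cols,
                     mean = vapply(cols, function(cc) mean(per_repeat[[cc]]), 0),
                     sd = vapply(cols, function(cc) stats::sd(per_repeat[[cc]]), 0))
  rownames(summ) <- NULL
  structure(list(per_fold = per_fold, per_repeat = per_repeat,
                 summary = summ, selections = selections,
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "psgkm_cv")
}

#' @export
print.psgkm_cv <- function(x, ...) {
  cat(sprintf("<psgkm_cv> %d x %d-fold stratified cross-validation (k = %d, seed %d)\n",
              x$repeats, x$folds, x$k, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %7.3f (sd %.3f)\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param cv a `psgkm_cv` object.
#' @param path output JSON path.
#' @export
write_cv_report <- function(cv, path) {
  obj <- list(folds = cv$folds, repeats = cv$repeats, k = cv$k,
              seed = cv$seed, summary = cv$summary,
              per_repeat = cv$per_repeat)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
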