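#' Fit a multi-miRNA logistic diagnostic panel
#'
#' Maximum-likelihood logistic regression of the class label on the panel
#' features (per-sample log2-scale relative expression, i.e. -ddCt). The
#' problem is convex, so the fit is deterministic given the data. Under
#' perfect separation the ML estimate diverges; the fit is then flagged and
#' refitted with a small ridge penalty (intercept unpenalized) so scores
#' remain finite and usable.
#'
#' @param features numeric sample x feature matrix (finite values).
#' @param labels per-sample class: logical, 0/1, or `"tumor"`/`"control"`
#'   (tumor = positive).
#' @param ridge penalty used only in the separation fallback.
#' @return list of class `panel_fit`: `coefficients` (intercept first),
#'   `scores` (fitted probabilities per sample), `separation` (logical
#'   flag), `labels` (0/1 as used).
#' @export
fit_panel <- function(features, labels, ridge = 1e-3) {
  features <- as.matrix(features)
  if (!is.numeric(features) || anyNA(features) || any(!is.finite(features))) {
    stop("features must be finite numeric values")
  }
  y <- panel_labels(labels, nrow(features))
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("need at least 2 samples per class")
  }
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("x%d", seq_len(ncol(features)))
  }
  dat <- data.frame(.y = y, features, check.names = FALSE)

  separation <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separation) {
    co <- ridge_logistic(cbind(1, features), y, lambda = ridge)
    scores <- as.vector(plogis(cbind(1, features) %*% co))
  } else {
    co <- coef(fit)
    scores <- as.vector(fitted(fit))
  }
  names(co) <- c("(Intercept)", colnames(features))
  structure(
    list(coefficients = co,
         scores = setNames(scores, rownames(features)),
         separation = separation,
         labels = y),
    class = "panel_fit"
  )
}

panel_labels <- function(labels, n) {
  if (length(labels) != n) stop("'labels' must have one entry per sample")
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("tumor", "control"))) {
      stop("character labels must be 'tumor'/'control'")
    }
    as.integer(labels == "tumor")
  } else {
    y <- as.integer(as.logical(labels))
    if (anyNA(y)) stop("labels must be coercible to 0/1")
    y
  }
}

# Newton iterations for ridge-penalized logistic log-likelihood;
# first column of X is the (unpenalized) intercept.
ridge_logistic <- function(X, y, lambda = 1e-3, tol = 1e-10, maxit = 100) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(X, y - mu) - pen %*% beta
    hess <- crossprod(X * w, X) + pen
    step <- solve(hess, grad)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' ROC curve and AUC
#'
#' The threshold is swept over the unique scores (predicted positive iff
#' score >= threshold); each threshold contributes a
#' (1-specificity, sensitivity) point and the AUC is the trapezoidal area,
#' which equals the concordance (rank-sum) statistic with ties counted 1/2.
#'
#' @param scores numeric score per sample (higher = more tumor-like).
#' @param labels class per sample (see [fit_panel()]).
#' @return list: `points` (data.frame `threshold`, `fpr`, `tpr`), `auc`.
#' @export
roc_curve <- function(scores, labels) {
  y <- panel_labels(labels, length(scores))
  if (all(y == 1) || all(y == 0)) {
    stop("both classes must be present to build a ROC curve")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- sum(y == 1)
  neg <- sum(y == 0)
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(tpr = sum(pred & y == 1) / pos, fpr = sum(pred & y == 0) / neg)
  }, c(tpr = 0, fpr = 0)))
  points <- data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  auc <- sum(diff(points$fpr) *
               (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  list(points = points, auc = auc)
}

#' Confusion matrix and sensitivity/specificity at a probability cutoff
#'
#' A sample is predicted positive iff its score is at or above the cutoff
#' (the boundary counts as positive). Sensitivity is `100 * TP / (TP + FN)`
#' and specificity `100 * TN / (TN + FP)`, in percent.
#'
#' @param scores numeric score per sample.
#' @param labels class per sample (see [fit_panel()]).
#' @param cutoff probability cutoff in (0, 1), default 0.5.
#' @return list: `confusion` (named counts TP, FP, TN, FN),
#'   `sensitivity`, `specificity` (percent).
#' @export
confusion_at_cutoff <- function(scores, labels, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  y <- panel_labels(labels, length(scores))
  pred <- scores >= cutoff
  tp <- sum(pred & y == 1)
  fp <- sum(pred & y == 0)
  tn <- sum(!pred & y == 0)
  fn <- sum(!pred & y == 1)
  c(list(confusion = c(TP = tp, FP = fp, TN = tn, FN = fn)),
    confusion_metrics(tp, fp, tn, fn))
}

#' Sensitivity and specificity from confusion counts
#'
#' @param tp,fp,tn,fn confusion-matrix counts.
#' @return list: `sensitivity`, `specificity` (percent).
#' @export
#' @examples
#' confusion_metrics(tp = 64, fp = 2, tn = 28, fn = 2)
confusion_metrics <- function(tp, fp, tn, fn) {
  list(sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp))
}
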