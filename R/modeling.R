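# Feature selection (category-wise mRMR + exhaustive QDA subset search under
# repeated stratified cross-validation) and the three recurrence classifiers.

#' Equal-frequency discretization
#' @keywords internal
discretize_ef <- function(x, bins = 8L) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Mutual information between two discrete vectors (bits)
#' @param a,b Vectors coercible to factors.
#' @return Non-negative scalar.
#' @export
mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log2(p[pos] / outer(px, py)[pos]))
}

#' Category-wise mRMR feature ranking
#'
#' Greedy minimum-redundancy maximum-relevance with the difference (MID)
#' criterion: the first feature maximizes MI(f; y); each next one maximizes
#' MI(f; y) minus the mean pairwise MI with the already selected features.
#' MI is estimated after equal-frequency discretization into `bins` bins.
#' Ties are broken by registry order. Constant features have zero MI and rank
#' last but are never excluded a priori.
#'
#' @param features Data.frame containing (at least) the registry columns of
#'   `category`.
#' @param labels Binary vector (logical or 0/1), both classes present.
#' @param category One of the five registry categories.
#' @param k Number of features to return (default 3).
#' @param bins Discretization bins (default 8).
#' @param criterion `"difference"` (default) or `"quotient"`.
#' @return Character vector of `k` names in selection order.
#' @export
mrmr_rank_per_category <- function(features, labels, category, k = 3L,
                                   bins = 8L,
                                   criterion = c("difference", "quotient")) {
  criterion <- match.arg(criterion)
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stop("both classes must be present")
  reg <- feature_registry()
  cand <- intersect(reg$name[reg$category == category], names(features))
  if (length(cand) < k) stop("fewer than k features available in category ", category)
  disc <- lapply(features[cand], discretize_ef, bins = bins)
  rel <- vapply(disc, mutual_information, numeric(1), b = labels)
  selected <- character(0)
  remaining <- cand
  mi_cache <- matrix(NA_real_, length(cand), length(cand),
                     dimnames = list(cand, cand))
  while (length(selected) < k) {
    score <- vapply(remaining, function(f) {
      if (length(selected) == 0) return(rel[f])
      red <- vapply(selected, function(s) {
        if (is.na(mi_cache[f, s])) {
          mi_cache[f, s] <<- mi_cache[s, f] <<- mutual_information(disc[[f]], disc[[s]])
        }
        mi_cache[f, s]
      }, numeric(1))
      if (criterion == "difference") rel[f] - mean(red)
      else rel[f] / max(mean(red), .Machine$double.eps)
    }, numeric(1))
    # ties broken by registry (candidate) order: which.max takes the first
    best <- remaining[which.max(score)]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

#' @keywords internal
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Exhaustive QDA subset search over cross-validated accuracy
#'
#' Evaluates every size-`subset_size` subset of the candidate features by mean
#' QDA accuracy over `n_iter` iterations of stratified `n_folds`-fold
#' cross-validation; all subsets share the identical fold splits drawn from one
#' seeded stream. Ties are broken by higher mean AUC, then lower candidate
#' rank-sum, then lexicographic order. Singular class covariances are ridged by
#' 1e-4 * trace / d.
#'
#' @param candidates Character vector of candidate feature names (the 15 mRMR
#'   picks in the default pipeline).
#' @param features Data.frame with the candidate columns.
#' @param labels Binary labels.
#' @param subset_size Subset size (default 7).
#' @param n_iter,n_folds Cross-validation design (defaults 100 and 3).
#' @param seed Integer seed for the fold stream.
#' @return Object of class `selection_result`: `selected`, `cv_accuracy`,
#'   `cv_auc`, `subsets` (all evaluated subsets), `candidates`, `seed`.
#' @export
qda_subset_search <- function(candidates, features, labels, subset_size = 7L,
                              n_iter = 100L, n_folds = 3L, seed = 1L) {
  labels <- as.integer(as.logical(labels))
  n <- length(labels)
  if (n < 3 * subset_size) {
    warning("n < 3 * subset_size; subset search may be unstable")
  }
  X <- as.matrix(features[, candidates, drop = FALSE])
  storage.mode(X) <- "double"
  subsets <- utils::combn(length(candidates), subset_size)
  set.seed(seed)
  folds <- vapply(seq_len(n_iter), function(i) stratified_folds(labels, n_folds),
                  integer(n))
  res <- qda_subset_cv_cpp(X, labels, t(subsets) - 1L, folds, 1e-4)
  acc <- res$accuracy; auc <- res$auc
  rank_sum <- colSums(matrix(match(candidates[subsets], candidates),
                             nrow = subset_size))
  ord <- order(-acc, -auc, rank_sum)
  # lexicographic final tie-break is inherent: combn enumerates subsets in
  # lexicographic order and order() is stable
  best <- ord[1]
  structure(list(
    selected = candidates[subsets[, best]],
    cv_accuracy = acc[best],
    cv_auc = auc[best],
    accuracy_all = acc,
    subsets = subsets,
    candidates = candidates,
    subset_size = subset_size, n_iter = n_iter, n_folds = n_folds,
    seed = seed), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", length(x$candidates), "candidates ->",
      length(x$selected), "selected; CV accuracy",
      sprintf("%.3f", x$cv_accuracy), "\n")
  cat(paste(" -", x$selected, collapse = "\n"), "\n")
  invisible(x)
}

#' Full two-stage feature selection
#'
#' Stage 1: the top `per_category` features of each of the five categories by
#' category-wise mRMR (15 candidates by default). Stage 2: exhaustive QDA
#' subset search among the candidates.
#'
#' @inheritParams qda_subset_search
#' @param features Feature data.frame (registry columns).
#' @param per_category Candidates per category (default 3).
#' @return A `selection_result` with a `per_category` field added.
#' @export
select_features <- function(features, labels, per_category = 3L,
                            subset_size = 7L, n_iter = 100L, n_folds = 3L,
                            seed = 1L) {
  cats <- unique(feature_registry()$category)
  per_cat <- lapply(cats, function(cc) {
    mrmr_rank_per_category(features, labels, cc, k = per_category)
  })
  names(per_cat) <- cats
  candidates <- unlist(per_cat, use.names = FALSE)
  out <- qda_subset_search(candidates, features, labels, subset_size,
                           n_iter, n_folds, seed)
  out$per_category <- per_cat
  out
}

# Gaussian discriminant fit on standardized features --------------------------

#' @keywords internal
gaussian_fit <- function(Z, y, pooled = FALSE, ridge_frac = 1e-4) {
  Z0 <- Z[y == 0, , drop = FALSE]; Z1 <- Z[y == 1, , drop = FALSE]
  d <- ncol(Z)
  reg <- function(C) {
    ok <- tryCatch({ chol(C); TRUE }, error = function(e) FALSE)
    if (!ok) C <- C + diag(ridge_frac * sum(diag(C)) / d, d)
    C
  }
  if (pooled) {
    Cp <- ((nrow(Z0) - 1) * stats::cov(Z0) + (nrow(Z1) - 1) * stats::cov(Z1)) /
      (nrow(Z) - 2)
    Cp <- reg(Cp)
    list(mean0 = colMeans(Z0), mean1 = colMeans(Z1), cov0 = Cp, cov1 = Cp,
         logprior0 = log(nrow(Z0) / nrow(Z)), logprior1 = log(nrow(Z1) / nrow(Z)))
  } else {
    list(mean0 = colMeans(Z0), mean1 = colMeans(Z1),
         cov0 = reg(stats::cov(Z0)), cov1 = reg(stats::cov(Z1)),
         logprior0 = log(nrow(Z0) / nrow(Z)), logprior1 = log(nrow(Z1) / nrow(Z)))
  }
}

#' @keywords internal
gaussian_log_odds <- function(fit, Z) {
  qf <- function(C, mu) {
    R <- chol(C)
    D <- sweep(Z, 2, mu)
    W <- backsolve(R, t(D), transpose = TRUE)
    colSums(W^2) + 2 * sum(log(diag(R)))
  }
  (-0.5 * qf(fit$cov1, fit$mean1) + fit$logprior1) -
    (-0.5 * qf(fit$cov0, fit$mean0) + fit$logprior0)
}

#' Train a recurrence classifier
#'
#' Features are standardized by training mean/SD (stored in the bundle). QDA
#' and LDA are Gaussian discriminants with class-specific and pooled
#' covariance respectively, empirical class priors, and a trace-scaled ridge
#' when a covariance is singular; scores are posterior probabilities of
#' recurrence, called at 0.5. SVM is a polynomial-kernel (degree 2) machine
#' whose score is the margin decision value, called at 0.
#'
#' @param features Data.frame containing the selected feature columns.
#' @param labels Binary recurrence labels.
#' @param selected Character vector of feature names to use.
#' @param kind `"QDA"`, `"LDA"` or `"SVM"`.
#' @param seed Recorded training seed (SVM fitting is deterministic for fixed
#'   inputs; the seed is metadata).
#' @return Object of class `recurrence_classifier`.
#' @export
recurrence_classifier <- function(features, labels, selected,
                                  kind = c("QDA", "LDA", "SVM"), seed = 1L) {
  kind <- match.arg(kind)
  labels <- as.integer(as.logical(labels))
  missing <- setdiff(selected, names(features))
  if (length(missing)) stop("missing feature column(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(features[, selected, drop = FALSE])
  if (any(!is.finite(X))) stop("selected features must be finite")
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  fit <- if (kind == "QDA") {
    gaussian_fit(Z, labels, pooled = FALSE)
  } else if (kind == "LDA") {
    gaussian_fit(Z, labels, pooled = TRUE)
  } else {
    m <- e1071::svm(Z, factor(labels, levels = c(0, 1)),
                    kernel = "polynomial", degree = 2, coef0 = 1, scale = FALSE)
    # orientation: e1071 decision values are positive for the first label
    pos_is_1 <- m$labels[1] == 2  # internal label index of factor level "1"
    list(sv = unname(as.matrix(m$SV)), coefs = as.numeric(m$coefs),
         rho = m$rho, gamma = m$gamma, coef0 = m$coef0, degree = m$degree,
         flip = !pos_is_1)
  }
  structure(list(kind = kind, selected = selected,
                 means = stats::setNames(mu, selected),
                 sds = stats::setNames(sdv, selected),
                 fit = fit, seed = seed),
            class = "recurrence_classifier")
}

#' @export
print.recurrence_classifier <- function(x, ...) {
  cat("<recurrence_classifier>", x$kind, "on", length(x$selected), "features:\n")
  cat(paste(" -", x$selected, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.recurrence_classifier <- function(object, ...) {
  print(object)
  cat("standardization means/SDs stored; training seed", object$seed, "\n")
  invisible(object)
}

#' Predict recurrence
#'
#' @param object A `recurrence_classifier`.
#' @param newdata Data.frame containing the selected feature columns.
#' @param ... Unused.
#' @return Data.frame with `score` (posterior probability for QDA/LDA, margin
#'   for SVM) and logical `call`.
#' @export
predict.recurrence_classifier <- function(object, newdata, ...) {
  missing <- setdiff(object$selected, names(newdata))
  if (length(missing)) {
    stop("missing feature column(s) at predict: ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(newdata[, object$selected, drop = FALSE])
  Z <- sweep(sweep(X, 2, object$means), 2, object$sds, "/")
  if (object$kind %in% c("QDA", "LDA")) {
    lo <- gaussian_log_odds(object$fit, Z)
    score <- 1 / (1 + exp(-lo))
    data.frame(score = score, call = score > 0.5)
  } else {
    f <- object$fit
    K <- (f$gamma * (Z %*% t(f$sv)) + f$coef0)^f$degree
    dec <- as.numeric(K %*% f$coefs) - f$rho
    if (isTRUE(f$flip)) dec <- -dec
    data.frame(score = dec, call = dec > 0)
  }
}

#' Classification metrics and ROC
#'
#' @param calls Logical/binary predicted classes.
#' @param scores Numeric scores (larger = more recurrence-like).
#' @param truth Logical/binary true classes.
#' @return Object of class `eval_report`: confusion counts (tp, fp, fn, tn),
#'   accuracy, recall (sensitivity), ppv, specificity, `auc` (midrank
#'   trapezoidal; NaN with warning if truth has one class) and `roc`
#'   (data.frame fpr/tpr).
#' @export
evaluate_classifier <- function(calls, scores, truth) {
  calls <- as.logical(calls); truth <- as.logical(truth)
  stopifnot(length(calls) == length(truth), length(scores) == length(truth))
  tp <- sum(calls & truth); fp <- sum(calls & !truth)
  fn <- sum(!calls & truth); tn <- sum(!calls & !truth)
  n <- length(truth)
  if (length(unique(truth)) < 2) {
    warning("truth contains a single class; AUC undefined")
    auc <- NaN
    roc <- data.frame(fpr = numeric(0), tpr = numeric(0))
  } else {
    r <- rank(scores)  # midranks handle ties
    n1 <- sum(truth); n0 <- n - n1
    auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    thr <- sort(unique(scores), decreasing = TRUE)
    roc <- data.frame(
      fpr = c(0, vapply(thr, function(t) sum(scores >= t & !truth) / n0, numeric(1))),
      tpr = c(0, vapply(thr, function(t) sum(scores >= t & truth) / n1, numeric(1))))
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / n,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NaN,
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NaN,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NaN,
                 auc = auc, roc = roc, n = n),
            class = "eval_report")
}

#' Metrics from a confusion matrix
#'
#' Convenience wrapper for published confusion tables.
#' @param tp,fp,fn,tn Confusion counts.
#' @return An `eval_report` (without ROC/AUC).
#' @export
metrics_from_confusion <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / n,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NaN,
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NaN,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NaN,
                 auc = NaN, roc = NULL, n = n),
            class = "eval_report")
}

#' Plot the ROC curve of an evaluation report
#' @param x An `eval_report` with ROC points.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.eval_report <- function(x, ...) {
  if (is.null(x$roc) || nrow(x$roc) == 0) stop("no ROC points available")
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$n, "\n")
  cat(sprintf("  confusion: TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  accuracy %.3f  recall %.3f  PPV %.3f  specificity %.3f  AUC %.3f\n",
              x$accuracy, x$recall, x$ppv, x$specificity, x$auc))
  invisible(x)
}
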