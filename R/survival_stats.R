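# Survival analysis around the classifier: Kaplan-Meier with log-rank,
# multivariable Cox (Efron ties), Cox risk scores with median/tertile
# stratification, Fisher exact and exact McNemar tests. Recurrence-free
# survival is time from diagnosis to recurrence or death, whichever first,
# censored at last follow-up; the synthetic generator emits this semantics.

#' Kaplan-Meier curves and log-rank test across groups
#'
#' @param times Follow-up times.
#' @param events Logical/0-1 event indicators.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return List: `curves` (per group: data.frame time/surv/n_risk),
#'   `chisq`, `df`, `p` (two-sided, chi-square with groups - 1 df). With no
#'   events anywhere the statistic is 0 and p = 1.
#' @export
km_logrank <- function(times, events, groups) {
  events <- as.integer(as.logical(events))
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 non-empty groups")
  if (any(table(groups) == 0)) stop("empty group")
  curves <- lapply(levels(groups), function(g) {
    sel <- groups == g
    sf <- survival::survfit(survival::Surv(times[sel], events[sel]) ~ 1)
    data.frame(time = sf$time, surv = sf$surv, n_risk = sf$n.risk)
  })
  names(curves) <- levels(groups)
  df <- nlevels(groups) - 1
  if (sum(events) == 0) {
    return(list(curves = curves, chisq = 0, df = df, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  chisq <- sd$chisq
  list(curves = curves, chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Median survival from a Kaplan-Meier curve
#' @param curve Data.frame time/surv as returned in [km_logrank()] `curves`.
#' @return First time at which the survival estimate drops to 0.5 or below
#'   (NA if it never does).
#' @export
km_median <- function(curve) {
  idx <- which(curve$surv <= 0.5)
  if (length(idx) == 0) NA_real_ else curve$time[min(idx)]
}

#' Multivariable Cox proportional hazards model
#'
#' Partial-likelihood fit with Efron tie handling over gender, T stage, N stage
#' and the classifier call. Reference levels are explicit configuration,
#' defaulting to female, T1, N0 and predicted non-recurrence, so hazard ratios
#' > 1 mean higher hazard for male / T2 / N1 / predicted recurrence. Constant
#' covariates are dropped with a warning; coefficient magnitudes above 10
#' trigger a separation warning.
#'
#' @param clinical Data.frame with `gender`, `t_stage`, `n_stage` columns.
#' @param calls Logical classifier calls (TRUE = predicted recurrence).
#' @param times,events Survival outcome.
#' @param reference Named list of reference levels.
#' @param ties Tie handling, `"efron"` (default) or `"breslow"`.
#' @return Data.frame: term, hr, ci_lo, ci_hi, p, coef, se.
#' @export
cox_multivariable <- function(clinical, calls, times, events,
                              reference = list(gender = "F", t_stage = "T1",
                                               n_stage = "N0", call = FALSE),
                              ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  lvl <- function(x, ref) {
    f <- factor(x)
    if (ref %in% levels(f)) f <- stats::relevel(f, ref = ref)
    f
  }
  df <- data.frame(
    gender = lvl(clinical$gender, reference$gender),
    t_stage = lvl(clinical$t_stage, reference$t_stage),
    n_stage = lvl(clinical$n_stage, reference$n_stage),
    call = factor(as.logical(calls), levels = c(reference$call, !reference$call)))
  keep <- vapply(df, function(x) length(unique(x)) > 1, logical(1))
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(names(df)[!keep], collapse = ", "))
    df <- df[, keep, drop = FALSE]
  }
  if (sum(events) < ncol(df)) warning("fewer events than covariates")
  fit <- survival::coxph(survival::Surv(times, as.integer(as.logical(events))) ~ .,
                         data = df, ties = ties)
  s <- summary(fit)
  co <- s$coefficients
  if (any(abs(co[, "coef"]) > 10)) warning("possible separation: |coef| > 10")
  data.frame(term = rownames(co),
             hr = co[, "exp(coef)"],
             ci_lo = s$conf.int[, "lower .95"],
             ci_hi = s$conf.int[, "upper .95"],
             p = co[, "Pr(>|z|)"],
             coef = co[, "coef"],
             se = co[, "se(coef)"],
             row.names = NULL)
}

#' Cox risk-score model over selected image features
#'
#' Fits a Cox model (Efron ties) on the standardized selected features; the
#' risk score is the linear predictor (a weighted sum of the features with the
#' regression coefficients as weights). Median and tertile cutpoints are
#' computed on the supplied dataset; new datasets should be stratified with
#' their own cutpoints via [stratify_scores()], mirroring per-dataset
#' cutpoint determination.
#'
#' @param features Data.frame containing the selected feature columns (finite).
#' @param selected Character vector of feature names (>= 1).
#' @param times,events Survival outcome; n >= 3 required for tertiles.
#' @return Object of class `risk_model`: coefficients, standardization
#'   means/sds, per-patient `scores`, `cutpoints` (median, tertiles) and group
#'   assignments `group2` / `group3`.
#' @export
cox_risk_scores <- function(features, selected, times, events) {
  if (length(times) < 3) stop("need at least 3 subjects for tertile cutpoints")
  X <- as.matrix(features[, selected, drop = FALSE])
  if (any(!is.finite(X))) stop("selected features must be finite")
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  dfz <- as.data.frame(Z)
  names(dfz) <- selected
  fit <- survival::coxph(
    survival::Surv(times, as.integer(as.logical(events))) ~ .,
    data = dfz, ties = "efron")
  coefs <- stats::coef(fit)
  coefs[is.na(coefs)] <- 0
  scores <- as.numeric(Z %*% coefs)
  rm <- structure(list(coefficients = stats::setNames(as.numeric(coefs), selected),
                       means = stats::setNames(mu, selected),
                       sds = stats::setNames(sdv, selected),
                       scores = scores),
                  class = "risk_model")
  strat <- stratify_scores(scores)
  rm$cutpoints <- strat$cutpoints
  rm$group2 <- strat$group2
  rm$group3 <- strat$group3
  if (all(coefs == 0)) {
    warning("all Cox coefficients are zero; risk grouping is degenerate")
    rm$degenerate <- TRUE
  }
  rm
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model> Cox coefficients over", length(x$coefficients), "features\n")
  print(round(x$coefficients, 4))
  cat("median cutpoint", sprintf("%.4f", x$cutpoints$median),
      "; tertiles", sprintf("%.4f / %.4f", x$cutpoints$tertiles[1],
                            x$cutpoints$tertiles[2]), "\n")
  invisible(x)
}

#' Risk scores for new data
#' @param object A `risk_model`.
#' @param newdata Data.frame with the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of linear-predictor risk scores.
#' @export
predict.risk_model <- function(object, newdata, ...) {
  sel <- names(object$coefficients)
  missing <- setdiff(sel, names(newdata))
  if (length(missing)) stop("missing feature column(s): ", paste(missing, collapse = ", "))
  X <- as.matrix(newdata[, sel, drop = FALSE])
  Z <- sweep(sweep(X, 2, object$means), 2, object$sds, "/")
  as.numeric(Z %*% object$coefficients)
}

#' Median and tertile stratification of risk scores
#'
#' Cutpoints are the 1/2 and {1/3, 2/3} sample quantiles (linear-interpolation
#' definition, type 7), computed on the supplied scores — i.e. per dataset.
#'
#' @param scores Numeric risk scores (length >= 3).
#' @return List: `cutpoints` (median, tertiles), `group2` (factor low/high) and
#'   `group3` (factor low/mid/high).
#' @export
stratify_scores <- function(scores) {
  if (length(scores) < 3) stop("need at least 3 scores")
  med <- stats::quantile(scores, 0.5, names = FALSE, type = 7)
  ter <- stats::quantile(scores, c(1, 2) / 3, names = FALSE, type = 7)
  g2 <- factor(ifelse(scores <= med, "low", "high"), levels = c("low", "high"))
  # findInterval tolerates tied cutpoints (degenerate score distributions)
  g3 <- factor(c("low", "mid", "high")[findInterval(scores, ter, left.open = TRUE) + 1],
               levels = c("low", "mid", "high"))
  list(cutpoints = list(median = med, tertiles = ter), group2 = g2, group3 = g3)
}

#' Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value: the sum over all tables with the observed margins
#' whose hypergeometric probability does not exceed the observed table's.
#' A zero margin gives p = 1 with a warning.
#'
#' @param a,b,c,d Cell counts, row-wise: \code{rbind(c(a, b), c(c, d))}.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    warning("zero margin; p = 1 by convention")
    return(1)
  }
  stats::fisher.test(matrix(counts, 2, 2, byrow = TRUE))$p.value
}

#' Exact McNemar test on paired classifier calls
#'
#' Correctness indicators of the two classifiers against the truth are paired;
#' with b and c the discordant counts, the exact two-sided p-value is the
#' binomial two-tail of min(b, c) out of b + c at rate 1/2 (p = 1 when
#' b = c = 0).
#'
#' @param calls_a,calls_b Paired predicted classes.
#' @param truth True classes.
#' @return Two-sided exact p-value.
#' @export
mcnemar_exact <- function(calls_a, calls_b, truth) {
  stopifnot(length(calls_a) == length(truth), length(calls_b) == length(truth))
  ca <- as.logical(calls_a) == as.logical(truth)
  cb <- as.logical(calls_b) == as.logical(truth)
  b <- sum(ca & !cb)
  cc <- sum(!ca & cb)
  if (b + cc == 0) return(1)
  min(1, stats::binom.test(min(b, cc), b + cc, 0.5)$p.value)
}
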