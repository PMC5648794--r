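test_that("log-rank handles no-event and identical-group degenerate inputs", {
  out <- km_logrank(c(1, 2, 3, 4), c(0, 0, 0, 0), c("a", "a", "b", "b"))
  expect_equal(out$chisq, 0)
  expect_equal(out$p, 1)
  t <- c(1, 3, 5, 7); e <- c(1, 0, 1, 1)
  out2 <- km_logrank(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_lt(out2$chisq, 1e-10)
  expect_error(km_logrank(t, e, rep("a", 4)), "2 non-empty groups")
})

test_that("log-rank statistic matches the hand-computed O-E table", {
  # group A events at 1, 2, 3; group B events at 4, 5, 6; no censoring
  times <- 1:6; events <- rep(1, 6); groups <- rep(c("A", "B"), each = 3)
  out <- km_logrank(times, events, groups)
  # oracle: observed-minus-expected per event time with hypergeometric variance
  nA <- 3; nB <- 3; O <- 0; E <- 0; V <- 0
  for (t in 1:6) {
    atA <- sum(times >= t & groups == "A"); atB <- sum(times >= t & groups == "B")
    n <- atA + atB
    dA <- as.integer(t <= 3)
    O <- O + dA
    E <- E + atA / n
    if (n > 1) V <- V + atA * atB / n^2
  }
  expect_equal(out$chisq, (O - E)^2 / V, tolerance = 1e-6)
  expect_equal(out$p, stats::pchisq((O - E)^2 / V, 1, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("KM estimate equals the empirical survival function without censoring", {
  set.seed(2)
  for (i in 1:5) {
    t <- rexp(40); g <- rep(c("x", "y"), 20)
    out <- km_logrank(t, rep(1, 40), g)
    for (gr in c("x", "y")) {
      cu <- out$curves[[gr]]
      emp <- vapply(cu$time, function(tt) mean(t[g == gr] > tt), numeric(1))
      expect_equal(cu$surv, emp, tolerance = 1e-12)
    }
  }
})

test_that("Cox recovers a known hazard ratio and rejects pure noise", {
  hits_ci <- 0; hits_null <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 500
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, rate = ifelse(x == 1, 3, 1))   # true HR 3
    cl <- data.frame(gender = sample(c("M", "F"), n, TRUE),
                     t_stage = sample(c("T1", "T2"), n, TRUE),
                     n_stage = sample(c("N0", "N1"), n, TRUE))
    fit <- cox_multivariable(cl, x == 1, t, rep(TRUE, n))
    row <- fit[fit$term == "callTRUE", ]
    if (row$ci_lo <= 3 && 3 <= row$ci_hi) hits_ci <- hits_ci + 1
    # independent covariate stays near zero
    x0 <- rbinom(n, 1, 0.5)
    fit0 <- cox_multivariable(cl, x0 == 1, rexp(n), rep(TRUE, n))
    if (abs(fit0[fit0$term == "callTRUE", "coef"]) < 0.2) hits_null <- hits_null + 1
  }
  expect_gte(hits_ci, 18)
  expect_gte(hits_null, 18)
})

test_that("Cox point estimates are invariant to exact duplication (Breslow)", {
  set.seed(33)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, ifelse(x == 1, 2, 1))
  cl <- data.frame(gender = sample(c("M", "F"), n, TRUE),
                   t_stage = sample(c("T1", "T2"), n, TRUE),
                   n_stage = sample(c("N0", "N1"), n, TRUE))
  f1 <- cox_multivariable(cl, x == 1, t, rep(TRUE, n), ties = "breslow")
  idx <- rep(seq_len(n), 2)
  f2 <- cox_multivariable(cl[idx, ], (x == 1)[idx], t[idx], rep(TRUE, 2 * n),
                          ties = "breslow")
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
})

test_that("constant covariates are dropped with a warning", {
  set.seed(5)
  n <- 80
  x <- rbinom(n, 1, 0.5)
  cl <- data.frame(gender = rep("M", n),
                   t_stage = sample(c("T1", "T2"), n, TRUE),
                   n_stage = sample(c("N0", "N1"), n, TRUE))
  expect_warning(
    fit <- cox_multivariable(cl, x == 1, rexp(n, 1 + x), rep(TRUE, n)),
    "constant")
  expect_false(any(grepl("gender", fit$term)))
})

test_that("risk scores stratify into exact tertiles and flag degeneracy", {
  set.seed(7)
  n <- 120
  df <- data.frame(f1 = rnorm(n), f2 = rnorm(n))
  t <- rexp(n, exp(0.8 * df$f1))
  rm_ <- cox_risk_scores(df, c("f1", "f2"), t, rep(TRUE, n))
  expect_equal(unname(table(rm_$group3)), rep(40L, 3), ignore_attr = TRUE)
  expect_equal(unname(table(rm_$group2)), c(60L, 60L), ignore_attr = TRUE)
  # positive-coefficient monotonicity of the linear predictor
  co <- rm_$coefficients
  up <- df[1, , drop = FALSE]; up$f1 <- up$f1 + 1
  if (co["f1"] > 0) expect_gt(predict(rm_, up), predict(rm_, df[1, , drop = FALSE]))
  # constant features -> all-zero coefficients -> degenerate flag
  dfc <- data.frame(f1 = rep(1, 30), f2 = rep(2, 30))
  w <- capture_warnings(
    rmc <- cox_risk_scores(dfc, c("f1", "f2"), rexp(30), rep(TRUE, 30)))
  expect_true(any(grepl("degenerate", w)))
  expect_true(rmc$degenerate)
  expect_true(all(rmc$scores == rmc$scores[1]))
  expect_error(cox_risk_scores(df[1:2, ], c("f1", "f2"), t[1:2], c(TRUE, TRUE)),
               "at least 3")
})

test_that("Cox risk scores are invariant to affine covariate rescaling", {
  set.seed(8)
  n <- 100
  df <- data.frame(f1 = rnorm(n), f2 = rnorm(n))
  t <- rexp(n, exp(0.5 * df$f1 - 0.3 * df$f2))
  rm1 <- cox_risk_scores(df, c("f1", "f2"), t, rep(TRUE, n))
  df2 <- data.frame(f1 = 10 * df$f1 + 5, f2 = -2 * df$f2)
  rm2 <- cox_risk_scores(df2, c("f1", "f2"), t, rep(TRUE, n))
  expect_equal(rm1$scores, rm2$scores, tolerance = 1e-6)
})

test_that("Fisher exact p-values reproduce published values and enumeration", {
  expect_equal(fisher_exact_2x2(30, 27, 35, 27), 0.7151, tolerance = 5e-5)
  expect_equal(fisher_exact_2x2(10, 10, 10, 10), 1)
  expect_warning(p0 <- fisher_exact_2x2(0, 0, 5, 5), "zero margin")
  expect_equal(p0, 1)
  set.seed(9)
  for (i in 1:30) {
    n <- sample(8:30, 1)
    cells <- as.vector(stats::rmultinom(1, n, rep(0.25, 4)))
    if (any(c(cells[1] + cells[2], cells[3] + cells[4],
              cells[1] + cells[3], cells[2] + cells[4]) == 0)) next
    expect_equal(fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4]),
                 oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
  # symmetry under row and column swaps
  expect_equal(fisher_exact_2x2(7, 3, 2, 9), fisher_exact_2x2(2, 9, 7, 3))
  expect_equal(fisher_exact_2x2(7, 3, 2, 9), fisher_exact_2x2(3, 7, 9, 2))
})

test_that("exact McNemar matches the binomial tail and its symmetries", {
  truth <- rep(TRUE, 20)
  a <- rep(TRUE, 20)
  expect_equal(mcnemar_exact(a, a, truth), 1)
  # discordants b = 1, c = 9 -> 2 * P(X <= 1 | Bin(10, 0.5))
  a2 <- c(rep(TRUE, 10), TRUE, rep(FALSE, 9))
  b2 <- c(rep(TRUE, 10), FALSE, rep(TRUE, 9))
  expect_equal(mcnemar_exact(a2, b2, truth), 2 * stats::pbinom(1, 10, 0.5),
               tolerance = 1e-12)
  expect_equal(mcnemar_exact(a2, b2, truth), mcnemar_exact(b2, a2, truth))
})
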