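test_that("HRT fits agree with the normal-equations oracle", {
  set.seed(41)
  for (i in 1:5) {
    n <- 60
    cr <- rep(c("A", "B", "C"), each = 20)
    XQ <- matrix(sample(c(0, 2), n * 2, replace = TRUE), n,
                 dimnames = list(NULL, c("q1", "q2")))
    y <- rnorm(n)
    fit <- fit_hrt(y, cr, raw_incidence(XQ))
    Xc <- model.matrix(~ 0 + factor(cr))
    X <- cbind(Xc, XQ)
    b_or <- solve(crossprod(X), crossprod(X, y))
    expect_equal(unname(fit$beta_Q), unname(b_or[4:5, 1]),
                 tolerance = 1e-10)
    expect_equal(fit$rss, sum((y - X %*% b_or)^2), tolerance = 1e-8)
  }
})

test_that("single-column Wald equals the squared t statistic", {
  set.seed(42)
  n <- 50
  cr <- rep(c("A", "B"), each = 25)
  x <- rnorm(n)
  y <- 0.3 * x + rnorm(n)
  fit <- fit_hrt(y, cr, raw_incidence(matrix(x, ncol = 1,
                                             dimnames = list(NULL, "q"))))
  w <- wald_test(fit)
  lf <- lm(y ~ 0 + factor(cr) + x)
  tval <- summary(lf)$coefficients["x", "t value"]
  expect_equal(w$W, tval^2, tolerance = 1e-10)
  expect_equal(w$df, 1L)
  expect_equal(w$score, -log10(pchisq(tval^2, 1, lower.tail = FALSE)),
               tolerance = 1e-10)
})

test_that("Wald p-values are uniform under the null", {
  set.seed(43)
  p <- replicate(400, {
    n <- 80
    cr <- rep(c("A", "B"), each = 40)
    x <- matrix(sample(c(0, 2), n, replace = TRUE), ncol = 1,
                dimnames = list(NULL, "q"))
    y <- rnorm(n)
    wald_test(fit_hrt(y, cr, raw_incidence(x)))$p
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  ci <- qbinom(c(0.005, 0.995), 400, 0.05) / 400
  expect_gte(mean(p < 0.05), ci[1])
  expect_lte(mean(p < 0.05), ci[2])
})

test_that("CSRT REML matches the independent gls oracle", {
  skip_if_not_installed("nlme")
  set.seed(44)
  n <- 300
  cr <- rep(c("A", "B", "C"), each = 100)
  x <- rnorm(n)
  sds <- c(A = 3, B = 1, C = 1.5)
  y <- as.numeric(factor(cr)) + 0.4 * x + rnorm(n, 0, sds[cr])
  inc <- raw_incidence(matrix(x, ncol = 1, dimnames = list(NULL, "q")))
  f <- fit_csrt_reml(y, cr, inc)
  d <- data.frame(y = y, cr = cr, x = x)
  g <- nlme::gls(y ~ 0 + cr + x, data = d,
                 weights = nlme::varIdent(form = ~ 1 | cr),
                 method = "REML")
  vs <- coef(g$modelStruct$varStruct, unconstrained = FALSE,
             allCoef = TRUE)
  expect_equal(unname(f$sigma2_cross[c("A", "B", "C")]),
               unname((g$sigma * vs[c("A", "B", "C")])^2),
               tolerance = 1e-4)
  expect_equal(unname(f$beta_Q), unname(coef(g)[["x"]]), tolerance = 1e-4)
  expect_equal(f$loglik_reml, as.numeric(stats::logLik(g)),
               tolerance = 1e-6)
  fm <- fit_csrt_reml(y, cr, inc, method = "ml")
  gm <- nlme::gls(y ~ 0 + cr + x, data = d,
                  weights = nlme::varIdent(form = ~ 1 | cr),
                  method = "ML")
  expect_equal(fm$loglik_ml, as.numeric(stats::logLik(gm)),
               tolerance = 1e-6)
})

test_that("CSRT behaves sensibly in homogeneous and degenerate cases", {
  set.seed(45)
  n <- 400
  cr <- rep(c("A", "B"), each = 200)
  x <- sample(c(0, 2), n, replace = TRUE)
  y <- 0.5 * x + rnorm(n)
  inc <- raw_incidence(matrix(x, ncol = 1, dimnames = list(NULL, "q")))
  fc <- fit_csrt_reml(y, cr, inc)
  fh <- fit_hrt(y, cr, inc)
  # equal true variances: estimates close to each other and to HRT beta
  expect_lt(abs(fc$sigma2_cross[["A"]] / fc$sigma2_cross[["B"]] - 1), 0.5)
  expect_equal(unname(fc$beta_Q), unname(fh$beta_Q), tolerance = 0.02)
  expect_true(all(diff(fc$loglik_trace) >= -1e-8))

  # y constant within crosses: variances at the floor, beta_Q ~ 0
  yc <- ifelse(cr == "A", 1, 2)
  fdeg <- fit_csrt_reml(yc, cr, inc)
  expect_lt(max(fdeg$sigma2_cross), 1e-6)
  expect_lt(abs(fdeg$beta_Q), 1e-6)
})

test_that("null-model cross variances drive the f-CSRT Wald", {
  set.seed(46)
  n <- 300
  cr <- rep(c("A", "B", "C"), each = 100)
  y <- rnorm(n, 0, c(A = 3, B = 1, C = 1)[cr])
  rm <- null_cross_variances(y, cr)
  expect_equal(rm$kind, "CSRT")
  expect_gt(rm$sigma2_cross[["A"]] / rm$sigma2_cross[["B"]], 4)
  # single cross: reduces to the REML variance of the intercept model
  y1 <- y[1:100]
  rm1 <- null_cross_variances(y1, rep("A", 100))
  expect_equal(unname(rm1$sigma2_cross), var(y1), tolerance = 1e-6)

  x <- sample(c(0, 2), n, replace = TRUE)
  inc <- raw_incidence(matrix(x, ncol = 1, dimnames = list(NULL, "q")))
  ff <- fit_fcsrt(y, cr, rm$sigma2_cross, inc)
  expect_equal(ff$kind, "f-CSRT")
  expect_equal(wald_test(ff)$df, 1L)
})

test_that("variance-explained formulas reproduce their closed forms", {
  mkfit <- function(rss, df) structure(list(rss = rss, df_resid = df),
                                       class = "mpp_fit")
  expect_equal(r2_adj_hrt(mkfit(50, 95), mkfit(100, 98)),
               1 - (50 / 95) / (100 / 98), tolerance = 1e-12)
  expect_equal(r2_adj_hrt(mkfit(10, 90), mkfit(10, 90)), 0)
  expect_equal(r2_adj_hrt(mkfit(0, 90), mkfit(10, 95)), 1)

  expect_equal(r2_lr_csrt(-100, -100, 50), 0)
  expect_equal(r2_lr_csrt(-75, -100, 50), 1 - exp(-1), tolerance = 1e-12)
  expect_warning(v <- r2_lr_csrt(-101, -100, 50), "clamped")
  expect_equal(v, 0)

  expect_equal(utz_adjust(0.5, 4, 100), 0.48, tolerance = 1e-12)
  expect_equal(utz_adjust(1, 4, 100), 1)
  expect_equal(utz_adjust(0, 5, 50), -0.1, tolerance = 1e-12)
})
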