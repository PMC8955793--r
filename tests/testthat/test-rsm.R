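test_that("OLS agrees with the normal-equations oracle to 10+ digits", {
  doms <- study_domains()
  runs <- study_runs()
  for (resp in c("Rs", "t2")) {
    fit <- study_fit(resp, reduce = FALSE)
    X <- fit$X; y <- runs[[resp]]
    beta_ne <- drop(solve(crossprod(X), crossprod(X, y)))
    expect_equal(unname(coef(fit)), unname(beta_ne), tolerance = 1e-11)
    # se / rmse / adj R2 recomputed from first principles
    res <- y - drop(X %*% beta_ne)
    df <- nrow(X) - ncol(X)
    s2 <- sum(res^2) / df
    expect_equal(fit$rmse, sqrt(s2), tolerance = 1e-12)
    expect_equal(unname(fit$se),
                 unname(sqrt(s2 * diag(solve(crossprod(X))))),
                 tolerance = 1e-10)
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    expect_equal(fit$adj_r2,
                 1 - (1 - r2) * (nrow(X) - 1) / df, tolerance = 1e-12)
  }
})

test_that("noise-free linear data is fit exactly", {
  d <- data.frame(x = c(-1, -0.5, 0, 0.5, 1))
  d$y <- 2 + 3 * d$x
  fit <- rsm_quad(y ~ x, d, reduce = FALSE,
                  terms = terms_from_labels(c("(Intercept)", "x"), "x"))
  expect_equal(unname(coef(fit)), c(2, 3), tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
})

test_that("backward elimination retains the significant term sets", {
  fit_rs <- study_fit("Rs")
  expect_setequal(fit_rs$terms$label,
                  c("(Intercept)", "U", "MD", "pH", "U:pH", "U^2", "pH^2"))
  expect_setequal(fit_rs$eliminated$term, c("MD^2", "U:MD", "MD:pH"))
  expect_true(all(fit_rs$p_values[fit_rs$terms$type != "intercept"] < 0.1))

  fit_t2 <- study_fit("t2")
  expect_setequal(fit_t2$terms$label,
                  c("(Intercept)", "U", "MD", "pH", "U:pH", "pH^2"))

  # a model whose terms are all already significant is a fixed point
  again <- drop_nonsignificant(fit_rs, alpha = 0.1)
  expect_equal(again$terms$label, fit_rs$terms$label)
  expect_equal(coef(again), coef(fit_rs), tolerance = 1e-12)
})

test_that("residuals are orthogonal to every retained column", {
  fit <- study_fit("Rs")
  expect_lt(max(abs(crossprod(fit$X, residuals(fit)))), 1e-10)
})

test_that("prediction at the center equals the intercept", {
  fit <- study_fit("Rs")
  expect_equal(unname(predict(fit, data.frame(U = 17.5, MD = 8.75, pH = 3))),
               unname(coef(fit)["(Intercept)"]), tolerance = 1e-12)
  # at the all-high corner the prediction is the coefficient sum
  expect_equal(unname(predict(fit, data.frame(U = 20, MD = 10, pH = 4))),
               sum(coef(fit)), tolerance = 1e-12)
})

test_that("interval half-widths behave as the OLS formulas dictate", {
  fit <- study_fit("Rs")
  at <- data.frame(U = 20, MD = 10, pH = 4)
  pi_ <- predict(fit, at, interval = "prediction")
  ci <- predict(fit, at, interval = "confidence")
  expect_gt(pi_$half_width, ci$half_width)
  # explicit formula check
  x <- drop(build_model_matrix(
    code_runs(at, study_domains()), fit$terms))
  lev <- drop(t(x) %*% fit$cov_unscaled %*% x)
  tq <- qt(0.975, fit$df_residual)
  expect_equal(pi_$half_width, tq * fit$rmse * sqrt(1 + lev),
               tolerance = 1e-12)
  expect_equal(ci$half_width, tq * fit$rmse * sqrt(lev), tolerance = 1e-12)
  # half-widths are smallest near the design centroid for this design
  hw_center <- predict(fit, data.frame(U = 17.5, MD = 8.75, pH = 3),
                       interval = "prediction")$half_width
  expect_lt(hw_center, pi_$half_width)
  # exact data gives zero-width intervals
  d <- data.frame(x = seq(-1, 1, 0.5)); d$y <- 1 + 2 * d$x
  f0 <- rsm_quad(y ~ x, d, reduce = FALSE,
                 terms = terms_from_labels(c("(Intercept)", "x"), "x"))
  expect_equal(predict(f0, data.frame(x = 0.3),
                       interval = "prediction")$half_width, 0,
               tolerance = 1e-9)
})

test_that("coded and engineering inputs give the same fit", {
  runs <- study_runs()
  coded <- code_runs(runs, study_domains())
  f_eng <- study_fit("Rs", reduce = FALSE)
  f_cod <- rsm_quad(Rs ~ U + MD + pH, coded, reduce = FALSE)
  expect_equal(coef(f_eng), coef(f_cod), tolerance = 1e-12)
})

test_that("degenerate fits are rejected with informative errors", {
  runs <- study_runs()[1:9, ]
  expect_error(rsm_quad(Rs ~ U + MD + pH, runs, domains = study_domains(),
                        reduce = FALSE), "more runs")
  # rank deficiency: duplicated single point
  d <- data.frame(x = rep(0, 5), y = rnorm(5))
  expect_error(rsm_quad(y ~ x, d, reduce = FALSE,
                        terms = terms_from_labels(c("(Intercept)", "x"), "x")),
               "rank deficient")
})

test_that("simulate() draws responses around the fitted surface", {
  fit <- study_fit("Rs")
  sims <- simulate(fit, nsim = 200, seed = 9)
  expect_equal(dim(sims), c(15, 200))
  m <- rowMeans(as.matrix(sims))
  expect_lt(max(abs(m - fitted(fit))), 4 * fit$rmse / sqrt(200) * 3)
})
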