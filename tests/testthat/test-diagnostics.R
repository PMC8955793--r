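test_that("adjusted response matches the closed-form mean-substitution", {
  fit <- study_fit("Rs")
  b <- coef(fit)
  coded <- code_runs(study_runs()[c("U", "MD", "pH")], study_domains())
  # independent arithmetic: other columns at their design means
  base <- b["(Intercept)"] + b["U"] * mean(coded$U) +
    b["pH"] * mean(coded$pH) + b["U:pH"] * mean(coded$U * coded$pH) +
    b["U^2"] * mean(coded$U^2) + b["pH^2"] * mean(coded$pH^2)
  ar <- adjusted_response(fit, "MD")
  expect_equal(ar$value, unname(base + b["MD"] * c(-1, 0, 1)),
               tolerance = 1e-12)
  # the published narrative scale: about 1.3 at low MD, about 1.8 at high
  expect_equal(ar$value[1], 1.3, tolerance = 0.05)
  expect_equal(ar$value[3], 1.8, tolerance = 0.05)

  ar_ph <- adjusted_response(fit, "pH")
  base_ph <- b["(Intercept)"] + b["U"] * mean(coded$U) +
    b["MD"] * mean(coded$MD) + b["U^2"] * mean(coded$U^2)
  lvl <- c(-1, 0, 1)
  expect_equal(ar_ph$value,
               unname(base_ph + b["pH"] * lvl + b["pH^2"] * lvl^2 +
                        b["U:pH"] * lvl * mean(coded$U)),
               tolerance = 1e-12)
  expect_equal(ar_ph$value[1], 1.7, tolerance = 0.05)
  expect_error(adjusted_response(fit, "flow"), "unknown factor")
})

test_that("Pareto ranking reproduces the published effect ordering", {
  pe <- pareto_effects(study_fit("Rs"))
  expect_equal(pe$term, c("MD", "pH", "U", "U:pH", "pH^2", "U^2"))
  signs <- setNames(pe$sign, pe$term)
  expect_equal(unname(signs[c("MD", "U:pH")]), c(1, 1))
  expect_equal(unname(signs[c("pH", "U", "U^2", "pH^2")]), rep(-1, 4))
  # magnitudes are |coefficient / SE|
  fit <- study_fit("Rs")
  expect_equal(pe$magnitude,
               sort(abs(coef(fit) / fit$se)[-1], decreasing = TRUE),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a zero coefficient ranks last in the Pareto chart", {
  set.seed(3)
  d <- data.frame(a = rep(c(-1, 0, 1), 4), b = rep(c(-1, 1), each = 6))
  d$y <- 1 + 2 * d$a + rnorm(12, 0, 0.1)   # b has no effect
  fit <- rsm_quad(y ~ a + b, d, reduce = FALSE,
                  terms = terms_from_labels(c("(Intercept)", "a", "b"),
                                            c("a", "b")))
  pe <- pareto_effects(fit)
  expect_equal(pe$term[1], "a")
  expect_equal(pe$term[nrow(pe)], "b")
})

test_that("interaction profiles are parallel iff no interaction is retained", {
  fit <- study_fit("Rs")
  # MD-U: no MD:U term retained -> parallel curves
  ip0 <- interaction_profile(fit, "MD", "U")
  expect_lt(attr(ip0, "parallelism"), 1e-10)
  # pH-U: retained interaction -> non-parallel with the analytic statistic
  ip1 <- interaction_profile(fit, "pH", "U")
  expect_equal(attr(ip1, "parallelism"), 2 * abs(coef(fit)["U:pH"]),
               ignore_attr = TRUE, tolerance = 1e-10)
  # every curve point is reproducible through predict()
  row <- ip1[57, ]
  expect_equal(row$value,
               unname(predict(fit, data.frame(U = row$fixed_level, MD = 0,
                                              pH = row$sweep),
                              coded = TRUE)),
               tolerance = 1e-12)
  expect_error(interaction_profile(fit, "pH", "pH"), "must differ")
})

test_that("contour panels flag the baseline-resolution region correctly", {
  fit <- study_fit("Rs")
  hi <- contour_grid(fit, "MD", 1)
  expect_true(hi$iso_contained)
  expect_gte(min(hi$z), 1.5)
  expect_length(hi$iso_lines, 0)

  lo <- contour_grid(fit, "MD", -1)
  expect_false(lo$iso_contained)
  expect_lt(min(lo$z), 1.5)
  expect_gt(length(lo$iso_lines), 0)
  # iso-line points evaluate to the iso level through predict()
  pts <- lo$iso_lines[[1]]
  vals <- predict(fit, data.frame(U = pts$x, pH = pts$y, MD = -1),
                  coded = TRUE)
  expect_lt(max(abs(vals - 1.5)), 0.002)  # grid-interpolation tolerance

  # degenerate iso level: everything is contained
  expect_true(contour_grid(fit, "MD", -1, iso_level = -Inf)$iso_contained)
  expect_warning(contour_grid(fit, "MD", 1.5), "extrapolat")
  # grid values are reproducible through predict()
  expect_equal(hi$z[51, 51],
               unname(predict(fit, data.frame(U = 0, pH = 0, MD = 1),
                              coded = TRUE)),
               tolerance = 1e-12)
})

test_that("plot methods run and return their diagnostic objects", {
  fit <- study_fit("Rs")
  png_file <- tempfile(fileext = ".png")
  grDevices::png(png_file)
  on.exit({grDevices::dev.off(); unlink(png_file)}, add = TRUE)
  expect_s3_class(plot(fit, "pareto"), "pareto_effects")
  expect_s3_class(plot(fit, "adjusted", factor = "MD"), "adjusted_response")
  expect_s3_class(plot(fit, "interaction", sweep = "pH", fixed = "U"),
                  "interaction_profile")
  expect_s3_class(plot(fit, "contour", fixed = "MD", fixed_level = 1),
                  "contour_grid")
})
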