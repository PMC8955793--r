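test_that("traces are bit-identical under a fixed seed", {
  truth <- ground_truth()
  pt <- data.frame(U = -1, MD = 1, pH = -1)
  set.seed(5); tr1 <- simulate_injection(pt, truth)
  set.seed(5); tr2 <- simulate_injection(pt, truth)
  expect_identical(tr1, tr2)
  camp1 <- simulate_campaign(pt, truth, n_injections = 2, seed = 12)
  camp2 <- simulate_campaign(pt, truth, n_injections = 2, seed = 12)
  expect_identical(camp1$responses, camp2$responses)
})

test_that("zero-noise traces round-trip through measurement within 1%", {
  truth <- ground_truth(rs_noise_sd = 0, tm_noise_sd = 0)
  grid <- build_candidates(study_domains())
  for (i in seq_len(nrow(grid))) {
    tr <- simulate_injection(grid[i, ], truth)
    pk <- detect_peaks(tr, min_separation = 0.05)
    expect_equal(nrow(pk), 2)
    rs_target <- attr(tr, "target_rs")
    expect_equal(peak_resolution(pk), rs_target,
                 tolerance = 0.01 * rs_target)
    expect_equal(pk$apex_time[2], attr(tr, "target_t2"),
                 tolerance = 1e-4 * attr(tr, "target_t2"))
  }
})

test_that("the simulated surfaces honour the ground-truth coefficients", {
  # high-MD/low-pH/low-U run: resolution and time implied by the surfaces
  truth <- ground_truth(rs_noise_sd = 0, tm_noise_sd = 0)
  pt <- data.frame(U = -1, MD = 1, pH = -1)
  tr <- simulate_injection(pt, truth)
  pk <- detect_peaks(tr, min_separation = 0.05)
  rs <- sum(amlodipine_coefficients("resolution") *
              c(1, -1, 1, -1, 1, 1, 1))    # published column at (-1,+1,-1)
  t2 <- sum(amlodipine_coefficients("time") * c(1, -1, 1, -1, 1, 1))
  expect_equal(peak_resolution(pk), rs, tolerance = 0.01 * rs)
  expect_equal(pk$apex_time[2], t2, tolerance = 0.01 * t2)
})

test_that("a zero-noise campaign recovers the generating coefficients", {
  truth <- ground_truth(rs_noise_sd = 0, tm_noise_sd = 0)
  coded <- code_runs(study_runs()[c("U", "MD", "pH")], study_domains())
  camp <- simulate_campaign(coded, truth, n_injections = 1, seed = 1,
                            sampling_hz = 50)
  tm <- terms_from_labels(names(amlodipine_coefficients("resolution")))
  fit <- rsm_quad(Rs ~ U + MD + pH, camp$responses, terms = tm,
                  reduce = FALSE)
  expect_lt(max(abs(coef(fit)[names(amlodipine_coefficients("resolution"))] -
                      amlodipine_coefficients("resolution"))), 1e-4)
})

test_that("campaign bookkeeping matches the design size", {
  truth <- ground_truth()
  coded <- code_runs(study_runs()[c("U", "MD", "pH")], study_domains())
  camp <- simulate_campaign(coded[1:3, ], truth, n_injections = 6, seed = 2)
  expect_equal(nrow(camp$injections), 18)
  expect_equal(nrow(camp$responses), 3)
  expect_equal(camp$responses$n, rep(6, 3))
  expect_true(all(camp$responses$Rs_sd >= 0))
})

test_that("tripling the injection noise triples the measured-Rs spread", {
  pt <- data.frame(U = 0, MD = 0, pH = 0)
  meas_sd <- function(sd_rs, n = 200, seed = 31) {
    truth <- ground_truth(rs_noise_sd = sd_rs, tm_noise_sd = 0)
    set.seed(seed)
    rs <- replicate(n, {
      tr <- simulate_injection(pt, truth)
      peak_resolution(detect_peaks(tr, min_separation = 0.05))
    })
    sd(rs)
  }
  s1 <- meas_sd(0.02)
  s3 <- meas_sd(0.06)
  expect_equal(s3 / s1, 3, tolerance = 0.2)
})

test_that("peak area ratios propagate to the enantiomeric ratio", {
  truth <- ground_truth(rs_noise_sd = 0, tm_noise_sd = 0,
                        area_ratio = c(2, 1))
  tr <- simulate_injection(data.frame(U = 0, MD = 0, pH = 0), truth)
  pk <- detect_peaks(tr, min_separation = 0.05)
  expect_equal(unname(enantiomer_ratio(pk)), c(200 / 3, 100 / 3),
               tolerance = 0.5)
})

test_that("pathological ground truths are rejected", {
  # resolution so large that the first peak would migrate before t = 0
  truth <- ground_truth(rs_coef = c("(Intercept)" = 500),
                        tm_coef = c("(Intercept)" = 5),
                        rs_noise_sd = 0, tm_noise_sd = 0)
  expect_error(simulate_injection(data.frame(U = 0, MD = 0, pH = 0), truth),
               "non-positive")
  expect_error(ground_truth(plate_number = -1))
  expect_error(simulate_injection(data.frame(U = 2, MD = 0, pH = 0),
                                  ground_truth()),
               "\\[-1, 1\\]")
})
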