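# The published 15-run optimization campaign, constructed in code so tests
# do not depend on the packaged CSV (one test cross-checks the two).
study_runs <- function() {
  data.frame(
    run = 1:15,
    U  = c(20, 15, 15, 15, 15, 17.5, 17.5, 15, 20, 20, 20, 17.5, 20, 15, 20),
    MD = c(10, 8.75, 10, 10, 10, 10, 7.5, 7.5, 7.5, 10, 8.75, 8.75, 8.75,
           7.5, 7.5),
    pH = c(2, 2, 4, 2, 3, 2, 3, 2, 2, 4, 3, 4, 2, 4, 4),
    Rs = c(1.73, 1.80, 1.61, 2.10, 1.96, 1.93, 1.40, 1.59, 1.31, 1.47,
           1.50, 1.49, 1.46, 1.19, 1.07),
    Rs_sd = c(0.03, 0.02, 0.05, 0.06, 0.08, 0.02, 0.03, 0.04, 0.02, 0.03,
              0.02, 0.08, 0.01, 0.04, 0.04),
    t2 = c(12.15, 16.42, 11.37, 17.83, 16.06, 14.73, 10.46, 15.58, 10.28,
           7.80, 10.19, 8.88, 10.27, 8.62, 6.04),
    t2_sd = c(0.47, 0.39, 0.55, 0.64, 0.58, 0.32, 0.37, 0.80, 0.36, 0.42,
              0.02, 0.77, 0.17, 0.37, 0.31))
}

study_domains <- function() {
  list(factor_domain("U", 15, 17.5, 20, "kV"),
       factor_domain("MD", 7.5, 8.75, 10, "% w/v"),
       factor_domain("pH", 2, 3, 4, "pH"))
}

study_fit <- function(response = "Rs", reduce = TRUE) {
  rsm_quad(stats::as.formula(paste(response, "~ U + MD + pH")),
           data = study_runs(), domains = study_domains(), reduce = reduce)
}

# synthetic Gaussian peak trace on a uniform grid
gaussian_trace <- function(apices, sigmas, areas, t_max = NULL, hz = 20) {
  if (is.null(t_max)) t_max <- max(apices) + 8 * max(sigmas)
  tt <- seq(0, t_max, by = 1 / (60 * hz))
  sig <- rep(0, length(tt))
  for (k in seq_along(apices))
    sig <- sig + areas[k] * stats::dnorm(tt, apices[k], sigmas[k])
  data.frame(time_min = tt, signal = sig)
}
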