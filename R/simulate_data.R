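#' Ground truth for synthetic electropherogram generation
#'
#' Bundles the generative model of the simulator: quadratic response
#' surfaces (named coefficient vectors over coded factors) for the
#' enantiomer resolution and the second-peak migration time, the
#' injection-to-injection noise SDs of the two summary responses, a
#' constant effective plate number controlling peak width, the S:R peak
#' area ratio, and an optional white detector noise SD.
#'
#' Defaults emulate the amlodipine/maltodextrin study conditions: the
#' published coefficient surfaces ([amlodipine_coefficients()]), noise SDs
#' of 0.04 resolution units and 0.45 min (mid-range of the study's
#' per-run SD columns, which span 0.01-0.08 and 0.02-0.80), and a plate
#' number of 50,000 (typical CE efficiency).
#'
#' @param rs_coef Named coefficient vector of the resolution surface.
#' @param tm_coef Named coefficient vector of the migration-time surface
#'   (minutes).
#' @param rs_noise_sd Per-injection SD of the target resolution.
#' @param tm_noise_sd Per-injection SD of the migration time, minutes.
#' @param plate_number Effective plate count N; FWHM follows
#'   `W = t * sqrt(8 ln 2 / N)`.
#' @param area_ratio Length-2 vector of relative peak areas (first,
#'   second).
#' @param trace_noise_sd White noise SD added to the trace, in units of
#'   the taller peak's height.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(rs_coef = amlodipine_coefficients("resolution"),
                         tm_coef = amlodipine_coefficients("time"),
                         rs_noise_sd = 0.04, tm_noise_sd = 0.45,
                         plate_number = 5e4, area_ratio = c(1, 1),
                         trace_noise_sd = 0) {
  stopifnot(is.numeric(rs_coef), !is.null(names(rs_coef)),
            is.numeric(tm_coef), !is.null(names(tm_coef)),
            rs_noise_sd >= 0, tm_noise_sd >= 0, plate_number > 0,
            length(area_ratio) == 2L, all(area_ratio > 0),
            trace_noise_sd >= 0)
  structure(list(rs_coef = rs_coef, tm_coef = tm_coef,
                 rs_noise_sd = rs_noise_sd, tm_noise_sd = tm_noise_sd,
                 plate_number = plate_number, area_ratio = area_ratio,
                 trace_noise_sd = trace_noise_sd),
            class = "ground_truth")
}

#' Simulate one electropherogram injection
#'
#' Draws the injection's migration time and target resolution from the
#' ground-truth surfaces plus Gaussian injection noise (the resolution is
#' truncated at zero), converts them into two equal-width Gaussian peaks —
#' FWHM `W = t2 * sqrt(8 ln 2 / N)` from the plate number, first-peak apex
#' `t1 = t2 - Rs * 2W / 1.18` by exact inversion of the FWHM resolution
#' formula — and samples the summed signal (areas in the ground-truth
#' ratio, total area 1) on a uniform grid over `[0, t2 + 2]` minutes.
#'
#' @param point One-row data frame (or named list) of coded factor levels
#'   in `[-1, 1]`.
#' @param truth A [ground_truth()] object.
#' @param sampling_hz Detector sampling rate, Hz (default 10).
#' @return Trace data frame (`time_min`, `signal`) with attributes
#'   `target_rs`, `target_t2`, `fwhm`, `t1`.
#' @export
simulate_injection <- function(point, truth, sampling_hz = 10) {
  stopifnot(inherits(truth, "ground_truth"))
  point <- as.data.frame(point)
  if (any(abs(unlist(point)) > 1))
    stop("coded factor levels must lie in [-1, 1]", call. = FALSE)
  t2 <- eval_surface(truth$tm_coef, point) +
    stats::rnorm(1L, 0, truth$tm_noise_sd)
  rs <- max(0, eval_surface(truth$rs_coef, point) +
                 stats::rnorm(1L, 0, truth$rs_noise_sd))
  if (t2 <= 0) stop("simulated migration time is non-positive", call. = FALSE)
  W <- t2 * sqrt(8 * log(2) / truth$plate_number)
  t1 <- t2 - rs * 2 * W / 1.18
  if (t1 <= 0)
    stop("first-peak time is non-positive; ground truth is pathological",
         call. = FALSE)
  sigma <- W / sqrt(8 * log(2))
  areas <- truth$area_ratio / sum(truth$area_ratio)
  tt <- seq(0, t2 + 2, by = 1 / (60 * sampling_hz))
  sig <- areas[1L] * stats::dnorm(tt, t1, sigma) +
         areas[2L] * stats::dnorm(tt, t2, sigma)
  if (truth$trace_noise_sd > 0)
    sig <- sig + stats::rnorm(length(tt), 0,
                              truth$trace_noise_sd * max(areas) /
                                (sigma * sqrt(2 * pi)))
  structure(data.frame(time_min = tt, signal = sig),
            target_rs = rs, target_t2 = t2, fwhm = W, t1 = t1)
}

#' Simulate a full design campaign and measure it
#'
#' Generates `n_injections` synthetic traces per design run, pushes every
#' trace through the measurement pipeline ([detect_peaks()],
#' [peak_resolution()]), and aggregates per-run means and SDs of the
#' measured resolution and second-peak migration time — the same summary
#' table an instrument campaign would yield. Deterministic for a given
#' seed.
#'
#' @param design A `doe_design` or a data frame of coded runs.
#' @param truth A [ground_truth()] object.
#' @param n_injections Injections per run (default 6).
#' @param seed Optional integer seed.
#' @param sampling_hz Detector sampling rate for the traces.
#' @param keep_traces Keep the raw traces in the result? (memory)
#' @return A list of class `ekc_campaign`: `responses` (one row per run:
#'   factor levels, `Rs`, `Rs_sd`, `t2`, `t2_sd`, `n`), `injections`
#'   (per-injection measurements), and optionally `traces`.
#' @export
simulate_campaign <- function(design, truth, n_injections = 6, seed = NULL,
                              sampling_hz = 10, keep_traces = FALSE) {
  runs <- if (inherits(design, "doe_design")) design$runs
          else as.data.frame(design)
  stopifnot(nrow(runs) >= 1L, n_injections >= 1L)
  if (!is.null(seed)) set.seed(seed)
  inj_rows <- list(); traces <- list()
  for (r in seq_len(nrow(runs))) {
    for (j in seq_len(n_injections)) {
      tr <- simulate_injection(runs[r, , drop = FALSE], truth,
                               sampling_hz = sampling_hz)
      pk <- detect_peaks(tr, min_separation = 0.05)
      if (nrow(pk) != 2L)
        stop(sprintf("run %d injection %d: expected 2 peaks, found %d",
                     r, j, nrow(pk)), call. = FALSE)
      inj_rows[[length(inj_rows) + 1L]] <- data.frame(
        run = r, injection = j,
        Rs = peak_resolution(pk), t2 = pk$apex_time[2L])
      if (keep_traces) traces[[length(traces) + 1L]] <- tr
    }
  }
  inj <- do.call(rbind, inj_rows)
  agg <- do.call(rbind, lapply(split(inj, inj$run), function(d)
    data.frame(Rs = mean(d$Rs), Rs_sd = stats::sd(d$Rs),
               t2 = mean(d$t2), t2_sd = stats::sd(d$t2),
               n = nrow(d))))
  responses <- cbind(run = seq_len(nrow(runs)), runs, agg)
  rownames(responses) <- NULL
  out <- list(responses = responses, injections = inj,
              truth = truth, n_injections = n_injections, seed = seed)
  if (keep_traces) out$traces <- traces
  class(out) <- "ekc_campaign"
  out
}

#' @export
print.ekc_campaign <- function(x, ...) {
  cat(sprintf("Simulated cEKC campaign: %d runs x %d injections\n",
              nrow(x$responses), x$n_injections))
  print(x$responses)
  invisible(x)
}
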