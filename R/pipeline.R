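#' Run the full method-optimization pipeline
#'
#' End-to-end driver tying the stages together: candidate enumeration and
#' D-optimal design selection, synthetic campaign generation (or use of a
#' supplied run table), response-surface fitting with backward
#' elimination, prediction at requested settings, and effect diagnostics.
#' All randomness flows through the single `seed` entry of the config, so
#' a config run twice yields an identical report.
#'
#' @param config Named list (validated before any stage runs):
#'   \describe{
#'     \item{factors}{list of [factor_domain()]s (default: the amlodipine
#'       domains).}
#'     \item{n_runs, n_starts, seed}{design options (defaults 15, 20, 1).}
#'     \item{data}{optional run table with engineering factor columns and
#'       a response column; when absent a campaign is simulated from
#'       `truth`.}
#'     \item{response}{response column name (default `"Rs"`).}
#'     \item{truth}{[ground_truth()] for simulation (default:
#'       [ground_truth()]).}
#'     \item{n_injections}{injections per simulated run (default 6).}
#'     \item{alpha}{retention level for backward elimination (default
#'       0.1).}
#'     \item{interval, level}{prediction interval kind and coverage
#'       (defaults `"prediction"`, 0.95).}
#'     \item{predict_at}{optional data frame of engineering settings to
#'       predict at.}
#'     \item{contour_fix}{named coded level of the factor fixed in the
#'       contour panel, e.g. `c(MD = 1)`.}
#'     \item{iso_level}{contour iso level (default 1.5).}
#'   }
#' @param out_dir Optional directory; when given, `report.json` plus
#'   `design.csv` and `responses.csv` sidecars are written there.
#' @return A report list with elements `design`, `responses`, `fit`
#'   (terms, coefficients, se, p values, rmse, adj R2), `predictions`,
#'   `pareto`, `contour` (summary), and `config_echo`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  allowed <- c("factors", "n_runs", "n_starts", "seed", "data", "response",
               "truth", "n_injections", "alpha", "interval", "level",
               "predict_at", "contour_fix", "iso_level")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(
    list(factors = amlodipine_domains(), n_runs = 15, n_starts = 20,
         seed = 1, data = NULL, response = "Rs", truth = ground_truth(),
         n_injections = 6, alpha = 0.1, interval = "prediction",
         level = 0.95, predict_at = NULL, contour_fix = NULL,
         iso_level = 1.5),
    config)
  domains <- as_domain_list(cfg$factors)
  factors <- names(domains)
  if (!is.null(cfg$contour_fix) &&
      !all(names(cfg$contour_fix) %in% factors))
    stop("contour_fix names an unknown factor", call. = FALSE)
  if (!is.null(cfg$predict_at)) {
    miss <- setdiff(factors, names(as.data.frame(cfg$predict_at)))
    if (length(miss))
      stop("predict_at lacks factor columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }

  terms <- full_quadratic(factors)
  design <- d_optimal(build_candidates(domains), terms,
                      n_runs = cfg$n_runs, n_starts = cfg$n_starts,
                      seed = cfg$seed)

  if (is.null(cfg$data)) {
    camp <- simulate_campaign(design, cfg$truth,
                              n_injections = cfg$n_injections,
                              seed = cfg$seed)
    runs <- decode_runs(camp$responses, domains)
  } else {
    runs <- as.data.frame(cfg$data)
    miss <- setdiff(c(factors, cfg$response), names(runs))
    if (length(miss))
      stop("data lacks columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
  }

  fml <- stats::as.formula(paste(cfg$response, "~",
                                 paste(factors, collapse = "+")))
  fit <- rsm_quad(fml, runs, domains = domains, reduce = TRUE,
                  alpha = cfg$alpha)

  preds <- NULL
  if (!is.null(cfg$predict_at)) {
    pd <- as.data.frame(cfg$predict_at)
    iv <- predict(fit, pd, interval = cfg$interval, level = cfg$level)
    preds <- cbind(pd, iv)
  }

  contour <- NULL
  if (!is.null(cfg$contour_fix)) {
    cg <- contour_grid(fit, names(cfg$contour_fix)[1L],
                       unname(cfg$contour_fix[1L]),
                       iso_level = cfg$iso_level)
    contour <- list(fixed_factor = cg$fixed_factor,
                    fixed_level = cg$fixed_level,
                    iso_level = cg$iso_level,
                    iso_contained = cg$iso_contained,
                    min_response = min(cg$z), max_response = max(cg$z))
  }

  report <- list(
    schema = "qekc-report/1",
    seed = cfg$seed,
    design = cbind(decode_runs(design$runs, domains),
                   stats::setNames(design$runs,
                                   paste0(factors, "_coded"))),
    design_det = design$det,
    d_efficiency = design$d_efficiency,
    responses = runs,
    fit = list(response = cfg$response, alpha = cfg$alpha,
               terms = fit$terms$label,
               coefficients = as.list(fit$coefficients),
               se = as.list(fit$se), p_values = as.list(fit$p_values),
               rmse = fit$rmse, adj_r2 = fit$adj_r2,
               eliminated = fit$eliminated$term),
    predictions = preds,
    pareto = pareto_effects(fit),
    contour = contour)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    utils::write.csv(report$design, file.path(out_dir, "design.csv"),
                     row.names = FALSE)
    utils::write.csv(report$responses, file.path(out_dir, "responses.csv"),
                     row.names = FALSE)
  }
  invisible(report)
}
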