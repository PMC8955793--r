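#' Published amlodipine enantioseparation study tables
#'
#' The package ships, as plain-text fixtures, the run table, factor
#' domains and reduced-model coefficient tables of the published
#' amlodipine/maltodextrin cEKC optimization study: 15 D-optimally chosen
#' factor combinations of applied voltage `U` (15-20 kV), maltodextrin
#' concentration `MD` (7.5-10% w/v) and background-electrolyte `pH` (2-4),
#' each with the mean and SD over six injections of the enantiomer
#' resolution `Rs` and the second-peak migration time `t2` (minutes).
#'
#' @return `amlodipine_runs()`: data frame with columns `run`, `U`, `MD`,
#'   `pH` (engineering units), `Rs`, `Rs_sd`, `t2`, `t2_sd`.
#' @examples
#' fit <- rsm_quad(Rs ~ U + MD + pH, amlodipine_runs(),
#'                 domains = amlodipine_domains())
#' coef(fit)
#' @export
amlodipine_runs <- function() {
  utils::read.csv(system.file("extdata", "amlodipine_runs.csv",
                              package = "qekc"))
}

#' @rdname amlodipine_runs
#' @return `amlodipine_domains()`: list of [factor_domain()] objects for
#'   `U`, `MD` and `pH`.
#' @export
amlodipine_domains <- function() {
  cfg <- jsonlite::read_json(system.file("extdata",
                                         "amlodipine_factors.json",
                                         package = "qekc"))
  as_domain_list(lapply(cfg, function(f)
    factor_domain(f$name, f$low, f$mid, f$high, f$unit)))
}

#' @rdname amlodipine_runs
#' @param response Which published surface: `"resolution"` (Rs) or
#'   `"time"` (t2, minutes).
#' @param full Return the full table (coefficient, SE, p value, adj R2,
#'   RMSE) instead of the named coefficient vector?
#' @return `amlodipine_coefficients()`: named coefficient vector of the
#'   published reduced model (or, with `full = TRUE`, a list with the
#'   coefficient table and fit statistics).
#' @export
amlodipine_coefficients <- function(response = c("resolution", "time"),
                                    full = FALSE) {
  response <- match.arg(response)
  tab <- jsonlite::read_json(system.file("extdata",
                                         "amlodipine_coefficients.json",
                                         package = "qekc"),
                             simplifyVector = TRUE)[[response]]
  co <- stats::setNames(tab$coefficient, tab$terms)
  if (!full) return(co)
  list(coefficients = co,
       se = stats::setNames(tab$se, tab$terms),
       p_value = stats::setNames(tab$p_value, tab$terms),
       adj_r2 = tab$adj_r2, rmse = tab$rmse)
}
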