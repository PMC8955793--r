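#' Fit a quadratic response-surface model on coded factors
#'
#' The central model of the package. Fits, by ordinary least squares on
#' coded factor levels, the second-order polynomial
#' \deqn{\hat y = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
#'   \sum_{i<j} \beta_{ij} x_i x_j,}
#' and (by default) prunes it by backward elimination: the model is refit
#' after removal of the non-intercept term with the largest p-value, until
#' every remaining term is significant at level `alpha`. Coefficients of
#' eliminated terms are treated as zero for prediction.
#'
#' The response is the per-run mean over replicate injections; standard
#' errors come from \eqn{s^2 (X'X)^{-1}} with
#' \eqn{s^2 = RSS/(n - p)}, p-values from two-sided t tests on
#' `n - p` degrees of freedom, and
#' \eqn{\bar R^2 = 1 - (1 - R^2)(n-1)/(n-p)}.
#'
#' @param formula A symbolic description of the form
#'   `response ~ factor1 + factor2 + ...`; the right-hand side lists the
#'   experimental factors (main effects only — quadratic and interaction
#'   terms are generated internally).
#' @param data Data frame with the response and one column per factor. If
#'   `domains` is supplied the factor columns are interpreted in
#'   engineering units and coded internally; otherwise they must already
#'   be coded.
#' @param domains Optional list of [factor_domain()] objects for coding.
#' @param terms Optional `quad_terms` set to fit instead of the full
#'   quadratic (e.g. an already-reduced model).
#' @param reduce Logical: apply backward elimination at level `alpha`?
#' @param alpha Significance level for retaining a term (default 0.1).
#' @return An object of class `rsm_quad` with components `coefficients`,
#'   `se`, `p_values`, `df_residual`, `rmse`, `r2`, `adj_r2`, `coef_cov`
#'   (scaled coefficient covariance), `cov_unscaled`, `terms`, `factors`,
#'   `domains`, `runs` (coded), `X`, `y`, `fitted.values`, `residuals`,
#'   `alpha`, `eliminated` (drop trace) and `call`. Methods:
#'   [predict.rsm_quad()], `print`, `summary`, `coef`, `vcov`,
#'   `residuals`, `fitted`, [simulate.rsm_quad()], [plot.rsm_quad()].
#' @examples
#' runs <- amlodipine_runs()
#' fit <- rsm_quad(Rs ~ U + MD + pH, data = runs,
#'                 domains = amlodipine_domains())
#' summary(fit)
#' predict(fit, data.frame(U = 20, MD = 10, pH = 4), interval = "prediction")
#' @export
rsm_quad <- function(formula, data, domains = NULL, terms = NULL,
                     reduce = TRUE, alpha = 0.1) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  response <- all.vars(formula[[2L]])
  factors <- all.vars(formula[[3L]])
  if (length(response) != 1L || !length(factors))
    stop("formula must be of the form response ~ f1 + f2 + ...", call. = FALSE)
  miss <- setdiff(c(response, factors), names(data))
  if (length(miss))
    stop("columns not found in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(domains)) {
    domains <- as_domain_list(domains)
    if (!setequal(names(domains), factors))
      stop("domain names must match the formula factors", call. = FALSE)
    domains <- domains[factors]
    coded <- code_runs(data[factors], domains)
  } else {
    coded <- data[factors]
  }
  y <- data[[response]]
  if (!is.numeric(y) || anyNA(y)) stop("response must be numeric without NA",
                                       call. = FALSE)
  if (is.null(terms)) terms <- full_quadratic(factors)

  fit <- rsm_ols(coded, y, terms)
  eliminated <- data.frame(term = character(), p_value = numeric())
  if (reduce) {
    repeat {
      pv <- fit$p_values
      cand <- which(fit$terms$type != "intercept" & pv >= alpha)
      if (!length(cand)) break
      # drop the worst term; ties on p broken by later term order
      worst_p <- max(pv[cand])
      drop_k <- max(cand[pv[cand] == worst_p])
      eliminated <- rbind(eliminated,
                          data.frame(term = fit$terms$label[drop_k],
                                     p_value = pv[drop_k]))
      keep <- fit$terms$label[-drop_k]
      fit <- rsm_ols(coded, y, subset_terms(terms, keep))
    }
  }

  fit$factors <- factors
  fit$domains <- domains
  fit$runs <- coded
  fit$response <- response
  fit$alpha <- alpha
  fit$eliminated <- eliminated
  fit$call <- match.call()
  class(fit) <- "rsm_quad"
  fit
}

# OLS core via QR (stats::lm.fit); se, p, covariance computed explicitly
rsm_ols <- function(coded, y, terms) {
  X <- build_model_matrix(coded, terms)
  n <- nrow(X); p <- ncol(X)
  if (n <= p)
    stop(sprintf("need more runs (%d) than model terms (%d)", n, p),
         call. = FALSE)
  lf <- stats::lm.fit(X, y)
  if (lf$rank < p)
    stop("model matrix is rank deficient for this design", call. = FALSE)
  beta <- lf$coefficients
  res <- lf$residuals
  df <- n - p
  rss <- sum(res^2)
  s2 <- rss / df
  XtXinv <- chol2inv(qr.R(lf$qr))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  se <- sqrt(s2 * diag(XtXinv))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  list(coefficients = beta, se = se, t_values = tval, p_values = pval,
       df_residual = df, rmse = sqrt(s2), r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / df,
       coef_cov = s2 * XtXinv, cov_unscaled = XtXinv,
       terms = terms, X = X, y = y,
       fitted.values = drop(X %*% beta), residuals = res)
}

#' @export
print.rsm_quad <- function(x, digits = 4, ...) {
  cat("Quadratic response-surface model (coded factors)\n")
  cat("Response:", x$response, "  runs:", nrow(x$X),
      "  terms:", ncol(x$X), "\n")
  print(round(x$coefficients, digits))
  cat(sprintf("RMSE %.4g on %d df, adj R-squared %.4g\n",
              x$rmse, x$df_residual, x$adj_r2))
  invisible(x)
}

#' @export
summary.rsm_quad <- function(object, ...) {
  tab <- cbind(Coefficient = object$coefficients, SE = object$se,
               t = object$t_values, `p value` = object$p_values)
  structure(list(coefficients = tab, rmse = object$rmse,
                 adj_r2 = object$adj_r2, r2 = object$r2,
                 df_residual = object$df_residual,
                 response = object$response, alpha = object$alpha,
                 eliminated = object$eliminated, call = object$call),
            class = "summary.rsm_quad")
}

#' @export
print.summary.rsm_quad <- function(x, digits = 4, ...) {
  cat("Quadratic response-surface fit:", x$response, "\n\n")
  stats::printCoefmat(x$coefficients, digits = digits,
                      P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nRMSE %.4g on %d df, R-squared %.4g, adj R-squared %.4g\n",
              x$rmse, x$df_residual, x$r2, x$adj_r2))
  if (nrow(x$eliminated)) {
    cat(sprintf("Terms eliminated at alpha = %g: %s\n", x$alpha,
                paste(x$eliminated$term, collapse = ", ")))
  }
  invisible(x)
}

#' @export
coef.rsm_quad <- function(object, ...) object$coefficients

#' @export
vcov.rsm_quad <- function(object, ...) object$coef_cov

#' @export
residuals.rsm_quad <- function(object, ...) object$residuals

#' @export
fitted.rsm_quad <- function(object, ...) object$fitted.values

#' Predict from a response-surface fit
#'
#' Evaluates the fitted polynomial at new factor settings, optionally with
#' a confidence or prediction interval: the half width is
#' \eqn{t_{1-(1-level)/2, df} \, s \sqrt{\delta + x'(X'X)^{-1}x}} with
#' \eqn{\delta = 1} for prediction intervals and 0 for confidence
#' intervals.
#'
#' @param object An `rsm_quad` fit.
#' @param newdata Data frame with one column per factor. Interpreted in
#'   engineering units when the fit holds domains (unless `coded = TRUE`);
#'   otherwise as coded levels. Defaults to the design runs.
#' @param interval `"none"`, `"prediction"` or `"confidence"`.
#' @param level Coverage probability of the interval.
#' @param coded Set `TRUE` if `newdata` is already coded although the fit
#'   holds domains.
#' @param ... Unused.
#' @return A numeric vector for `interval = "none"`, otherwise a data
#'   frame with columns `fit`, `lwr`, `upr`, `half_width`.
#' @export
predict.rsm_quad <- function(object, newdata = NULL,
                             interval = c("none", "prediction", "confidence"),
                             level = 0.95, coded = is.null(object$domains),
                             ...) {
  interval <- match.arg(interval)
  if (is.null(newdata)) {
    pts <- object$runs
  } else {
    newdata <- as.data.frame(newdata)
    miss <- setdiff(object$factors, names(newdata))
    if (length(miss))
      stop("newdata lacks factor columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    pts <- newdata[object$factors]
    if (!coded) pts <- code_runs(pts, object$domains)
  }
  X <- build_model_matrix(pts, object$terms)
  yhat <- drop(X %*% object$coefficients)
  if (interval == "none") return(yhat)
  delta <- if (interval == "prediction") 1 else 0
  lev <- drop(rowSums((X %*% object$cov_unscaled) * X))
  hw <- stats::qt(1 - (1 - level) / 2, object$df_residual) *
    object$rmse * sqrt(delta + lev)
  data.frame(fit = yhat, lwr = yhat - hw, upr = yhat + hw, half_width = hw)
}

#' Simulate responses from a fitted response surface
#'
#' Draws `nsim` response vectors at the design runs, each the fitted value
#' plus iid Gaussian noise with standard deviation equal to the residual
#' RMSE — the parametric bootstrap convention of [stats::simulate()].
#'
#' @param object An `rsm_quad` fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns of simulated responses.
#' @export
simulate.rsm_quad <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted.values)
  out <- as.data.frame(
    matrix(object$fitted.values + stats::rnorm(n * nsim, 0, object$rmse),
           n, nsim, dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
  out
}

#' Drop non-significant terms from a fitted model
#'
#' Re-runs backward elimination on an existing fit at a (possibly new)
#' significance level and returns the reduced refit.
#'
#' @param fit An `rsm_quad` fit.
#' @param alpha Significance level for retention.
#' @return A reduced `rsm_quad` fit.
#' @export
drop_nonsignificant <- function(fit, alpha = 0.1) {
  stopifnot(inherits(fit, "rsm_quad"))
  data <- cbind(fit$runs, stats::setNames(data.frame(fit$y), fit$response))
  rsm_quad(stats::as.formula(paste(fit$response, "~",
                                   paste(fit$factors, collapse = "+"))),
           data = data, domains = NULL, terms = fit$terms,
           reduce = TRUE, alpha = alpha)
}
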