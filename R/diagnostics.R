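#' Adjusted response of a single factor
#'
#' The predicted response at each coded level of one factor while the
#' effects of everything else are averaged out: every other model column is
#' replaced by its mean over the design runs, and interaction columns that
#' involve the factor use the level times the design mean of the partner
#' factor. All values are reproducible through the fitted coefficients; no
#' independent model math is involved.
#'
#' @param fit An `rsm_quad` fit.
#' @param factor Name of the factor to profile.
#' @param levels Coded levels at which to evaluate (default -1, 0, +1).
#' @return Data frame of class `adjusted_response` with columns `factor`,
#'   `level`, `value`.
#' @export
adjusted_response <- function(fit, factor, levels = c(-1, 0, 1)) {
  stopifnot(inherits(fit, "rsm_quad"))
  if (!factor %in% fit$factors)
    stop("unknown factor: ", factor, call. = FALSE)
  tm <- fit$terms
  colmeans <- colMeans(fit$X)
  partner_mean <- function(f) mean(fit$runs[[f]])
  value_at <- function(l) {
    x <- colmeans
    for (k in seq_len(nrow(tm))) {
      involved <- identical(tm$f1[k], factor) || identical(tm$f2[k], factor)
      if (!involved) next
      x[k] <- switch(tm$type[k],
        main        = l,
        quadratic   = l^2,
        interaction = l * partner_mean(if (identical(tm$f1[k], factor))
                                         tm$f2[k] else tm$f1[k]))
    }
    sum(x * fit$coefficients)
  }
  out <- data.frame(factor = factor, level = levels,
                    value = vapply(levels, value_at, 0))
  class(out) <- c("adjusted_response", "data.frame")
  out
}

#' Pareto chart data of standardized effects
#'
#' Ranks the non-intercept terms of a fit by the magnitude of their
#' t statistic (coefficient divided by standard error), signed by the
#' coefficient. The t scale — not the raw coefficient — makes terms with
#' different column scalings comparable and reproduces the customary
#' effect ordering.
#'
#' @param fit An `rsm_quad` fit with at least one non-intercept term.
#' @return Data frame of class `pareto_effects` with columns `term`,
#'   `t_value`, `magnitude`, `sign`, sorted by decreasing magnitude.
#' @export
pareto_effects <- function(fit) {
  stopifnot(inherits(fit, "rsm_quad"))
  keep <- fit$terms$type != "intercept"
  if (!any(keep)) stop("fit has no non-intercept terms", call. = FALSE)
  tv <- (fit$coefficients / fit$se)[keep]
  out <- data.frame(term = fit$terms$label[keep], t_value = tv,
                    magnitude = abs(tv), sign = ifelse(tv >= 0, 1, -1))
  out <- out[order(-out$magnitude), ]
  rownames(out) <- NULL
  class(out) <- c("pareto_effects", "data.frame")
  out
}

#' Interaction profile of two factors
#'
#' Predicted response along one factor on a continuous coded scale, with a
#' second factor fixed at each of several levels and all remaining factors
#' held at 0. Parallel curves indicate no interaction; the attached
#' `parallelism` statistic is the largest absolute deviation of the
#' (high minus low) curve difference from its mean over the sweep, which is
#' zero exactly when no interaction term links the two factors.
#'
#' @param fit An `rsm_quad` fit.
#' @param sweep Factor varied continuously.
#' @param fixed Factor held at `fixed_levels`.
#' @param fixed_levels Coded levels of the fixed factor.
#' @param n Number of sweep grid points.
#' @return Data frame of class `interaction_profile` with columns `sweep`
#'   (coded level), `fixed_level`, `value`, and attributes `sweep_factor`,
#'   `fixed_factor`, `parallelism`.
#' @export
interaction_profile <- function(fit, sweep, fixed,
                                fixed_levels = c(-1, 0, 1), n = 101) {
  stopifnot(inherits(fit, "rsm_quad"))
  bad <- setdiff(c(sweep, fixed), fit$factors)
  if (length(bad))
    stop("unknown factor: ", paste(bad, collapse = ", "), call. = FALSE)
  if (identical(sweep, fixed))
    stop("sweep and fixed factor must differ", call. = FALSE)
  grid <- seq(-1, 1, length.out = n)
  curves <- lapply(fixed_levels, function(l) {
    pts <- as.data.frame(stats::setNames(rep(list(0), length(fit$factors)),
                                         fit$factors))[rep(1L, n), , drop = FALSE]
    pts[[sweep]] <- grid
    pts[[fixed]] <- l
    data.frame(sweep = grid, fixed_level = l,
               value = predict(fit, pts, coded = TRUE))
  })
  out <- do.call(rbind, curves)
  rownames(out) <- NULL
  dif <- curves[[length(curves)]]$value - curves[[1L]]$value
  attr(out, "sweep_factor") <- sweep
  attr(out, "fixed_factor") <- fixed
  attr(out, "parallelism") <- max(abs(dif - mean(dif)))
  class(out) <- c("interaction_profile", "data.frame")
  out
}

#' Contour grid of the fitted surface with a resolution iso-line
#'
#' Predicted response over a square grid of two coded factors with the
#' third fixed, plus the iso-line at `iso_level` (by default the baseline
#' resolution criterion 1.5) extracted by marching-squares interpolation.
#' `iso_contained` reports whether the whole panel satisfies the criterion
#' (minimum of the grid at or above `iso_level`) — the "no red line" case.
#'
#' @param fit An `rsm_quad` fit over exactly three factors.
#' @param fixed_factor Name of the factor to fix.
#' @param fixed_level Coded level of the fixed factor; values outside
#'   `[-1, 1]` trigger an extrapolation warning.
#' @param n Grid resolution per axis (default 101).
#' @param iso_level Iso-line level (default 1.5).
#' @return List of class `contour_grid` with elements `x`, `y` (grid
#'   coordinates), `z` (n-by-n prediction matrix; rows follow `x`),
#'   `free_factors`, `fixed_factor`, `fixed_level`, `iso_level`,
#'   `iso_contained`, and `iso_lines` (list of `x`/`y` paths, possibly
#'   empty).
#' @export
contour_grid <- function(fit, fixed_factor, fixed_level, n = 101,
                         iso_level = 1.5) {
  stopifnot(inherits(fit, "rsm_quad"))
  if (length(fit$factors) != 3L)
    stop("contour_grid requires a three-factor model", call. = FALSE)
  if (!fixed_factor %in% fit$factors)
    stop("unknown factor: ", fixed_factor, call. = FALSE)
  if (abs(fixed_level) > 1)
    warning("fixed level outside [-1, 1]: extrapolating the surface")
  free <- setdiff(fit$factors, fixed_factor)
  g <- seq(-1, 1, length.out = n)
  pts <- expand.grid(x = g, y = g, KEEP.OUT.ATTRS = FALSE)
  newd <- data.frame(pts$x, pts$y, fixed_level)
  names(newd) <- c(free, fixed_factor)
  z <- matrix(predict(fit, newd, coded = TRUE), n, n)
  iso <- grDevices::contourLines(g, g, z, levels = iso_level)
  structure(list(x = g, y = g, z = z, free_factors = free,
                 fixed_factor = fixed_factor, fixed_level = fixed_level,
                 iso_level = iso_level,
                 iso_contained = min(z) >= iso_level,
                 iso_lines = lapply(iso, function(l) l[c("x", "y")])),
            class = "contour_grid")
}

#' Plot diagnostics of a response-surface fit
#'
#' Base-graphics renderings of the standard DoE diagnostics: the Pareto
#' chart of standardized effects, adjusted response profiles, interaction
#' profiles, or a filled contour panel with the iso-line overlaid.
#'
#' @param x An `rsm_quad` fit.
#' @param which One of `"pareto"`, `"adjusted"`, `"interaction"`,
#'   `"contour"`.
#' @param factor,sweep,fixed Factor names for the profile plots (defaults:
#'   first factors of the model).
#' @param fixed_level,iso_level Contour panel settings.
#' @param ... Passed to the underlying plotting calls.
#' @return Invisibly, the diagnostic object that was plotted.
#' @export
plot.rsm_quad <- function(x, which = c("pareto", "adjusted", "interaction",
                                       "contour"),
                          factor = x$factors[1L], sweep = x$factors[1L],
                          fixed = x$factors[2L], fixed_level = 0,
                          iso_level = 1.5, ...) {
  which <- match.arg(which)
  obj <- switch(which,
    pareto = {
      pe <- pareto_effects(x)
      graphics::barplot(rev(pe$t_value), names.arg = rev(pe$term),
                        horiz = TRUE, las = 1,
                        xlab = "standardized effect (t)",
                        main = paste("Pareto of effects:", x$response), ...)
      graphics::abline(v = 0)
      pe
    },
    adjusted = {
      ar <- adjusted_response(x, factor)
      graphics::plot(ar$level, ar$value, type = "b", xlab = factor,
                     ylab = paste("adjusted", x$response),
                     main = "Adjusted response", ...)
      ar
    },
    interaction = {
      ip <- interaction_profile(x, sweep, fixed)
      lv <- unique(ip$fixed_level)
      graphics::matplot(
        matrix(ip$sweep, ncol = length(lv)),
        matrix(ip$value, ncol = length(lv)), type = "l", lty = 1,
        xlab = sweep, ylab = paste("predicted", x$response),
        main = paste0("Interaction: ", sweep, " x ", fixed), ...)
      graphics::legend("topright", legend = paste(fixed, "=", lv),
                       lty = 1, col = seq_along(lv), bty = "n")
      ip
    },
    contour = {
      cg <- contour_grid(x, fixed, fixed_level, iso_level = iso_level)
      graphics::image(cg$x, cg$y, cg$z, xlab = cg$free_factors[1L],
                      ylab = cg$free_factors[2L],
                      main = sprintf("%s (%s = %g)", x$response,
                                     cg$fixed_factor, cg$fixed_level), ...)
      graphics::contour(cg$x, cg$y, cg$z, add = TRUE)
      for (l in cg$iso_lines)
        graphics::lines(l$x, l$y, col = "red", lwd = 2)
      cg
    })
  invisible(obj)
}
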