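#' Define an experimental factor domain
#'
#' A factor domain gives the engineering levels of one separation factor at
#' its low, mid and high settings. Statistics are computed on coded levels:
#' `low` maps to -1, `mid` to 0 and `high` to +1, so that regression
#' coefficients of different factors are directly comparable.
#'
#' @param name Short factor label, e.g. `"U"`, `"MD"`, `"pH"`.
#' @param low,mid,high Engineering values of the three levels
#'   (`low < mid < high`). `mid` defaults to the midpoint.
#' @param unit Unit string, e.g. `"kV"`, `"% w/v"`; informational only.
#' @return An object of class `factor_domain`.
#' @seealso [code_value()], [build_candidates()], [amlodipine_domains()]
#' @examples
#' U <- factor_domain("U", 15, 17.5, 20, unit = "kV")
#' code_value(U, 20)    # +1
#' code_value(U, 16.25) # -0.5
#' @export
factor_domain <- function(name, low, mid = (low + high) / 2, high, unit = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(low), is.numeric(mid), is.numeric(high),
            length(low) == 1L, length(mid) == 1L, length(high) == 1L,
            is.finite(low), is.finite(mid), is.finite(high))
  if (!(low < mid && mid < high))
    stop("factor domain requires low < mid < high", call. = FALSE)
  structure(list(name = name, low = low, mid = mid, high = high,
                 unit = as.character(unit)),
            class = "factor_domain")
}

#' @export
print.factor_domain <- function(x, ...) {
  cat(sprintf("factor %s [%s]: -1 = %g, 0 = %g, +1 = %g\n",
              x$name, x$unit, x$low, x$mid, x$high))
  invisible(x)
}

as_domain_list <- function(domains) {
  if (inherits(domains, "factor_domain")) domains <- list(domains)
  if (!length(domains) || !all(vapply(domains, inherits, TRUE, "factor_domain")))
    stop("'domains' must be a list of factor_domain objects", call. = FALSE)
  names(domains) <- vapply(domains, `[[`, "", "name")
  domains
}

#' Code and decode engineering factor levels
#'
#' Coding maps an engineering value onto the standardized scale where the
#' domain's low/mid/high levels become -1/0/+1:
#' `coded = (value - mid) / ((high - low)/2)`. `decode_value()` is the exact
#' inverse. Values outside `[low, high]` are allowed and return coded values
#' outside `[-1, 1]` (extrapolation; callers may flag it).
#'
#' @param domain A [factor_domain()].
#' @param value Numeric vector of engineering values.
#' @param coded Numeric vector of coded values.
#' @return Numeric vector of coded (resp. engineering) values.
#' @export
code_value <- function(domain, value) {
  stopifnot(inherits(domain, "factor_domain"), is.numeric(value))
  (value - domain$mid) / ((domain$high - domain$low) / 2)
}

#' @rdname code_value
#' @export
decode_value <- function(domain, coded) {
  stopifnot(inherits(domain, "factor_domain"), is.numeric(coded))
  coded * (domain$high - domain$low) / 2 + domain$mid
}

#' Code (or decode) the factor columns of a run table
#'
#' Matches data-frame columns to domains by name and applies [code_value()]
#' (or [decode_value()]) to each; other columns pass through unchanged.
#'
#' @param data A data frame with one column per factor, named as the domains.
#' @param domains List of [factor_domain()] objects.
#' @return The data frame with factor columns replaced by their coded
#'   (resp. engineering) values.
#' @export
code_runs <- function(data, domains) {
  domains <- as_domain_list(domains)
  miss <- setdiff(names(domains), names(data))
  if (length(miss))
    stop("missing factor columns: ", paste(miss, collapse = ", "), call. = FALSE)
  for (nm in names(domains)) data[[nm]] <- code_value(domains[[nm]], data[[nm]])
  data
}

#' @rdname code_runs
#' @export
decode_runs <- function(data, domains) {
  domains <- as_domain_list(domains)
  miss <- setdiff(names(domains), names(data))
  if (length(miss))
    stop("missing factor columns: ", paste(miss, collapse = ", "), call. = FALSE)
  for (nm in names(domains)) data[[nm]] <- decode_value(domains[[nm]], data[[nm]])
  data
}

#' Enumerate the three-level factorial candidate grid
#'
#' Builds the full factorial grid of coded levels \{-1, 0, +1\} over the given
#' domains: the candidate set from which a D-optimal subset is selected.
#' Enumeration is deterministic and order-stable (lexicographic with the
#' first factor varying fastest).
#'
#' @param domains List of [factor_domain()] objects.
#' @return Data frame of coded candidate points, one column per factor,
#'   `3^K` rows for `K` factors.
#' @seealso [d_optimal()]
#' @export
build_candidates <- function(domains) {
  domains <- as_domain_list(domains)
  grid <- do.call(expand.grid,
                  c(stats::setNames(rep(list(c(-1, 0, 1)), length(domains)),
                                    names(domains)),
                    KEEP.OUT.ATTRS = FALSE))
  as.data.frame(grid)
}

#' Electric field strength of a CE separation
#'
#' Converts an applied voltage and capillary total length into the field
#' strength customarily reported next to the voltage, rounded to the nearest
#' integer V/cm.
#'
#' @param voltage_kv Applied voltage in kV.
#' @param total_length_cm Capillary total length in cm.
#' @return Field strength in V/cm (rounded).
#' @examples
#' field_strength(20, 45.5)  # 440
#' field_strength(15.5, 47)  # 330
#' @export
field_strength <- function(voltage_kv, total_length_cm) {
  stopifnot(is.numeric(voltage_kv), is.numeric(total_length_cm))
  if (any(voltage_kv <= 0) || any(total_length_cm <= 0))
    stop("voltage and capillary length must be positive", call. = FALSE)
  round(1000 * voltage_kv / total_length_cm)
}
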