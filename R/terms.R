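#' Polynomial model terms for response-surface fitting
#'
#' A term set describes the columns of the polynomial model matrix: the
#' intercept, main effects `x_i`, pure quadratics `x_i^2`, and two-way
#' interactions `x_i x_j`. `full_quadratic()` builds the complete
#' second-order set: for `K` factors it has `1 + 2K + K(K-1)/2` terms
#' (10 for `K = 3`).
#'
#' Term labels follow a fixed convention used throughout the package:
#' `"(Intercept)"`, `"U"`, `"U^2"`, `"U:pH"` (interaction factors in the
#' order the factors were declared).
#'
#' @param factors Character vector of factor names.
#' @return An object of class `quad_terms`: a data frame with columns
#'   `type` (`intercept`, `main`, `quadratic`, `interaction`), `f1`, `f2`
#'   and `label`.
#' @examples
#' full_quadratic(c("U", "MD", "pH"))
#' @export
full_quadratic <- function(factors) {
  stopifnot(is.character(factors), length(factors) >= 1L,
            !anyDuplicated(factors))
  K <- length(factors)
  rows <- list(data.frame(type = "intercept", f1 = NA_character_,
                          f2 = NA_character_, label = "(Intercept)"))
  for (f in factors)
    rows[[length(rows) + 1L]] <- data.frame(type = "main", f1 = f,
                                            f2 = NA_character_, label = f)
  for (f in factors)
    rows[[length(rows) + 1L]] <- data.frame(type = "quadratic", f1 = f,
                                            f2 = NA_character_,
                                            label = paste0(f, "^2"))
  if (K >= 2L)
    for (i in seq_len(K - 1L)) for (j in seq(i + 1L, K))
      rows[[length(rows) + 1L]] <- data.frame(
        type = "interaction", f1 = factors[i], f2 = factors[j],
        label = paste(factors[i], factors[j], sep = ":"))
  out <- do.call(rbind, rows)
  structure(out, factors = factors, class = c("quad_terms", "data.frame"))
}

#' @export
print.quad_terms <- function(x, ...) {
  cat("polynomial terms (", nrow(x), "):\n  ",
      paste(x$label, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# keep a subset of a term set by label, preserving attributes
subset_terms <- function(terms, labels) {
  keep <- terms$label %in% labels
  out <- terms[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, factors = attr(terms, "factors"),
            class = c("quad_terms", "data.frame"))
}

#' Reconstruct a term set from term labels
#'
#' Parses labels of the package's convention (`"(Intercept)"`, `"U"`,
#' `"U^2"`, `"U:pH"`) back into a `quad_terms` object, e.g. to evaluate a
#' published coefficient table as a response surface.
#'
#' @param labels Character vector of term labels.
#' @param factors Factor names; inferred from the labels when omitted.
#' @return A `quad_terms` object with one row per label, in label order.
#' @export
terms_from_labels <- function(labels, factors = NULL) {
  stopifnot(is.character(labels), length(labels) >= 1L,
            !anyDuplicated(labels))
  parse1 <- function(lab) {
    if (lab == "(Intercept)")
      return(data.frame(type = "intercept", f1 = NA_character_,
                        f2 = NA_character_, label = lab))
    if (grepl("\\^2$", lab))
      return(data.frame(type = "quadratic", f1 = sub("\\^2$", "", lab),
                        f2 = NA_character_, label = lab))
    if (grepl(":", lab, fixed = TRUE)) {
      fs <- strsplit(lab, ":", fixed = TRUE)[[1L]]
      if (length(fs) != 2L) stop("bad interaction label: ", lab, call. = FALSE)
      return(data.frame(type = "interaction", f1 = fs[1L], f2 = fs[2L],
                        label = lab))
    }
    data.frame(type = "main", f1 = lab, f2 = NA_character_, label = lab)
  }
  out <- do.call(rbind, lapply(labels, parse1))
  if (is.null(factors)) {
    factors <- unique(stats::na.omit(c(rbind(out$f1, out$f2))))
  }
  structure(out, factors = factors, class = c("quad_terms", "data.frame"))
}

#' Build a polynomial model matrix from coded points
#'
#' One row per point, one column per term, columns ordered and labelled as
#' in the term set. The intercept column is all ones; quadratic columns are
#' squared coded levels; interaction columns are products.
#'
#' @param points Data frame (or matrix with column names) of coded factor
#'   levels; must contain every factor the term set references.
#' @param terms A `quad_terms` object, e.g. from [full_quadratic()].
#' @return Numeric matrix with `nrow(points)` rows and `nrow(terms)` columns.
#' @export
build_model_matrix <- function(points, terms) {
  stopifnot(inherits(terms, "quad_terms"))
  points <- as.data.frame(points)
  needed <- unique(stats::na.omit(c(terms$f1, terms$f2)))
  miss <- setdiff(needed, names(points))
  if (length(miss))
    stop("points lack factor columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- nrow(points)
  X <- matrix(NA_real_, n, nrow(terms),
              dimnames = list(NULL, terms$label))
  for (k in seq_len(nrow(terms))) {
    X[, k] <- switch(terms$type[k],
      intercept   = rep(1, n),
      main        = points[[terms$f1[k]]],
      quadratic   = points[[terms$f1[k]]]^2,
      interaction = points[[terms$f1[k]]] * points[[terms$f2[k]]])
  }
  if (anyNA(X) || any(!is.finite(X)))
    stop("non-finite values in model matrix", call. = FALSE)
  X
}

#' Evaluate a named coefficient vector as a response surface
#'
#' Treats a named coefficient vector (labels per the package convention) as
#' a polynomial surface over coded factors and evaluates it at the given
#' points. Useful for published coefficient tables and for the synthetic
#' ground-truth surfaces.
#'
#' @param coef Named numeric vector of polynomial coefficients.
#' @param points Data frame of coded factor levels.
#' @return Numeric vector of surface values, one per row of `points`.
#' @examples
#' co <- c("(Intercept)" = 1.67, MD = 0.224)
#' eval_surface(co, data.frame(MD = c(-1, 1)))
#' @export
eval_surface <- function(coef, points) {
  stopifnot(is.numeric(coef), !is.null(names(coef)))
  tm <- terms_from_labels(names(coef))
  drop(build_model_matrix(points, tm) %*% coef)
}
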