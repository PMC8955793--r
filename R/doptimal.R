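#' Select a D-optimal run subset by Fedorov exchange
#'
#' Searches for the `n_runs`-point subset of a candidate grid that maximizes
#' the determinant of the information matrix \eqn{X'X} of the polynomial
#' model, i.e. minimizes the generalized variance of the coefficient
#' estimates. The search is a classical single-point Fedorov exchange: from
#' a random nonsingular start, every (design point, candidate) swap is
#' scored and the swap with the largest determinant gain is applied,
#' repeating until no swap improves; the whole procedure is restarted from
#' `n_starts` random starts and the best design returned. Candidates may be
#' selected more than once (replicated runs are legitimate in D-optimal
#' designs). Determinant gains are accepted only above a small relative
#' threshold, and candidate ties are broken by lowest candidate index, so
#' the result is reproducible for a given seed.
#'
#' @param candidates Data frame of coded candidate points (e.g. from
#'   [build_candidates()]).
#' @param terms Model term set ([full_quadratic()] or a subset).
#' @param n_runs Number of runs to select; must be at least the number of
#'   model terms.
#' @param n_starts Number of random restarts.
#' @param seed Integer seed controlling the random starts; `NULL` leaves
#'   the RNG state alone.
#' @param max_sweeps Safety cap on exchange sweeps per start.
#' @return An object of class `doe_design`: a list with `runs` (the coded
#'   design points), `indices` (candidate rows, with replacement), `terms`,
#'   `X` (model matrix), `det` (det of `X'X`), `d_efficiency` (percent),
#'   and `history` (the non-decreasing determinant trajectory of the best
#'   start).
#' @seealso [d_efficiency()]
#' @examples
#' dom <- amlodipine_domains()
#' cand <- build_candidates(dom)
#' des <- d_optimal(cand, full_quadratic(names(cand)), n_runs = 15,
#'                  n_starts = 5, seed = 1)
#' des$d_efficiency
#' @export
d_optimal <- function(candidates, terms, n_runs, n_starts = 20, seed = NULL,
                      max_sweeps = 200) {
  candidates <- as.data.frame(candidates)
  stopifnot(inherits(terms, "quad_terms"), nrow(candidates) >= 1L)
  Xc <- build_model_matrix(candidates, terms)
  p <- ncol(Xc)
  nc <- nrow(Xc)
  if (n_runs < p)
    stop(sprintf("n_runs (%d) must be at least the number of model terms (%d)",
                 n_runs, p), call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }

  det_of <- function(idx) det(crossprod(Xc[idx, , drop = FALSE]))

  best <- NULL
  for (s in seq_len(n_starts)) {
    # random nonsingular start (bounded retries)
    idx <- NULL
    for (try in seq_len(100L)) {
      cand_idx <- sample.int(nc, n_runs, replace = n_runs > nc)
      if (det_of(cand_idx) > 1e-12) { idx <- cand_idx; break }
    }
    if (is.null(idx)) next
    d_cur <- det_of(idx)
    hist <- d_cur
    for (sweep in seq_len(max_sweeps)) {
      # best single exchange over all (design point, candidate) pairs;
      # ties broken by lowest candidate index via strict improvement scan
      best_gain <- d_cur * (1 + 1e-9)
      best_i <- 0L; best_j <- 0L
      for (i in seq_len(n_runs)) {
        trial <- idx
        for (j in seq_len(nc)) {
          if (j == idx[i]) next
          trial[i] <- j
          d_try <- det(crossprod(Xc[trial, , drop = FALSE]))
          if (d_try > best_gain) { best_gain <- d_try; best_i <- i; best_j <- j }
          trial[i] <- idx[i]
        }
      }
      if (best_i == 0L) break
      idx[best_i] <- best_j
      d_cur <- best_gain
      hist <- c(hist, d_cur)
    }
    if (is.null(best) || d_cur > best$det) {
      best <- list(indices = idx, det = d_cur, history = hist)
    }
  }
  if (is.null(best))
    stop("no nonsingular starting design found; candidates may not span the model",
         call. = FALSE)

  idx <- sort(best$indices)
  runs <- candidates[idx, , drop = FALSE]
  rownames(runs) <- NULL
  X <- build_model_matrix(runs, terms)
  structure(list(runs = runs, indices = idx, terms = terms, X = X,
                 det = best$det,
                 d_efficiency = 100 * best$det^(1 / p) / n_runs,
                 history = best$history,
                 n_runs = n_runs, n_starts = n_starts, seed = seed),
            class = "doe_design")
}

#' @export
print.doe_design <- function(x, ...) {
  cat(sprintf("D-optimal design: %d runs, %d model terms\n",
              x$n_runs, nrow(x$terms)))
  cat(sprintf("det(X'X) = %.6g, D-efficiency = %.1f%%\n",
              x$det, x$d_efficiency))
  print(x$runs)
  invisible(x)
}

#' D-efficiency of a design
#'
#' Normalized determinant criterion
#' \eqn{100 \cdot \det(X'X)^{1/p} / n}, where `p` is the number of model
#' terms and `n` the number of runs. An orthogonal design attains 100%.
#'
#' @param design A `doe_design`, or a data frame of coded runs (then
#'   `terms` must be given).
#' @param terms Model term set, required when `design` is a plain run table.
#' @return D-efficiency in percent, in `(0, 100]` for a nonsingular design.
#' @export
d_efficiency <- function(design, terms = NULL) {
  if (inherits(design, "doe_design")) {
    X <- design$X
  } else {
    stopifnot(inherits(terms, "quad_terms"))
    X <- build_model_matrix(as.data.frame(design), terms)
  }
  dd <- det(crossprod(X))
  if (!is.finite(dd) || dd <= 0)
    stop("singular information matrix", call. = FALSE)
  100 * dd^(1 / ncol(X)) / nrow(X)
}
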