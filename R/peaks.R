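#' Read or validate an electropherogram trace
#'
#' Traces are two-column tables: `time_min` (strictly increasing,
#' approximately uniform sampling) and `signal` (detector units). Files may
#' carry a third `injection` column for multi-injection runs.
#'
#' @param path Path to a CSV file with columns `time_min`, `signal` and
#'   optionally `injection`.
#' @return A data frame with the trace columns.
#' @export
read_trace <- function(path) {
  tr <- utils::read.csv(path)
  need <- c("time_min", "signal")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    stop("trace file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tr
}

check_trace <- function(trace) {
  stopifnot(is.data.frame(trace))
  t <- trace$time_min; s <- trace$signal
  if (is.null(t) || is.null(s)) stop("trace needs time_min and signal columns",
                                     call. = FALSE)
  if (length(t) != length(s)) stop("time and signal lengths differ",
                                   call. = FALSE)
  if (length(t) < 50L) stop("trace too short (need >= 50 samples)",
                            call. = FALSE)
  if (any(!is.finite(t)) || any(!is.finite(s)))
    stop("non-finite values in trace", call. = FALSE)
  if (any(diff(t) <= 0)) stop("trace time must be strictly increasing",
                              call. = FALSE)
  invisible(trace)
}

# linear interpolation of the time at which the signal crosses `level`
# between samples k and k+1
cross_time <- function(t, s, k, level) {
  t[k] + (level - s[k]) * (t[k + 1L] - t[k]) / (s[k + 1L] - s[k])
}

#' Detect and measure peaks in an electropherogram
#'
#' Finds local maxima above a height threshold, refines each apex by
#' parabolic interpolation of the three samples around the maximum,
#' measures the full width at half maximum (FWHM) by linear interpolation
#' of the half-height crossings, and integrates the area by the
#' trapezoidal rule over the peak window (valley-to-valley, clipped to
#' 1.5 FWHM on either side of the apex, whichever is narrower).
#'
#' For traces holding several peaks the half-height crossing on the side
#' facing a neighbouring peak can be lifted by overlap; the width of the
#' first (last) peak is therefore taken as twice the half width on its
#' outer flank. Interior peaks use both crossings where found.
#'
#' @param trace Trace data frame (`time_min`, `signal`).
#' @param min_height_frac Minimum peak height as a fraction of the global
#'   signal maximum.
#' @param min_separation Minimum apex separation in minutes; of two closer
#'   maxima only the higher is kept.
#' @return A data frame of class `peak_table`, one row per peak in
#'   migration order: `apex_time`, `height`, `fwhm`, `area`, `t_start`,
#'   `t_end`. Zero rows when no peak qualifies.
#' @seealso [peak_resolution()], [enantiomer_ratio()]
#' @export
detect_peaks <- function(trace, min_height_frac = 0.05, min_separation = 0.1) {
  check_trace(trace)
  t <- trace$time_min; s <- trace$signal
  n <- length(s)
  smax <- max(s)
  empty <- data.frame(apex_time = numeric(), height = numeric(),
                      fwhm = numeric(), area = numeric(),
                      t_start = numeric(), t_end = numeric())
  class(empty) <- c("peak_table", "data.frame")
  if (smax <= 0) return(empty)
  thr <- min_height_frac * smax

  ds <- diff(s)
  cand <- which(ds[-length(ds)] > 0 & ds[-1L] <= 0) + 1L   # local maxima
  cand <- cand[s[cand] >= thr]
  if (!length(cand)) return(empty)
  # enforce minimum separation, keeping higher peaks first
  cand <- cand[order(-s[cand])]
  kept <- integer()
  for (k in cand)
    if (!length(kept) || all(abs(t[k] - t[kept]) >= min_separation))
      kept <- c(kept, k)
  kept <- sort(kept)

  # valley boundaries between adjacent kept apices, outer bounds at trace ends
  bounds_idx <- c(1L,
                  vapply(seq_len(length(kept) - 1L), function(i) {
                    seg <- seg_range(kept[i], kept[i + 1L])
                    seg[which.min(s[seg])]
                  }, 0L),
                  n)

  rows <- lapply(seq_along(kept), function(i) {
    k <- kept[i]
    lo <- bounds_idx[i]; hi <- bounds_idx[i + 1L]
    # parabolic apex refinement
    if (k > 1L && k < n) {
      y1 <- s[k - 1L]; y2 <- s[k]; y3 <- s[k + 1L]
      denom <- y1 - 2 * y2 + y3
      off <- if (denom < 0) 0.5 * (y1 - y3) / denom else 0
      off <- max(-0.5, min(0.5, off))
      apex <- t[k] + off * (t[k + 1L] - t[k])
      height <- y2 - 0.25 * (y1 - y3) * off
    } else {
      apex <- t[k]; height <- s[k]
    }
    half <- height / 2
    # half-height crossings within the peak's segment
    left <- NA_real_; right <- NA_real_
    j <- k
    while (j > lo && s[j - 1L] >= half) j <- j - 1L
    if (j > lo) left <- cross_time(t, s, j - 1L, half)
    j <- k
    while (j < hi && s[j + 1L] >= half) j <- j + 1L
    if (j < hi) right <- cross_time(t, s, j, half)
    multi <- length(kept) > 1L
    hw_l <- apex - left; hw_r <- right - apex
    fwhm <- if (multi && i == 1L && is.finite(hw_l)) 2 * hw_l
            else if (multi && i == length(kept) && is.finite(hw_r)) 2 * hw_r
            else if (is.finite(hw_l) && is.finite(hw_r)) hw_l + hw_r
            else if (is.finite(hw_l)) 2 * hw_l
            else if (is.finite(hw_r)) 2 * hw_r
            else NA_real_
    # integration window: valleys clipped to 1.5 FWHM around the apex
    t_lo <- max(t[lo], if (is.finite(fwhm)) apex - 1.5 * fwhm else t[lo])
    t_hi <- min(t[hi], if (is.finite(fwhm)) apex + 1.5 * fwhm else t[hi])
    seg <- which(t >= t_lo & t <= t_hi)
    area <- if (length(seg) > 1L)
      sum(diff(t[seg]) * (s[seg][-1L] + s[seg][-length(seg)]) / 2)
    else NA_real_
    data.frame(apex_time = apex, height = height, fwhm = fwhm,
               area = area, t_start = t_lo, t_end = t_hi)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$apex_time), ]
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

seg_range <- function(a, b) seq(a, b)

#' Enantiomer resolution from migration times and FWHM widths
#'
#' The separation quality metric computed from full widths at half maximum:
#' \deqn{R_s = 1.18 \, (t_2 - t_1) / (W_1 + W_2).}
#' Dimensionless; `Rs >= 1.5` denotes baseline separation. The value is
#' invariant under a common rescaling of all times and widths.
#'
#' @param t1,t2 Apex migration times of the first and second peak
#'   (`t2 >= t1`), minutes.
#' @param w1,w2 FWHM of the two peaks, minutes.
#' @return Resolution value(s); vectorized over the arguments.
#' @export
resolution_fwhm <- function(t1, t2, w1, w2) {
  if (any(t2 < t1)) stop("t2 must not precede t1", call. = FALSE)
  if (any(w1 + w2 <= 0)) stop("peak widths must be positive", call. = FALSE)
  1.18 * (t2 - t1) / (w1 + w2)
}

#' Resolution between consecutive peaks of a peak table
#'
#' @param peaks A `peak_table` from [detect_peaks()] with at least two
#'   rows.
#' @return Numeric vector of length `nrow(peaks) - 1`: resolution between
#'   each consecutive pair in migration order.
#' @export
peak_resolution <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) < 2L) stop("need at least two peaks", call. = FALSE)
  i <- seq_len(nrow(peaks) - 1L)
  resolution_fwhm(peaks$apex_time[i], peaks$apex_time[i + 1L],
                  peaks$fwhm[i], peaks$fwhm[i + 1L])
}

#' Enantiomeric ratio from peak areas
#'
#' Area percentages of the two enantiomer peaks, summing to 100. The first
#' value belongs to the first-migrating peak.
#'
#' @param peaks A `peak_table` with exactly two rows.
#' @return Named numeric vector `c(first = ..., second = ...)` of area
#'   percentages.
#' @export
enantiomer_ratio <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) != 2L)
    stop("enantiomeric ratio requires exactly two peaks", call. = FALSE)
  a <- peaks$area
  if (any(!is.finite(a)) || any(a <= 0))
    stop("peak areas must be positive", call. = FALSE)
  pct <- 100 * a / sum(a)
  c(first = pct[1L], second = pct[2L])
}

#' Annotate enantiomer migration order
#'
#' Labels time-sorted peaks with their enantiomer identity. For the
#' amlodipine/maltodextrin system the (S)-(-)-enantiomer migrates first,
#' followed by the (R)-(+)-enantiomer; the mapping is configurable for
#' systems with the opposite order. A single peak is labelled
#' `"unresolved"`.
#'
#' @param peaks A `peak_table`, time-sorted.
#' @param order Character vector of labels applied in migration order
#'   (default `c("S", "R")`).
#' @return The peak table with an `enantiomer` column added.
#' @export
label_migration_order <- function(peaks, order = c("S", "R")) {
  stopifnot(is.data.frame(peaks))
  n <- nrow(peaks)
  peaks$enantiomer <- if (n == 1L) "unresolved"
                      else rep_len(order, n)
  peaks
}
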