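# Kinetic-parameter extraction from ThT aggregation curves: moving-average
# smoothing, symmetric-difference derivatives, 5%-of-maximum derivative
# threshold segmentation, replicate lag alignment, dose-series layout.

#' Centered moving-average smoothing
#'
#' Unweighted centered moving average over \code{window} points. At the
#' boundaries the window shrinks symmetrically (never asymmetrically), so the
#' output has the same length as the input and constant regions are
#' unchanged.
#'
#' @param y numeric series.
#' @param window odd integer >= 3, smaller than \code{length(y)};
#'   default 11.
#' @return smoothed series, same length as \code{y}.
#' @export
smooth_ma <- function(y, window = 11L) {
  n <- length(y)
  if (window %% 2L != 1L || window < 3L)
    stop("window must be an odd integer >= 3")
  if (window >= n)
    stop("window (", window, ") must be smaller than the series length (",
         n, ")")
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- mean(y[(i - h):(i + h)])
  }
  out
}

#' Symmetric-difference-quotient derivative
#'
#' Numerical first derivative \eqn{d_i = (y_{i+h} - y_{i-h}) /
#' (t_{i+h} - t_{i-h})} with half-width \code{h = depth / 2}. A "depth
#' window" of 4 points thus spans indices \eqn{i-2 \ldots i+2}. Near the
#' boundaries the largest available symmetric half-width (minimum 1) is used;
#' the two endpoints fall back to the one-sided difference. The second
#' derivative is obtained by applying this operator to the first-derivative
#' series.
#'
#' @param t strictly increasing times.
#' @param y values, same length as \code{t}.
#' @param depth even integer, full span of the difference stencil in index
#'   steps (default 4, i.e. half-width 2).
#' @return derivative series, same length as \code{y}.
#' @export
sym_derivative <- function(t, y, depth = 4L) {
  n <- length(y)
  stopifnot(length(t) == n, depth >= 2L, depth %% 2L == 0L)
  if (n < depth + 1L) stop("series too short for derivative depth ", depth)
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  half <- depth %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    if (h >= 1L) {
      out[i] <- (y[i + h] - y[i - h]) / (t[i + h] - t[i - h])
    } else if (i == 1L) {
      out[i] <- (y[2L] - y[1L]) / (t[2L] - t[1L])
    } else {
      out[i] <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
    }
  }
  out
}

#' Segment the growth phase of a sigmoidal curve
#'
#' Growth start is the first index where the first derivative reaches
#' \code{threshold_frac} (default 5\%) of its maximum; growth end is the
#' first index after the derivative maximum where it falls back to or below
#' that threshold (the last index if it never does). The lag time is the time
#' at growth start.
#'
#' @param t times (h).
#' @param d1 first-derivative series.
#' @param threshold_frac fraction of the derivative maximum (default 0.05).
#' @return list with \code{defined} (logical), \code{start}, \code{end},
#'   \code{argmax} (1-based indices), \code{lag_time} (h) and, when growth is
#'   undefined, a \code{reason}. Flat or decreasing curves (non-positive
#'   derivative maximum) yield \code{defined = FALSE} rather than zeros.
#' @export
segment_growth <- function(t, d1, threshold_frac = 0.05) {
  stopifnot(length(t) == length(d1), threshold_frac > 0, threshold_frac < 1)
  dmax <- max(d1)
  if (!is.finite(dmax) || dmax <= 0)
    return(list(defined = FALSE, reason = "no growth detected",
                start = NA_integer_, end = NA_integer_,
                argmax = NA_integer_, lag_time = NA_real_))
  thr <- threshold_frac * dmax
  imax <- which.max(d1)
  start <- which(d1 >= thr)[1L]
  after <- which(d1 <= thr & seq_along(d1) > imax)
  end <- if (length(after)) after[1L] else length(d1)
  list(defined = TRUE, start = start, end = end, argmax = imax,
       lag_time = t[start])
}

#' Extract kinetic parameters from one aggregation curve
#'
#' Applies the standard processing order: moving-average smoothing, first and
#' second symmetric-difference derivatives (the second computed from the
#' smoothed first), 5\%-threshold growth segmentation, then
#' \itemize{
#'   \item \code{lag_time}: time before the first derivative reaches 5\% of
#'     its maximum;
#'   \item \code{growth_duration}: time between growth start and end;
#'   \item \code{max_growth_rate}: maximal first derivative;
#'   \item \code{average_growth_rate}: fluorescence difference between growth
#'     end and start divided by the growth duration;
#'   \item \code{initial_growth_rate}: mean of the first 20 first-derivative
#'     values of the recording (elongation assays are linear from t = 0);
#'   \item \code{plateau_height}: mean of the 50 points following growth end
#'     (all remaining points, with a warning flag, if fewer than 50);
#'   \item \code{acceleration_max}: maximal second derivative.
#' }
#'
#' @param curve a \code{tht_curve}, or a list/data.frame with numeric
#'   \code{t} (h) and \code{y} (FI).
#' @param window smoothing window (odd, default 11).
#' @param deriv_depth derivative stencil span (default 4).
#' @param threshold_frac segmentation threshold fraction (default 0.05).
#' @param n_initial number of leading derivative points averaged for the
#'   initial growth rate (default 20).
#' @param n_plateau number of post-growth points averaged for the plateau
#'   height (default 50).
#' @return an object of class \code{kinetic_parameters}: a list with the
#'   seven parameters, \code{growth_start}/\code{growth_end} times, a
#'   \code{defined} flag with \code{reason}, and \code{provenance}
#'   (0-based indices used).
#' @export
extract_parameters <- function(curve, window = 11L, deriv_depth = 4L,
                               threshold_frac = 0.05, n_initial = 20L,
                               n_plateau = 50L) {
  t <- curve$t
  y <- curve$y
  stopifnot(is.numeric(t), is.numeric(y), length(t) == length(y))
  if (length(t) < 60L) stop("curve must have at least 60 points")
  ys <- smooth_ma(y, window)
  d1 <- sym_derivative(t, ys, deriv_depth)
  d2 <- sym_derivative(t, d1, deriv_depth)
  seg <- segment_growth(t, d1, threshold_frac)
  undefined <- function(reason) {
    structure(list(defined = FALSE, reason = reason,
                   lag_time = NA_real_, growth_start = NA_real_,
                   growth_end = NA_real_, growth_duration = NA_real_,
                   max_growth_rate = NA_real_, average_growth_rate = NA_real_,
                   initial_growth_rate = NA_real_, plateau_height = NA_real_,
                   acceleration_max = NA_real_, plateau_truncated = NA,
                   provenance = list()),
              class = "kinetic_parameters")
  }
  if (!seg$defined) return(undefined(seg$reason))
  i0 <- seg$start
  i1 <- seg$end
  dur <- t[i1] - t[i0]
  plateau_idx <- seq(min(i1 + 1L, length(t)),
                     min(i1 + n_plateau, length(t)))
  plateau_truncated <- length(plateau_idx) < n_plateau
  if (plateau_truncated)
    warning("only ", length(plateau_idx),
            " points after growth end for the plateau mean (wanted ",
            n_plateau, ")")
  structure(list(
    defined = TRUE, reason = NA_character_,
    lag_time = seg$lag_time,
    growth_start = t[i0],
    growth_end = t[i1],
    growth_duration = dur,
    max_growth_rate = max(d1),
    average_growth_rate = if (dur > 0) (ys[i1] - ys[i0]) / dur else NA_real_,
    initial_growth_rate = mean(d1[seq_len(min(n_initial, length(d1)))]),
    plateau_height = mean(ys[plateau_idx]),
    acceleration_max = max(d2),
    plateau_truncated = plateau_truncated,
    provenance = list(start_index = i0 - 1L, end_index = i1 - 1L,
                      argmax_index = seg$argmax - 1L,
                      plateau_indices = range(plateau_idx) - 1L,
                      window = window, deriv_depth = deriv_depth,
                      threshold_frac = threshold_frac)),
    class = "kinetic_parameters")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  if (!x$defined) {
    cat("Kinetic parameters: undefined (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat("Kinetic parameters:\n")
  for (f in c("lag_time", "growth_duration", "max_growth_rate",
              "average_growth_rate", "initial_growth_rate",
              "plateau_height", "acceleration_max"))
    cat(sprintf("  %-20s %s\n", f, format(signif(x[[f]], 6))))
  invisible(x)
}

#' Align replicate curves to their mean lag time
#'
#' Each replicate is shifted along the time axis by (mean lag - own lag) with
#' linear re-interpolation onto the common grid, so that after alignment all
#' lag times equal the pre-alignment mean. Shifts sum to zero. If any
#' replicate has an undefined lag, alignment is skipped for the whole set
#' with a warning.
#'
#' @param curves list of \code{tht_curve}-like objects (shared time grid).
#' @param ... parameters passed to \code{\link{extract_parameters}} for lag
#'   determination.
#' @return list with \code{curves} (aligned), \code{shifts} (h),
#'   \code{lags} (raw lag times, h) and \code{aligned} (logical).
#' @export
align_replicates <- function(curves, ...) {
  stopifnot(length(curves) >= 2L)
  lags <- vapply(curves, function(cv) extract_parameters(cv, ...)$lag_time,
                 numeric(1))
  if (anyNA(lags)) {
    warning("undefined lag time in replicate set; alignment skipped")
    return(list(curves = curves, shifts = rep(NA_real_, length(curves)),
                lags = lags, aligned = FALSE))
  }
  shifts <- mean(lags) - lags
  out <- mapply(function(cv, s) {
    cv$y <- shift_curve(cv$t, cv$y, s)
    cv
  }, curves, shifts, SIMPLIFY = FALSE)
  list(curves = out, shifts = shifts, lags = lags, aligned = TRUE)
}

#' Logarithmically equidistant dose series
#'
#' Geometric progression of \code{n} inhibitor:monomer molar ratios between
#' \code{ratio_min} and \code{ratio_max} (endpoints exact), optionally
#' prepended with a ratio-0 control. The default reproduces a ten-point
#' 1:5000 to 1:1 design.
#'
#' @param ratio_min,ratio_max series bounds (0 < min < max).
#' @param n number of non-zero ratios (>= 2).
#' @param include_control prepend 0 (default FALSE).
#' @return numeric vector of ratios.
#' @examples
#' r <- build_dose_series()
#' sprintf("1:%.0f", 1 / r)   # three steps below 1:1 prints "1:17"
#' @export
build_dose_series <- function(ratio_min = 1 / 5000, ratio_max = 1, n = 10L,
                              include_control = FALSE) {
  stopifnot(ratio_min > 0, ratio_min < ratio_max)
  if (n < 2L) stop("n must be >= 2")
  r <- exp(seq(log(ratio_min), log(ratio_max), length.out = n))
  r[1L] <- ratio_min
  r[n] <- ratio_max
  if (include_control) r <- c(0, r)
  r
}

#' Per-curve kinetic-parameter table for a ThT set
#'
#' Runs \code{\link{extract_parameters}} on every well, optionally after
#' per-condition replicate lag alignment, and appends condition-aggregated
#' mean and SD rows.
#'
#' @param set a \code{tht_set}.
#' @param align align replicates to their mean lag first (default FALSE).
#' @param normalize \code{"raw"} or \code{"max"} (divide each curve by its
#'   maximum before extraction).
#' @param ... passed to \code{\link{extract_parameters}}.
#' @return data.frame, one row per well plus \code{mean}/\code{sd} rows per
#'   condition (column \code{stat}).
#' @export
extract_kinetics <- function(set, align = FALSE,
                             normalize = c("raw", "max"), ...) {
  stopifnot(inherits(set, "tht_set"))
  normalize <- match.arg(normalize)
  params <- c("lag_time", "growth_duration", "max_growth_rate",
              "average_growth_rate", "initial_growth_rate",
              "plateau_height", "acceleration_max")
  curves <- lapply(set$anno$well, function(w) tht_curve(set, w))
  names(curves) <- set$anno$well
  if (normalize == "max")
    curves <- lapply(curves, function(cv) { cv$y <- cv$y / max(cv$y); cv })
  if (align) {
    for (r in unique(set$anno$ratio)) {
      idx <- which(set$anno$ratio == r)
      if (length(idx) >= 2L) {
        al <- align_replicates(curves[idx], ...)
        curves[idx] <- al$curves
      }
    }
  }
  rows <- lapply(seq_along(curves), function(i) {
    kp <- suppressWarnings(extract_parameters(curves[[i]], ...))
    cbind(set$anno[i, c("well", "ratio", "replicate")],
          stat = "curve",
          as.data.frame(kp[params]),
          defined = kp$defined)
  })
  tab <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(unique(tab$ratio), function(r) {
    sub <- tab[tab$ratio == r & tab$defined, params, drop = FALSE]
    mk <- function(stat, fun) {
      vals <- if (nrow(sub)) vapply(sub, fun, numeric(1)) else
        stats::setNames(rep(NA_real_, length(params)), params)
      cbind(data.frame(well = NA, ratio = r, replicate = NA, stat = stat),
            as.data.frame(as.list(vals)), defined = nrow(sub) > 0)
    }
    rbind(mk("mean", mean), mk("sd", stats::sd))
  }))
  out <- rbind(tab, agg)
  rownames(out) <- NULL
  out
}

#' Compare kinetic trends on raw versus max-normalized curves
#'
#' Extracts the parameter table twice (raw and per-curve max-normalized) and
#' reports, per parameter, the Spearman rank correlation of the
#' condition-mean trend across the dose series between the two treatments.
#' Scale-invariant parameters (lag time, growth duration) are identical in
#' both tables; for the others a rank correlation of 1 shows the dose trends
#' are insensitive to normalization.
#'
#' @param set a \code{tht_set} with at least 2 conditions.
#' @param ... passed to \code{\link{extract_kinetics}}.
#' @return list with \code{raw}, \code{normalized} (parameter tables) and
#'   \code{rank_correlation} (named numeric vector).
#' @export
compare_normalization <- function(set, ...) {
  stopifnot(inherits(set, "tht_set"),
            length(unique(set$anno$ratio)) >= 2L)
  raw <- extract_kinetics(set, normalize = "raw", ...)
  nrm <- extract_kinetics(set, normalize = "max", ...)
  params <- c("lag_time", "growth_duration", "max_growth_rate",
              "average_growth_rate", "initial_growth_rate",
              "plateau_height", "acceleration_max")
  mr <- raw[raw$stat == "mean", ]
  mn <- nrm[nrm$stat == "mean", ]
  mn <- mn[match(mr$ratio, mn$ratio), ]
  rc <- vapply(params, function(p)
    suppressWarnings(stats::cor(mr[[p]], mn[[p]], method = "spearman",
                                use = "complete.obs")), numeric(1))
  list(raw = raw, normalized = nrm, rank_correlation = rc)
}
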