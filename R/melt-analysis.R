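#' Temperature-ramp fluorescence curve
#'
#' A nucleic-acid-dye fluorescence trace recorded while heating phage
#' particles; the dye reports DNA released into solution, so the genome-exit
#' transition appears as a sigmoidal fluorescence rise on top of the dye's
#' own (declining) temperature response.
#'
#' @param temperature degrees C, strictly increasing, within 4-99
#' @param fluorescence arbitrary units
#' @param condition optional named list of metadata (pH, NaCl_mM, MgCl2_mM,
#'   phage, ...)
#' @return a data frame of class `melt_curve`
#' @export
melt_curve <- function(temperature, fluorescence, condition = list()) {
  stopifnot(length(temperature) == length(fluorescence),
            length(temperature) >= 20L,
            all(temperature >= 4), all(temperature <= 99),
            !is.unsorted(temperature, strictly = TRUE))
  structure(data.frame(temperature = temperature,
                       fluorescence = fluorescence),
            condition = condition,
            class = c("melt_curve", "data.frame"))
}

#' Savitzky-Golay smoothing of a melt curve
#'
#' Local quadratic (degree-2 polynomial) smoothing; the filter's endpoint
#' rows use one-sided polynomial fits so temperatures are unchanged and no
#' points are dropped.
#'
#' @param curve a [melt_curve()]
#' @param window odd window length in points, `3 <= window < n/2`
#' @return the smoothed `melt_curve`
#' @export
smooth_melt <- function(curve, window = 7) {
  stopifnot(inherits(curve, "melt_curve"))
  n <- nrow(curve)
  if (window %% 2 != 1 || window < 3 || window >= n / 2)
    stop("window must be odd, >= 3 and < n/2 (n = ", n, ")")
  f <- signal::sgolayfilt(curve$fluorescence, p = 2, n = window)
  melt_curve(curve$temperature, f, attr(curve, "condition"))
}

#' Extract the DNA-exit temperature from a melt curve
#'
#' Smooths the curve ([smooth_melt()]), differentiates it by central
#' differences, and reports the temperature of the global maximum of
#' `sign * dF/dT` restricted to temperatures above `t_min` (the release
#' region; the low-temperature part of the ramp is dominated by dye
#' equilibration). The rise attributable to the peak (the integral of the
#' baseline-subtracted derivative across the peak) must exceed
#' `min_prominence` of the total signal range, otherwise no release is
#' reported.
#'
#' @param curve a [melt_curve()]
#' @param window smoothing window, points
#' @param min_prominence minimum peak rise as a fraction of the total
#'   fluorescence range
#' @param t_min lower bound of the release region, degrees C
#' @param sign `"+"` (release = fluorescence increase, the default) or
#'   `"-"` for instruments that report the opposite first derivative of a
#'   globally decreasing signal
#' @param refine_span half-width (degrees C) of the local quadratic fit used
#'   to place the derivative apex between grid points; 0 disables refinement
#' @param locate_window wider smoothing window (points) used only to locate
#'   the peak before refinement; robust against derivative noise spikes
#' @return an object of class `melt_result`: `tex` (NA when no release),
#'   `released` flag, `prominence` (fraction), `derivative` data frame
#' @export
extract_tex <- function(curve, window = 7, min_prominence = 0.05,
                        t_min = 30, sign = c("+", "-"), refine_span = 4,
                        locate_window = 15) {
  sign <- match.arg(sign)
  stopifnot(inherits(curve, "melt_curve"))
  n <- nrow(curve)
  deriv_of <- function(win) {
    sm <- smooth_melt(curve, win)
    tt <- sm$temperature; ff <- sm$fluorescence
    d <- c(diff(ff)[1L] / diff(tt)[1L],
           (ff[3:n] - ff[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)]),
           diff(ff)[n - 1L] / diff(tt)[n - 1L])
    if (sign == "-") -d else d
  }
  tt <- curve$temperature
  d <- deriv_of(window)
  w_loc <- min(locate_window, window + 2 * floor((n / 2 - 1 - window) / 2))
  w_loc <- w_loc - (1 - w_loc %% 2)  # keep odd
  d_loc <- if (w_loc > window) deriv_of(w_loc) else d

  reg <- which(tt > t_min)
  if (!length(reg)) stop("no points above t_min = ", t_min)
  pk <- reg[which.max(d_loc[reg])]
  d_base <- stats::median(d_loc[reg])
  d_peak <- d_loc[pk]

  prominence <- 0
  released <- FALSE
  tex <- NA_real_
  if (d_peak > 0 && d_peak > d_base) {
    half <- d_base + (d_peak - d_base) / 2
    lo <- pk; while (lo > reg[1L] && d_loc[lo - 1L] > half) lo <- lo - 1L
    hi <- pk; while (hi < n && d_loc[hi + 1L] > half) hi <- hi + 1L
    # widen to the surrounding minima to integrate the whole peak
    while (lo > reg[1L] && d_loc[lo - 1L] > d_base &&
           d_loc[lo - 1L] <= d_loc[lo]) lo <- lo - 1L
    while (hi < n && d_loc[hi + 1L] > d_base &&
           d_loc[hi + 1L] <= d_loc[hi]) hi <- hi + 1L
    seg <- lo:hi
    # only the positive excess above the (non-negative part of the)
    # baseline counts as release: a declining probe signal contributes none
    y <- pmax(d_loc[seg] - max(d_base, 0), 0)
    rise <- sum(diff(tt[seg]) * (y[-1L] + y[-length(y)]) / 2)
    range_f <- diff(range(curve$fluorescence))
    prominence <- if (range_f > 0) rise / range_f else 0
    if (prominence >= min_prominence) {
      released <- TRUE
      tex <- tt[pk]
      if (refine_span > 0) {
        i <- which(abs(tt - tt[pk]) <= refine_span)
        if (length(i) >= 5L) {
          b <- stats::coef(stats::lm(d[i] ~ stats::poly(tt[i], 2, raw = TRUE)))
          apex <- -b[[2L]] / (2 * b[[3L]])
          step <- stats::median(diff(tt))
          if (is.finite(apex) && b[[3L]] < 0 &&
              abs(apex - tt[pk]) <= 4 * step)
            tex <- apex
        }
      }
    }
  }
  structure(list(tex = tex, released = released, prominence = prominence,
                 derivative = data.frame(temperature = tt, dFdT = d),
                 condition = attr(curve, "condition")),
            class = "melt_result")
}

#' @export
print.melt_result <- function(x, ...) {
  if (x$released)
    cat(sprintf("T_ex = %.2f degC (peak rise %.0f%% of signal range)\n",
                x$tex, 100 * x$prominence))
  else cat("no release detected\n")
  invisible(x)
}

#' Condition-wise DNA-exit temperature comparison table
#'
#' Groups extracted T_ex values by condition and phage, averages replicates,
#' and reports the difference `reference - other` per condition (by default
#' wild-type minus the decoration-deleted mutant, so a positive delta means
#' the decoration protein stabilises the capsid). Replicate uncertainty is
#' the standard error `sd/sqrt(n)`; differences carry the propagated error.
#'
#' @param results data frame with columns `condition`, `phage`, `tex` (one
#'   row per replicate curve)
#' @param reference phage label taken as the reference (minuend)
#' @return data frame: condition, per-phage mean and se, `delta_tex`,
#'   `delta_se`
#' @export
compare_tex <- function(results, reference = "wt") {
  stopifnot(all(c("condition", "phage", "tex") %in% names(results)))
  phages <- unique(results$phage)
  if (!reference %in% phages) stop("reference phage '", reference, "' absent")
  others <- setdiff(phages, reference)
  if (length(others) != 1L)
    stop("expected exactly two phage groups, got: ",
         paste(phages, collapse = ", "))
  other <- others

  agg <- function(ph) {
    d <- results[results$phage == ph, ]
    sp <- split(d$tex, d$condition)
    data.frame(condition = names(sp),
               mean = vapply(sp, mean, numeric(1)),
               se = vapply(sp, function(x)
                 if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_,
                 numeric(1)),
               n = vapply(sp, length, integer(1)),
               row.names = NULL)
  }
  a <- agg(reference); b <- agg(other)
  unmatched <- union(setdiff(a$condition, b$condition),
                     setdiff(b$condition, a$condition))
  if (length(unmatched))
    stop("conditions present in only one group: ",
         paste(unmatched, collapse = ", "))
  m <- merge(a, b, by = "condition", suffixes = c("_ref", "_other"))
  m$delta_tex <- m$mean_ref - m$mean_other
  m$delta_se <- sqrt(ifelse(is.na(m$se_ref), 0, m$se_ref^2) +
                     ifelse(is.na(m$se_other), 0, m$se_other^2))
  names(m)[names(m) == "mean_ref"] <- paste0("tex_", reference)
  names(m)[names(m) == "mean_other"] <- paste0("tex_", other)
  m
}
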