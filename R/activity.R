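#' Initial rate of a fluorometric kinetic trace
#'
#' Slope of an ordinary least-squares line over the early, linear part of the
#' trace. The window is the longest initial segment (starting at the first
#' point, at least `min_points` points) whose linear fit reaches R-squared
#' >= `r2_min`, followed by a saturation trim: trailing points whose
#' residuals are strongly negative relative to the window's residual scatter
#' (the signature of a developing plateau, which R-squared alone detects
#' poorly) are dropped one at a time. This is robust both to the lag of the
#' coupled enzyme cascade and to late saturation. If no window qualifies,
#' the first `min_points` points are used with a warning. A zero-variance
#' (constant) trace has rate 0 by convention.
#'
#' @param times Times, minutes (strictly increasing, >= 5 points).
#' @param intensities Fluorescence intensities, a.u.
#' @param protein_concentration Optional concentration (micromolar) used to
#'   normalise the rate.
#' @param min_points Minimum window size.
#' @param r2_min Linearity requirement for the window.
#' @return A list of class `varsite_rate`: `initial_rate` (a.u./min),
#'   `normalised_rate` (a.u./min/uM, `NA` without a concentration), `window`
#'   (indices used) and `r_squared`.
#' @export
initial_rate <- function(times, intensities, protein_concentration = NULL,
                         min_points = 5L, r2_min = 0.98) {
  if (length(times) != length(intensities)) {
    stop("times and intensities must have equal length")
  }
  if (length(times) < min_points) {
    stop("need at least ", min_points, " points")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  n <- length(times)
  window_fit <- function(m) {
    t <- times[1:m]; y <- intensities[1:m]
    if (stats::var(y) == 0) {
      return(list(slope = 0, r2 = 1, m = m, resid = rep(0, m)))
    }
    fit <- stats::lm.fit(cbind(1, t), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    list(slope = unname(fit$coefficients[2]), r2 = r2, m = m,
         resid = fit$residuals)
  }
  pick <- NULL
  for (m in rev(seq(min_points, n))) {
    cand <- window_fit(m)
    if (cand$r2 >= r2_min) {
      pick <- cand
      break
    }
  }
  if (!is.null(pick)) {
    # trim a developing plateau: drop trailing points whose residual is
    # strongly negative relative to the scatter of the rest of the window
    eps <- 1e-8 * max(abs(intensities), 1)
    while (pick$m > min_points) {
      scale <- max(stats::sd(utils::head(pick$resid, -1)), eps)
      if (pick$resid[pick$m] < -3 * scale) {
        pick <- window_fit(pick$m - 1L)
      } else {
        break
      }
    }
  }
  if (is.null(pick)) {
    warning("no initial window reached R^2 >= ", r2_min,
            "; falling back to the first ", min_points, " points")
    t <- times[1:min_points]; y <- intensities[1:min_points]
    fit <- stats::lm.fit(cbind(1, t), y)
    r2 <- if (stats::var(y) == 0) 1 else
      1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    pick <- list(slope = unname(fit$coefficients[2]), r2 = r2, m = min_points)
  }
  rate <- unname(pick$slope)
  out <- list(initial_rate = rate,
              normalised_rate = if (is.null(protein_concentration)) NA_real_
                                else rate / protein_concentration,
              window = seq_len(pick$m), r_squared = pick$r2)
  class(out) <- "varsite_rate"
  out
}

#' Activity ratio of a variant relative to WT and knock-out controls
#'
#' The knock-out control (an inactive active-site mutant, e.g. K175C)
#' defines the assay's detection floor. The default ratio subtracts it:
#' `(median(variant) - median(ko)) / (median(wt) - median(ko))`, so WT maps
#' to exactly 1 and the knock-out to exactly 0. A variant is flagged below
#' detection when its median rate does not exceed the knock-out median by
#' more than `k` times the knock-out interquartile range. The ratio is
#' invariant under a common linear rescaling of all rates (detector gain).
#'
#' @param variant_rates Numeric vector of replicate rates for the variant.
#' @param wt_rates,ko_rates Replicate rates for wild type and knock-out
#'   (>= 2 replicates each).
#' @param k Detection-limit multiplier on the knock-out IQR.
#' @param subtract_ko Subtract the knock-out signal (default); otherwise the
#'   ratio is `median(variant)/median(wt)`.
#' @return A list of class `varsite_activity_ratio`: `ratio_to_wt` (ratio of
#'   medians, the headline number), `median_of_ratios` (alternative
#'   aggregation), `iqr` (IQR of per-replicate ratios), `below_detection`,
#'   `n_replicates`.
#' @export
activity_ratio <- function(variant_rates, wt_rates, ko_rates, k = 1,
                           subtract_ko = TRUE) {
  if (length(wt_rates) < 2L || length(ko_rates) < 2L) {
    stop("need >= 2 replicates for WT and knock-out controls")
  }
  med_v <- stats::median(variant_rates)
  med_wt <- stats::median(wt_rates)
  med_ko <- stats::median(ko_rates)
  if (med_wt <= med_ko) {
    stop("assay invalid: WT median rate does not exceed knock-out median")
  }
  if (subtract_ko) {
    denom <- med_wt - med_ko
    ratio <- (med_v - med_ko) / denom
    rep_ratios <- (variant_rates - med_ko) / denom
  } else {
    ratio <- med_v / med_wt
    rep_ratios <- variant_rates / med_wt
  }
  below <- med_v <= med_ko + k * stats::IQR(ko_rates)
  out <- list(ratio_to_wt = ratio,
              median_of_ratios = stats::median(rep_ratios),
              iqr = stats::IQR(rep_ratios),
              below_detection = below,
              n_replicates = length(variant_rates))
  class(out) <- "varsite_activity_ratio"
  out
}

#' @export
print.varsite_activity_ratio <- function(x, ...) {
  cat(sprintf("Activity ratio to WT: %.3f (IQR %.3f, n = %d)%s\n",
              x$ratio_to_wt, x$iqr, x$n_replicates,
              if (x$below_detection) " [below detection limit]" else ""))
  invisible(x)
}

#' Flag reactions that may have saturated the assay
#'
#' The positive control carries the product concentration expected if every
#' substrate molecule were converted; any reaction whose initial rate
#' implies at least that concentration is flagged as possibly saturated.
#'
#' @param positive_control_rate Rate of the full-conversion control (> 0).
#' @param reaction_rates Numeric vector of reaction rates.
#' @return Logical vector, `TRUE` where the reaction rate reaches or exceeds
#'   the control rate.
#' @export
saturation_check <- function(positive_control_rate, reaction_rates) {
  if (!is.numeric(positive_control_rate) || positive_control_rate <= 0) {
    stop("positive control rate must be > 0")
  }
  reaction_rates >= positive_control_rate
}

#' Compute activity ratios for a full trace table
#'
#' Applies [initial_rate()] per sample/replicate and [activity_ratio()] per
#' variant against named WT and knock-out samples.
#'
#' @param traces Long data frame: `sample`, `replicate`, `time_min`,
#'   `intensity`, optional `concentration`.
#' @param wt,ko Sample labels of the wild-type and knock-out controls.
#' @param k Detection-limit multiplier (see [activity_ratio()]).
#' @return Data frame: `sample`, `ratio_to_wt`, `iqr`, `below_detection`,
#'   `n_replicates` (controls included: WT at 1, knock-out at 0).
#' @export
activity_table <- function(traces, wt = "WT", ko = "KO", k = 1) {
  req <- c("sample", "replicate", "time_min", "intensity")
  if (!all(req %in% names(traces))) {
    stop("traces must have columns ", paste(req, collapse = ", "))
  }
  rates <- do.call(rbind, lapply(split(traces,
                                       list(traces$sample, traces$replicate),
                                       drop = TRUE), function(g) {
    conc <- if ("concentration" %in% names(g)) g$concentration[1] else NULL
    r <- initial_rate(g$time_min, g$intensity, protein_concentration = conc)
    rate <- if (!is.null(conc)) r$normalised_rate else r$initial_rate
    data.frame(sample = g$sample[1], replicate = g$replicate[1],
               rate = rate, stringsAsFactors = FALSE)
  }))
  if (!all(c(wt, ko) %in% rates$sample)) {
    stop("traces must contain the control samples '", wt, "' and '", ko, "'")
  }
  wt_rates <- rates$rate[rates$sample == wt]
  ko_rates <- rates$rate[rates$sample == ko]
  out <- do.call(rbind, lapply(split(rates, rates$sample), function(g) {
    ar <- activity_ratio(g$rate, wt_rates, ko_rates, k = k)
    data.frame(sample = g$sample[1], ratio_to_wt = ar$ratio_to_wt,
               iqr = ar$iqr, below_detection = ar$below_detection,
               n_replicates = ar$n_replicates, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
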