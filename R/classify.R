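#' Thresholds for the activity/stability/foldedness classification
#'
#' Defaults are the published decision boundaries: red-shift below 6 nm upon
#' unfolding marks a misfolded starting state; a first transition midpoint
#' more than 5 degC below wild type marks a stability penalty; activity below
#' 60% of wild type marks an activity penalty. All inequalities are strict.
#'
#' @param misfolded_red_shift nm.
#' @param stability_penalty degC below the wild-type T_m1.
#' @param activity_penalty Fraction of wild-type activity.
#' @return A `varsite_thresholds` list.
#' @export
classification_thresholds <- function(misfolded_red_shift = 6,
                                      stability_penalty = 5,
                                      activity_penalty = 0.60) {
  stopifnot(misfolded_red_shift > 0, stability_penalty > 0,
            activity_penalty > 0)
  obj <- list(misfolded_red_shift = misfolded_red_shift,
              stability_penalty = stability_penalty,
              activity_penalty = activity_penalty)
  class(obj) <- "varsite_thresholds"
  obj
}

#' Fitness classes
#' @export
fitness_classes <- c("wt_like", "activity_penalty", "stability_penalty",
                     "activity_and_stability_penalty", "inactive_stable",
                     "inactive_unstable", "misfolded", "unclassifiable")

#' Classify a variant by foldedness, stability and activity
#'
#' Decision order: (1) a red-shift below the misfolded threshold dominates
#' everything -- such variants are inactive because they start misfolded,
#' not necessarily through active-site effects; (2) activity below the assay
#' detection limit splits into `inactive_stable` / `inactive_unstable` by
#' the stability criterion; (3) otherwise activity below 60% of WT and/or
#' T_m1 more than 5 degC below WT give the corresponding penalty class;
#' (4) anything left is `wt_like`. Missing measurements give an explicit
#' `unclassifiable` with a reason, never a silent default.
#'
#' @param tm1 Variant first transition midpoint, degC.
#' @param activity Activity ratio to WT.
#' @param red_shift Unfolding red-shift, nm.
#' @param below_detection Logical: activity below the knock-out-defined
#'   detection limit.
#' @param wt_tm1 Wild-type T_m1, degC.
#' @param thresholds A [classification_thresholds()] object.
#' @return A list of class `varsite_class`: `class` (one of
#'   [fitness_classes]) and `criteria` (character vector of triggered
#'   criteria, or the reason for unclassifiability).
#' @export
classify <- function(tm1, activity, red_shift, below_detection, wt_tm1,
                     thresholds = classification_thresholds()) {
  missing <- c(tm1 = is.na(tm1), activity = is.na(activity),
               red_shift = is.na(red_shift),
               below_detection = is.na(below_detection),
               wt_tm1 = is.na(wt_tm1))
  if (any(missing)) {
    out <- list(class = "unclassifiable",
                criteria = paste("missing:",
                                 paste(names(missing)[missing],
                                       collapse = ", ")))
    class(out) <- "varsite_class"
    return(out)
  }
  unstable <- (wt_tm1 - tm1) > thresholds$stability_penalty
  crit <- character()
  if (red_shift < thresholds$misfolded_red_shift) {
    cls <- "misfolded"
    crit <- sprintf("red_shift %.2f < %g nm", red_shift,
                    thresholds$misfolded_red_shift)
  } else if (isTRUE(below_detection)) {
    cls <- if (unstable) "inactive_unstable" else "inactive_stable"
    crit <- c("activity below detection limit",
              if (unstable) sprintf("T_m1 %.2f more than %g degC below WT",
                                    tm1, thresholds$stability_penalty))
  } else {
    low_act <- activity < thresholds$activity_penalty
    if (low_act) {
      crit <- c(crit, sprintf("activity %.2f < %g x WT", activity,
                              thresholds$activity_penalty))
    }
    if (unstable) {
      crit <- c(crit, sprintf("T_m1 %.2f more than %g degC below WT", tm1,
                              thresholds$stability_penalty))
    }
    cls <- if (low_act && unstable) "activity_and_stability_penalty"
           else if (low_act) "activity_penalty"
           else if (unstable) "stability_penalty"
           else "wt_like"
  }
  out <- list(class = cls, criteria = crit)
  class(out) <- "varsite_class"
  out
}

#' Classify a table of variants
#'
#' @param variants Data frame with columns `name`, `tm1`, `activity`,
#'   `red_shift`, `below_detection`; the WT row (name `"WT"`) supplies the
#'   reference T_m1 unless `wt_tm1` is given.
#' @param wt_tm1 Optional explicit wild-type T_m1.
#' @param thresholds A [classification_thresholds()] object.
#' @return The input with appended `class` and `criteria` columns.
#' @export
classify_variants <- function(variants, wt_tm1 = NULL,
                              thresholds = classification_thresholds()) {
  if (is.null(wt_tm1)) {
    wt_row <- which(toupper(variants$name) == "WT")
    if (length(wt_row) != 1L) {
      stop("supply wt_tm1 or include exactly one 'WT' row")
    }
    wt_tm1 <- variants$tm1[wt_row]
  }
  res <- lapply(seq_len(nrow(variants)), function(i) {
    classify(variants$tm1[i], variants$activity[i], variants$red_shift[i],
             variants$below_detection[i], wt_tm1, thresholds)
  })
  variants$class <- vapply(res, `[[`, character(1), "class")
  variants$criteria <- vapply(res, function(r)
    paste(r$criteria, collapse = "; "), character(1))
  variants
}
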