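#' Barycentric mean of an emission spectrum
#'
#' The intensity-weighted mean emission wavelength,
#' `sum(lambda * I(lambda)) / sum(I(lambda))` -- the spectral centre of mass
#' used to track the tryptophan environment during unfolding. It is
#' invariant under uniform intensity scaling and shifts linearly with a
#' uniform wavelength shift.
#'
#' @param wavelengths Wavelengths, nm (>= 3 values).
#' @param intensities Matching intensities, arbitrary units, >= 0.
#' @return Barycentric mean, nm (always within the wavelength window).
#' @export
barycentric_mean <- function(wavelengths, intensities) {
  if (length(wavelengths) != length(intensities)) {
    stop("wavelengths and intensities must have equal length")
  }
  if (length(wavelengths) < 3L) stop("need at least 3 spectral points")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  total <- sum(intensities)
  if (total <= 0) stop("total intensity is zero")
  sum(wavelengths * intensities) / total
}

#' Build a melt curve from temperature-ramped spectra
#'
#' Collapses each temperature's emission spectrum to its barycentric mean.
#'
#' @param spectra Long-format data frame with columns `temperature`,
#'   `wavelength`, `intensity` (one spectrum per distinct temperature).
#' @return A data frame of class `varsite_melt_curve` with columns
#'   `temperature` (sorted, strictly increasing) and `bcm` (nm).
#' @export
build_melt_curve <- function(spectra) {
  req <- c("temperature", "wavelength", "intensity")
  if (!all(req %in% names(spectra))) {
    stop("spectra must have columns ", paste(req, collapse = ", "))
  }
  by_t <- split(spectra, spectra$temperature)
  if (length(by_t) < 5L) stop("need spectra at >= 5 temperatures")
  temps <- as.numeric(names(by_t))
  bcm <- vapply(by_t, function(s) {
    if (anyDuplicated(s$wavelength)) {
      stop("duplicate temperature/wavelength combination at T = ",
           s$temperature[1], " degC (duplicated spectra?)")
    }
    barycentric_mean(s$wavelength, s$intensity)
  }, numeric(1))
  ord <- order(temps)
  out <- data.frame(temperature = temps[ord], bcm = as.numeric(bcm[ord]))
  class(out) <- c("varsite_melt_curve", "data.frame")
  out
}

sigmoid1 <- function(T, i_n, i_d, tm1, a) {
  i_n + (i_d - i_n) / (1 + exp((tm1 - T) / a))
}

sigmoid2 <- function(T, i_n, i_2, i_d, tm1, a, tm2, b) {
  i_n + (i_2 - i_n) / (1 + exp((tm1 - T) / a)) +
    (i_d - i_2) / (1 + exp((tm2 - T) / b))
}

melt_fit_result <- function(model, params, rss, n, converged,
                            message = NULL) {
  k <- length(params) + 1  # + residual variance
  aicc <- if (converged && n - k - 1 > 0) {
    n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  } else {
    Inf
  }
  obj <- c(list(model = model, rss = rss, n = n, aicc = aicc,
                converged = converged, message = message), as.list(params))
  class(obj) <- "varsite_melt_fit"
  obj
}

#' @export
print.varsite_melt_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Melt fit (", x$model, "): NOT CONVERGED -- ", x$message, "\n",
        sep = "")
    return(invisible(x))
  }
  cat(sprintf("Melt fit (%s): T_m1 = %.2f degC", x$model, x$tm1))
  if (!is.null(x$tm2)) cat(sprintf(", T_m2 = %.2f degC", x$tm2))
  cat(sprintf(", red shift = %.2f nm, RSS = %.3g\n", x$i_d - x$i_n, x$rss))
  invisible(x)
}

# shared multi-start scaffolding: baselines from the curve ends, transition
# candidates at the steepest-slope temperature +/- offsets
melt_starts <- function(curve) {
  n <- nrow(curve)
  n_edge <- max(2L, ceiling(0.1 * n))
  i_n0 <- mean(utils::head(curve$bcm, n_edge))
  i_d0 <- mean(utils::tail(curve$bcm, n_edge))
  slope <- diff(curve$bcm) / diff(curve$temperature)
  t_mid <- curve$temperature[-n] + diff(curve$temperature) / 2
  t_steep <- t_mid[which.max(abs(slope))]
  list(i_n = i_n0, i_d = i_d0,
       tm_candidates = t_steep + c(0, -5, 5, -10, 10))
}

try_nls <- function(formula, data, start, lower, upper) {
  tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      formula, data = data, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200))),
    error = function(e) NULL
  )
}

#' Fit a single-transition melt model
#'
#' Least-squares fit of
#' `I_N + (I_D - I_N) / (1 + exp((T_m1 - T)/a))` to a barycentric-mean melt
#' curve, with multi-start initialisation (baselines from the first/last 10%
#' of points; transition candidates at the steepest-slope temperature and
#' +/- 5, 10 degC; `a` starting at 2 degC). The best residual sum of squares
#' wins. A curve with no resolvable transition (flat to within 0.05 nm, or
#' no start converging) is returned flagged, never silently.
#'
#' @param curve A `varsite_melt_curve` (or data frame with `temperature`,
#'   `bcm`).
#' @return A `varsite_melt_fit` with fields `i_n`, `i_d`, `tm1`, `a`, `rss`,
#'   `aicc`, `converged`.
#' @export
fit_single_transition <- function(curve) {
  if (nrow(curve) < 6L) stop("need at least 6 points for a single-transition fit")
  rng <- range(curve$temperature)
  if (diff(range(curve$bcm)) < 0.05) {
    return(melt_fit_result("single", list(i_n = NA, i_d = NA, tm1 = NA, a = NA),
                           rss = NA_real_, n = nrow(curve), converged = FALSE,
                           message = "no transition: curve is flat"))
  }
  st <- melt_starts(curve)
  best <- NULL
  for (tm0 in st$tm_candidates) {
    if (tm0 < rng[1] || tm0 > rng[2]) next
    fit <- try_nls(bcm ~ sigmoid1(temperature, i_n, i_d, tm1, a),
                   data = curve,
                   start = list(i_n = st$i_n, i_d = st$i_d, tm1 = tm0, a = 2),
                   lower = c(-Inf, -Inf, rng[1], 1e-3),
                   upper = c(Inf, Inf, rng[2], Inf))
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(melt_fit_result("single", list(i_n = NA, i_d = NA, tm1 = NA, a = NA),
                           rss = NA_real_, n = nrow(curve), converged = FALSE,
                           message = "no start converged"))
  }
  p <- as.list(stats::coef(best$fit))
  melt_fit_result("single", p[c("i_n", "i_d", "tm1", "a")], best$rss,
                  nrow(curve), converged = TRUE)
}

#' Fit a two-transition melt model
#'
#' Least-squares fit of the double sigmoid
#' `I_N + (I_2 - I_N)/(1 + exp((T_m1 - T)/a)) +
#'  (I_D - I_2)/(1 + exp((T_m2 - T)/b))`. Parameters are relabelled if
#' needed so that `T_m1 < T_m2`; `T_m1` is the first transition.
#'
#' @inheritParams fit_single_transition
#' @return A `varsite_melt_fit` with fields `i_n`, `i_2`, `i_d`, `tm1`, `a`,
#'   `tm2`, `b`.
#' @export
fit_two_transition <- function(curve) {
  if (nrow(curve) < 9L) stop("need at least 9 points for a two-transition fit")
  rng <- range(curve$temperature)
  if (diff(range(curve$bcm)) < 0.05) {
    return(melt_fit_result("two_transition",
                           list(i_n = NA, i_2 = NA, i_d = NA, tm1 = NA,
                                a = NA, tm2 = NA, b = NA),
                           rss = NA_real_, n = nrow(curve), converged = FALSE,
                           message = "no transition: curve is flat"))
  }
  st <- melt_starts(curve)
  span <- diff(rng)
  best <- NULL
  for (tm0 in st$tm_candidates) {
    for (sep in c(0.15, 0.3) * span) {
      tm1_0 <- max(rng[1], tm0 - sep / 2)
      tm2_0 <- min(rng[2], tm0 + sep / 2)
      fit <- try_nls(
        bcm ~ sigmoid2(temperature, i_n, i_2, i_d, tm1, a, tm2, b),
        data = curve,
        start = list(i_n = st$i_n, i_2 = (st$i_n + st$i_d) / 2, i_d = st$i_d,
                     tm1 = tm1_0, a = 2, tm2 = tm2_0, b = 2),
        lower = c(-Inf, -Inf, -Inf, rng[1], 1e-3, rng[1], 1e-3),
        upper = c(Inf, Inf, Inf, rng[2], Inf, rng[2], Inf))
      if (is.null(fit)) next
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(melt_fit_result("two_transition",
                           list(i_n = NA, i_2 = NA, i_d = NA, tm1 = NA,
                                a = NA, tm2 = NA, b = NA),
                           rss = NA_real_, n = nrow(curve), converged = FALSE,
                           message = "no start converged"))
  }
  p <- as.list(stats::coef(best$fit))
  if (p$tm2 < p$tm1) {
    # swap the two transitions; the intermediate baseline transforms as
    # I_2' = I_N + I_D - I_2 so the model value is unchanged
    p <- list(i_n = p$i_n, i_2 = p$i_n + p$i_d - p$i_2, i_d = p$i_d,
              tm1 = p$tm2, a = p$b, tm2 = p$tm1, b = p$a)
  }
  melt_fit_result("two_transition",
                  p[c("i_n", "i_2", "i_d", "tm1", "a", "tm2", "b")],
                  best$rss, nrow(curve), converged = TRUE)
}

#' Choose between single- and two-transition fits
#'
#' Selection by small-sample-corrected Akaike information criterion; ties
#' (and anything within `tol`) go to the simpler single-transition model.
#'
#' @param single_fit,double_fit Results of [fit_single_transition()] and
#'   [fit_two_transition()] on the same curve.
#' @param tol AICc margin the two-transition model must beat.
#' @return The selected `varsite_melt_fit`; if neither converged, a flagged
#'   result.
#' @export
select_model <- function(single_fit, double_fit, tol = 0) {
  if (!single_fit$converged && !double_fit$converged) {
    return(melt_fit_result("none", list(), NA_real_, single_fit$n,
                           converged = FALSE,
                           message = "neither model converged"))
  }
  if (!double_fit$converged) return(single_fit)
  if (!single_fit$converged) return(double_fit)
  if (double_fit$aicc < single_fit$aicc - tol) double_fit else single_fit
}

#' Unfolding red-shift from a melt fit
#'
#' The difference between the unfolded and folded fluorescence baselines,
#' `I_D - I_N`, in nm. Values below ~6 nm are the signature of a misfolded
#' starting state (the unfolded-state emission is mutation-insensitive, so a
#' small shift means the folded-state emission was already red).
#'
#' @param fit A converged `varsite_melt_fit`.
#' @return Red-shift in nm.
#' @export
red_shift <- function(fit) {
  stopifnot(inherits(fit, "varsite_melt_fit"))
  if (!fit$converged) stop("cannot compute red-shift from a flagged fit")
  fit$i_d - fit$i_n
}

#' Red-shift from raw pre-/post-transition averages
#'
#' Model-free alternative to [red_shift()]: mean barycentric mean of the last
#' `frac` of points minus that of the first `frac`.
#'
#' @param curve A `varsite_melt_curve`.
#' @param frac Fraction of points averaged at each end.
#' @return Red-shift in nm.
#' @export
red_shift_raw <- function(curve, frac = 0.1) {
  n <- nrow(curve)
  k <- max(2L, ceiling(frac * n))
  mean(utils::tail(curve$bcm, k)) - mean(utils::head(curve$bcm, k))
}

#' Fit melt curves for replicated variants
#'
#' Runs [build_melt_curve()], both transition fits and [select_model()] per
#' variant and replicate, and summarises each variant by the median and range
#' of T_m1 and red-shift across replicates.
#'
#' @param spectra Long data frame: `variant`, `replicate`, `temperature`,
#'   `wavelength`, `intensity`.
#' @return List with `fits` (per replicate: variant, replicate, model, tm1,
#'   tm2, red_shift, converged) and `summary` (per variant medians/ranges).
#' @export
fit_melt_replicates <- function(spectra) {
  req <- c("variant", "replicate", "temperature", "wavelength", "intensity")
  if (!all(req %in% names(spectra))) {
    stop("spectra must have columns ", paste(req, collapse = ", "))
  }
  groups <- split(spectra, list(spectra$variant, spectra$replicate),
                  drop = TRUE)
  fits <- do.call(rbind, lapply(groups, function(g) {
    curve <- build_melt_curve(g)
    f1 <- fit_single_transition(curve)
    f2 <- if (nrow(curve) >= 9L) fit_two_transition(curve) else
      melt_fit_result("two_transition", list(), NA_real_, nrow(curve), FALSE,
                      "too few points")
    f <- select_model(f1, f2)
    data.frame(variant = g$variant[1], replicate = g$replicate[1],
               model = f$model,
               tm1 = if (f$converged) f$tm1 else NA_real_,
               tm2 = if (f$converged && !is.null(f$tm2)) f$tm2 else NA_real_,
               red_shift = if (f$converged) f$i_d - f$i_n else NA_real_,
               converged = f$converged, stringsAsFactors = FALSE)
  }))
  rownames(fits) <- NULL
  summary <- do.call(rbind, lapply(split(fits, fits$variant), function(g) {
    data.frame(variant = g$variant[1],
               tm1 = stats::median(g$tm1, na.rm = TRUE),
               tm1_range = diff(range(g$tm1, na.rm = TRUE)),
               red_shift = stats::median(g$red_shift, na.rm = TRUE),
               red_shift_range = diff(range(g$red_shift, na.rm = TRUE)),
               n_replicates = nrow(g),
               n_converged = sum(g$converged), stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(fits = fits, summary = summary)
}
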