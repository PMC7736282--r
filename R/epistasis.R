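#' Parse a mutation string
#'
#' Mutations are written `K41D` (wild-type residue, position, mutant
#' residue) and multi-mutants joined by `-` or `+` (`"K41D-A201R"`). The
#' wild type is an empty mutation list (name `"WT"` or empty string).
#'
#' @param x Character vector of mutation strings.
#' @return List of data frames with columns `wt`, `position`, `mut`.
#' @export
parse_mutations <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s == "" || toupper(s) == "WT") {
      return(data.frame(wt = character(), position = integer(),
                        mut = character()))
    }
    parts <- strsplit(s, "[-+/]")[[1]]
    m <- regmatches(parts, regexec("^([A-Z])([0-9]+)([A-Z])$", parts))
    bad <- vapply(m, length, integer(1)) != 4L
    if (any(bad)) {
      stop("cannot parse mutation(s): ", paste(parts[bad], collapse = ", "))
    }
    out <- data.frame(wt = vapply(m, `[`, character(1), 2),
                      position = as.integer(vapply(m, `[`, character(1), 3)),
                      mut = vapply(m, `[`, character(1), 4))
    if (anyDuplicated(out$position)) {
      stop("duplicate mutated position in '", s, "'")
    }
    out
  })
}

#' Per-mutation effects on melting temperature and activity
#'
#' For every single mutant in the table, the change relative to wild type:
#' `dTm = Tm1(mutant) - Tm1(WT)` and `dActivity = activity(mutant) -
#' activity(WT)`. The wild type itself has both effects identically 0.
#'
#' @param variants Data frame with columns `name`, `mutations` (string, ""
#'   or "WT" for wild type), `tm1` and optionally `activity`.
#' @return Data frame of class `varsite_effects`: `mutation`, `d_tm`,
#'   `d_activity`.
#' @export
single_effects <- function(variants) {
  muts <- parse_mutations(variants$mutations)
  n_mut <- vapply(muts, nrow, integer(1))
  wt_row <- which(n_mut == 0L)
  if (length(wt_row) != 1L) {
    stop("variant table must contain exactly one wild-type row")
  }
  tm_wt <- variants$tm1[wt_row]
  act_wt <- if ("activity" %in% names(variants)) variants$activity[wt_row]
            else NA_real_
  singles <- which(n_mut == 1L)
  out <- data.frame(
    mutation = vapply(muts[singles], function(m)
      paste0(m$wt, m$position, m$mut), character(1)),
    d_tm = variants$tm1[singles] - tm_wt,
    d_activity = if ("activity" %in% names(variants))
      variants$activity[singles] - act_wt else NA_real_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("varsite_effects", "data.frame")
  attr(out, "tm_wt") <- tm_wt
  attr(out, "activity_wt") <- act_wt
  out
}

#' Melting-temperature epistasis for multi-mutants
#'
#' For each variant, the expected dTm under additivity is the sum of its
#' constituent single-mutation dTm values; the deviation
#' `observed - expected` measures epistasis, negative values meaning the
#' combination is worse than additive. Single mutants (and WT) deviate 0 by
#' definition. Multi-mutants with a missing constituent single mutant are
#' skipped with a warning. An `expected_activity_mult` column carries a
#' multiplicative (log-ratio additive) null for the activity ratio, the
#' natural analogue for a strictly positive ratio scale; it is `NA` for
#' variants whose constituent activities are censored at 0.
#'
#' @param variants Data frame as in [single_effects()].
#' @param effects Optional precomputed [single_effects()] table.
#' @return Data frame of class `varsite_epistasis`: `name`, `n_mutations`,
#'   `observed_d_tm`, `expected_d_tm`, `deviation`,
#'   `expected_activity_mult`.
#' @export
epistasis <- function(variants, effects = single_effects(variants)) {
  muts <- parse_mutations(variants$mutations)
  tm_wt <- attr(effects, "tm_wt")
  act_wt <- attr(effects, "activity_wt")
  has_act <- "activity" %in% names(variants)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    m <- muts[[i]]
    if (nrow(m) == 0L) {
      return(data.frame(name = variants$name[i], n_mutations = 0L,
                        observed_d_tm = 0, expected_d_tm = 0, deviation = 0,
                        expected_activity_mult = if (has_act) act_wt else NA_real_,
                        stringsAsFactors = FALSE))
    }
    labels <- paste0(m$wt, m$position, m$mut)
    idx <- match(labels, effects$mutation)
    if (anyNA(idx)) {
      if (nrow(m) > 1L) {
        warning("skipping ", variants$name[i],
                ": missing constituent single mutant(s) ",
                paste(labels[is.na(idx)], collapse = ", "))
        return(NULL)
      }
      # a single mutant is its own constituent
      idx <- i
      expected <- variants$tm1[i] - tm_wt
    } else {
      expected <- sum(effects$d_tm[idx])
    }
    observed <- variants$tm1[i] - tm_wt
    exp_act <- NA_real_
    if (has_act && !anyNA(idx) && length(idx) >= 1L && !is.na(act_wt) &&
        act_wt > 0) {
      ratios <- (effects$d_activity[idx] + act_wt) / act_wt
      exp_act <- if (all(ratios > 0)) act_wt * prod(ratios) else NA_real_
    }
    data.frame(name = variants$name[i], n_mutations = nrow(m),
               observed_d_tm = observed, expected_d_tm = expected,
               deviation = if (nrow(m) == 1L) 0 else observed - expected,
               expected_activity_mult = exp_act, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("varsite_epistasis", "data.frame")
  out
}
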