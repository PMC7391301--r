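# Median-effect (Chou-Talalay) synergy quantification: fraction affected,
# median-effect fits, Combination Index, Dose Reduction Index, Fa-CI
# tables and potent-synergy classification.

#' Fraction affected for growth inhibition
#'
#' Fa = 1 - X_combo / X_ctl, where X is the measured cell number (or any
#' proportional readout such as normalised radiance): 0 means no effect
#' relative to control, 1 complete growth inhibition. The raw value is
#' returned; clamping into the fittable open interval happens inside
#' \code{\link{fit_median_effect}}.
#'
#' @param x_combo Measured value(s) under treatment.
#' @param x_ctl Control value(s); must be positive.
#' @return Numeric vector of raw fractions affected.
#' @export
fa_growth <- function(x_combo, x_ctl) {
  if (any(x_ctl <= 0)) stop("`x_ctl` must be positive", call. = FALSE)
  1 - x_combo / x_ctl
}

# Clamp raw fa into the open unit interval used for fitting.
clamp_fa <- function(fa, lo = 0.005, hi = 0.995) pmin(pmax(fa, lo), hi)

#' Fit the median-effect model to a dose-response series
#'
#' Linearises the median-effect equation fa/(1-fa) = (D/Dm)^m as
#' log10(fa/(1-fa)) = m log10(D) - m log10(Dm) and fits it by ordinary
#' least squares. Raw fractions affected outside (0.005, 0.995) are
#' clamped to those bounds for fitting and flagged.
#'
#' @param dose Positive dose vector.
#' @param fa Raw fractions affected (same length); alternatively supply
#'   \code{effect} and \code{control} to derive fa via
#'   \code{\link{fa_growth}}.
#' @param effect,control Optional measured and control values.
#' @param drug Optional drug (or pair-entity) label.
#' @param clamp Length-2 clamping bounds for fitting.
#' @return An object of class \code{"median_effect"}: list with \code{m}
#'   (slope), \code{dm} (median-effect dose Dm), \code{r_fit} (Pearson
#'   correlation of the linearised fit), \code{n_points_used},
#'   \code{n_clamped}, \code{data} and \code{fit} (the underlying
#'   \code{lm}).
#' @export
fit_median_effect <- function(dose, fa = NULL, effect = NULL, control = NULL,
                              drug = "drug", clamp = c(0.005, 0.995)) {
  if (is.null(fa)) {
    if (is.null(effect) || is.null(control)) {
      stop("supply either `fa` or both `effect` and `control`", call. = FALSE)
    }
    fa <- fa_growth(effect, control)
  }
  if (any(dose <= 0)) stop("all doses must be positive", call. = FALSE)
  if (length(dose) != length(fa)) stop("`dose` and `fa` lengths differ",
                                       call. = FALSE)
  clamped <- fa < clamp[1L] | fa > clamp[2L]
  fa_fit <- clamp_fa(fa, clamp[1L], clamp[2L])
  if (length(unique(dose)) < 2L) {
    stop("need at least 2 distinct doses with usable fa", call. = FALSE)
  }
  x <- log10(dose)
  y <- log10(fa_fit / (1 - fa_fit))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2L])
  if (!is.finite(m) || m <= 0) {
    stop("median-effect slope is not positive; dose-response is not increasing",
         call. = FALSE)
  }
  dm <- 10^(-unname(stats::coef(fit)[1L]) / m)
  structure(list(
    drug = drug, m = m, dm = dm,
    r_fit = stats::cor(x, y),
    n_points_used = length(dose), n_clamped = sum(clamped),
    data = data.frame(dose = dose, fa = fa, fa_fit = fa_fit,
                      clamped = clamped),
    fit = fit
  ), class = "median_effect")
}

#' @export
print.median_effect <- function(x, ...) {
  cat(sprintf(
    "Median-effect fit [%s]: m = %.4g, Dm = %.4g (r = %.4f, %d points%s)\n",
    x$drug, x$m, x$dm, x$r_fit, x$n_points_used,
    if (x$n_clamped > 0L) sprintf(", %d clamped", x$n_clamped) else ""
  ))
  invisible(x)
}

#' @export
summary.median_effect <- function(object, ...) {
  print(object)
  cat(sprintf("EC50 = %.4g, EC75 = %.4g, EC90 = %.4g (dose units)\n",
              effective_conc(object, 50), effective_conc(object, 75),
              effective_conc(object, 90)))
  invisible(object)
}

#' @export
coef.median_effect <- function(object, ...) {
  c(m = object$m, dm = object$dm)
}

#' Predicted fraction affected at given doses
#'
#' @param object A \code{"median_effect"} fit.
#' @param newdata Optional positive dose vector (defaults to the fitted
#'   doses).
#' @param ... Unused.
#' @return Predicted fa values under the fitted median-effect curve.
#' @export
predict.median_effect <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$dose else newdata
  if (any(d <= 0)) stop("doses must be positive", call. = FALSE)
  z <- (d / object$dm)^object$m
  z / (1 + z)
}

#' @export
residuals.median_effect <- function(object, ...) {
  stats::residuals(object$fit)
}

#' Plot a median-effect fit
#'
#' Observed fa against dose (log axis) with the fitted median-effect
#' curve.
#'
#' @param x A \code{"median_effect"} fit.
#' @param ... Passed to \code{plot}.
#' @export
plot.median_effect <- function(x, ...) {
  d <- x$data$dose
  grid <- exp(seq(log(min(d) / 2), log(max(d) * 2), length.out = 100))
  plot(d, x$data$fa, log = "x", xlab = "dose", ylab = "fraction affected",
       ylim = c(0, 1), main = sprintf("%s: m = %.3g, Dm = %.3g",
                                      x$drug, x$m, x$dm), ...)
  graphics::lines(grid, predict(x, grid))
  graphics::abline(h = 0.5, lty = 3)
  graphics::abline(v = x$dm, lty = 3)
  invisible(x)
}

#' Dose needed for a given effect
#'
#' Inverts the median-effect equation: Dx = Dm * (fa/(1-fa))^(1/m).
#'
#' @param fit A \code{"median_effect"} fit.
#' @param fa Target fraction(s) affected, strictly in (0, 1).
#' @return Dose(s) Dx.
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect"))
  if (any(fa <= 0 | fa >= 1)) {
    stop("`fa` must lie strictly in (0, 1)", call. = FALSE)
  }
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Effective concentration at a percent-effect level
#'
#' EC_level = Dx(level/100); EC50 equals Dm by definition.
#'
#' @param fit A \code{"median_effect"} fit.
#' @param level Effect level in percent, strictly in (0, 100).
#' @return Dose(s).
#' @export
effective_conc <- function(fit, level) {
  if (any(level <= 0 | level >= 100)) {
    stop("`level` must lie strictly in (0, 100)", call. = FALSE)
  }
  dose_for_effect(fit, level / 100)
}

#' Combination Index and Dose Reduction Index at one combination point
#'
#' CI = sum over drugs of (combination dose / Dx), where Dx is the dose
#' of each drug alone reaching the same fraction affected (mutually
#' exclusive form; \code{exclusive = FALSE} adds the two-drug cross
#' term). DRI_i = Dx_i / dose_i. Dx values come from per-drug
#' median-effect fits, or can be supplied directly (e.g. equivalent
#' single doses read off in vivo dose-response curves).
#'
#' @param doses Per-drug combination doses (0 for an absent drug).
#' @param fa Fraction affected of the combination, strictly in (0, 1);
#'   required with \code{fits}.
#' @param fits List of \code{"median_effect"} fits, one per drug.
#' @param dx Per-drug equivalent single doses at the combination's
#'   effect, bypassing \code{fits}.
#' @param exclusive Use the mutually exclusive CI form (no cross term;
#'   the default and the CompuSyn convention).
#' @return A list of class \code{"combo_point"}: \code{doses},
#'   \code{fa}, \code{dx}, \code{ci}, \code{dri} (NA where the combo
#'   dose is 0).
#' @export
combination_index <- function(doses, fa = NULL, fits = NULL, dx = NULL,
                              exclusive = TRUE) {
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  if (is.null(dx)) {
    if (is.null(fits) || is.null(fa)) {
      stop("supply `dx`, or `fits` together with `fa`", call. = FALSE)
    }
    if (length(fits) != length(doses)) {
      stop("need one median-effect fit per drug", call. = FALSE)
    }
    check_scalar(fa, "fa", lower = 0, upper = 1, open_lower = TRUE,
                 open_upper = TRUE)
    dx <- vapply(fits, dose_for_effect, numeric(1), fa = fa)
  }
  if (length(dx) != length(doses)) stop("`dx` and `doses` lengths differ",
                                        call. = FALSE)
  if (any(dx <= 0)) stop("equivalent doses `dx` must be positive",
                         call. = FALSE)
  terms <- doses / dx
  ci <- sum(terms)
  if (!exclusive) {
    if (length(doses) != 2L) {
      stop("the non-exclusive cross term is defined for two drugs",
           call. = FALSE)
    }
    ci <- ci + prod(terms)
  }
  dri <- ifelse(doses > 0, dx / doses, NA_real_)
  structure(list(doses = doses, fa = fa, dx = dx, ci = ci, dri = dri,
                 exclusive = exclusive),
            class = "combo_point")
}

#' @export
print.combo_point <- function(x, ...) {
  cat(sprintf("Combination point: CI = %.4g (%s form)%s\n", x$ci,
              if (x$exclusive) "exclusive" else "non-exclusive",
              if (!is.null(x$fa)) sprintf(", Fa = %.3g", x$fa) else ""))
  cat("  dose:", paste(signif(x$doses, 4), collapse = ", "),
      " Dx:", paste(signif(x$dx, 4), collapse = ", "),
      " DRI:", paste(signif(x$dri, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Dose Reduction Index
#'
#' DRI = Dx / D_combo: the fold saving of a drug when the combination
#' reaches the same effect as the single agent. DRI > 1 means the
#' combination achieves the effect with less drug.
#'
#' @param dx Single-agent dose reaching the effect.
#' @param d_combo Dose of that drug in the combination; must be positive.
#' @return DRI value(s).
#' @export
dose_reduction_index <- function(dx, d_combo) {
  if (any(d_combo <= 0)) stop("`d_combo` must be positive", call. = FALSE)
  dx / d_combo
}

#' Classify potent synergy across combination orientations
#'
#' A combination is potent when every tested orientation (which drug was
#' varied against fixed doses of the other(s)) contains at least one
#' point with Fa above \code{fa_min} and CI below \code{ci_max}.
#'
#' @param points A data frame with columns \code{fa} and \code{ci} (and
#'   optionally \code{orientation}), or a list of such data frames, one
#'   per orientation.
#' @param fa_min Minimum fraction affected (default 0.7, "major
#'   enhancement").
#' @param ci_max Maximum Combination Index (default 0.7, synergy).
#' @return An object of class \code{"synergy_assessment"}: list with
#'   \code{potent}, \code{per_orientation} (logical), \code{criteria}
#'   and \code{points}.
#' @export
classify_potent <- function(points, fa_min = 0.7, ci_max = 0.7) {
  if (is.data.frame(points)) {
    points <- if ("orientation" %in% names(points)) {
      split(points, points$orientation)
    } else {
      list(points)
    }
  }
  if (length(points) == 0L) stop("need at least one orientation",
                                 call. = FALSE)
  per <- vapply(points, function(p) {
    any(p$fa > fa_min & p$ci < ci_max)
  }, logical(1))
  structure(list(potent = all(per), per_orientation = per,
                 criteria = c(fa_min = fa_min, ci_max = ci_max),
                 points = points),
            class = "synergy_assessment")
}

#' @export
print.synergy_assessment <- function(x, ...) {
  cat(sprintf(
    "Synergy assessment: %s (need Fa > %g and CI < %g in each of %d orientation(s))\n",
    if (x$potent) "POTENT synergy" else "not potent",
    x$criteria["fa_min"], x$criteria["ci_max"], length(x$per_orientation)
  ))
  invisible(x)
}

#' Fa-CI plot of a synergy assessment
#'
#' @param x A \code{"synergy_assessment"}.
#' @param ... Passed to \code{plot}.
#' @export
plot.synergy_assessment <- function(x, ...) {
  pts <- do.call(rbind, lapply(x$points, function(p) p[, c("fa", "ci")]))
  plot(pts$fa, pts$ci, xlab = "Fa", ylab = "CI", xlim = c(0, 1),
       ylim = c(0, max(1.5, max(pts$ci))), ...)
  graphics::abline(h = 1, lty = 2)
  graphics::rect(x$criteria["fa_min"], 0, 1, x$criteria["ci_max"],
                 border = NA, col = grDevices::adjustcolor("grey", 0.3))
  invisible(x)
}

#' Three-drug Combination Index via the pair-as-entity device
#'
#' A fixed-ratio drug pair is treated as a single entity (entity dose =
#' sum of the component doses), fitted with its own median-effect model
#' from pair-alone rows, and combined with the third drug:
#' CI = D_pair/Dx_pair(fa) + D_third/Dx_third(fa). The dose-response
#' table must contain pair-alone rows (drugs 1 and 2 dosed, drug 3 at
#' 0), third-drug-alone rows, and triple rows; the drug1:drug2 ratio may
#' not drift by more than 1\% across pair-containing rows.
#'
#' @param tbl Dose-response data frame in the combination dialect
#'   (columns \code{drug1_dose}, \code{drug2_dose}, \code{drug3_dose},
#'   \code{effect_value}, \code{control_value}).
#' @param ratio_tol Maximum relative drift of the pair ratio.
#' @return A list with \code{pair_fit}, \code{third_fit} and
#'   \code{points}: a data frame (one row per triple combination) with
#'   \code{fa}, \code{ci}, and DRIs for the pair entity and the third
#'   drug.
#' @export
three_drug_ci <- function(tbl, ratio_tol = 0.01) {
  need <- c("drug1_dose", "drug2_dose", "drug3_dose", "effect_value",
            "control_value")
  if (!all(need %in% names(tbl))) {
    stop(sprintf("`tbl` needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  d1 <- tbl$drug1_dose
  d2 <- tbl$drug2_dose
  d3 <- tbl$drug3_dose
  pair_rows <- d1 > 0 & d2 > 0 & d3 == 0
  third_rows <- d1 == 0 & d2 == 0 & d3 > 0
  triple_rows <- d1 > 0 & d2 > 0 & d3 > 0
  if (!any(pair_rows)) stop("no pair-alone rows", call. = FALSE)
  if (!any(third_rows)) stop("no third-drug-alone rows", call. = FALSE)
  if (!any(triple_rows)) stop("no triple rows", call. = FALSE)
  ratios <- (d2 / d1)[pair_rows | triple_rows]
  if (diff(range(ratios)) > ratio_tol * stats::median(ratios)) {
    stop(sprintf("pair ratio drifts more than %.1f%% across rows",
                 100 * ratio_tol), call. = FALSE)
  }
  fa_all <- fa_growth(tbl$effect_value, tbl$control_value)
  pair_fit <- fit_median_effect((d1 + d2)[pair_rows], fa_all[pair_rows],
                                drug = "pair")
  third_fit <- fit_median_effect(d3[third_rows], fa_all[third_rows],
                                 drug = "third")
  tri <- which(triple_rows)
  fa_tri <- clamp_fa(fa_all[tri])
  dx_pair <- dose_for_effect(pair_fit, fa_tri)
  dx_third <- dose_for_effect(third_fit, fa_tri)
  pair_dose <- (d1 + d2)[tri]
  points <- data.frame(
    pair_dose = pair_dose, third_dose = d3[tri], fa = fa_tri,
    ci = pair_dose / dx_pair + d3[tri] / dx_third,
    dri_pair = dx_pair / pair_dose, dri_third = dx_third / d3[tri],
    row.names = NULL
  )
  list(pair_fit = pair_fit, third_fit = third_fit, points = points)
}

#' Normalise growth series to day 0
#'
#' Each replicate's trajectory (e.g. radiance total flux or cell counts)
#' is divided by its own day-0 value, then the replicates are averaged
#' per timepoint. The normalised treated-versus-vehicle values at a
#' matched day feed \code{\link{fa_growth}}.
#'
#' @param series Data frame with columns \code{day}, \code{replicate},
#'   \code{value}.
#' @return Data frame with columns \code{day} and \code{value} (mean
#'   normalised), with the per-replicate normalised series as attribute
#'   \code{"replicates"}.
#' @export
growth_series_normalize <- function(series) {
  need <- c("day", "replicate", "value")
  if (!all(need %in% names(series))) {
    stop("`series` needs columns day, replicate, value", call. = FALSE)
  }
  out <- lapply(split(series, series$replicate), function(s) {
    d0 <- s$value[s$day == 0]
    if (length(d0) != 1L) {
      stop(sprintf("replicate '%s' needs exactly one day-0 value",
                   s$replicate[1L]), call. = FALSE)
    }
    if (d0 <= 0) {
      stop(sprintf("replicate '%s' has non-positive day-0 value",
                   s$replicate[1L]), call. = FALSE)
    }
    s$value <- s$value / d0
    s
  })
  norm <- do.call(rbind, c(out, make.row.names = FALSE))
  agg <- stats::aggregate(value ~ day, data = norm, FUN = mean)
  structure(agg[order(agg$day), , drop = FALSE], replicates = norm)
}
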