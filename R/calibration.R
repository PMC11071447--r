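#' Dose-response data: replicate assay signals per concentration
#'
#' Container for the calibration data of one assay run: for each antigen
#' concentration (pg/mL in the diluted sample), the replicate flow distances
#' (cm) read at the detection frame. Summary statistics use the standard
#' error of the mean, `sem = sd / sqrt(n)`.
#'
#' @param concentration numeric vector of concentrations, one per group.
#' @param signals list of numeric replicate vectors, parallel to
#'   `concentration`; or a data frame with columns `concentration` and
#'   `signal` (then `concentration` may be omitted).
#' @return An object of class `dose_response` with a `summary` data frame
#'   (`concentration, n, mean, sd, sem`) and the replicate list.
#' @export
dose_response <- function(concentration, signals) {
  if (missing(signals) && is.data.frame(concentration)) {
    df <- concentration
    if (!all(c("concentration", "signal") %in% names(df)))
      stop_capflow("data frame needs columns concentration, signal", "capflow_schema_error")
    signals <- split(df$signal, df$concentration)
    concentration <- as.numeric(names(signals))
  }
  o <- order(concentration)
  concentration <- concentration[o]
  signals <- signals[o]
  if (anyDuplicated(concentration))
    stop_capflow("duplicate concentrations; merge replicates first", "capflow_schema_error")
  sm <- data.frame(
    concentration = concentration,
    n = vapply(signals, length, integer(1)),
    mean = vapply(signals, mean, numeric(1)),
    sd = vapply(signals, sd, numeric(1)))
  sm$sem <- sm$sd / sqrt(sm$n)
  structure(list(summary = sm, replicates = setNames(signals, concentration)),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> %d concentrations, %d signals total\n",
              nrow(x$summary), sum(x$summary$n)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.dose_response <- function(x, ...) {
  sm <- x$summary
  plot(sm$concentration, sm$mean, xlab = "concentration (pg/mL)",
       ylab = "signal (cm)", main = "Dose response", ...)
  segments(sm$concentration, sm$mean - sm$sem, sm$concentration, sm$mean + sm$sem)
  invisible(x)
}

#' Welch two-sample t-test (unequal variances)
#'
#' Two-sided two-sample t-test with the Welch-Satterthwaite degrees of
#' freedom, the comparison the assay uses between each concentration and the
#' negative control. Degenerate zero-variance inputs are resolved by the mean
#' difference: equal means give p = 1, different means p = 0 (flagged).
#'
#' @param a,b numeric samples with at least 2 values each.
#' @return list `statistic` (t), `df`, `p_value`, `degenerate` (logical).
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop_capflow("each sample needs >= 2 values", "capflow_domain_error")
  if (var(a) == 0 && var(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(statistic = if (same) 0 else Inf * sign(mean(a) - mean(b)),
                df = NA_real_, p_value = if (same) 1 else 0, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, degenerate = FALSE)
}

#' Limit of detection against the negative control
#'
#' The LOD is the smallest nonzero concentration whose replicate signals
#' differ from the zero-concentration negative control in a Welch t-test at
#' raw `p < alpha` (each concentration tested individually, no
#' multiple-testing correction — the caveat being an inflated family-wise
#' false-positive rate).
#'
#' @param dr a [dose_response()] containing concentration 0 with `n >= 2`.
#' @param alpha significance level (default 0.05).
#' @return the LOD concentration, or `NA` if no concentration is
#'   significant. The per-concentration p-values are attached as attribute
#'   `"p_values"`.
#' @export
find_lod <- function(dr, alpha = 0.05) {
  stopifnot(inherits(dr, "dose_response"))
  ctrl <- dr$replicates[dr$summary$concentration == 0]
  if (!length(ctrl) || length(ctrl[[1]]) < 2)
    stop_capflow("dose_response must contain a zero-concentration control with n >= 2",
                 "capflow_contract_error")
  ctrl <- ctrl[[1]]
  conc <- dr$summary$concentration[dr$summary$concentration > 0]
  p <- vapply(as.character(conc), function(cc) {
    welch_t_test(dr$replicates[[cc]], ctrl)$p_value
  }, numeric(1))
  hit <- conc[p < alpha]
  structure(if (length(hit)) min(hit) else NA_real_, p_values = setNames(p, conc))
}

#' Fit a four-parameter logistic calibration curve
#'
#' Fits the 4PL sigmoid on log10 concentration,
#' `y = lower + (upper - lower) / (1 + exp((xmid - x) / scal))`, to the
#' replicate signals. The zero-concentration control is placed one decade
#' below the smallest nonzero concentration on the log axis. If the mean
#' response has an interior maximum (hook effect) and at least 5
#' concentrations lie at or below it, only the pre-peak limb is fitted and
#' the excluded concentrations are flagged. When the sigmoid fit fails to
#' converge the fit falls back to a straight line in concentration.
#'
#' @param dr a [dose_response()] with at least 5 distinct concentrations.
#' @return An object of class `calibration_fit`: `model` ("4PL sigmoid" or
#'   "linear"), `params` (lower, upper, ec50, slope — or intercept, slope),
#'   `r2`, `direction` ("increasing"/"decreasing"), `lod`, `linear_range`,
#'   `excluded` (hook-limb concentrations), `fallback` flag.
#' @export
fit_sigmoid <- function(dr) {
  stopifnot(inherits(dr, "dose_response"))
  sm <- dr$summary
  if (nrow(sm) < 5)
    stop_capflow("need >= 5 distinct concentrations", "capflow_contract_error")
  ipeak <- which.max(sm$mean)
  excluded <- numeric(0)
  use <- sm$concentration
  if (ipeak > 1 && ipeak < nrow(sm) && ipeak >= 5) {
    use <- sm$concentration[seq_len(ipeak)]
    excluded <- sm$concentration[-seq_len(ipeak)]
  }
  x_of <- pseudo_log10(use)
  df <- do.call(rbind, lapply(seq_along(use), function(i) {
    data.frame(x = x_of[i], y = dr$replicates[[as.character(use[i])]])
  }))
  # scaleOffset makes the convergence test valid on zero-residual (noiseless)
  # data, cf. ?nls; a second attempt uses the SSfpl self-start.
  ctrl <- stats::nls.control(maxiter = 500, tol = 1e-10, scaleOffset = 1)
  fit <- tryCatch(
    nls(y ~ A + (B - A) / (1 + exp((xmid - x) / scal)),
        data = df, start = fpl_start(df), control = ctrl),
    error = function(e) tryCatch(
      nls(y ~ SSfpl(x, A, B, xmid, scal), data = df, control = ctrl),
      error = function(e2) NULL))
  lod <- tryCatch(as.numeric(find_lod(dr)), error = function(e) NA_real_)
  lr <- tryCatch(linear_range(dr), error = function(e) NULL)
  if (is.null(fit)) {
    lf <- lm(y ~ conc, data = data.frame(conc = rep(use, sm$n[match(use, sm$concentration)]),
                                         y = df$y))
    co <- coef(lf)
    return(structure(list(model = "linear",
                          params = c(intercept = unname(co[1]), slope = unname(co[2])),
                          r2 = summary(lf)$r.squared,
                          direction = if (co[2] >= 0) "increasing" else "decreasing",
                          lod = lod, linear_range = lr, excluded = excluded,
                          fallback = TRUE, span = range(use), dr = dr),
                     class = "calibration_fit"))
  }
  co <- coef(fit)
  pred <- predict(fit)
  r2 <- 1 - sum((df$y - pred)^2) / sum((df$y - mean(df$y))^2)
  increasing <- unname((co["B"] - co["A"]) / co["scal"]) > 0
  structure(list(model = "4PL sigmoid",
                 params = c(lower = unname(if (increasing) min(co[c("A", "B")]) else max(co[c("A", "B")])),
                            upper = unname(if (increasing) max(co[c("A", "B")]) else min(co[c("A", "B")])),
                            ec50 = unname(10^co["xmid"]),
                            slope = unname(1 / co["scal"])),
                 raw = co,
                 r2 = r2,
                 direction = if (increasing) "increasing" else "decreasing",
                 lod = lod, linear_range = lr, excluded = excluded,
                 fallback = FALSE, span = range(use), dr = dr),
            class = "calibration_fit")
}

# log10 with the zero-concentration control mapped one decade below the
# smallest nonzero concentration.
pseudo_log10 <- function(conc) {
  nz <- conc[conc > 0]
  floor_x <- log10(min(nz)) - 1
  ifelse(conc > 0, log10(conc), floor_x)
}

# crude self-start for the shifted logistic on already-log x
fpl_start <- function(df) {
  ymin <- min(df$y); ymax <- max(df$y)
  xmed <- median(df$x)
  up <- mean(df$y[df$x > xmed]) >= mean(df$y[df$x <= xmed])
  list(A = if (up) ymin else ymax, B = if (up) ymax else ymin,
       xmid = xmed, scal = diff(range(df$x)) / 4)
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> %s (%s), r2 = %0.4f%s\n", x$model, x$direction,
              x$r2, if (x$fallback) " [linear fallback]" else ""))
  print(round(x$params, 6))
  if (length(x$excluded))
    cat("hook limb excluded at concentrations:", paste(x$excluded, collapse = ", "), "\n")
  if (!is.null(x$linear_range))
    cat(sprintf("linear range %g-%g pg/mL (r2 = %0.3f); LOD = %s pg/mL\n",
                x$linear_range$range[1], x$linear_range$range[2],
                x$linear_range$r2, format(x$lod)))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) object$params

#' Predict the assay signal from concentration
#'
#' @param object a `calibration_fit`.
#' @param concentration concentrations (pg/mL) at which to evaluate the fit.
#' @param ... unused.
#' @export
predict.calibration_fit <- function(object, concentration, ...) {
  if (missing(concentration)) concentration <- object$dr$summary$concentration
  if (object$model == "linear") {
    return(object$params["intercept"] + object$params["slope"] * concentration)
  }
  co <- object$raw
  x <- pseudo_log10_at(concentration, object)
  unname(co["A"] + (co["B"] - co["A"]) / (1 + exp((co["xmid"] - x) / co["scal"])))
}

pseudo_log10_at <- function(conc, object) {
  nz <- object$dr$summary$concentration
  nz <- nz[nz > 0]
  floor_x <- log10(min(nz)) - 1
  ifelse(conc > 0, log10(conc), floor_x)
}

# Invert a calibration fit: signal -> concentration on the fitted span.
invert_calibration <- function(calib, signal) {
  if (calib$model == "linear") {
    if (calib$params["slope"] == 0)
      stop_capflow("flat calibration cannot be inverted", "capflow_degenerate_fit")
    return(unname((signal - calib$params["intercept"]) / calib$params["slope"]))
  }
  co <- calib$raw
  lo <- min(co[c("A", "B")]); hi <- max(co[c("A", "B")])
  eps <- 1e-9 * max(1, hi - lo)
  s <- pmin(pmax(signal, lo + eps), hi - eps)
  x <- unname(co["xmid"] - co["scal"] * log((co["B"] - co["A"]) / (s - co["A"]) - 1))
  10^x
}

#' Linear range of a dose response
#'
#' Searches all contiguous windows of at least `min_points` consecutive
#' concentrations and returns the widest — the one spanning the most grid
#' concentrations, ties broken by higher r-squared — whose ordinary
#' least-squares fit of mean signal against concentration achieves
#' `r2 >= r2_min`. Counting grid points (rather than concentration span)
#' keeps a sparse tail of high concentrations from outweighing the dense
#' rising limb calibration grids are designed around.
#'
#' @param dr a [dose_response()].
#' @param r2_min minimum r-squared for a window to qualify (default 0.75).
#' @param min_points minimum window length (default 3).
#' @return list `range` (c(lo, hi) in concentration), `slope`, `intercept`,
#'   `r2`, or `NULL` (with a warning) when no window qualifies.
#' @export
linear_range <- function(dr, r2_min = 0.75, min_points = 3L) {
  stopifnot(inherits(dr, "dose_response"))
  sm <- dr$summary
  n <- nrow(sm)
  if (n < min_points)
    stop_capflow("fewer concentrations than min_points", "capflow_contract_error")
  best <- NULL
  for (i in seq_len(n - min_points + 1)) {
    for (j in (i + min_points - 1):n) {
      cc <- sm$concentration[i:j]; yy <- sm$mean[i:j]
      f <- lm(yy ~ cc)
      ssr <- sum(residuals(f)^2); tss <- sum((yy - mean(yy))^2)
      r2 <- if (tss > 0) 1 - ssr / tss else 1
      if (r2 < r2_min) next
      width <- j - i + 1
      if (is.null(best) || width > best$width ||
          (width == best$width && r2 > best$r2)) {
        best <- list(range = range(cc), slope = unname(coef(f)[2]),
                     intercept = unname(coef(f)[1]), r2 = r2, width = width,
                     n_points = j - i + 1)
      }
    }
  }
  if (is.null(best)) {
    warn_capflow(sprintf("no contiguous window of >= %d points reaches r2 >= %g",
                         min_points, r2_min), "capflow_no_linear_range")
    return(NULL)
  }
  best$width <- NULL
  best
}

#' Classify a sample signal into a concentration tier
#'
#' Inverts the calibration to a concentration and compares it against two
#' concentration cut points. Decreasing calibrations are handled by the
#' inversion itself (a high signal then maps to a low concentration). A
#' signal outside the calibrated signal span is clamped to the nearest
#' endpoint and flagged as extrapolated. A concentration exactly at a cut is
#' assigned to the higher tier.
#'
#' The default cuts, 14.95 and 54.95 ng/mL, are the midpoints between the
#' clinical groups low 8.6-11.9, middle 18.0-23.1 and high 86.8-197 ng/mL
#' (undiluted plasma equivalents); pass cuts in the units of the calibration.
#'
#' @param signal flow distance (cm) at the detection frame.
#' @param calib a [fit_sigmoid()] calibration.
#' @param cuts two increasing concentration cut points.
#' @return An object of class `tier_label`: `label` ("low"/"middle"/"high"),
#'   `concentration`, `boundaries`, `extrapolated`.
#' @export
classify_tier <- function(signal, calib, cuts = c(14.95, 54.95)) {
  stopifnot(inherits(calib, "calibration_fit"), length(cuts) == 2, cuts[1] < cuts[2])
  span_sig <- range(predict(calib, calib$span))
  extrapolated <- signal < span_sig[1] - 1e-12 || signal > span_sig[2] + 1e-12
  conc <- invert_calibration(calib, min(max(signal, span_sig[1]), span_sig[2]))
  label <- if (conc < cuts[1]) "low" else if (conc < cuts[2]) "middle" else "high"
  structure(list(label = label, concentration = conc, boundaries = cuts,
                 extrapolated = extrapolated),
            class = "tier_label")
}

#' @export
print.tier_label <- function(x, ...) {
  cat(sprintf("<tier_label> %s (concentration %0.4g; cuts %g/%g)%s\n",
              x$label, x$concentration, x$boundaries[1], x$boundaries[2],
              if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' Convert concentrations between diluted and undiluted samples
#'
#' A sample assayed at dilution fraction `f` (10% blood means `f = 0.1`)
#' contains `f` times the original concentration; converting to the
#' undiluted equivalent divides by `f`, re-diluting multiplies. When a unit
#' is supplied, undiluted equivalents of pg/mL values are reported in ng/mL
#' (and ng/mL values re-diluted at 10x or stronger in pg/mL), matching the
#' convention of reporting blood/plasma levels in ng/mL.
#'
#' @param conc concentration value (or a `concentration` object from a
#'   previous call).
#' @param dilution_fraction volume fraction in (0, 1].
#' @param direction `"to_undiluted"` or `"to_diluted"`.
#' @param unit `NULL` for a bare number, or `"pg/mL"` / `"ng/mL"`.
#' @return numeric when `unit` is NULL, else a `concentration` object with
#'   fields `value` and `unit`.
#' @export
convert_dilution <- function(conc, dilution_fraction,
                             direction = c("to_undiluted", "to_diluted"),
                             unit = NULL) {
  direction <- match.arg(direction)
  if (dilution_fraction <= 0 || dilution_fraction > 1)
    stop_capflow("dilution_fraction must be in (0, 1]", "capflow_domain_error")
  if (inherits(conc, "concentration")) {
    unit <- conc$unit
    conc <- conc$value
  }
  value <- if (direction == "to_undiluted") conc / dilution_fraction
           else conc * dilution_fraction
  if (is.null(unit)) return(value)
  if (!unit %in% c("pg/mL", "ng/mL"))
    stop_capflow("unit must be pg/mL or ng/mL", "capflow_domain_error")
  strong <- dilution_fraction <= 0.1
  if (direction == "to_undiluted" && unit == "pg/mL" && strong) {
    value <- value / 1000; unit <- "ng/mL"
  } else if (direction == "to_diluted" && unit == "ng/mL" && strong) {
    value <- value * 1000; unit <- "pg/mL"
  }
  structure(list(value = value, unit = unit), class = "concentration")
}

#' @export
print.concentration <- function(x, ...) {
  cat(format(x$value), x$unit, "\n")
  invisible(x)
}

#' @export
as.double.concentration <- function(x, ...) x$value  # as.numeric() dispatches here

#' Pairwise Welch comparisons between signal groups
#'
#' All pairwise [welch_t_test()]s between named replicate groups (e.g. the
#' low / middle / high clinical tiers), with significance flags at `alpha`.
#'
#' @param groups named list of numeric replicate vectors (each `n >= 2`).
#' @param alpha significance level (default 0.05).
#' @return data frame `group1, group2, statistic, df, p_value, significant`.
#' @export
group_comparison <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  pairs <- utils::combn(seq_along(groups), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    w <- welch_t_test(groups[[i]], groups[[j]])
    data.frame(group1 = nm[i], group2 = nm[j], statistic = w$statistic,
               df = w$df, p_value = w$p_value, significant = w$p_value < alpha)
  }))
  out
}

#' Read a replicate-signal CSV into a dose_response
#'
#' Expected schema: `sample_id, concentration_pg_ml, dilution_fraction,
#' channel_id, signal_cm` (only `concentration_pg_ml` and `signal_cm` are
#' required).
#'
#' @param path CSV path.
#' @return a [dose_response()].
#' @export
read_signals <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("concentration_pg_ml", "signal_cm") %in% names(df)))
    stop_capflow("signal CSV needs concentration_pg_ml and signal_cm", "capflow_schema_error")
  dose_response(data.frame(concentration = df$concentration_pg_ml,
                           signal = df$signal_cm))
}
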