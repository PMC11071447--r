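#' Physical parameters of capillary imbibition
#'
#' The Lucas-Washburn law writes the imbibition distance as
#' `L = sqrt(D t)` with `D = R * gamma_LG * cos(theta) / (2 mu)`: capillary
#' radius `R`, liquid-gas interfacial tension `gamma_LG`, contact angle
#' `theta` and dynamic viscosity `mu`.
#'
#' @param R effective capillary radius (cm).
#' @param gamma_LG liquid-gas interfacial tension (g/s^2, i.e. dyn/cm).
#' @param theta contact angle in degrees, in `[0, 180]`.
#' @param mu dynamic viscosity (g/(cm s), i.e. poise).
#' @return An object of class `physical_params`.
#' @export
physical_params <- function(R, gamma_LG, theta, mu) {
  if (R <= 0 || gamma_LG <= 0 || mu <= 0)
    stop_capflow("R, gamma_LG and mu must be positive", "capflow_domain_error")
  if (theta < 0 || theta > 180)
    stop_capflow("theta must be in [0, 180] degrees", "capflow_domain_error")
  structure(list(R = R, gamma_LG = gamma_LG, theta = theta, mu = mu),
            class = "physical_params")
}

#' Diffusion coefficient from liquid properties
#'
#' Evaluates `D = R * gamma_LG * cos(theta) / (2 mu)`. A contact angle above
#' 90 degrees means the liquid does not wet the matrix; the nominal `D` would
#' be negative, so 0 is returned with a warning.
#'
#' @param p a [physical_params()] object.
#' @return diffusion coefficient `D` (cm^2/s).
#' @export
diffusion_from_physics <- function(p) {
  stopifnot(inherits(p, "physical_params"))
  D <- p$R * p$gamma_LG * cos(p$theta * pi / 180) / (2 * p$mu)
  if (D < 0) {
    warn_capflow("contact angle > 90 degrees: non-wetting liquid, D set to 0",
                 "capflow_nonwetting")
    return(0)
  }
  D
}

#' Per-frame diffusion coefficient series
#'
#' Computes `D_i = L_i^2 / t_i` at every frame with `t_i > 0` and smooths the
#' series with a centred moving average (window shrinking at the
#' boundaries). A drift of this series away from a constant signals deviation
#' from single-regime Lucas-Washburn flow.
#'
#' @param profile a [flow_profile()].
#' @param ma_window moving-average width in frames (default 10).
#' @return An object of class `diffusion_series` with fields `frame_index`,
#'   `D_value` (smoothed), `D_raw`, `ma_window`, `frame_rate`.
#' @export
pointwise_diffusion <- function(profile, ma_window = 10L) {
  stopifnot(inherits(profile, "flow_profile"))
  keep <- profile$frame_index > 0
  if (sum(keep) < ma_window + 1)
    stop_capflow("profile shorter than ma_window + 1 frames", "capflow_window_error")
  fr <- profile$frame_index[keep]
  t <- frames_to_seconds(fr, profile$frame_rate)
  D <- profile$distance_cm[keep]^2 / t
  structure(list(frame_index = fr,
                 D_value = moving_average(D, ma_window),
                 D_raw = D, ma_window = ma_window,
                 frame_rate = profile$frame_rate),
            class = "diffusion_series")
}

#' @export
print.diffusion_series <- function(x, ...) {
  cat(sprintf("<diffusion_series> %d frames, MA width %d, D %0.4g .. %0.4g cm^2/s\n",
              length(x$frame_index), x$ma_window, min(x$D_value), max(x$D_value)))
  invisible(x)
}

# Instantaneous diffusion rate d(L^2)/dt by first differences, one value per
# frame >= 1. Unlike the cumulative L^2/t series this reacts immediately at a
# regime change, which is what the crossover estimator needs.
instantaneous_diffusion <- function(profile) {
  L2 <- profile$distance_cm^2
  dt <- diff(frames_to_seconds(profile$frame_index, profile$frame_rate))
  list(frame_index = profile$frame_index[-1], D_inst = diff(L2) / dt)
}

#' Fit the Lucas-Washburn law to a flow profile
#'
#' Least-squares fit of `L = sqrt(D t)` over a frame window. With
#' `s = sqrt(D)` the model is linear-through-origin in `sqrt(t)`, so the
#' least-squares solution is closed form: `s_hat = sum(L sqrt(t)) / sum(t)`.
#' `method = "linearized"` instead regresses `L^2` on `t` through the origin
#' (`D_hat = sum(L^2 t) / sum(t^2)`); the two agree on noiseless data.
#'
#' @param profile a [flow_profile()].
#' @param window `c(first_frame, last_frame)` (inclusive) or `NULL` for the
#'   full profile. The `t = 0` sample is always excluded.
#' @param method `"sqrt"` (default, least squares on `L`) or `"linearized"`.
#' @return An object of class `lw_fit` with `D_hat`, `window`, `rss`, `r2`.
#' @export
fit_lw <- function(profile, window = NULL, method = c("sqrt", "linearized")) {
  stopifnot(inherits(profile, "flow_profile"))
  method <- match.arg(method)
  if (is.null(window)) window <- range(profile$frame_index)
  keep <- profile$frame_index >= window[1] & profile$frame_index <= window[2] &
    profile$frame_index > 0
  if (sum(keep) < 3)
    stop_capflow("window must contain at least 3 frames with t > 0", "capflow_window_error")
  t <- frames_to_seconds(profile$frame_index[keep], profile$frame_rate)
  L <- profile$distance_cm[keep]
  if (all(L == 0))
    stop_capflow("all distances zero in window: degenerate fit", "capflow_degenerate_fit")
  D_hat <- if (method == "sqrt") (sum(L * sqrt(t)) / sum(t))^2
           else sum(L^2 * t) / sum(t^2)
  fitted <- sqrt(D_hat * t)
  rss <- sum((L - fitted)^2)
  tss <- sum((L - mean(L))^2)
  structure(list(D_hat = D_hat, window = as.integer(window), rss = rss,
                 r2 = if (tss > 0) 1 - rss / tss else NA_real_,
                 method = method, n = length(L),
                 frame_rate = profile$frame_rate,
                 channel_id = profile$channel_id,
                 data = list(t = t, L = L)),
            class = "lw_fit")
}

#' @export
print.lw_fit <- function(x, ...) {
  cat(sprintf("<lw_fit> channel %s, frames %d..%d (n = %d): D_hat = %0.5g cm^2/s, r2 = %0.4f\n",
              x$channel_id, x$window[1], x$window[2], x$n, x$D_hat, x$r2))
  invisible(x)
}

#' @export
coef.lw_fit <- function(object, ...) c(D = object$D_hat)

#' @export
predict.lw_fit <- function(object, t = object$data$t, ...) sqrt(object$D_hat * t)

#' @export
residuals.lw_fit <- function(object, ...) object$data$L - predict(object)

#' @export
plot.lw_fit <- function(x, ...) {
  plot(x$data$t, x$data$L, xlab = "time (s)", ylab = "L (cm)",
       main = sprintf("L-W fit, D = %.4g cm^2/s", x$D_hat), ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 200)
  lines(tt, sqrt(x$D_hat * tt), col = 2)
  invisible(x)
}

#' Compare Lucas-Washburn fits over several windows
#'
#' Fits each window with [fit_lw()] and reports the matrix of pairwise
#' `D_i / D_j` ratios. Ratios above 1 for an early window against the full
#' profile indicate a fast initial regime.
#'
#' @param profile a [flow_profile()].
#' @param windows list of `c(first, last)` frame ranges.
#' @param ... passed to [fit_lw()].
#' @return list with `fits` (list of `lw_fit`) and `ratio` (matrix).
#' @export
compare_windows <- function(profile, windows, ...) {
  fits <- lapply(windows, function(w) fit_lw(profile, window = w, ...))
  D <- vapply(fits, function(f) f$D_hat, numeric(1))
  ratio <- outer(D, D, "/")
  lab <- vapply(windows, function(w) paste(w, collapse = ":"), character(1))
  dimnames(ratio) <- list(lab, lab)
  structure(list(fits = fits, ratio = ratio), class = "lw_window_comparison")
}

#' @export
print.lw_window_comparison <- function(x, ...) {
  for (f in x$fits) print(f)
  cat("D ratio matrix (row / column):\n")
  print(round(x$ratio, 3))
  invisible(x)
}

#' Select the optimal detection frame
#'
#' Two strategies for choosing the frame at which the flow distance is read
#' out as the assay signal:
#'
#' * `"halfway"`: estimate the crossover frame `t_c` at which the flow leaves
#'   its fast initial regime, from the pooled instantaneous diffusion series
#'   `d(L^2)/dt` (per-profile smoothing with a `ma_window`-frame moving
#'   average, then averaging across profiles). The early level is the maximum
#'   over frames 1-15, the late level the median of the final third; `t_c` is
#'   the interpolated first crossing of their midpoint. Returns
#'   `round(t_c / 2)` — the halfway point of the initial steep increase.
#' * `"max_separation"`: the frame maximising the one-way between/within
#'   variance ratio of the flow distance across concentration groups.
#'
#' @param profiles for `"halfway"`, a list of [flow_profile()]s (or a list of
#'   such lists keyed by concentration, which is flattened); for
#'   `"max_separation"`, a named list mapping concentration to a list of
#'   profiles (at least two concentrations).
#' @param method `"halfway"` or `"max_separation"`.
#' @param ma_window smoothing width for the diffusion series.
#' @param default_frame frame returned (with a warning) when no crossover is
#'   detectable; default 25.
#' @return integer frame index.
#' @export
select_detection_frame <- function(profiles, method = c("halfway", "max_separation"),
                                   ma_window = 10L, default_frame = 25L) {
  method <- match.arg(method)
  if (method == "halfway") {
    flat <- flatten_profiles(profiles)
    series <- lapply(flat, function(p) {
      di <- instantaneous_diffusion(p)
      moving_average(di$D_inst, ma_window)
    })
    n <- min(lengths(series))
    pooled <- rowMeans(do.call(cbind, lapply(series, function(s) s[seq_len(n)])))
    frames <- seq_len(n)  # frame index of first-difference i is i
    early <- max(pooled[frames <= 15])
    late <- median(pooled[frames > floor(2 * n / 3)])
    mid <- (early + late) / 2
    below <- which(pooled < mid)
    below <- below[below > which.max(pooled[frames <= 15])]
    if (early <= late * 1.05 || !length(below)) {
      warn_capflow("no diffusion crossover detected; returning default frame",
                   "capflow_no_crossover")
      return(as.integer(default_frame))
    }
    i <- below[1]
    t_c <- if (i == 1) frames[1]
           else frames[i - 1] + (pooled[i - 1] - mid) / (pooled[i - 1] - pooled[i])
    as.integer(floor(t_c / 2 + 0.5))
  } else {
    if (!is.list(profiles) || length(profiles) < 2 ||
        !all(vapply(profiles, is.list, logical(1))))
      stop_capflow("max_separation needs >= 2 concentration groups", "capflow_domain_error")
    groups <- lapply(profiles, function(g) {
      do.call(cbind, lapply(g, function(p) p$distance_cm))
    })
    n <- min(vapply(groups, nrow, integer(1)))
    f_ratio <- vapply(seq_len(n), function(i) {
      vals <- lapply(groups, function(m) m[i, ])
      between <- var(vapply(vals, mean, numeric(1)))
      within <- mean(vapply(vals, var, numeric(1)))
      if (!is.finite(within) || within == 0) return(if (between > 0) Inf else 0)
      between / within
    }, numeric(1))
    as.integer(which.max(f_ratio) - 1L)  # row i holds frame index i - 1
  }
}

flatten_profiles <- function(x) {
  if (inherits(x, "flow_profile")) return(list(x))
  out <- list()
  for (el in x) {
    if (inherits(el, "flow_profile")) out <- c(out, list(el))
    else out <- c(out, flatten_profiles(el))
  }
  out
}
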