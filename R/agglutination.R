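#' Kinetic parameters of the particle immunoagglutination model
#'
#' The model follows antibody-conjugated particles (Abp) binding antigen (Ag)
#' by mass-action kinetics, in dimensionless model units:
#'
#' * primary binding `Abp + Ag <-> Abp.Ag` (rates `kon1`, `koff1`);
#' * agglutination `Abp + Abp.Ag <-> Abp2.Ag` (rates `kon2`, `koff2`) — the
#'   two-particle complex Abp2.Ag is the agglutination readout;
#' * antigen excess `Ag + Abp.Ag -> Abp.Ag2` (rate `kon3`, no dissociation),
#'   which sequesters single particles at high antigen and produces the hook
#'   effect.
#'
#' Defaults are the representative rate-constant set used throughout:
#' `kon1 = 6, koff1 = 0.1, kon2 = 1, koff2 = 0.05, kon3 = 2`.
#'
#' @param kon1,koff1,kon2,koff2,kon3 non-negative rate constants.
#' @param abp0 initial antibody-particle concentration (normalisation unit).
#' @param ag0 initial antigen concentration.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(kon1 = 6, koff1 = 0.1, kon2 = 1, koff2 = 0.05,
                           kon3 = 2, abp0 = 10, ag0 = 10) {
  k <- c(kon1, koff1, kon2, koff2, kon3)
  if (any(k < 0) || ag0 < 0) stop_capflow("rate constants and ag0 must be >= 0", "capflow_domain_error")
  if (abp0 <= 0) stop_capflow("abp0 must be positive", "capflow_domain_error")
  structure(list(kon1 = kon1, koff1 = koff1, kon2 = kon2, koff2 = koff2,
                 kon3 = kon3, abp0 = abp0, ag0 = ag0),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> kon1=%g koff1=%g kon2=%g koff2=%g kon3=%g | Abp0=%g Ag0=%g\n",
              x$kon1, x$koff1, x$kon2, x$koff2, x$kon3, x$abp0, x$ag0))
  invisible(x)
}

species_names <- c("abp", "ag", "abp_ag", "abp2_ag", "abp_ag2")

#' Default restriction ranges for the rate constants
#'
#' Admissible ranges for randomised exploration of the kinetic parameter
#' space, spanning the representative rate-constant set a factor of 10 in
#' both directions. Within these ranges the simulated dose curve keeps its
#' rise-plateau-hook shape, only shifting along the antigen axis.
#'
#' @return named list of `c(min, max)` ranges for `kon1, koff1, kon2, koff2,
#'   kon3`, plus `abp0` and `ag0` spans.
#' @export
kinetic_restriction_ranges <- function() {
  base <- c(kon1 = 6, koff1 = 0.1, kon2 = 1, koff2 = 0.05, kon3 = 2)
  out <- lapply(base, function(v) c(min = v / 10, max = v * 10))
  c(out, list(abp0 = c(min = 1, max = 20), ag0 = c(min = 0, max = 50)))
}

#' Draw random kinetic parameters within the restriction ranges
#'
#' Rate constants are sampled log-uniformly within
#' [kinetic_restriction_ranges()]; initial concentrations uniformly.
#'
#' @param n number of parameter sets.
#' @return list of [kinetic_params()] objects.
#' @export
sample_kinetic_params <- function(n = 1L) {
  rr <- kinetic_restriction_ranges()
  lapply(seq_len(n), function(i) {
    k <- vapply(rr[1:5], function(r) exp(stats::runif(1, log(r[["min"]]), log(r[["max"]]))),
                numeric(1))
    kinetic_params(k[["kon1"]], k[["koff1"]], k[["kon2"]], k[["koff2"]], k[["kon3"]],
                   abp0 = stats::runif(1, rr$abp0[["min"]], rr$abp0[["max"]]),
                   ag0 = stats::runif(1, rr$ag0[["min"]], rr$ag0[["max"]]))
  })
}

#' Time derivatives of the agglutination state
#'
#' Pure mass-action right-hand side of the five-species system. The state is
#' `(abp, ag, abp_ag, abp2_ag, abp_ag2)`. `abp_ag2` carries a production term
#' only, which closes both mass balances: particle mass
#' `abp + abp_ag + 2 abp2_ag + abp_ag2` and antigen mass
#' `ag + abp_ag + abp2_ag + 2 abp_ag2` are conserved.
#'
#' @param state named or ordered numeric vector of the five concentrations.
#' @param params a [kinetic_params()] object.
#' @return named numeric vector of time derivatives.
#' @export
agg_derivatives <- function(state, params) {
  stopifnot(inherits(params, "kinetic_params"))
  s <- as_state(state)
  k <- c(params$kon1, params$koff1, params$kon2, params$koff2, params$kon3)
  setNames(.agg_rhs_cpp(s, k), species_names)
}

as_state <- function(state) {
  if (!is.null(names(state)) && all(species_names %in% names(state))) {
    state <- state[species_names]
  }
  if (length(state) != 5) stop_capflow("state needs 5 species", "capflow_domain_error")
  as.numeric(state)
}

#' Simulate the immunoagglutination kinetics
#'
#' Integrates the five-species system from the initial state
#' `(abp0, ag0, 0, 0, 0)` with an adaptive Dormand-Prince Runge-Kutta 5(4)
#' scheme. Both conservation laws are checked at every stored time; a
#' relative drift above `cons_tol` raises an integration error.
#'
#' @param params a [kinetic_params()] object.
#' @param t_end final model time (default 1, where binding has levelled off
#'   for the representative rate constants).
#' @param n_steps number of stored output times (default 200).
#' @param rtol,atol solver tolerances.
#' @param cons_tol accepted relative drift of the conservation sums.
#' @return An object of class `kinetic_trajectory`: `times`, `states`
#'   (matrix, columns `abp, ag, abp_ag, abp2_ag, abp_ag2`), `params`.
#' @export
simulate_kinetics <- function(params, t_end = 1, n_steps = 200L,
                              rtol = 1e-8, atol = 1e-10, cons_tol = 1e-6) {
  stopifnot(inherits(params, "kinetic_params"))
  if (t_end <= 0) stop_capflow("t_end must be positive", "capflow_domain_error")
  times <- seq(0, t_end, length.out = n_steps + 1L)
  y0 <- c(params$abp0, params$ag0, 0, 0, 0)
  states <- .agg_integrate_cpp(y0, c(params$kon1, params$koff1, params$kon2,
                                     params$koff2, params$kon3),
                               times, rtol, atol)
  colnames(states) <- species_names
  traj <- structure(list(times = times, states = states, params = params),
                    class = "kinetic_trajectory")
  drift <- max(conservation_drift(traj))
  if (is.finite(drift) && drift > cons_tol)
    stop_capflow(sprintf("mass conservation violated (relative drift %.2e)", drift),
                 "capflow_integration_error")
  traj
}

#' Relative drift of the two conservation sums along a trajectory
#'
#' @param traj a `kinetic_trajectory`.
#' @return numeric of length 2: max relative drift of the particle and
#'   antigen mass sums from their initial values.
#' @export
conservation_drift <- function(traj) {
  s <- traj$states
  particle <- s[, "abp"] + s[, "abp_ag"] + 2 * s[, "abp2_ag"] + s[, "abp_ag2"]
  antigen <- s[, "ag"] + s[, "abp_ag"] + s[, "abp2_ag"] + 2 * s[, "abp_ag2"]
  scale <- c(max(particle[1], 1e-12), max(antigen[1], 1e-12))
  c(particle = max(abs(particle - particle[1])) / scale[1],
    antigen = max(abs(antigen - antigen[1])) / scale[2])
}

#' @export
print.kinetic_trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("<kinetic_trajectory> t in [0, %g], %d points; Abp2.Ag(t_end)/Abp0 = %0.4g\n",
              max(x$times), n, x$states[n, "abp2_ag"] / x$params$abp0))
  invisible(x)
}

#' @export
as.data.frame.kinetic_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states)
}

#' @export
plot.kinetic_trajectory <- function(x, normalize = TRUE, ...) {
  s <- x$states
  if (normalize) s <- s / x$params$abp0
  plot(x$times, s[, "abp2_ag"], type = "l", col = 2, ylim = range(s),
       xlab = "model time", ylab = if (normalize) "concentration / Abp0" else "concentration",
       main = "Immunoagglutination kinetics", ...)
  for (j in c(1, 2, 3, 5)) lines(x$times, s[, j], col = j + 2)
  legend("topright", legend = colnames(s), col = c(3, 4, 5, 2, 7), lty = 1, cex = 0.8)
  invisible(x)
}

#' Simulated dose-response curve of normalised agglutination
#'
#' Runs one kinetics simulation per antigen level and samples the normalised
#' agglutination `Abp2.Ag(t_sample) / abp0`. Over a wide log-spaced antigen
#' grid the curve rises, plateaus, and falls again in the antigen-excess
#' (hook/prozone) zone.
#'
#' @param params_base a [kinetic_params()]; its `ag0` is overridden.
#' @param ag_grid non-negative, sorted antigen levels.
#' @param t_sample sampling time (default 1).
#' @param ... passed to [simulate_kinetics()].
#' @return An object of class `dose_curve`: `ag0`, `norm_agg` (Abp2.Ag /
#'   abp0), `norm_mono` (Abp.Ag / abp0), `abp0`, `t_sample`.
#' @export
dose_curve <- function(params_base, ag_grid, t_sample = 1, ...) {
  stopifnot(inherits(params_base, "kinetic_params"))
  if (is.unsorted(ag_grid) || any(ag_grid < 0))
    stop_capflow("ag_grid must be sorted and non-negative", "capflow_domain_error")
  res <- vapply(ag_grid, function(ag) {
    p <- params_base
    p$ag0 <- ag
    tr <- simulate_kinetics(p, t_end = t_sample, n_steps = 50L, ...)
    n <- nrow(tr$states)
    c(tr$states[n, "abp2_ag"], tr$states[n, "abp_ag"]) / p$abp0
  }, numeric(2))
  structure(list(ag0 = ag_grid, norm_agg = res[1, ], norm_mono = res[2, ],
                 abp0 = params_base$abp0, t_sample = t_sample),
            class = "dose_curve")
}

#' @export
print.dose_curve <- function(x, ...) {
  cat(sprintf("<dose_curve> %d antigen levels in [%g, %g], Abp0 = %g, t = %g; peak %0.4g\n",
              length(x$ag0), min(x$ag0), max(x$ag0), x$abp0, x$t_sample,
              max(x$norm_agg)))
  invisible(x)
}

#' @export
plot.dose_curve <- function(x, ...) {
  plot(x$ag0, x$norm_agg, log = if (min(x$ag0) > 0) "x" else "",
       type = "b", xlab = "antigen (model units)",
       ylab = "Abp2.Ag / Abp0", main = "Simulated dose response", ...)
  invisible(x)
}

#' Locate the hook (prozone) peak of a dose curve
#'
#' Grid argmax of the normalised agglutination; ties break toward the lower
#' antigen level. A maximum on the grid boundary means no interior hook peak
#' and is flagged.
#'
#' @param curve a [dose_curve()] (or any list with `ag0` and `norm_agg`).
#' @return list `ag_at_peak`, `peak_value`, `index`, `interior` (logical).
#' @export
find_hook_peak <- function(curve) {
  y <- curve$norm_agg
  if (length(y) < 3) stop_capflow("need >= 3 grid points", "capflow_domain_error")
  i <- which.max(y)  # which.max already takes the first (lowest ag0) tie
  interior <- i > 1 && i < length(y)
  if (!interior)
    warn_capflow("dose curve is monotone on the grid: no interior hook peak",
                 "capflow_no_interior_peak")
  list(ag_at_peak = curve$ag0[i], peak_value = y[i], index = i,
       interior = interior)
}

#' Crossing point of two dose curves (particle-concentration shift)
#'
#' Lowering the particle amount shifts the dose curve toward lower antigen;
#' the low- and high-particle curves then cross, the low-particle assay
#' trending down where the high-particle one still trends up. Returns the
#' smallest antigen level at which `high - low` changes sign, located by
#' linear interpolation between grid points.
#'
#' @param curve_low_abp,curve_high_abp [dose_curve()]s on a shared `ag0` grid.
#' @return list `ag_cross` (NA if none), `crossing` (logical), `degenerate`
#'   (TRUE when the curves are identical).
#' @export
find_crossing <- function(curve_low_abp, curve_high_abp) {
  if (!isTRUE(all.equal(curve_low_abp$ag0, curve_high_abp$ag0)))
    stop_capflow("curves must share the antigen grid", "capflow_domain_error")
  d <- curve_high_abp$norm_agg - curve_low_abp$norm_agg
  if (all(d == 0)) {
    warn_capflow("curves are identical: degenerate crossing", "capflow_degenerate_crossing")
    return(list(ag_cross = curve_low_abp$ag0[1], crossing = TRUE, degenerate = TRUE))
  }
  for (i in seq_len(length(d) - 1)) {
    if (d[i] == 0) return(list(ag_cross = curve_low_abp$ag0[i], crossing = TRUE,
                               degenerate = FALSE))
    if (d[i] * d[i + 1] < 0) {
      x0 <- curve_low_abp$ag0[i]; x1 <- curve_low_abp$ag0[i + 1]
      w <- d[i] / (d[i] - d[i + 1])
      return(list(ag_cross = x0 + w * (x1 - x0), crossing = TRUE, degenerate = FALSE))
    }
  }
  warn_capflow("no sign change between the curves", "capflow_no_crossing")
  list(ag_cross = NA_real_, crossing = FALSE, degenerate = FALSE)
}
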