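#' Configuration of the synthetic assay world
#'
#' The generator renders the causal chain the assay rests on: antigen
#' concentration drives particle immunoagglutination (mass-action kinetics),
#' agglutination raises the interfacial tension at the wetting front, which
#' raises the early-stage Lucas-Washburn diffusion coefficient and hence the
#' flow distance at the detection frame. Flow profiles are two-regime: a fast
#' initial imbibition `L = sqrt(D_early t)` up to `crossover_frame`, then
#' `L = sqrt(L_c^2 + D_late (t - t_c))` (continuous, piecewise
#' Lucas-Washburn).
#'
#' Defaults state the reference conditions: 30 fps video, 1,500 frames
#' (50 s), crossover at frame 50, early-to-late diffusion ratio of a few
#' fold, and geometry of the wax-printed chip (2.1 x 0.3 cm channels,
#' 0.3 cm loading zone). `D_early` defaults to the value the physics map
#' produces at `gamma_max`; `noise_sd_cm` is a free parameter (the reference
#' work reports only standard errors) set to 0.01 cm, sub-pixel at the
#' default 40 px/cm scale.
#'
#' @param seed integer RNG seed.
#' @param fps frame rate (default 30).
#' @param n_frames frames per profile (default 1500).
#' @param D_early,D_late early/late diffusion coefficients, cm^2/s
#'   (`D_early >= D_late > 0`).
#' @param crossover_frame regime-change frame (default 50).
#' @param noise_sd_cm additive Gaussian noise on the front distance.
#' @param channel_length_cm,channel_width_cm,loading_zone_cm chip geometry.
#' @param pixel_scale px/cm used when rendering videos.
#' @param pixel_noise_sd additive pixel noise in rendered videos.
#' @param wet_contrast luminance drop behind the wetting front.
#' @param gamma_min,gamma_max interfacial-tension bounds (dyn/cm) for the
#'   agglutination-to-tension map.
#' @param R_eff,theta,mu effective capillary radius (cm), contact angle
#'   (deg) and viscosity (poise) for the physics map.
#' @param kinetic a [kinetic_params()] block.
#' @param conc_per_ag_unit pg/mL per model antigen unit (default 5, placing
#'   the simulated hook peak near the tens-of-pg/mL plateau seen in real
#'   calibrations).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, fps = 30, n_frames = 1500L,
                         D_early = NULL, D_late = 0.02, crossover_frame = 50L,
                         noise_sd_cm = 0.01,
                         channel_length_cm = 2.1, channel_width_cm = 0.3,
                         loading_zone_cm = 0.3, pixel_scale = 40,
                         pixel_noise_sd = 0, wet_contrast = 0.35,
                         gamma_min = 50, gamma_max = 72,
                         R_eff = 5e-5, theta = 60, mu = 0.01,
                         kinetic = kinetic_params(),
                         conc_per_ag_unit = 5) {
  if (is.null(D_early))
    D_early <- diffusion_from_physics(physical_params(R_eff, gamma_max, theta, mu))
  if (!(D_early >= D_late && D_late > 0))
    stop_capflow("need D_early >= D_late > 0", "capflow_domain_error")
  if (crossover_frame <= 0 || crossover_frame >= n_frames)
    stop_capflow("crossover_frame must lie inside (0, n_frames)", "capflow_domain_error")
  if (noise_sd_cm < 0) stop_capflow("noise_sd_cm must be >= 0", "capflow_domain_error")
  structure(list(seed = as.integer(seed), fps = fps, n_frames = as.integer(n_frames),
                 D_early = D_early, D_late = D_late,
                 crossover_frame = as.integer(crossover_frame),
                 noise_sd_cm = noise_sd_cm,
                 channel_length_cm = channel_length_cm,
                 channel_width_cm = channel_width_cm,
                 loading_zone_cm = loading_zone_cm,
                 pixel_scale = pixel_scale, pixel_noise_sd = pixel_noise_sd,
                 wet_contrast = wet_contrast,
                 gamma_min = gamma_min, gamma_max = gamma_max,
                 R_eff = R_eff, theta = theta, mu = mu,
                 kinetic = kinetic, conc_per_ag_unit = conc_per_ag_unit),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> seed %d: %d frames @ %g fps, D %g -> %g cm^2/s at frame %d, noise %g cm\n",
              x$seed, x$n_frames, x$fps, x$D_early, x$D_late,
              x$crossover_frame, x$noise_sd_cm))
  invisible(x)
}

# Noiseless two-regime Lucas-Washburn distance at times t (seconds).
two_regime_L <- function(t, D_early, D_late, t_c) {
  ifelse(t <= t_c, sqrt(D_early * t),
         sqrt(D_early * t_c + D_late * (t - t_c)))
}

#' Generate a ground-truth flow profile
#'
#' Renders the two-regime profile of `cfg`, adds i.i.d. Gaussian noise of
#' `noise_sd_cm`, enforces front monotonicity and caps at the channel
#' length. The noiseless truth and generator parameters are attached as
#' attribute `"ground_truth"`.
#'
#' @param cfg a [synth_config()].
#' @param D_early optional override of `cfg$D_early` (used by [gen_assay()]).
#' @param channel_id profile label.
#' @param seed RNG seed; defaults to `cfg$seed`. Pass `NULL` to draw from the
#'   current RNG stream (for replicate generation).
#' @return a [flow_profile()] with attribute `ground_truth` (list `D_early`,
#'   `D_late`, `crossover_frame`, `L_true`).
#' @export
gen_profile <- function(cfg, D_early = cfg$D_early, channel_id = "ch1",
                        seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  frames <- seq_len(cfg$n_frames) - 1L
  t <- frames_to_seconds(frames, cfg$fps)
  L <- two_regime_L(t, D_early, cfg$D_late, cfg$crossover_frame / cfg$fps)
  L_true <- pmin(L, cfg$channel_length_cm)
  noisy <- if (cfg$noise_sd_cm > 0) {
    eps <- if (is.null(seed)) rnorm(length(L), 0, cfg$noise_sd_cm)
           else with_seed(seed, rnorm(length(L), 0, cfg$noise_sd_cm))
    L + eps
  } else L
  noisy <- pmin(pmax(cummax(noisy), 0), cfg$channel_length_cm)
  noisy[1] <- 0  # the front starts at the loading-zone exit
  prof <- flow_profile(noisy, cfg$fps, channel_id = channel_id,
                       channel_length_cm = cfg$channel_length_cm)
  attr(prof, "ground_truth") <- list(D_early = D_early, D_late = cfg$D_late,
                                     crossover_frame = cfg$crossover_frame,
                                     L_true = L_true)
  prof
}

#' Map normalised agglutination to interfacial tension
#'
#' Agglutinated particles are retained in the paper matrix, leaving a cleaner
#' wetting front and a higher interfacial tension; tension is the dominant
#' liquid property driving the capillary flow rate. The map is linear in the
#' normalised agglutination level — the minimal assumption consistent with
#' the observed direction and dominance.
#'
#' @param norm_agg normalised agglutination in `[0, 1]` (values outside are
#'   clamped with a warning).
#' @param gamma_min,gamma_max tension bounds (dyn/cm).
#' @return interfacial tension `gamma_min + norm_agg * (gamma_max - gamma_min)`.
#' @export
gamma_from_agglutination <- function(norm_agg, gamma_min = 50, gamma_max = 72) {
  if (any(norm_agg < 0 | norm_agg > 1)) {
    warn_capflow("norm_agg outside [0, 1]: clamped", "capflow_clamped")
    norm_agg <- pmin(pmax(norm_agg, 0), 1)
  }
  gamma_min + norm_agg * (gamma_max - gamma_min)
}

#' Generate a replicate assay dataset with ground truth
#'
#' Chains the full causal story: for each concentration, the kinetics
#' simulation gives the normalised agglutination, [gamma_from_agglutination()]
#' the interfacial tension, the Lucas-Washburn physics the early diffusion
#' coefficient, [gen_profile()] a noisy flow profile, and
#' [signal_at_frame()] the replicate signal. All randomness derives from
#' `cfg$seed`, so identical configurations reproduce identical datasets.
#'
#' @param cfg a [synth_config()].
#' @param concentrations pg/mL levels, must include 0 (negative control).
#' @param n_replicates replicates per concentration (default 8, two chips of
#'   four channels).
#' @param detection_frame frame at which the signal is read (default 25).
#' @return list with `dose_response` (a [dose_response()]) and
#'   `ground_truth` (data frame `concentration, norm_agg, gamma, D_early,
#'   signal_true`).
#' @export
gen_assay <- function(cfg, concentrations, n_replicates = 8L,
                      detection_frame = 25L) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!any(concentrations == 0))
    stop_capflow("concentrations must include the 0 control", "capflow_contract_error")
  concentrations <- sort(unique(concentrations))
  ag_grid <- concentrations / cfg$conc_per_ag_unit
  dc <- dose_curve(cfg$kinetic, ag_grid, t_sample = 1)
  gamma <- gamma_from_agglutination(dc$norm_agg, cfg$gamma_min, cfg$gamma_max)
  D_early <- vapply(gamma, function(g) {
    diffusion_from_physics(physical_params(cfg$R_eff, g, cfg$theta, cfg$mu))
  }, numeric(1))
  t_det <- frames_to_seconds(detection_frame, cfg$fps)
  signal_true <- vapply(seq_along(concentrations), function(i) {
    two_regime_L(t_det, D_early[i], cfg$D_late, cfg$crossover_frame / cfg$fps)
  }, numeric(1))
  signals <- with_seed(cfg$seed, {
    lapply(seq_along(concentrations), function(i) {
      vapply(seq_len(n_replicates), function(r) {
        p <- gen_profile(cfg, D_early = D_early[i],
                         channel_id = sprintf("c%g_r%d", concentrations[i], r),
                         seed = NULL)
        signal_at_frame(p, detection_frame)
      }, numeric(1))
    })
  })
  list(dose_response = dose_response(concentrations, signals),
       ground_truth = data.frame(concentration = concentrations,
                                 norm_agg = dc$norm_agg, gamma = gamma,
                                 D_early = D_early, signal_true = signal_true))
}

#' Render a flow profile as a synthetic channel video
#'
#' Produces a luminance stack in which, frame by frame, the pixels behind
#' the wetting front (along the flow axis, inside each ROI) are darkened by
#' `cfg$wet_contrast` on a white background; the front column is
#' `round(L * pixel_scale)`. Optional i.i.d. pixel noise of
#' `cfg$pixel_noise_sd` is added. Not photorealistic — sufficient for the
#' tracking contract.
#'
#' @param profile a [flow_profile()], or a list of them (one per ROI).
#' @param layout a [channel_layout()]; defaults to a single-channel layout
#'   sized to `cfg`.
#' @param cfg a [synth_config()].
#' @return a [video_stack()].
#' @export
gen_video <- function(profile, layout = NULL, cfg = synth_config()) {
  if (inherits(profile, "flow_profile")) profile <- list(profile)
  if (is.null(layout)) layout <- default_layout(cfg, n_channels = length(profile))
  stopifnot(inherits(layout, "channel_layout"))
  r <- layout$rois
  if (length(profile) != nrow(r))
    stop_capflow("one profile per ROI required", "capflow_domain_error")
  nfr <- max(vapply(profile, function(p) length(p$frame_index), integer(1)))
  width <- max(r$x1) + 4L
  height <- max(r$y1) + 4L
  ps <- cfg$pixel_scale
  frames <- lapply(seq_len(nfr), function(f) {
    fr <- matrix(1, nrow = height, ncol = width)
    for (i in seq_len(nrow(r))) {
      L <- profile[[i]]$distance_cm[min(f, length(profile[[i]]$distance_cm))]
      n_wet <- round(L * ps)
      if (n_wet > 0) {
        if (layout$flow_axis == "x") {
          x_wet <- (r$x0[i] + 1):min(r$x0[i] + n_wet, r$x1[i])
          fr[(r$y0[i] + 1):r$y1[i], x_wet] <- 1 - cfg$wet_contrast
        } else {
          y_wet <- (r$y0[i] + 1):min(r$y0[i] + n_wet, r$y1[i])
          fr[y_wet, (r$x0[i] + 1):r$x1[i]] <- 1 - cfg$wet_contrast
        }
      }
    }
    fr
  })
  if (cfg$pixel_noise_sd > 0) {
    frames <- with_seed(cfg$seed, lapply(frames, function(fr) {
      fr + matrix(rnorm(length(fr), 0, cfg$pixel_noise_sd), nrow(fr), ncol(fr))
    }))
  }
  video_stack(frames, cfg$fps, ps)
}

#' Default chip layout for a synthetic configuration
#'
#' Stacks `n_channels` horizontal channel ROIs, each spanning the full
#' trackable channel length at `cfg$pixel_scale`, separated by 4-px gaps.
#'
#' @param cfg a [synth_config()].
#' @param n_channels number of channels (default 4, one chip).
#' @return a [channel_layout()].
#' @export
default_layout <- function(cfg, n_channels = 4L) {
  len_px <- ceiling(cfg$channel_length_cm * cfg$pixel_scale)
  wid_px <- max(3L, round(cfg$channel_width_cm * cfg$pixel_scale))
  rois <- do.call(rbind, lapply(seq_len(n_channels), function(i) {
    y0 <- (i - 1L) * (wid_px + 4L) + 2L
    data.frame(x0 = 2L, y0 = y0, x1 = 2L + len_px, y1 = y0 + wid_px,
               channel_id = paste0("ch", i))
  }))
  channel_layout(rois, flow_axis = "x",
                 channel_length_cm = cfg$channel_length_cm,
                 channel_width_cm = cfg$channel_width_cm,
                 loading_zone_cm = cfg$loading_zone_cm)
}
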