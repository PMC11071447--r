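#' Read and validate a run configuration
#'
#' Configurations are JSON. Required keys: `frame_rate`, `seed`,
#' `detection_frame`, `alpha`. Optional blocks: `synth` (arguments for
#' [synth_config()]), `kinetic` (arguments for [kinetic_params()]),
#' `concentrations`, `n_replicates`, `windows` (list of two-element frame
#' ranges for [compare_windows()]), `cuts` (tier boundaries, pg/mL in the
#' diluted sample), `video_dir` + `pixel_scale` + `rois` for tracking real
#' frame stacks. Referenced paths must exist at validation time.
#'
#' @param config path to a JSON file, or an equivalent named list.
#' @return the validated configuration list (class `run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_capflow(paste("config file not found:", config), "capflow_validation_error")
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  required <- c("frame_rate", "seed", "detection_frame", "alpha")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop_capflow(paste("config missing required keys:", paste(missing, collapse = ", ")),
                 "capflow_validation_error")
  if (!is.null(config$video_dir) && !dir.exists(config$video_dir))
    stop_capflow("config video_dir does not exist", "capflow_validation_error")
  if (is.null(config$schema_version)) config$schema_version <- "1"
  class(config) <- c("run_config", class(config))
  config
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- unclass(config)
  jsonlite::write_json(plain[order(names(plain))], tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full assay pipeline
#'
#' Orchestrates track -> fit -> calibrate -> classify. With a `synth` block
#' the input data are generated by [gen_assay()] (plus one rendered profile
#' per concentration); with a `video_dir` the profiles are tracked from a
#' PGM frame directory. Every output file name is prefixed by a hash of the
#' configuration, so a rerun with the same configuration overwrites its own
#' outputs and produces identical files; stages write their outputs as they
#' complete, so a late failure leaves earlier stage outputs intact.
#'
#' @param config a path, list, or [read_run_config()] result.
#' @param out_dir output directory (created if needed).
#' @return list with the output `files` (profiles CSV, fits JSON,
#'   calibration JSON, tier CSV, log), the `hash`, and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stem <- function(name) file.path(out_dir, paste0(substr(hash, 1, 8), "_", name))
  log_lines <- character(0)
  note <- function(stage, msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s: %s", format(Sys.time()), stage, msg))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      note(name, paste("FAILED:", conditionMessage(e)))
      writeLines(log_lines, stem("run.log"))
      stop_capflow(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                   "capflow_stage_error")
    })
    note(name, sprintf("done in %.2f s", proc.time()[["elapsed"]] - t0))
    res
  }

  files <- list()
  # --- stage: profiles (synthesis or tracking) -------------------------------
  synth_out <- NULL
  profiles <- NULL
  if (!is.null(config$video_dir)) {
    profiles <- stage("track", {
      stack <- read_frame_dir(config$video_dir, config$frame_rate, config$pixel_scale)
      layout <- channel_layout(as.data.frame(config$rois))
      track_front(stack, layout,
                  threshold_rel = config$threshold_rel %||% 0.5,
                  baseline_frame = config$baseline_frame %||% 0L)
    })
  } else {
    synth_out <- stage("synth", {
      cfg <- do.call(synth_config, c(list(seed = config$seed),
                                     as_plain_list(config$synth)))
      if (!is.null(config$kinetic))
        cfg$kinetic <- do.call(kinetic_params, as_plain_list(config$kinetic))
      conc <- config$concentrations %||% c(0, 1, 5, 10, 20, 30, 40)
      assay <- gen_assay(cfg, conc, n_replicates = config$n_replicates %||% 8L,
                         detection_frame = config$detection_frame)
      profs <- lapply(seq_along(conc), function(i) {
        gen_profile(cfg, D_early = assay$ground_truth$D_early[i],
                    channel_id = paste0("conc_", conc[i]),
                    seed = (config$seed + i) %% .Machine$integer.max)
      })
      list(cfg = cfg, assay = assay, profiles = profs)
    })
    profiles <- synth_out$profiles
  }
  files$profiles <- stem("profiles.csv")
  write_profiles(profiles, files$profiles, chip_id = substr(hash, 1, 8))
  note("profiles", sprintf("%d profiles written", length(profiles)))

  # --- stage: Lucas-Washburn fits -------------------------------------------
  fits <- stage("fit", {
    windows <- config$windows %||% list(c(1, 50), c(1, min(1000, length(profiles[[1]]$frame_index) - 1)))
    lapply(profiles, function(p) {
      cw <- compare_windows(p, windows)
      list(channel_id = p$channel_id,
           fits = lapply(cw$fits, function(f) {
             list(window = f$window, D_hat = f$D_hat, r2 = f$r2)
           }),
           ratio_first_to_last = cw$ratio[1, length(windows)])
    })
  })
  files$fits <- stem("fits.json")
  jsonlite::write_json(fits, files$fits, auto_unbox = TRUE, digits = NA)

  # --- stage: calibration ----------------------------------------------------
  calib <- NULL
  if (!is.null(synth_out)) {
    calib <- stage("calibrate", {
      dr <- synth_out$assay$dose_response
      fit <- fit_sigmoid(dr)
      list(fit = fit, lod = as.numeric(fit$lod), linear_range = fit$linear_range)
    })
    files$calibration <- stem("calibration.json")
    jsonlite::write_json(list(model = calib$fit$model,
                              params = as.list(calib$fit$params),
                              r2 = calib$fit$r2,
                              direction = calib$fit$direction,
                              lod_pg_ml = calib$lod,
                              linear_range = calib$linear_range[c("range", "slope", "r2")],
                              config_hash = hash),
                         files$calibration, auto_unbox = TRUE, digits = NA)

    # --- stage: classification ----------------------------------------------
    tiers <- stage("classify", {
      cuts <- config$cuts %||% c(15, 35)
      dr <- synth_out$assay$dose_response
      gt <- synth_out$assay$ground_truth
      do.call(rbind, lapply(seq_len(nrow(dr$summary)), function(i) {
        conc <- dr$summary$concentration[i]
        sig <- dr$replicates[[as.character(conc)]]
        truth <- if (conc < cuts[1]) "low" else if (conc < cuts[2]) "middle" else "high"
        data.frame(concentration = conc, replicate = seq_along(sig), signal_cm = sig,
                   tier = vapply(sig, function(s) classify_tier(s, calib$fit, cuts)$label,
                                 character(1)),
                   true_tier = truth)
      }))
    })
    files$tiers <- stem("tiers.csv")
    write.csv(cbind(tiers, config_hash = hash), files$tiers, row.names = FALSE)
  }

  files$log <- stem("run.log")
  writeLines(log_lines, files$log)
  list(files = files, hash = hash, profiles = profiles, fits = fits,
       synth = synth_out, calibration = calib)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_plain_list <- function(x) {
  if (is.null(x)) return(list())
  lapply(as.list(x), function(v) if (is.list(v)) unlist(v) else v)
}
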