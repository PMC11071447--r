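#' Flow profile: wetting-front distance versus frame index
#'
#' A flow profile records, for one paper channel, the position of the
#' advancing wetting front (in cm, measured from the downstream edge of the
#' loading zone) at each video frame. Frame indices start at 0; together with
#' the frame rate they convert to seconds via [frames_to_seconds()].
#'
#' @param distance_cm numeric vector of front positions, one per frame.
#' @param frame_rate frames per second (must be positive).
#' @param channel_id label for the channel.
#' @param frame_index integer frame indices; defaults to `0:(n-1)`.
#' @param channel_length_cm physical channel length bounding the distances.
#' @param dry logical flag set by the tracker when no wetting was detected.
#' @return An object of class `flow_profile`.
#' @seealso [track_front()], [enforce_monotone()], [signal_at_frame()]
#' @export
flow_profile <- function(distance_cm, frame_rate, channel_id = "ch1",
                         frame_index = seq_along(distance_cm) - 1L,
                         channel_length_cm = 2.1, dry = FALSE) {
  if (frame_rate <= 0) stop_capflow("frame_rate must be positive", "capflow_domain_error")
  if (length(distance_cm) != length(frame_index))
    stop_capflow("distance_cm and frame_index lengths differ", "capflow_domain_error")
  if (any(distance_cm < -1e-12) || any(distance_cm > channel_length_cm + 1e-9))
    stop_capflow("distances must lie in [0, channel_length_cm]", "capflow_domain_error")
  structure(
    list(channel_id = as.character(channel_id),
         frame_index = as.integer(frame_index),
         distance_cm = pmin(pmax(as.numeric(distance_cm), 0), channel_length_cm),
         frame_rate = frame_rate,
         channel_length_cm = channel_length_cm,
         dry = isTRUE(dry)),
    class = "flow_profile")
}

#' @export
print.flow_profile <- function(x, ...) {
  cat(sprintf("<flow_profile> channel %s: %d frames @ %g fps, front %0.3f -> %0.3f cm%s\n",
              x$channel_id, length(x$frame_index), x$frame_rate,
              min(x$distance_cm), max(x$distance_cm),
              if (x$dry) " [DRY]" else ""))
  invisible(x)
}

#' @export
as.data.frame.flow_profile <- function(x, ...) {
  data.frame(channel_id = x$channel_id,
             frame = x$frame_index,
             time_s = frames_to_seconds(x$frame_index, x$frame_rate),
             distance_cm = x$distance_cm)
}

#' @export
plot.flow_profile <- function(x, ...) {
  df <- as.data.frame(x)
  plot(df$time_s, df$distance_cm, type = "l",
       xlab = "time (s)", ylab = "front distance (cm)",
       main = paste("Flow profile,", x$channel_id), ...)
  invisible(x)
}

#' Enforce a physically monotone wetting front
#'
#' Capillary fronts cannot recede; apparent retreats in a tracked profile are
#' flicker/threshold noise. Replaces the distance trace by its running
#' maximum. Idempotent.
#'
#' @param profile a [flow_profile()].
#' @return The profile with non-decreasing `distance_cm`.
#' @export
enforce_monotone <- function(profile) {
  stopifnot(inherits(profile, "flow_profile"))
  profile$distance_cm <- cummax(profile$distance_cm)
  profile
}

#' Convert frame indices to seconds
#'
#' @param frame_index non-negative frame index (vectorised).
#' @param frame_rate frames per second, positive. The chips in the reference
#'   setup were filmed at 30 fps, so 1,500 frames correspond to 50 s.
#' @return time in seconds, `frame_index / frame_rate`.
#' @export
frames_to_seconds <- function(frame_index, frame_rate) {
  if (frame_rate <= 0) stop_capflow("frame_rate must be positive", "capflow_domain_error")
  if (any(frame_index < 0)) stop_capflow("frame index must be non-negative", "capflow_domain_error")
  frame_index / frame_rate
}

#' Assay signal: flow distance at the detection frame
#'
#' The assay reads out the front position at a fixed, optimised frame index
#' (default 25, about 1 s at 30 fps). No interpolation: profiles are
#' per-frame.
#'
#' @param profile a [flow_profile()].
#' @param frame integer frame index present in the profile.
#' @return distance in cm at that frame.
#' @export
signal_at_frame <- function(profile, frame = 25L) {
  stopifnot(inherits(profile, "flow_profile"))
  i <- match(as.integer(frame), profile$frame_index)
  if (is.na(i))
    stop_capflow(sprintf("frame %d not in profile (0..%d)", frame,
                         max(profile$frame_index)), "capflow_index_error")
  profile$distance_cm[i]
}

#' Write / read flow profiles as CSV
#'
#' Schema: `chip_id, channel_id, frame, time_s, distance_cm`, one row per
#' frame and channel.
#'
#' @param profiles a `flow_profile` or list of them.
#' @param path CSV file path.
#' @param chip_id chip label stored in the first column.
#' @return `write_profiles` returns `path` invisibly; `read_profiles` returns
#'   a named list of `flow_profile` objects.
#' @export
write_profiles <- function(profiles, path, chip_id = "chip1") {
  if (inherits(profiles, "flow_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    cbind(chip_id = chip_id, as.data.frame(p))
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @param frame_rate frame rate to attach when reading (fps).
#' @param channel_length_cm channel length to attach when reading.
#' @export
read_profiles <- function(path, frame_rate = 30, channel_length_cm = 2.1) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel_id", "frame", "distance_cm")
  if (!all(need %in% names(df)))
    stop_capflow("profile CSV missing required columns", "capflow_schema_error")
  lapply(split(df, df$channel_id), function(d) {
    d <- d[order(d$frame), ]
    flow_profile(d$distance_cm, frame_rate, channel_id = d$channel_id[1],
                 frame_index = d$frame, channel_length_cm = channel_length_cm)
  })
}
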