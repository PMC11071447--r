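#' Track the wetting front in each channel of a video stack
#'
#' For every channel ROI, intensities are sampled along the channel's central
#' axis (median over a 3-pixel band) and compared frame-by-frame against a
#' pre-flow baseline frame. The front in a frame is the farthest along-axis
#' pixel whose absolute intensity change exceeds `threshold_rel` times the
#' maximum wetted-region change seen in that channel over the whole stack.
#' Positions convert to cm via the stack's `pixel_scale` and are measured from
#' the upstream ROI edge (the downstream edge of the loading zone); profiles
#' are truncated at `channel_length_cm`.
#'
#' A channel in which no pixel ever changes is reported as a dry channel: an
#' all-zero profile with `dry = TRUE` and a warning.
#'
#' @param stack a [video_stack()].
#' @param layout a [channel_layout()]; ROIs must lie inside the frames and
#'   span at least 95% of `channel_length_cm` at the stack's pixel scale.
#' @param threshold_rel detection threshold as a fraction of the maximum
#'   wetted change, in (0, 1); default 0.5.
#' @param baseline_frame 0-based index of a frame captured before visible
#'   flow; default 0.
#' @return list of [flow_profile()] objects, one per ROI, monotone-enforced.
#' @export
track_front <- function(stack, layout, threshold_rel = 0.5, baseline_frame = 0L) {
  stopifnot(inherits(stack, "video_stack"), inherits(layout, "channel_layout"))
  if (threshold_rel <= 0 || threshold_rel >= 1)
    stop_capflow("threshold_rel must be in (0, 1)", "capflow_domain_error")
  nfr <- length(stack$frames)
  if (baseline_frame < 0 || baseline_frame >= nfr)
    stop_capflow("baseline_frame outside stack", "capflow_index_error")
  d <- stack$dim
  r <- layout$rois
  if (any(r$x0 < 0) || any(r$y0 < 0) || any(r$x1 > d[2]) || any(r$y1 > d[1]))
    stop_capflow("ROI outside frame bounds", "capflow_geometry_error")

  lapply(seq_len(nrow(r)), function(i) {
    axis_mat <- channel_axis_matrix(stack, r[i, ], layout$flow_axis)
    extent_cm <- ncol(axis_mat) / stack$pixel_scale
    if (extent_cm < layout$channel_length_cm * 0.95)
      stop_capflow(sprintf("ROI %s spans %.2f cm < 95%% of channel length %.2f cm",
                           r$channel_id[i], extent_cm, layout$channel_length_cm),
                   "capflow_geometry_error")
    change <- abs(sweep(axis_mat, 2, axis_mat[baseline_frame + 1L, ]))
    max_change <- max(change)
    if (max_change <= 0) {
      warn_capflow(sprintf("channel %s: no intensity change detected (dry channel)",
                           r$channel_id[i]), "capflow_dry_channel")
      return(flow_profile(rep(0, nfr), stack$frame_rate,
                          channel_id = r$channel_id[i],
                          channel_length_cm = layout$channel_length_cm,
                          dry = TRUE))
    }
    thr <- threshold_rel * max_change
    dist <- apply(change, 1, function(row) {
      f <- which(row > thr)
      if (!length(f)) 0 else max(f) / stack$pixel_scale
    })
    prof <- flow_profile(pmin(dist, layout$channel_length_cm), stack$frame_rate,
                         channel_id = r$channel_id[i],
                         channel_length_cm = layout$channel_length_cm)
    enforce_monotone(prof)
  })
}

# Matrix of central-axis intensities for one ROI: rows = frames, columns =
# along-axis pixel positions (0-based position p is column p + 1). The axis
# value at each position is the median over a band of up to 3 pixels centred
# on the channel midline.
channel_axis_matrix <- function(stack, roi, flow_axis) {
  xs <- (roi$x0 + 1):roi$x1
  ys <- (roi$y0 + 1):roi$y1
  if (flow_axis == "x") {
    mid <- ys[ceiling(length(ys) / 2)]
    band <- intersect((mid - 1):(mid + 1), ys)
    t(vapply(stack$frames, function(fr) {
      apply(fr[band, xs, drop = FALSE], 2, median)
    }, numeric(length(xs))))
  } else {
    mid <- xs[ceiling(length(xs) / 2)]
    band <- intersect((mid - 1):(mid + 1), xs)
    t(vapply(stack$frames, function(fr) {
      apply(fr[ys, band, drop = FALSE], 1, median)
    }, numeric(length(ys))))
  }
}
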