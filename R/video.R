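#' Video stack: an ordered sequence of intensity frames
#'
#' Frames are numeric matrices (rows = y, columns = x) holding a single
#' luminance plane; colour frames (3-d arrays with an RGB third dimension)
#' are converted with the Rec.601 luma weights. All frames must share one
#' size.
#'
#' @param frames list of matrices, or a 3-d array `[y, x, frame]`.
#' @param frame_rate frames per second.
#' @param pixel_scale pixels per cm.
#' @return An object of class `video_stack`.
#' @export
video_stack <- function(frames, frame_rate, pixel_scale) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  if (!length(frames)) stop_capflow("empty frame stack", "capflow_domain_error")
  frames <- lapply(frames, as_luminance)
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop_capflow("all frames must share identical dimensions", "capflow_geometry_error")
  if (frame_rate <= 0 || pixel_scale <= 0)
    stop_capflow("frame_rate and pixel_scale must be positive", "capflow_domain_error")
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_scale = pixel_scale, dim = d),
            class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  cat(sprintf("<video_stack> %d frames of %dx%d px @ %g fps, %g px/cm\n",
              length(x$frames), x$dim[1], x$dim[2], x$frame_rate, x$pixel_scale))
  invisible(x)
}

# Collapse an RGB frame to a single luminance plane (Rec.601 weights);
# grayscale matrices pass through.
as_luminance <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (is.array(frame) && length(dim(frame)) == 3 && dim(frame)[3] == 3) {
    return(0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3])
  }
  stop_capflow("frames must be matrices or RGB arrays", "capflow_domain_error")
}

#' Channel layout: ROI geometry of the paper chip
#'
#' Rectangular, axis-aligned channel regions in pixel coordinates (0-based,
#' half-open: a channel spanning pixels 0..83 has `x0 = 0, x1 = 84`). Each ROI
#' should cover the trackable part of the channel, starting at the downstream
#' edge of the loading zone; liquid flows towards increasing x (or y when
#' `flow_axis = "y"`).
#'
#' @param rois data frame with columns `x0, y0, x1, y1` (and optionally
#'   `channel_id`), or a list of length-4 vectors.
#' @param flow_axis `"x"` or `"y"`: image axis along which the liquid flows.
#' @param channel_length_cm trackable channel length (default 2.1 cm, the
#'   printed channel size of the reference chip).
#' @param channel_width_cm channel width (default 0.3 cm).
#' @param loading_zone_cm length of the sample loading area that sits
#'   upstream of each ROI and is excluded from tracking (default 0.3 cm).
#' @return An object of class `channel_layout`.
#' @export
channel_layout <- function(rois, flow_axis = c("x", "y"),
                           channel_length_cm = 2.1, channel_width_cm = 0.3,
                           loading_zone_cm = 0.3) {
  flow_axis <- match.arg(flow_axis)
  if (!is.data.frame(rois)) {
    rois <- as.data.frame(do.call(rbind, lapply(rois, function(r) {
      setNames(as.list(r[1:4]), c("x0", "y0", "x1", "y1"))
    })))
  }
  need <- c("x0", "y0", "x1", "y1")
  if (!all(need %in% names(rois)))
    stop_capflow("rois need columns x0, y0, x1, y1", "capflow_schema_error")
  if (is.null(rois$channel_id)) rois$channel_id <- paste0("ch", seq_len(nrow(rois)))
  if (any(rois$x1 <= rois$x0) || any(rois$y1 <= rois$y0))
    stop_capflow("ROIs must have positive extent", "capflow_geometry_error")
  if (rois_overlap(rois))
    stop_capflow("channel ROIs must not overlap", "capflow_geometry_error")
  structure(list(rois = rois, flow_axis = flow_axis,
                 channel_length_cm = channel_length_cm,
                 channel_width_cm = channel_width_cm,
                 loading_zone_cm = loading_zone_cm),
            class = "channel_layout")
}

rois_overlap <- function(r) {
  n <- nrow(r)
  if (n < 2) return(FALSE)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (r$x0[i] < r$x1[j] && r$x0[j] < r$x1[i] &&
        r$y0[i] < r$y1[j] && r$y0[j] < r$y1[i]) return(TRUE)
  }
  FALSE
}

#' @export
print.channel_layout <- function(x, ...) {
  cat(sprintf("<channel_layout> %d channel(s), flow along %s, %g x %g cm (+%g cm loading)\n",
              nrow(x$rois), x$flow_axis, x$channel_length_cm,
              x$channel_width_cm, x$loading_zone_cm))
  invisible(x)
}

#' Read and write ASCII PGM (P2) frames
#'
#' Minimal plain-text image I/O so frame stacks can be stored without binary
#' formats. A directory of frames is read in lexicographic order.
#'
#' @param path file (or directory for the `_dir` variants) path.
#' @param frame numeric matrix with values in `[0, 1]`.
#' @param maxval integer grey-level ceiling used for quantisation.
#' @return `read_pgm` a matrix in `[0, 1]`; `write_pgm` the path, invisibly.
#' @export
write_pgm <- function(frame, path, maxval = 255L) {
  q <- round(pmin(pmax(frame, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(q), nrow(q)), as.character(maxval)), con)
  write(t(q), file = con, ncolumns = ncol(q))
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (tok[1] != "P2") stop_capflow("only ASCII PGM (P2) is supported", "capflow_schema_error")
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxval <- as.numeric(tok[4])
  px <- as.numeric(tok[-(1:4)])
  if (length(px) != w * h) stop_capflow("corrupt PGM payload", "capflow_schema_error")
  matrix(px, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' @rdname write_pgm
#' @param stack a [video_stack()] to write, one `frame_%04d.pgm` per frame.
#' @export
write_frame_dir <- function(stack, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$frames)) {
    write_pgm(stack$frames[[i]], file.path(path, sprintf("frame_%04d.pgm", i - 1)))
  }
  invisible(path)
}

#' @rdname write_pgm
#' @param frame_rate,pixel_scale calibration attached to the stack read from
#'   a frame directory.
#' @export
read_frame_dir <- function(path, frame_rate, pixel_scale) {
  files <- sort(list.files(path, pattern = "\\.pgm$", full.names = TRUE))
  if (!length(files)) stop_capflow("no PGM frames found", "capflow_schema_error")
  video_stack(lapply(files, read_pgm), frame_rate, pixel_scale)
}
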