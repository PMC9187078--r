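# Loading stills, frame sampling, segment manifests and the field-of-view mask.

#' Construct a still picture
#'
#' Wraps an RGB pixel array together with its identity in a capsule study:
#' which examination, which camera (forward/backward), which colorectal
#' segment, and its position within the segment's series.
#'
#' @param pixels H x W x 3 numeric array with values in 0..255.
#' @param study_id Character study/examination identifier.
#' @param camera `"f"` (forward) or `"b"` (backward).
#' @param segment One of [segment_levels()].
#' @param index Non-negative integer position within the segment series.
#' @return An object of class `still_picture`.
#' @export
still_picture <- function(pixels, study_id = "study", camera = "f",
                          segment = "cecum_ascending", index = 0L) {
  assert_rgb_array(pixels)
  camera <- match.arg(camera, CAMERA_LEVELS)
  segment <- match.arg(segment, SEGMENT_LEVELS)
  stopifnot(index >= 0)
  structure(
    list(pixels = pixels, study_id = study_id, camera = camera,
         segment = segment, index = as.integer(index)),
    class = "still_picture"
  )
}

#' @export
print.still_picture <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<still_picture %s %s/%s #%d, %dx%d>\n",
              x$study_id, x$camera, x$segment, x$index, d[1], d[2]))
  invisible(x)
}

#' @export
dim.still_picture <- function(x) dim(x$pixels)

#' Identifier string for a still (study:camera:segment:index)
#' @param still A `still_picture`.
#' @return Character scalar.
#' @export
still_id <- function(still) {
  paste(still$study_id, still$camera, still$segment, still$index, sep = ":")
}

#' Load a still picture from an image file
#'
#' Reads a JPEG or PNG file into a [still_picture()]. Capsule-conformant
#' stills are 576x576 pixels; other sizes are accepted with a warning.
#' Grayscale images are replicated to three channels.
#'
#' @param path Path to a JPEG/PNG file.
#' @inheritParams still_picture
#' @return A `still_picture`.
#' @export
load_still <- function(path, study_id = "study", camera = "f",
                       segment = "cecum_ascending", index = 0L) {
  img <- tryCatch(
    EBImage::readImage(path),
    error = function(e) stop("cannot decode image file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) {
    arr <- array(rep(arr, 3L), c(dim(arr), 3L))
  }
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  # EBImage stores (x = column, y = row); transpose to row-major H x W x 3
  pixels <- aperm(arr, c(2, 1, 3))
  pixels <- round(pmin(pmax(pixels, 0), 1) * 255)
  if (dim(pixels)[1] != 576L || dim(pixels)[2] != 576L) {
    warning(sprintf("still '%s' is %dx%d, not the standard 576x576",
                    path, dim(pixels)[1], dim(pixels)[2]), call. = FALSE)
  }
  still_picture(pixels, study_id = study_id, camera = camera,
                segment = segment, index = index)
}

#' Write a still picture to an image file
#'
#' @param still A `still_picture`.
#' @param path Output path; format from extension (.png or .jpg).
#' @return `path`, invisibly.
#' @export
write_still <- function(still, path) {
  arr <- aperm(still$pixels / 255, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(arr, colormode = "Color"), path)
  invisible(path)
}

#' Uniform frame-sampling indices
#'
#' Selects `n` indices uniformly from `0 .. n_frames-1` with both endpoints
#' included (for `n >= 2`): index_i = round(i * (L-1) / (n-1)), half-up.
#'
#' @param n_frames Number of frames available (L).
#' @param n Number of frames to select.
#' @return Integer vector of 0-based frame indices, strictly increasing.
#' @export
sample_frame_indices <- function(n_frames, n = 50L) {
  n_frames <- as.integer(n_frames)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (n_frames < n) {
    stop(sprintf("frame range has %d frames, fewer than the %d requested",
                 n_frames, n), call. = FALSE)
  }
  if (n == 1L) return(0L)
  i <- 0:(n - 1L)
  as.integer(floor(i * (n_frames - 1) / (n - 1) + 0.5))
}

#' Extract still pictures from a frame sequence
#'
#' Samples `n_stills` frames uniformly (endpoints included) from a segment's
#' frame sequence, in temporal order. The frame source is either a list of
#' H x W x 3 pixel arrays or a character vector of frame image files; MPEG
#' container decoding to frames is upstream of this function.
#'
#' @param frames List of RGB arrays, or character vector of image paths,
#'   covering the segment's frame range in temporal order.
#' @param n_stills Number of stills to extract (default 50, the per-segment
#'   series length of a standard capsule study).
#' @inheritParams still_picture
#' @return List of `still_picture`, `index` running 0..n_stills-1.
#' @export
extract_stills <- function(frames, n_stills = 50L, study_id = "study",
                           camera = "f", segment = "cecum_ascending") {
  idx <- sample_frame_indices(length(frames), n_stills)
  lapply(seq_along(idx), function(k) {
    fr <- if (is.character(frames)) {
      load_still(frames[idx[k] + 1L], study_id, camera, segment, k - 1L)
    } else {
      still_picture(frames[[idx[k] + 1L]], study_id, camera, segment, k - 1L)
    }
    fr
  })
}

#' Read and validate a segment manifest
#'
#' A manifest declares the human partition of a capsule recording: one row per
#' (camera, segment) with the frame source. Columns: `source` (file, directory
#' or glob), `camera` in `f`/`b`, `segment` in [segment_levels()], optional
#' `start_frame`,`end_frame` (0-based, inclusive) for video-frame sources.
#'
#' @param manifest Path to a CSV file, or a data.frame.
#' @return Validated data.frame with `camera` and `segment` as factors.
#' @export
read_manifest <- function(manifest) {
  m <- if (is.character(manifest)) {
    utils::read.csv(manifest, stringsAsFactors = FALSE)
  } else {
    as.data.frame(manifest, stringsAsFactors = FALSE)
  }
  required <- c("source", "camera", "segment")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    stop("manifest lacks required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(m) == 0L) stop("manifest is empty", call. = FALSE)
  if (!all(m$camera %in% CAMERA_LEVELS)) {
    stop("manifest camera values must be one of: ",
         paste(CAMERA_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (!all(m$segment %in% SEGMENT_LEVELS)) {
    stop("manifest segment values must be one of: ",
         paste(SEGMENT_LEVELS, collapse = ", "), call. = FALSE)
  }
  key <- paste(m$camera, m$segment)
  if (anyDuplicated(key)) {
    stop("manifest maps (camera, segment) pair(s) more than once: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  m$camera <- factor(m$camera, levels = CAMERA_LEVELS)
  m$segment <- factor(m$segment, levels = SEGMENT_LEVELS)
  m[order(m$camera, m$segment), , drop = FALSE]
}

#' Estimate the effective optical region of a still
#'
#' Capsule stills have a circular field of view; the image corners outside the
#' optics are near-black. The effective-region mask is estimated by labelling
#' near-black connected components (grayscale < `corner_threshold`) that touch
#' an image corner and taking their complement. When no such component exists,
#' or when the dark region covers the whole frame (no contrast to segment),
#' the mask is all-true and downstream intensity exclusion handles the rest.
#' An explicit user-supplied mask always overrides estimation.
#'
#' @param still A `still_picture`.
#' @param corner_threshold Grayscale intensity below which a pixel counts as
#'   near-black (default 30).
#' @return H x W logical matrix, `TRUE` = inside the field of view.
#' @export
estimate_fov_mask <- function(still, corner_threshold = 30) {
  g <- rec601_gray(still$pixels)
  dark <- g < corner_threshold
  if (!any(dark)) return(matrix(TRUE, nrow(g), ncol(g)))
  # connected components on the dark set (EBImage works column-major x,y)
  lab <- EBImage::bwlabel(t(dark))
  h <- nrow(g); w <- ncol(g)
  corner_labels <- unique(c(lab[1, 1], lab[w, 1], lab[1, h], lab[w, h]))
  corner_labels <- corner_labels[corner_labels > 0]
  if (length(corner_labels) == 0L) return(matrix(TRUE, h, w))
  mask <- !(t(lab) %in% corner_labels)
  mask <- matrix(mask, h, w)
  if (!any(mask)) return(matrix(TRUE, h, w))  # all-dark degenerate still
  mask
}

#' Read a mask override image
#'
#' @param path Single-channel PNG; nonzero pixels mark the inside of the
#'   field of view.
#' @return H x W logical matrix.
#' @export
read_mask <- function(path) {
  img <- as.array(EBImage::readImage(path))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  t(img) > 0
}
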