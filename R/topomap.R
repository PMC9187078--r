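# Assembling per-still profiles into a topographic severity map, rendering
# the stacked-bar figure and exporting/importing the percent-severity table.

# Fixed stacked-bar palette: MES0 light gray, MES1 yellow, MES2 magenta,
# MES3 red.
MAP_COLORS <- c(MES0 = "gray80", MES1 = "yellow", MES2 = "magenta",
                MES3 = "red")

#' Assemble severity profiles into a topographic map
#'
#' Orders per-still profiles anatomically — per camera, segments
#' cecum_ascending -> transverse -> descending_sigmoid -> rectum, indices
#' ascending within each segment — into a positional map along the
#' colorectum. Excluded stills are retained in place (they render as blank
#' columns). Input order is irrelevant; duplicate (camera, segment, index)
#' positions are an error.
#'
#' @param profiles data.frame of severity profiles (rows as returned by
#'   [severity_profile()] / [profile_still()]), each carrying `camera`,
#'   `segment`, `index`.
#' @param study_id Study identifier attached to the map.
#' @return A `topographic_map`: the ordered data.frame with an added
#'   `position` column (1-based position within each camera track) and
#'   attribute `study_id`.
#' @export
build_topographic_map <- function(profiles, study_id = "study") {
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0)
  need <- c("camera", "segment", "index")
  if (!all(need %in% names(profiles)) ||
      anyNA(profiles[need])) {
    stop("every profile must carry camera, segment and index", call. = FALSE)
  }
  if (!all(profiles$camera %in% CAMERA_LEVELS) ||
      !all(profiles$segment %in% SEGMENT_LEVELS)) {
    stop("unknown camera or segment value in profiles", call. = FALSE)
  }
  key <- paste(profiles$camera, profiles$segment, profiles$index)
  if (anyDuplicated(key)) {
    stop("duplicate still position(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  ord <- order(factor(profiles$camera, levels = CAMERA_LEVELS),
               factor(profiles$segment, levels = SEGMENT_LEVELS),
               profiles$index)
  m <- profiles[ord, , drop = FALSE]
  rownames(m) <- NULL
  m$position <- stats::ave(seq_len(nrow(m)), m$camera, FUN = seq_along)
  structure(m, class = c("topographic_map", "data.frame"),
            study_id = study_id)
}

#' Render a topographic severity map
#'
#' One stacked column per still along the positional axis, bottom-to-top
#' MES0 (light gray), MES1 (yellow), MES2 (magenta), MES3 (red); excluded
#' stills appear as blank columns at their position; segment boundaries are
#' marked; one panel per camera track.
#'
#' @param map A `topographic_map`.
#' @param out_path Optional output file (`.png` or `.svg`); `NULL` returns
#'   the plot without writing.
#' @param format `"png"` or `"svg"`; default from `out_path` extension.
#' @param width,height Figure size in inches.
#' @return The ggplot object, invisibly when writing.
#' @export
render_map <- function(map, out_path = NULL, format = NULL,
                       width = 10, height = 4) {
  stopifnot(inherits(map, "topographic_map"), nrow(map) > 0)
  long <- do.call(rbind, lapply(0:3, function(k) {
    data.frame(camera = map$camera, position = map$position,
               class = CLASS_NAMES[k + 1L],
               frac = ifelse(map$excluded, 0, map[[paste0("frac", k)]]))
  }))
  # stack order: MES0 drawn at the bottom of the column
  long$class <- factor(long$class, levels = rev(names(MAP_COLORS)))
  long$camera <- factor(long$camera, levels = CAMERA_LEVELS)
  boundaries <- do.call(rbind, lapply(split(map, map$camera), function(tr) {
    if (nrow(tr) == 0) return(NULL)
    ends <- cumsum(table(factor(tr$segment, levels = SEGMENT_LEVELS)))
    data.frame(camera = factor(tr$camera[1], levels = CAMERA_LEVELS),
               x = utils::head(as.numeric(ends), -1) + 0.5)
  }))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$position, y = .data$frac,
                                    fill = .data$class)) +
    ggplot2::geom_col(width = 1, position = "stack") +
    ggplot2::scale_fill_manual(values = MAP_COLORS, name = NULL,
                               breaks = names(MAP_COLORS)) +
    ggplot2::facet_wrap(~camera, ncol = 1,
                        labeller = ggplot2::as_labeller(
                          c(f = "forward camera", b = "backward camera"))) +
    ggplot2::labs(x = "still position along colorectum (cecum → rectum)",
                  y = "% area", title = attr(map, "study_id")) +
    ggplot2::scale_y_continuous(labels = function(v) v * 100) +
    ggplot2::theme_minimal()
  if (!is.null(boundaries) && nrow(boundaries) > 0) {
    p <- p + ggplot2::geom_vline(data = boundaries,
                                 ggplot2::aes(xintercept = .data$x),
                                 linetype = "dashed", colour = "gray40")
  }
  if (is.null(out_path)) return(p)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(out_path))
    if (!format %in% c("png", "svg")) format <- "png"
  }
  dev <- if (format == "svg") grDevices::svg else "png"
  ggplot2::ggsave(out_path, p, device = dev, width = width, height = height,
                  dpi = 150)
  invisible(p)
}

#' Export a topographic map as a percent-severity table
#'
#' One row per still in track order with the four severity percentages
#' (fractions x 100, half-up to 1 decimal) and the excluded flag. Excluded
#' stills have empty percentage cells. Raw fractions are emitted alongside,
#' so the rounding residue in the percentage columns (rows summing to
#' 99.9/100.1) loses no information.
#'
#' @param map A `topographic_map`.
#' @param out_path Optional CSV path; `NULL` returns the table only.
#' @return The exported data.frame, invisibly when writing.
#' @export
export_table <- function(map, out_path = NULL) {
  stopifnot(inherits(map, "topographic_map"))
  tab <- data.frame(still_id = map$still_id, camera = map$camera,
                    segment = map$segment, index = map$index,
                    position = map$position)
  for (k in 0:3) {
    tab[[paste0("pct", k)]] <- ifelse(map$excluded, NA_real_,
                                      round_half_up(map[[paste0("frac", k)]] * 100, 1))
    tab[[paste0("frac", k)]] <- map[[paste0("frac", k)]]
  }
  for (k in 0:3) tab[[paste0("area", k)]] <- map[[paste0("area", k)]]
  tab$total <- map$total
  tab$excluded <- map$excluded
  if (is.null(out_path)) return(tab)
  utils::write.csv(tab, out_path, row.names = FALSE, na = "")
  invisible(tab)
}

#' Re-import an exported percent-severity table
#'
#' @param path CSV written by [export_table()].
#' @return data.frame with the same columns; empty percentage cells of
#'   excluded stills read back as `NA`.
#' @export
import_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialise a topographic map to JSON
#'
#' @param map A `topographic_map`.
#' @param out_path JSON output path.
#' @return `out_path`, invisibly.
#' @export
write_map_json <- function(map, out_path) {
  payload <- list(study_id = attr(map, "study_id"),
                  profiles = as.data.frame(map))
  jsonlite::write_json(payload, out_path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_path)
}
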