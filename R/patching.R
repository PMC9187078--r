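# Sliding-window tiling and the blackout/overexposure exclusion rules.

#' Patch exclusion rule
#'
#' Thresholds for dropping uninterpretable patches before classification. A
#' patch is a *blackout* when the fraction of its pixels with grayscale
#' intensity strictly below `low_cut` strictly exceeds `low_frac`, and
#' *overexposed* when the fraction strictly above `high_cut` strictly exceeds
#' `high_frac`. Defaults: >1% of pixels < 70, or >5% of pixels > 230, on the
#' Rec.601 luma (the channel is configurable).
#'
#' @param low_cut,low_frac Blackout intensity cut and fraction (70, 0.01).
#' @param high_cut,high_frac Overexposure cut and fraction (230, 0.05).
#' @param channel `"gray"` (Rec.601 luma, default) or `"r"`, `"g"`, `"b"`.
#' @return An object of class `exclusion_rule`.
#' @export
exclusion_rule <- function(low_cut = 70, low_frac = 0.01,
                           high_cut = 230, high_frac = 0.05,
                           channel = c("gray", "r", "g", "b")) {
  channel <- match.arg(channel)
  stopifnot(0 <= low_cut, low_cut < high_cut, high_cut <= 255,
            0 < low_frac, low_frac < 1, 0 < high_frac, high_frac < 1)
  structure(list(low_cut = low_cut, low_frac = low_frac,
                 high_cut = high_cut, high_frac = high_frac,
                 channel = channel),
            class = "exclusion_rule")
}

#' Enumerate the patch grid of an image
#'
#' All fully-in-bounds `patch_size` x `patch_size` windows at offsets that are
#' multiples of `stride`, enumerated left-to-right then top-to-bottom
#' (upper-left first, rightwards, then downwards). Windows are half-open:
#' `[row, row+patch_size) x [col, col+patch_size)` with 0-based offsets.
#'
#' @param height,width Image dimensions in pixels.
#' @param patch_size Window side (default 128).
#' @param stride Offset step (default 32).
#' @return data.frame with columns `row`, `col`, `size`; zero rows when the
#'   patch does not fit.
#' @export
#' @examples
#' nrow(tile_grid(576, 576))  # 225 = 15 x 15
tile_grid <- function(height, width, patch_size = 128L, stride = 32L) {
  stopifnot(patch_size >= 1, stride >= 1)
  rows <- if (height >= patch_size) seq(0L, height - patch_size, by = stride) else integer(0)
  cols <- if (width >= patch_size) seq(0L, width - patch_size, by = stride) else integer(0)
  n <- length(rows) * length(cols)
  data.frame(
    row = rep(as.integer(rows), each = length(cols)),
    col = rep(as.integer(cols), times = length(rows)),
    size = rep(as.integer(patch_size), n)
  )
}

# Pixel sub-array of one patch window; spec is a list/row with row, col, size.
patch_pixels <- function(still, spec) {
  pixels <- if (inherits(still, "still_picture")) still$pixels else still
  d <- dim(pixels)
  if (spec$row < 0 || spec$col < 0 ||
      spec$row + spec$size > d[1] || spec$col + spec$size > d[2]) {
    stop(sprintf("patch window [%d,%d)x[%d,%d) out of bounds for %dx%d image",
                 spec$row, spec$row + spec$size, spec$col, spec$col + spec$size,
                 d[1], d[2]), call. = FALSE)
  }
  pixels[spec$row + seq_len(spec$size), spec$col + seq_len(spec$size), ,
         drop = FALSE]
}

rule_channel <- function(pixels, rule) {
  switch(rule$channel,
         gray = rec601_gray(pixels),
         r = pixels[, , 1], g = pixels[, , 2], b = pixels[, , 3])
}

#' Count low- and high-intensity pixels in a patch
#'
#' @param still A `still_picture` or H x W x 3 array.
#' @param spec One patch window (list or one-row data.frame with `row`,
#'   `col`, `size`).
#' @param rule An [exclusion_rule()].
#' @return Named integer vector `c(n_low, n_high)`: counts of patch pixels
#'   with intensity strictly below `low_cut` / strictly above `high_cut`.
#' @export
patch_gray_stats <- function(still, spec, rule = exclusion_rule()) {
  v <- rule_channel(patch_pixels(still, spec), rule)
  c(n_low = sum(v < rule$low_cut), n_high = sum(v > rule$high_cut))
}

#' Decide whether a patch is excluded
#'
#' Applies the blackout and overexposure rules with strict inequalities: with
#' the default rule on a 128x128 patch (16384 pixels), 164 dark pixels
#' (164/16384 > 1%) trigger a blackout while 163 do not, and 820 bright
#' pixels (820/16384 > 5%) trigger overexposure while 819 do not. Blackout is
#' checked first when both hold.
#'
#' @inheritParams patch_gray_stats
#' @return List with `excluded` (logical) and `reason` (`"none"`,
#'   `"blackout"` or `"overexposed"`).
#' @export
is_excluded <- function(still, spec, rule = exclusion_rule()) {
  n <- patch_gray_stats(still, spec, rule)
  npix <- spec$size^2
  if (n[["n_low"]] / npix > rule$low_frac) {
    list(excluded = TRUE, reason = "blackout")
  } else if (n[["n_high"]] / npix > rule$high_frac) {
    list(excluded = TRUE, reason = "overexposed")
  } else {
    list(excluded = FALSE, reason = "none")
  }
}

#' Inventory all patch windows of a still with exclusion decisions
#'
#' @inheritParams extract_patches
#' @return data.frame `row`, `col`, `size`, `inside_mask`, `excluded`,
#'   `reason`, in grid enumeration order.
#' @export
patch_inventory <- function(still, mask = NULL, rule = exclusion_rule(),
                            patch_size = 128L, stride = 32L,
                            min_inside = 1.0) {
  pixels <- if (inherits(still, "still_picture")) still$pixels else still
  d <- dim(pixels)
  grid <- tile_grid(d[1], d[2], patch_size, stride)
  if (!is.null(mask) && !all(dim(mask) == d[1:2])) {
    stop("mask dimensions do not match the still", call. = FALSE)
  }
  n <- nrow(grid)
  inside <- rep(TRUE, n)
  excluded <- logical(n)
  reason <- rep("none", n)
  for (i in seq_len(n)) {
    sp <- grid[i, ]
    if (!is.null(mask)) {
      mwin <- mask[sp$row + seq_len(sp$size), sp$col + seq_len(sp$size)]
      inside[i] <- mean(mwin) >= min_inside
    }
    if (inside[i]) {
      e <- is_excluded(pixels, sp, rule)
      excluded[i] <- e$excluded
      reason[i] <- e$reason
    }
  }
  cbind(grid, inside_mask = inside, excluded = excluded, reason = reason)
}

#' Extract the eligible patch windows of a still
#'
#' Tiles the still with [tile_grid()], keeps windows lying entirely inside
#' the effective-region mask (configurable minimum inside fraction), and
#' drops windows failing [is_excluded()]. Output order is grid enumeration
#' order, so the result is always a subset of [tile_grid()].
#'
#' @param still A `still_picture` or H x W x 3 array.
#' @param mask Optional H x W logical effective-region mask (`NULL` = all
#'   inside).
#' @param rule An [exclusion_rule()].
#' @param patch_size,stride Grid geometry (defaults 128, 32).
#' @param min_inside Minimum fraction of window pixels that must be inside
#'   the mask (default 1.0 = fully inside).
#' @return data.frame with columns `row`, `col`, `size`.
#' @export
extract_patches <- function(still, mask = NULL, rule = exclusion_rule(),
                            patch_size = 128L, stride = 32L,
                            min_inside = 1.0) {
  inv <- patch_inventory(still, mask, rule, patch_size, stride, min_inside)
  keep <- inv$inside_mask & !inv$excluded
  inv[keep, c("row", "col", "size"), drop = FALSE]
}
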