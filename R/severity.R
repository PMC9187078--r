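# Per-still severity: percent-area fractions of per-class pixel unions.

#' Construct a classified patch grid
#'
#' The classification result for one still: each eligible patch window with
#' its class label, plus the still's dimensions and identity.
#'
#' @param specs data.frame with columns `row`, `col`, `size` (as produced by
#'   [extract_patches()]).
#' @param labels Integer class labels 0..5, one per spec.
#' @param height,width Still dimensions in pixels.
#' @param still_id Identity string; see [still_id()].
#' @return An object of class `classified_grid`.
#' @export
classified_grid <- function(specs, labels, height = 576L, width = 576L,
                            still_id = "still") {
  labels <- assert_label(labels)
  stopifnot(nrow(specs) == length(labels))
  if (nrow(specs) > 0) {
    stopifnot(all(specs$row >= 0), all(specs$col >= 0),
              all(specs$row + specs$size <= height),
              all(specs$col + specs$size <= width))
    dup <- duplicated(cbind(specs[, c("row", "col", "size")], labels))
    if (any(dup)) {
      # duplicate (window, label) pairs are tolerated (unions are
      # idempotent) and collapsed
      specs <- specs[!dup, , drop = FALSE]
      labels <- labels[!dup]
    }
  }
  structure(list(still_id = still_id,
                 items = cbind(specs, label = labels),
                 height = as.integer(height), width = as.integer(width)),
            class = "classified_grid")
}

# Exact area of a union of axis-aligned half-open rectangles
# [r0,r1) x [c0,c1), by column-slab sweep with row-interval union.
rect_union_area <- function(r0, c0, r1, c1) {
  if (length(r0) == 0L) return(0)
  xs <- sort(unique(c(c0, c1)))
  total <- 0
  for (i in seq_len(length(xs) - 1L)) {
    left <- xs[i]; w <- xs[i + 1L] - left
    sel <- which(c0 <= left & c1 >= xs[i + 1L])
    if (length(sel) == 0L) next
    ord <- order(r0[sel])
    a <- r0[sel][ord]; b <- r1[sel][ord]
    covered <- 0; cs <- a[1]; ce <- b[1]
    for (k in seq_along(a)[-1]) {
      if (a[k] > ce) {
        covered <- covered + (ce - cs); cs <- a[k]; ce <- b[k]
      } else if (b[k] > ce) {
        ce <- b[k]
      }
    }
    covered <- covered + (ce - cs)
    total <- total + covered * w
  }
  total
}

#' Pixel-union area of one class in a classified grid
#'
#' With the class-k patches numbered S1..Sn, the class area is the number of
#' distinct pixels in S1 U S2 U ... U Sn — overlapping windows are not
#' double-counted. Computed exactly by a scanline interval union; invariant
#' to item order and to duplicate windows.
#'
#' @param grid A [classified_grid()].
#' @param label Class label 0..5.
#' @return Pixel count (0 when no patch carries the label).
#' @export
class_area <- function(grid, label) {
  it <- grid$items[grid$items$label == assert_label(label), , drop = FALSE]
  rect_union_area(it$row, it$col, it$row + it$size, it$col + it$size)
}

#' Severity profile of a classified still
#'
#' Computes area0..area3 as the per-class pixel unions of the MES0..MES3
#' patches, total area as their arithmetic sum (a pixel covered by patches
#' of two different grades contributes to both areas), and the severity
#' fractions areaK/total. Classes 4 (inadequate) and 5 (ileal) never enter
#' the total. When total area is 0 — e.g. every patch was inadequate — the
#' still is excluded from evaluation and its fractions are `NA`.
#'
#' @param grid A [classified_grid()].
#' @param camera,segment,index Optional identity carried into the profile.
#' @return One-row data.frame: `still_id`, `camera`, `segment`, `index`,
#'   `area0`..`area3`, `total`, `frac0`..`frac3`, `excluded`.
#' @export
severity_profile <- function(grid, camera = NA_character_,
                             segment = NA_character_, index = NA_integer_) {
  areas <- vapply(0:3, function(k) class_area(grid, k), numeric(1))
  total <- sum(areas)
  excluded <- total == 0
  fr <- if (excluded) rep(NA_real_, 4) else areas / total
  out <- data.frame(still_id = grid$still_id, camera = camera,
                    segment = segment, index = index)
  out[paste0("area", 0:3)] <- as.list(areas)
  out$total <- total
  out[paste0("frac", 0:3)] <- as.list(fr)
  out$excluded <- excluded
  out
}

#' Classify a still and compute its severity profile
#'
#' Convenience wrapper chaining [extract_patches()], [predict_patches()]
#' and [severity_profile()] for one still.
#'
#' @param still A `still_picture`.
#' @param model A `ccemap_model`.
#' @param mask Optional effective-region mask; `"estimate"` to call
#'   [estimate_fov_mask()], `NULL` for none.
#' @param rule An [exclusion_rule()].
#' @return One-row profile data.frame as in [severity_profile()].
#' @export
profile_still <- function(still, model, mask = NULL,
                          rule = exclusion_rule()) {
  if (identical(mask, "estimate")) mask <- estimate_fov_mask(still)
  specs <- extract_patches(still, mask, rule)
  labels <- if (nrow(specs) == 0L) {
    integer(0)
  } else {
    patches <- lapply(seq_len(nrow(specs)),
                      function(i) patch_pixels(still, specs[i, ]))
    predict_patches(model, patches)$label
  }
  d <- dim(still$pixels)
  grid <- classified_grid(specs, labels, d[1], d[2], still_id(still))
  severity_profile(grid, camera = still$camera, segment = still$segment,
                   index = still$index)
}
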