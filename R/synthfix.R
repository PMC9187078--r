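# Synthetic stills and labelled patch sets with known ground truth:
# class-coded textures, circular field of view, blackout and overexposure
# defects. These stand in for clinical images, which the pipeline never
# requires for its own verification.

# Texture parameters. The class signature lives in the red-minus-blue offset
# (see synth_texture_key()); a shared luminance field carries a 32-pixel
# periodic ripple (so every 32-stride window sees the same phase) plus
# seeded noise. Amplitudes are chosen so that clean textures never trip the
# intensity exclusion rules: channel values stay within [72, 228].
TEXTURE_BASE <- 150
TEXTURE_RIPPLE <- 12
TEXTURE_NOISE_SD <- 3
TEXTURE_NOISE_CLAMP <- 9

# Paint class textures over an H x W label field (values 0..5, NA = leave
# black). Returns an H x W x 3 array in 0..255. Vectorised over pixels.
paint_textures <- function(label_field) {
  h <- nrow(label_field); w <- ncol(label_field)
  key <- synth_texture_key()
  rowc <- row(label_field) - 1L; colc <- col(label_field) - 1L
  phase <- ifelse(is.na(label_field), 0, label_field * pi / 3)
  g <- TEXTURE_BASE +
    TEXTURE_RIPPLE * sin(2 * pi * (rowc + colc) / 32 + phase) +
    pmin(pmax(matrix(stats::rnorm(h * w, sd = TEXTURE_NOISE_SD), h, w),
              -TEXTURE_NOISE_CLAMP), TEXTURE_NOISE_CLAMP)
  delta <- matrix(NA_real_, h, w)
  for (k in 0:5) {
    delta[label_field == k & !is.na(label_field)] <- key$delta[key$label == k]
  }
  px <- array(0, c(h, w, 3))
  on <- !is.na(label_field)
  px[, , 1][on] <- g[on] + delta[on]
  px[, , 2][on] <- g[on]
  px[, , 3][on] <- g[on] - delta[on]
  round(pmin(pmax(px, 0), 255))
}

#' Layout for a synthetic still
#'
#' Declares how a synthetic still is painted: class regions (axis-aligned
#' rectangles, later regions override earlier ones), an optional circular
#' field of view (outside is black), and defect regions painted below the
#' blackout threshold or above the overexposure threshold.
#'
#' @param side Image side in pixels (default 576).
#' @param regions data.frame with columns `r0`, `c0`, `r1`, `c1` (0-based,
#'   half-open) and `label` (class 0..5). Must cover the field of view.
#' @param fov Optional list `list(center = c(row, col), radius = r)`.
#' @param defects Optional data.frame `r0`, `c0`, `r1`, `c1`, `type` with
#'   type in `"blackout"`, `"overexposed"`.
#' @param seed Integer seed; mandatory (textures carry seeded noise).
#' @return An object of class `layout_spec`.
#' @export
layout_spec <- function(side = 576L,
                        regions = data.frame(r0 = 0, c0 = 0, r1 = side,
                                             c1 = side, label = 0L),
                        fov = NULL, defects = NULL, seed = 1L) {
  stopifnot(is.data.frame(regions), nrow(regions) >= 1,
            all(c("r0", "c0", "r1", "c1", "label") %in% names(regions)))
  if (anyNA(regions$label) || !all(regions$label %in% 0:5)) {
    stop("every layout region must carry a class label in 0..5",
         call. = FALSE)
  }
  if (!is.null(defects)) {
    stopifnot(all(defects$type %in% c("blackout", "overexposed")))
  }
  structure(list(side = as.integer(side), regions = regions, fov = fov,
                 defects = defects, seed = as.integer(seed)),
            class = "layout_spec")
}

#' Generate a synthetic still with ground truth
#'
#' Paints each layout region with its class texture (decodable by the
#' oracle classifier), blacks out everything outside the field-of-view
#' disc, and stamps defect regions with out-of-range intensities (grayscale
#' below 70 for blackout, above 230 for overexposure) so they trigger the
#' corresponding exclusion rule. Bit-deterministic for a fixed seed.
#'
#' @param layout A [layout_spec()].
#' @inheritParams still_picture
#' @return List with `still` (a `still_picture`) and `truth` (H x W integer
#'   matrix of per-pixel class labels; `NA` outside the field of view and
#'   in defect regions).
#' @export
generate_synthetic_still <- function(layout, study_id = "synthetic",
                                     camera = "f",
                                     segment = "cecum_ascending",
                                     index = 0L) {
  stopifnot(inherits(layout, "layout_spec"))
  side <- layout$side
  label_field <- matrix(NA_integer_, side, side)
  for (i in seq_len(nrow(layout$regions))) {
    rg <- layout$regions[i, ]
    rr <- max(rg$r0, 0):min(rg$r1 - 1, side - 1) + 1L
    cc <- max(rg$c0, 0):min(rg$c1 - 1, side - 1) + 1L
    label_field[rr, cc] <- as.integer(rg$label)
  }
  inside <- matrix(TRUE, side, side)
  if (!is.null(layout$fov)) {
    ctr <- layout$fov$center
    inside <- (row(inside) - 1 - ctr[1])^2 + (col(inside) - 1 - ctr[2])^2 <=
      layout$fov$radius^2
    label_field[!inside] <- NA_integer_
  }
  if (anyNA(label_field[inside])) {
    stop("layout regions do not cover the field of view", call. = FALSE)
  }
  withr::with_seed(layout$seed, {
    px <- paint_textures(label_field)
    if (!is.null(layout$defects)) {
      for (i in seq_len(nrow(layout$defects))) {
        df <- layout$defects[i, ]
        rr <- (df$r0 + 1):df$r1; cc <- (df$c0 + 1):df$c1
        v <- if (df$type == "blackout") {
          matrix(stats::runif(length(rr) * length(cc), 0, 30),
                 length(rr), length(cc))
        } else {
          matrix(stats::runif(length(rr) * length(cc), 240, 255),
                 length(rr), length(cc))
        }
        v <- round(v)
        for (ch in 1:3) px[rr, cc, ch] <- v  # gray defect: no class signature
        label_field[rr, cc] <- NA_integer_
      }
    }
    list(still = still_picture(px, study_id = study_id, camera = camera,
                               segment = segment, index = index),
         truth = label_field)
  })
}

#' Generate a labelled synthetic patch set
#'
#' `6 * n_per_class` pure-texture patches (one class each), shuffled with
#' the given seed and split into train/validation. The default split ratio
#' 5/6 yields the package's standard benchmark of 3,000 training and 600
#' validation patches at `n_per_class = 600`.
#'
#' @param n_per_class Patches per class (>= 1).
#' @param seed Integer seed.
#' @param patch_size Patch side (default 128).
#' @param train_frac Fraction assigned to the training split (default 5/6).
#' @return List with `train` and `validation`, each `list(x = <list of
#'   patches>, y = <integer labels>)`, plus `counts` (per-class totals).
#' @export
generate_labeled_patchset <- function(n_per_class, seed = 1L,
                                      patch_size = 128L, train_frac = 5 / 6) {
  stopifnot(n_per_class >= 1)
  n <- 6L * n_per_class
  withr::with_seed(seed, {
    y <- rep(0:5, each = n_per_class)
    x <- lapply(y, function(k) {
      paint_textures(matrix(k, patch_size, patch_size))
    })
    ord <- sample.int(n)
    x <- x[ord]; y <- y[ord]
    n_train <- max(1L, min(n - 1L, round(train_frac * n)))
    list(train = list(x = x[seq_len(n_train)], y = y[seq_len(n_train)]),
         validation = list(x = x[-seq_len(n_train)], y = y[-seq_len(n_train)]),
         counts = stats::setNames(rep(n_per_class, 6), CLASS_NAMES))
  })
}

#' Script the severity profile of a synthetic study
#'
#' Helper building the per-still profile script consumed by
#' [generate_study()]: `n_per_segment` stills per segment for both cameras
#' with the given target fractions.
#'
#' @param n_per_segment Stills per (camera, segment).
#' @param fracs Length-4 target fractions (MES0..MES3) summing to 1, or the
#'   string `"excluded"`; recycled over stills. May also be a function
#'   `(camera, segment, index) -> fractions or "excluded"`.
#' @return data.frame `camera`, `segment`, `index`, `frac0`..`frac3`,
#'   `excluded`.
#' @export
make_profile_script <- function(n_per_segment = 5L,
                                fracs = c(1, 0, 0, 0)) {
  rows <- expand.grid(index = seq_len(n_per_segment) - 1L,
                      segment = SEGMENT_LEVELS, camera = CAMERA_LEVELS,
                      stringsAsFactors = FALSE)
  get_frac <- function(camera, segment, index) {
    if (is.function(fracs)) fracs(camera, segment, index) else fracs
  }
  out <- lapply(seq_len(nrow(rows)), function(i) {
    f <- get_frac(rows$camera[i], rows$segment[i], rows$index[i])
    if (identical(f, "excluded")) {
      data.frame(camera = rows$camera[i], segment = rows$segment[i],
                 index = rows$index[i], frac0 = NA, frac1 = NA, frac2 = NA,
                 frac3 = NA, excluded = TRUE)
    } else {
      data.frame(camera = rows$camera[i], segment = rows$segment[i],
                 index = rows$index[i], frac0 = f[1], frac1 = f[2],
                 frac2 = f[3], frac3 = f[4], excluded = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Generate a full synthetic capsule study
#'
#' Emits a dual-camera, four-segment series of synthetic stills whose
#' oracle-classified pipeline output reproduces the scripted per-still
#' severity fractions within the patch-quantisation tolerance (about 0.05
#' for 32-pixel strides; see the methods vignette). Each scripted still is
#' painted as vertical class strips with widths proportional to the target
#' fractions; stills scripted as `excluded` are painted entirely with the
#' inadequate-quality texture, so every patch classifies to class 4 and the
#' still's total severity area is zero.
#'
#' @param script data.frame as produced by [make_profile_script()]: one row
#'   per still with `camera`, `segment`, `index`, `frac0`..`frac3`,
#'   `excluded`.
#' @param seed Integer seed.
#' @param side Still side in pixels (default 576).
#' @param study_id Study identifier.
#' @return List with `stills` (list of `still_picture`), `script` (the
#'   input, with an added `still_id` column) and `seed`.
#' @export
generate_study <- function(script, seed = 1L, side = 576L,
                           study_id = "synthetic-study") {
  stopifnot(is.data.frame(script), nrow(script) > 0)
  fr <- as.matrix(script[paste0("frac", 0:3)])
  ok <- script$excluded | abs(rowSums(fr) - 1) < 1e-9
  if (!all(ok, na.rm = TRUE) || anyNA(ok)) {
    stop("scripted fractions must sum to 1 over MES0..MES3, or the still ",
         "must be marked excluded", call. = FALSE)
  }
  stills <- vector("list", nrow(script))
  for (i in seq_len(nrow(script))) {
    row <- script[i, ]
    if (row$excluded) {
      regions <- data.frame(r0 = 0, c0 = 0, r1 = side, c1 = side, label = 4L)
    } else {
      f <- as.numeric(row[paste0("frac", 0:3)])
      bounds <- round(cumsum(c(0, f)) * side)
      keep <- which(diff(bounds) > 0)
      regions <- data.frame(r0 = 0, c0 = bounds[keep], r1 = side,
                            c1 = bounds[keep + 1L], label = keep - 1L)
    }
    lay <- layout_spec(side = side, regions = regions,
                       seed = (seed + i) %% .Machine$integer.max)
    stills[[i]] <- generate_synthetic_still(
      lay, study_id = study_id, camera = row$camera, segment = row$segment,
      index = row$index)$still
  }
  script$still_id <- vapply(stills, still_id, character(1))
  list(stills = stills, script = script, seed = seed)
}

#' Run the severity pipeline over a study's stills
#'
#' Profiles every still with [profile_still()] and assembles the
#' topographic map — the end-to-end path from images to map.
#'
#' @param stills List of `still_picture`.
#' @param model A `ccemap_model` (default: the oracle classifier).
#' @param mask `"estimate"`, `NULL`, or a fixed mask passed to every still.
#' @param rule An [exclusion_rule()].
#' @param study_id Map identifier (default from the first still).
#' @return A `topographic_map`.
#' @export
map_study <- function(stills, model = make_oracle_classifier(),
                      mask = NULL, rule = exclusion_rule(),
                      study_id = NULL) {
  stopifnot(length(stills) > 0)
  profiles <- do.call(rbind, lapply(stills, profile_still, model = model,
                                    mask = mask, rule = rule))
  if (is.null(study_id)) study_id <- stills[[1]]$study_id
  build_topographic_map(profiles, study_id = study_id)
}
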