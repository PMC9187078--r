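# Shared fixtures and independent oracles for the test suite. The oracles
# here deliberately use a different algorithm from the package code they
# check (naive enumeration / boolean-canvas rasterization).

# Independent tiling oracle: enumerate every offset pair by brute force.
brute_tile <- function(height, width, patch_size, stride) {
  out <- list()
  r <- 0L
  while (r + patch_size <= height) {
    c <- 0L
    while (c + patch_size <= width) {
      out[[length(out) + 1L]] <- c(r, c)
      c <- c + stride
    }
    r <- r + stride
  }
  if (length(out) == 0L) {
    return(data.frame(row = integer(0), col = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(row = m[, 1], col = m[, 2])
}

# Independent union-area oracle: rasterize windows on a boolean canvas.
canvas_area <- function(specs, height, width) {
  canvas <- matrix(FALSE, height, width)
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    canvas[sp$row + seq_len(sp$size), sp$col + seq_len(sp$size)] <- TRUE
  }
  sum(canvas)
}

# Constant-valued RGB patch.
const_patch <- function(value, size = 128L) {
  array(value, c(size, size, 3L))
}

# Mid-gray still of the standard size.
gray_still <- function(value = 128, side = 576L) {
  still_picture(array(value, c(side, side, 3L)))
}

# A patch painted with the synthetic texture of class k (decodable by the
# oracle classifier).
texture_patch <- function(k, size = 128L, seed = 1L) {
  withr::with_seed(seed, ccemap:::paint_textures(matrix(k, size, size)))
}

# Random classified grid for property tests: small canvas, random windows.
random_grid <- function(seed, max_side = 60L) {
  withr::with_seed(seed, {
    h <- sample(20:max_side, 1)
    w <- sample(20:max_side, 1)
    n <- sample(1:8, 1)
    size <- sample(4:12, 1)
    specs <- data.frame(
      row = sample(0:(h - size), n, replace = TRUE),
      col = sample(0:(w - size), n, replace = TRUE),
      size = size
    )
    labels <- sample(0:5, n, replace = TRUE)
    list(grid = classified_grid(specs, labels, h, w), h = h, w = w,
         specs = specs, labels = labels)
  })
}
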