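# Sliding-window tiling and the intensity exclusion rules.

test_that("tile_grid matches the closed-form counts and enumeration order", {
  g <- tile_grid(576, 576)
  expect_identical(nrow(g), 225L)  # 15 offsets per axis
  expect_identical(sort(unique(g$row)), as.integer(seq(0, 448, 32)))
  # left-to-right then top-to-bottom: col varies fastest
  expect_identical(g$row[1:16], c(rep(0L, 15), 32L))
  expect_identical(g$col[1:3], c(0L, 32L, 64L))

  g1 <- tile_grid(128, 128)
  expect_identical(nrow(g1), 1L)
  expect_identical(c(g1$row, g1$col), c(0L, 0L))

  expect_identical(nrow(tile_grid(127, 576)), 0L)
})

test_that("tile_grid equals brute-force enumeration on random geometries", {
  withr::with_seed(99, {
    for (i in 1:100) {
      h <- sample(1:80, 1); w <- sample(1:80, 1)
      size <- sample(1:20, 1); stride <- sample(1:10, 1)
      got <- tile_grid(h, w, size, stride)
      want <- brute_tile(h, w, size, stride)
      expect_identical(got[c("row", "col")],
                       want, info = sprintf("h=%d w=%d size=%d stride=%d",
                                            h, w, size, stride))
    }
  })
})

test_that("patch intensity counts are exact and channel is Rec.601 luma", {
  spec <- list(row = 0L, col = 0L, size = 128L)
  expect_identical(patch_gray_stats(const_patch(0), spec),
                   c(n_low = 16384L, n_high = 0L))
  expect_identical(patch_gray_stats(const_patch(255), spec),
                   c(n_low = 0L, n_high = 16384L))

  p <- const_patch(128)
  p[, , 1][seq_len(164)] <- 0; p[, , 2][seq_len(164)] <- 0
  p[, , 3][seq_len(164)] <- 0
  expect_identical(patch_gray_stats(p, spec),
                   c(n_low = 164L, n_high = 0L))

  # luma weighting: pure blue 200 has luma round(0.114*200) = 23 < 70
  blue <- const_patch(0); blue[, , 3] <- 200
  expect_identical(patch_gray_stats(blue, spec)[["n_low"]], 16384L)
  # but on the blue channel itself nothing is below 70
  rule_b <- exclusion_rule(channel = "b")
  expect_identical(patch_gray_stats(blue, spec, rule_b)[["n_low"]], 0L)

  expect_error(patch_gray_stats(const_patch(10, 64), spec), "out of bounds")
})

test_that("exclusion thresholds are strict at the printed boundaries", {
  spec <- list(row = 0L, col = 0L, size = 128L)
  dark_patch <- function(n) {
    p <- const_patch(128)
    for (ch in 1:3) p[, , ch][seq_len(n)] <- 0
    p
  }
  bright_patch <- function(n) {
    p <- const_patch(128)
    for (ch in 1:3) p[, , ch][seq_len(n)] <- 255
    p
  }
  # 163/16384 = 0.995% <= 1% keeps; 164/16384 = 1.001% > 1% excludes
  expect_false(is_excluded(dark_patch(163), spec)$excluded)
  e <- is_excluded(dark_patch(164), spec)
  expect_true(e$excluded); expect_identical(e$reason, "blackout")
  # 819/16384 = 4.999% <= 5% keeps; 820/16384 = 5.005% > 5% excludes
  expect_false(is_excluded(bright_patch(819), spec)$excluded)
  e <- is_excluded(bright_patch(820), spec)
  expect_true(e$excluded); expect_identical(e$reason, "overexposed")
  # exactly-at-cut intensities do not count (< 70, > 230 are strict)
  at_cut <- const_patch(70)
  expect_identical(patch_gray_stats(at_cut, spec)[["n_low"]], 0L)
  at_hi <- const_patch(230)
  expect_identical(patch_gray_stats(at_hi, spec)[["n_high"]], 0L)
})

test_that("blackout takes precedence when both rules fire", {
  p <- const_patch(128)
  for (ch in 1:3) {
    p[, , ch][seq_len(200)] <- 0
    p[, , ch][200 + seq_len(900)] <- 255
  }
  e <- is_excluded(p, list(row = 0L, col = 0L, size = 128L))
  expect_identical(e$reason, "blackout")
})

test_that("exclusion depends only on the pixel multiset, not arrangement", {
  withr::with_seed(4, {
    p <- const_patch(128)
    vals <- sample(0:255, 16384, replace = TRUE)
    for (ch in 1:3) p[, , ch] <- matrix(vals, 128, 128)
    perm <- sample.int(16384)
    q <- p
    for (ch in 1:3) q[, , ch] <- matrix(as.vector(p[, , ch])[perm], 128, 128)
    spec <- list(row = 0L, col = 0L, size = 128L)
    expect_identical(is_excluded(p, spec), is_excluded(q, spec))
  })
})

test_that("extract_patches honours the mask and the exclusion rules", {
  s <- gray_still(128)
  expect_identical(nrow(extract_patches(s)), 225L)      # nothing fires
  expect_identical(nrow(extract_patches(gray_still(0))), 0L)  # all blackout

  mask <- matrix(FALSE, 576, 576)
  mask[1:160, 1:160] <- TRUE
  got <- extract_patches(s, mask)
  expect_identical(nrow(got), 4L)
  expect_identical(got$row, c(0L, 0L, 32L, 32L))
  expect_identical(got$col, c(0L, 32L, 0L, 32L))

  expect_error(extract_patches(s, matrix(TRUE, 10, 10)),
               "mask dimensions")
})

test_that("extracted patches are always a subset of the tile grid", {
  lay <- layout_spec(regions = data.frame(r0 = 0, c0 = 0, r1 = 576, c1 = 576,
                                          label = 2L),
                     fov = list(center = c(288, 288), radius = 260),
                     defects = data.frame(r0 = 100, c0 = 300, r1 = 300,
                                          c1 = 500, type = "overexposed"),
                     seed = 12)
  s <- generate_synthetic_still(lay)$still
  got <- extract_patches(s, estimate_fov_mask(s))
  grid_keys <- with(tile_grid(576, 576), paste(row, col))
  expect_true(all(with(got, paste(row, col)) %in% grid_keys))
})

test_that("relaxing thresholds or growing the mask never loses patches", {
  lay <- layout_spec(regions = data.frame(r0 = 0, c0 = 0, r1 = 576, c1 = 576,
                                          label = 1L),
                     defects = data.frame(r0 = c(0, 400), c0 = c(0, 200),
                                          r1 = c(180, 520), c1 = c(180, 360),
                                          type = c("blackout", "overexposed")),
                     seed = 21)
  s <- generate_synthetic_still(lay)$still
  base <- nrow(extract_patches(s))
  relaxed <- nrow(extract_patches(s, rule = exclusion_rule(low_frac = 0.5,
                                                           high_frac = 0.5)))
  expect_gte(relaxed, base)

  big_mask <- matrix(TRUE, 576, 576)
  small_mask <- big_mask; small_mask[, 300:576] <- FALSE
  expect_lte(nrow(extract_patches(s, small_mask)),
             nrow(extract_patches(s, big_mask)))
})
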