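# The synthetic-still generator and its self-consistency with the
# exclusion rules and the oracle classifier.

test_that("synthetic stills are bit-deterministic under a fixed seed", {
  lay <- layout_spec(regions = data.frame(r0 = 0, c0 = 0, r1 = 576, c1 = 576,
                                          label = 1L),
                     fov = list(center = c(288, 288), radius = 270),
                     defects = data.frame(r0 = 50, c0 = 250, r1 = 250,
                                          c1 = 450, type = "blackout"),
                     seed = 17)
  a <- generate_synthetic_still(lay)
  b <- generate_synthetic_still(lay)
  expect_identical(a$still$pixels, b$still$pixels)
  expect_identical(a$truth, b$truth)
  # a different seed produces different noise
  lay2 <- lay; lay2$seed <- 18L
  expect_false(identical(generate_synthetic_still(lay2)$still$pixels,
                         a$still$pixels))
})

test_that("layouts must cover the field of view and carry classes", {
  expect_error(layout_spec(regions = data.frame(r0 = 0, c0 = 0, r1 = 10,
                                                c1 = 10, label = NA)),
               "class label")
  partial <- layout_spec(regions = data.frame(r0 = 0, c0 = 0, r1 = 100,
                                              c1 = 576, label = 0L))
  expect_error(generate_synthetic_still(partial), "do not cover")
})

test_that("generated defect regions trigger the matching exclusion rule", {
  lay <- layout_spec(regions = data.frame(r0 = 0, c0 = 0, r1 = 576, c1 = 576,
                                          label = 0L),
                     defects = data.frame(r0 = c(100, 350), c0 = c(100, 350),
                                          r1 = c(300, 550), c1 = c(300, 550),
                                          type = c("blackout", "overexposed")),
                     seed = 23)
  s <- generate_synthetic_still(lay)$still
  grid <- tile_grid(576, 576)
  inside <- function(sp, r0, c0, r1, c1) {
    sp$row >= r0 && sp$col >= c0 && sp$row + sp$size <= r1 &&
      sp$col + sp$size <= c1
  }
  n_black <- 0; n_bright <- 0
  for (i in seq_len(nrow(grid))) {
    sp <- grid[i, ]
    if (inside(sp, 100, 100, 300, 300)) {
      e <- is_excluded(s, sp)
      expect_true(e$excluded); expect_identical(e$reason, "blackout")
      n_black <- n_black + 1
    } else if (inside(sp, 350, 350, 550, 550)) {
      e <- is_excluded(s, sp)
      expect_true(e$excluded); expect_identical(e$reason, "overexposed")
      n_bright <- n_bright + 1
    }
  }
  # stride-32 offsets fully inside [100,300) are {128,160}; inside
  # [350,550) they are {352,384,416}
  expect_identical(c(n_black, n_bright), c(4, 9))
  # clean texture regions never trip the rules
  clean <- list(row = 416L, col = 0L, size = 128L)
  expect_false(is_excluded(s, clean)$excluded)
})

test_that("labelled patch sets have exact counts, split and determinism", {
  ps <- generate_labeled_patchset(100, seed = 1)
  n <- length(ps$train$y) + length(ps$validation$y)
  expect_identical(n, 600L)
  all_y <- c(ps$train$y, ps$validation$y)
  expect_identical(as.integer(table(factor(all_y, 0:5))), rep(100L, 6))
  expect_identical(length(ps$train$y), 500L)  # 5/6 split

  ps2 <- generate_labeled_patchset(100, seed = 1)
  expect_identical(ps, ps2)
  expect_false(identical(ps, generate_labeled_patchset(100, seed = 2)))

  tiny <- generate_labeled_patchset(1, seed = 3)
  expect_identical(length(tiny$train$y) + length(tiny$validation$y), 6L)
})

test_that("profile scripts validate their fractions", {
  bad <- make_profile_script(1, c(0.5, 0.5, 0.5, 0))
  expect_error(generate_study(bad), "sum to 1")
  ok <- make_profile_script(1, c(0.5, 0.25, 0.25, 0))
  expect_silent(study <- generate_study(ok, seed = 1, side = 192))
  expect_length(study$stills, 8)  # 4 segments x 2 cameras x 1 still
})

test_that("an all-MES0 scripted study maps to pure MES0 fractions", {
  script <- make_profile_script(2, c(1, 0, 0, 0))
  study <- generate_study(script, seed = 6)
  map <- map_study(study$stills)
  expect_identical(nrow(map), 16L)
  expect_true(all(!map$excluded))
  expect_true(all(map$frac0 == 1))
  expect_true(all(map$frac1 == 0 & map$frac2 == 0 & map$frac3 == 0))
})
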