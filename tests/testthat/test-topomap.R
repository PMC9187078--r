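# Map assembly, rendering and the percent-severity table.

# Minimal profile rows for map tests, bypassing image processing.
fake_profile <- function(camera, segment, index, fracs = c(1, 0, 0, 0),
                         excluded = FALSE) {
  areas <- if (excluded) rep(0, 4) else fracs * 16384
  out <- data.frame(still_id = paste("st", camera, segment, index, sep = ":"),
                    camera = camera, segment = segment, index = index)
  out[paste0("area", 0:3)] <- as.list(areas)
  out$total <- sum(areas)
  out[paste0("frac", 0:3)] <- as.list(if (excluded) rep(NA_real_, 4) else fracs)
  out$excluded <- excluded
  out
}

demo_profiles <- function(n_per_segment = 3) {
  rows <- expand.grid(index = seq_len(n_per_segment) - 1L,
                      segment = segment_levels(), camera = camera_levels(),
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    fake_profile(rows$camera[i], rows$segment[i], rows$index[i],
                 fracs = c(0.5, 0.25, 0.25, 0))
  }))
}

test_that("map assembly orders tracks anatomically and is input-order free", {
  profiles <- demo_profiles(50)  # 4 segments x 50 per camera
  map <- build_topographic_map(profiles)
  f_track <- map[map$camera == "f", ]
  expect_identical(nrow(f_track), 200L)
  expect_identical(unique(as.character(f_track$segment)), segment_levels())
  expect_identical(f_track$position, 1:200)
  by_seg <- split(f_track$index, factor(f_track$segment, segment_levels()))
  expect_true(all(vapply(by_seg, function(i) all(diff(i) > 0), logical(1))))

  shuffled <- withr::with_seed(5, profiles[sample.int(nrow(profiles)), ])
  expect_equal(as.data.frame(build_topographic_map(shuffled)),
               as.data.frame(map))
})

test_that("duplicate still positions are rejected by name", {
  profiles <- rbind(fake_profile("f", "rectum", 7),
                    fake_profile("f", "rectum", 7))
  expect_error(build_topographic_map(profiles), "f rectum 7")
  expect_error(build_topographic_map(demo_profiles()[0, ]), "nrow")
})

test_that("excluded stills are kept in place as blanks", {
  profiles <- rbind(fake_profile("f", "rectum", 0),
                    fake_profile("f", "rectum", 1, excluded = TRUE),
                    fake_profile("f", "rectum", 2))
  map <- build_topographic_map(profiles)
  expect_identical(map$position, 1:3)
  expect_true(map$excluded[2])
})

test_that("rendered maps have one column per still and segment boundaries", {
  map <- build_topographic_map(demo_profiles(3))
  p <- render_map(map)
  built <- ggplot2::ggplot_build(p)
  bars <- built$data[[1]]
  # one stacked column (4 classes) per still per camera panel
  expect_identical(nrow(bars), 4L * nrow(map))
  expect_identical(sort(unique(bars$x)), as.numeric(1:12))
  vlines <- built$data[[2]]
  expect_identical(sort(unique(vlines$xintercept)), c(3.5, 6.5, 9.5))

  path <- withr::local_tempfile(fileext = ".png")
  render_map(map, path)
  expect_true(file.exists(path) && file.size(path) > 0)
})

test_that("camera tracks render independently", {
  profiles <- demo_profiles(2)
  both <- ggplot2::ggplot_build(render_map(build_topographic_map(profiles)))
  f_only <- ggplot2::ggplot_build(
    render_map(build_topographic_map(profiles[profiles$camera == "f", ])))
  pick_f <- function(b) {
    d <- b$data[[1]]
    d <- d[d$PANEL == levels(d$PANEL)[1], c("x", "ymin", "ymax", "fill")]
    d[order(d$x, d$ymin, d$fill), ]
  }
  expect_equal(pick_f(both), pick_f(f_only), ignore_attr = TRUE)
})

test_that("export rounds half-up to one decimal and flags excluded rows", {
  profiles <- rbind(fake_profile("f", "rectum", 0, c(1, 0, 0, 0)),
                    fake_profile("f", "rectum", 1, c(1, 1, 1, 0) / 3),
                    fake_profile("f", "rectum", 2, excluded = TRUE))
  map <- build_topographic_map(profiles)
  tab <- export_table(map)
  expect_equal(unlist(tab[1, paste0("pct", 0:3)], use.names = FALSE),
               c(100, 0, 0, 0))
  expect_equal(unlist(tab[2, paste0("pct", 0:3)], use.names = FALSE),
               c(33.3, 33.3, 33.3, 0))
  expect_true(tab$excluded[3])
  expect_true(all(is.na(tab[3, paste0("pct", 0:3)])))
})

test_that("the exported table round-trips at 1-decimal precision", {
  map <- build_topographic_map(rbind(
    fake_profile("f", "transverse", 0, c(0.123, 0.456, 0.321, 0.1)),
    fake_profile("b", "rectum", 0, c(0.5, 0, 0, 0.5)),
    fake_profile("b", "rectum", 1, excluded = TRUE)))
  path <- withr::local_tempfile(fileext = ".csv")
  export_table(map, path)
  back <- import_table(path)
  expect_identical(nrow(back), 3L)
  for (k in 0:3) {
    want <- ifelse(map$excluded, NA_real_,
                   floor(map[[paste0("frac", k)]] * 1000 + 0.5) / 10)
    expect_equal(back[[paste0("pct", k)]], want)
  }
  expect_identical(back$excluded, map$excluded)
})

test_that("map JSON serialisation keeps all profiles", {
  map <- build_topographic_map(demo_profiles(2))
  path <- withr::local_tempfile(fileext = ".json")
  write_map_json(map, path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(nrow(payload$profiles), nrow(map))
  expect_identical(payload$study_id, "study")
})
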