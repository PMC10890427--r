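test_that("stack read round-trips generator output pixel-identically", {
  gs <- generate_stack(synth_spec(n_slices = 3, height = 64, width = 64,
                                  seed = 11))
  dir <- withr::local_tempdir()
  write_stack(gs$stack, dir)
  back <- read_stack(dir, stack_meta(um_per_px = 1.4))
  expect_equal(back$meta$n_slices, 3L)
  expect_identical(dim(back$slices[[1]]), c(64L, 64L))
  for (z in 1:3) {
    expect_equal(back$slices[[z]], gs$stack$slices[[z]])
  }
  # 16-bit intensities survive without rescaling
  st16 <- gs$stack
  st16$slices <- lapply(st16$slices, function(m) m * 257)
  dir16 <- withr::local_tempdir()
  write_stack(st16, dir16, bits = 16L) # 16-bit series goes out as TIFF
  back16 <- read_stack(dir16, stack_meta(um_per_px = 1.4))
  expect_equal(back16$slices[[1]], st16$slices[[1]])
})

test_that("slice order is natural-numeric regardless of zero padding", {
  expect_equal(natural_sort(c("img10.png", "img2.png", "img1.png")),
               c("img1.png", "img2.png", "img10.png"))
  expect_equal(natural_sort(c("s003.png", "s10.png", "s2.png")),
               c("s2.png", "s003.png", "s10.png"))
  dir <- withr::local_tempdir()
  # lexicographic order would put slice10 before slice2
  png::writePNG(matrix(40 / 255, 8, 8), file.path(dir, "slice2.png"))
  png::writePNG(matrix(90 / 255, 8, 8), file.path(dir, "slice9.png"))
  png::writePNG(matrix(10 / 255, 8, 8), file.path(dir, "slice10.png"))
  st <- read_stack(dir, stack_meta(um_per_px = 1))
  expect_equal(vapply(st$slices, function(m) m[1, 1], 0), c(40, 90, 10))
})

test_that("reading an empty or inconsistent directory errors usefully", {
  dir <- withr::local_tempdir()
  expect_error(read_stack(dir, stack_meta(um_per_px = 1)), "no images found")
  png::writePNG(matrix(0, 64, 64), file.path(dir, "a01.png"))
  png::writePNG(matrix(0, 32, 32), file.path(dir, "a02.png"))
  expect_error(read_stack(dir, stack_meta(um_per_px = 1)), "a02\\.png")
})

test_that("mask stacks write as {0,255} images and round-trip binarized", {
  m1 <- matrix(FALSE, 16, 16); m1[4:8, 4:8] <- TRUE
  m2 <- matrix(FALSE, 16, 16)
  dir <- withr::local_tempdir()
  manifest <- write_mask_stack(list(m1, m2), dir)
  expect_equal(manifest$file, c("0001.png", "0002.png"))
  raw <- png::readPNG(file.path(dir, "0001.png")) * 255
  expect_true(all(raw %in% c(0, 255)))
  expect_true(all(png::readPNG(file.path(dir, "0002.png")) == 0))
  back <- read_stack(dir, stack_meta(um_per_px = 1))
  expect_equal(back$slices[[1]] > 0, m1)
  expect_equal(back$slices[[2]] > 0, m2)
})

test_that("metrics tables round-trip and carry the micron conversion", {
  meta <- stack_meta(um_per_px = 2)
  rec <- region_metrics(cbind(3, 3:7), meta, slice_index = 1L, label = 1L,
                        type = "microfracture")
  expect_equal(rec$area_um2, rec$area_px2 * 4) # 25 px^2 -> 100 um^2 at 2 um/px
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(rec, path)
  back <- read_metrics_table(path)
  for (col in names(rec)) {
    if (is.numeric(rec[[col]])) {
      expect_equal(back[[col]], rec[[col]], tolerance = 1e-6)
    } else {
      expect_equal(back[[col]], rec[[col]])
    }
  }
  # empty table gives a header-only CSV
  write_metrics_table(empty <- rec[0, ], path)
  expect_equal(nrow(read_metrics_table(path)), 0L)
  expect_equal(names(read_metrics_table(path)), names(rec))
})

test_that("metadata sidecar round-trips", {
  gs <- generate_stack(synth_spec(n_slices = 1, height = 48, width = 48))
  dir <- withr::local_tempdir()
  write_stack(gs$stack, dir)
  meta <- read_meta_sidecar(dir)
  expect_equal(meta$um_per_px, 1.4)
  expect_equal(meta$material, "synthetic")
})
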