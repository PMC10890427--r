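test_that("Canny gradients match a 1-D convolution oracle on a step edge", {
  img <- matrix(0, 32, 32); img[, 17:32] <- 200
  cfg <- detect_config()
  e <- canny_edges(img, cfg)
  cols <- unique(which(e, arr.ind = TRUE)[, 2])
  expect_true(length(cols) > 0)
  expect_true(all(cols %in% 16:18))

  expect_false(any(canny_edges(matrix(7, 16, 16)))) # zero gradient

  # gradient magnitude at the step equals the 1-D convolution of the row
  # profile with the same sampled Gaussian-derivative kernel
  g <- microfract:::gaussian_kernel(cfg$canny_sigma)
  d <- microfract:::gaussian_deriv_kernel(cfg$canny_sigma)
  profile <- img[16, ]
  h <- (length(d) - 1) / 2
  padded <- c(rep(profile[1], h), profile, rep(profile[32], h))
  oracle <- vapply(seq_along(profile), function(j) {
    sum(d * padded[j:(j + 2 * h)])
  }, 0)
  gx <- microfract:::conv_separable(img, g, d)
  expect_lt(max(abs(gx[16, ] - oracle)), 1e-6)
})

test_that("edge-described regions are interior contours inside the specimen", {
  specimen <- matrix(TRUE, 20, 20)
  edges <- matrix(FALSE, 20, 20)
  edges[8:13, 8] <- TRUE; edges[8:13, 13] <- TRUE
  edges[8, 8:13] <- TRUE; edges[13, 8:13] <- TRUE
  r <- regions_from_edges(edges, specimen)
  expect_equal(r$n_regions, 1L)
  expect_equal(sum(r$label_image == 1L), 16L) # 4x4 interior of a 6x6 contour

  # the exterior specimen contour alone yields no feature
  spec2 <- matrix(FALSE, 20, 20); spec2[3:18, 3:18] <- TRUE
  boundary <- matrix(FALSE, 20, 20)
  boundary[3:18, 3] <- TRUE; boundary[3:18, 18] <- TRUE
  boundary[3, 3:18] <- TRUE; boundary[18, 3:18] <- TRUE
  expect_equal(regions_from_edges(boundary, spec2)$n_regions, 0L)

  # k planted closed contours give k regions
  edges3 <- matrix(FALSE, 40, 40)
  put_square <- function(m, r0, c0, s) {
    m[r0:(r0 + s), c0] <- TRUE; m[r0:(r0 + s), c0 + s] <- TRUE
    m[r0, c0:(c0 + s)] <- TRUE; m[r0 + s, c0:(c0 + s)] <- TRUE
    m
  }
  edges3 <- put_square(edges3, 5, 5, 5)
  edges3 <- put_square(edges3, 20, 8, 6)
  edges3 <- put_square(edges3, 10, 25, 7)
  expect_equal(regions_from_edges(edges3, matrix(TRUE, 40, 40))$n_regions, 3L)
})

test_that("region typing applies the size, circularity and eccentricity rules", {
  cfg <- detect_config()
  meta <- stack_meta(um_per_px = 1.4)
  short <- region_metrics(cbind(3, 2:5), meta)  # char length 4
  expect_equal(classify_region(short, cfg), "artifact")

  five <- region_metrics(cbind(3, 2:6), meta)   # char length exactly 5
  expect_gte(five$eccentricity, 0.95)
  expect_equal(classify_region(five, cfg), "microfracture") # boundary inclusive

  disk <- expand.grid(row = 1:21, col = 1:21)
  disk <- as.matrix(disk[(disk$row - 11)^2 + (disk$col - 11)^2 <= 100, ])
  round_blob <- region_metrics(disk, meta)
  expect_equal(classify_region(round_blob, cfg), "pore")
})

test_that("per-slice detection separates planted cracks from pores", {
  blank <- matrix(10, 64, 64)
  meta <- stack_meta(um_per_px = 1.4)
  suppressWarnings(d0 <- detect_microfractures(blank, meta = meta))
  expect_false(any(d0$fracture_mask))
  expect_equal(nrow(d0$records), 0L)

  # one planted 15-px crack and one 10-px-diameter pore
  spec <- synth_spec(height = 96, width = 96, noise_sigma = 0,
                     two_phase = FALSE)
  specimen <- microfract:::specimen_mask_for(spec)
  img <- matrix(spec$background, 96, 96)
  img[specimen] <- spec$matrix_level
  img[40, 30:44] <- spec$void_level                       # 15-px crack
  pore <- microfract:::disk_pixels(60, 60, 5, 96, 96)     # 10-px pore
  img[pore] <- spec$void_level
  d <- detect_microfractures(img, meta = meta)
  expect_equal(sort(unique(d$records$type)), c("microfracture", "pore"))
  expect_equal(sum(d$records$type == "microfracture"), 1L)
  crack_rec <- d$records[d$records$type == "microfracture", ]
  expect_equal(crack_rec$char_length_px, 15)
  # the mask contains the crack only
  expect_true(all(d$fracture_mask[40, 30:44]))
  expect_false(any(d$fracture_mask[pore]))
})

test_that("detection is deterministic and monotone in the extension cutoff", {
  gs <- generate_stack(synth_spec(n_slices = 1, seed = 21))
  img <- gs$stack$slices[[1]]
  meta <- gs$stack$meta
  a <- detect_microfractures(img, meta = meta)
  b <- detect_microfractures(img, meta = meta)
  expect_identical(a$records, b$records)
  expect_identical(a$fracture_mask, b$fracture_mask)

  # fracture mask is inside the void foreground
  seg <- segment_voids(img)
  expect_true(all(seg$voids[a$fracture_mask]))

  counts <- vapply(c(3L, 5L, 8L, 12L), function(minext) {
    d <- detect_microfractures(img,
                               det_cfg = detect_config(min_extension_px = minext),
                               meta = meta)
    sum(d$records$type == "microfracture")
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})
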