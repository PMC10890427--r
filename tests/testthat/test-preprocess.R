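test_that("binarization handles flat, bimodal and synthetic slices", {
  expect_warning(m <- binarize(matrix(0, 8, 8)), "constant")
  expect_false(any(m))

  two <- cbind(matrix(10, 16, 8), matrix(200, 16, 8))
  split <- binarize(two, preprocess_config())
  expect_equal(split, two > 100, ignore_attr = TRUE)

  # foreground count tracks planted feature area on a synthetic slice
  gs <- generate_stack(synth_spec(n_slices = 1, seed = 4))
  img <- gs$stack$slices[[1]]
  seg <- segment_voids(img)
  planted <- sum(vapply(gs$truth$features[[1]],
                        function(f) nrow(f$pixels), 0))
  expect_lt(abs(sum(seg$voids) - planted) / planted, 0.05)
})

test_that("small-region removal follows the '< min_px' rule and is monotone", {
  m <- matrix(FALSE, 8, 8); m[4, 4] <- TRUE
  expect_false(any(remove_small_regions(m, 2)))

  exactly <- matrix(FALSE, 8, 8); exactly[3, 3:5] <- TRUE # 3 px component
  expect_equal(remove_small_regions(exactly, 3), exactly)  # kept at boundary
  expect_false(any(remove_small_regions(exactly, 4)))

  rm5 <- remove_small_regions(random_mask(seed = 7), 5)
  expect_equal(remove_small_regions(rm5, 5), rm5) # idempotent

  # surviving components match a brute-force labeling oracle, and raising
  # min_px never increases the count
  for (seed in 1:3) {
    mask <- random_mask(p = 0.25, seed = seed)
    prev <- Inf
    for (min_px in c(2, 5, 9)) {
      out <- remove_small_regions(mask, min_px)
      lbl <- bf_label_2d(mask)
      sizes <- table(lbl[lbl > 0])
      keep <- as.integer(names(sizes))[sizes >= min_px]
      expect_equal(out, matrix(lbl %in% keep, 64, 64))
      n_out <- max(label_components(out))
      expect_lte(n_out, prev)
      prev <- n_out
    }
  }
})

test_that("gap filling fills exactly the enclosed background", {
  ring <- matrix(FALSE, 7, 7)
  ring[2:6, 2] <- TRUE; ring[2:6, 6] <- TRUE
  ring[2, 2:6] <- TRUE; ring[6, 2:6] <- TRUE
  solid <- matrix(FALSE, 7, 7); solid[2:6, 2:6] <- TRUE
  expect_equal(fill_gaps(ring), solid)

  open_shape <- matrix(FALSE, 7, 7); open_shape[3, 2:6] <- TRUE
  expect_equal(fill_gaps(open_shape), open_shape) # nothing enclosed

  for (seed in 1:4) {
    mask <- random_mask(n = 32, p = 0.3, seed = seed)
    out <- fill_gaps(mask)
    expect_true(all(out[mask]))                    # extensive
    expect_equal(bf_enclosed_background(out), 0)   # flood-fill oracle
    expect_equal(fill_gaps(out), out)              # idempotent
  }
})

test_that("the preprocessing chain is the stated composition", {
  expect_false(any(preprocess_slice(matrix(0, 16, 16) + 1,
                                    preprocess_config(threshold_method = "fixed",
                                                      fixed_threshold = 5))))

  img <- matrix(10, 32, 32)
  img[5:14, 5:14] <- 200 # solid 10x10 square
  img[25, 25] <- 200     # isolated pixel
  cfg <- preprocess_config()
  out <- preprocess_slice(img, cfg)
  expect_equal(sum(out), 100)
  expect_true(all(out[5:14, 5:14]))

  # equals manual chaining on an arbitrary fixture
  gs <- generate_stack(synth_spec(n_slices = 1, height = 96, width = 96,
                                  seed = 9))
  fix <- gs$stack$slices[[1]]
  manual <- remove_small_regions(
    fill_gaps(remove_small_regions(binarize(fix, cfg), cfg$min_region_px)),
    cfg$min_region_px)
  expect_equal(preprocess_slice(fix, cfg), manual)

  # output never contains a small component or enclosed background
  expect_equal(bf_enclosed_background(manual), 0)
  lbl <- label_components(manual)
  if (max(lbl) > 0) expect_gte(min(table(lbl[lbl > 0])), cfg$min_region_px)
})
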