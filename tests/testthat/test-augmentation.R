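test_that("salt and pepper noise hits the seeded fraction of pixels", {
  im <- toy_image(100, 100)
  expect_identical(apply_salt_pepper(im, density = 0, seed = 1), im)

  sat <- apply_salt_pepper(im, density = 1, seed = 1)
  expect_true(all(sat %in% c(0, 1)))

  out <- apply_salt_pepper(im, density = 0.05, seed = 7)
  corrupted <- sum(apply(out != im, c(1, 2), any))
  # binomial(10000, 0.05) central 99% interval
  expect_gte(corrupted, qbinom(0.005, 10000, 0.05))
  expect_lte(corrupted, qbinom(0.995, 10000, 0.05))
  # corrupted pixels are pure black or white on all channels
  hit <- apply(out != im, c(1, 2), any)
  for (c in 1:3) expect_true(all(out[, , c][hit] %in% c(0, 1)))

  expect_identical(apply_salt_pepper(im, 0.05, seed = 7), out)
  expect_false(identical(apply_salt_pepper(im, 0.05, seed = 8), out))
  expect_error(apply_salt_pepper(im, density = 1.2), "density")
})

test_that("gaussian blur matches a brute-force convolution oracle", {
  const <- array(0.4, c(12, 12, 3))
  expect_equal(apply_gaussian_blur(const, 1), const, tolerance = 1e-12)

  im <- toy_image(11, 11, seed = 3)
  expect_equal(apply_gaussian_blur(im, 1), oracle_blur(im, 1), tolerance = 1e-12)

  # single bright pixel: centre strictly decreases, mass conserved
  spot <- array(0, c(21, 21, 3)); spot[11, 11, ] <- 1
  bl <- apply_gaussian_blur(spot, 1)
  expect_lt(bl[11, 11, 1], 1)
  expect_equal(sum(bl[, , 1]), 1, tolerance = 0.01)

  # vanishing sigma approaches the identity
  expect_equal(apply_gaussian_blur(im, 1e-3), im, tolerance = 1e-9)
  expect_error(apply_gaussian_blur(im, 0), "sigma")
})

test_that("random_affine is seeded and degenerates to the identity", {
  im <- toy_image(16, 16)
  expect_equal(random_affine(im, c(1, 1), c(0, 0), seed = 1), im)
  a <- random_affine(im, seed = 5)
  expect_identical(random_affine(im, seed = 5), a)
  expect_false(identical(random_affine(im, seed = 6), a))
  expect_equal(dim(a), dim(im))
  expect_error(random_affine(im, scale_range = c(2, 1)), "scale")
})

test_that("a 90-degree rotation moves a marker to its analytic position", {
  im <- array(0, c(9, 9, 3)); im[2, 5, ] <- 1
  r <- random_affine(im, scale_range = c(1, 1),
                     rotation_range_deg = c(90, 90), seed = 1)
  # centre (5,5); (row 2, col 5) = (x 0, y 3) -> CCW 90 -> (-3, 0) = (row 5, col 2)
  expect_equal(r[5, 2, 1], 1)
  expect_equal(sum(r), 3)
})

test_that("fixed rotations and flips behave geometrically", {
  im <- toy_image(16, 16)
  expect_error(fixed_rotation(im, 90), "angle")
  expect_equal(flip_image(flip_image(im, "horizontal"), "horizontal"), im)
  expect_equal(flip_image(flip_image(im, "vertical"), "vertical"), im)

  m <- array(c(1, 3, 2, 4), c(2, 2, 1))[, , c(1, 1, 1)]
  fv <- flip_image(m, "vertical")
  expect_equal(fv[, , 1], matrix(c(3, 1, 4, 2), 2, 2))

  # rotating a centred disk by 45 then 315 degrees returns it (within
  # interpolation error; empirically ~0.012 mean abs diff at 64 pixels)
  n <- 64
  d <- sqrt(outer((1:n - (n + 1) / 2)^2, (1:n - (n + 1) / 2)^2, `+`))
  disk <- array(rep(as.numeric(d < 20), 3), c(n, n, 3))
  back <- fixed_rotation(fixed_rotation(disk, 45), 315)
  expect_lt(mean(abs(back - disk)), 0.03)
})

test_that("colour jitter and equalization honour their contracts", {
  im <- toy_image(16, 16)
  expect_equal(color_jitter(im, 0, 1), im)
  expect_error(color_jitter(im, 0.1, 0), "saturation_factor")
  shifted <- color_jitter(im, hue_delta = 0.25)
  expect_false(identical(shifted, im))
  expect_true(all(shifted >= 0 & shifted <= 1))

  const <- array(0.6, c(8, 8, 3))
  expect_equal(equalize_contrast(const), const)

  # 50/50 two-level image maps to the value extremes
  v <- array(0, c(8, 8, 3))
  v[1:4, , ] <- 0.3; v[5:8, , ] <- 0.7
  eq <- equalize_contrast(v)
  expect_setequal(round(unique(as.vector(eq)), 10), c(0, 1))

  # an 8-bit ramp already has a flat histogram: equalization ~ identity
  ramp_v <- matrix(rep(seq(0, 1, length.out = 256), 2), 256, 2)
  ramp <- array(rep(ramp_v, 3), c(256, 2, 3))
  eqr <- equalize_contrast(ramp)
  expect_lt(max(abs(eqr - ramp)), 0.02)
})

test_that("operators preserve shape and range on generated images", {
  ds <- generate_leaf_dataset(2, 2, image_size = c(32, 32, 3), seed = 4)
  for (im in ds$images) {
    for (out in list(apply_salt_pepper(im, 0.05, 1), apply_gaussian_blur(im, 0.5),
                     random_affine(im, seed = 2), fixed_rotation(im, 135),
                     flip_image(im, "vertical"), color_jitter(im, 0.05, 1.2),
                     equalize_contrast(im))) {
      expect_equal(dim(out), dim(im))
      expect_true(all(out >= 0 & out <= 1))
    }
  }
})

test_that("plans validate their operator sets and serialize", {
  p1 <- augmentation_plan("ad1", seed = 3)
  expect_setequal(vapply(p1$operators, `[[`, character(1), "op"),
                  c("salt_pepper", "gaussian_blur", "random_affine"))
  p2 <- augmentation_plan("ad2", seed = 3)
  expect_equal(p2$expansion_factor, 10L)
  ops2 <- vapply(p2$operators, `[[`, character(1), "op")
  expect_equal(sum(ops2 == "rotate"), 4)
  expect_equal(sum(ops2 == "flip"), 2)
  expect_error(augmentation_plan("ad2", expansion_factor = 5), "10-way")
  expect_error(augmentation_plan("ad1", expansion_factor = 0), "expansion_factor")

  path <- tempfile(fileext = ".json")
  write_aug_plan(p2, path)
  back <- read_aug_plan(path)
  expect_equal(back$name, "ad2")
  expect_equal(back$expansion_factor, 10L)
})

test_that("expand_dataset multiplies counts, keeps proportions, is seeded", {
  ds <- generate_leaf_dataset(3, c(10), image_size = c(16, 16, 3), seed = 2)
  # pass-through plan
  none <- expand_dataset(ds, augmentation_plan("none"))
  expect_identical(none$images, ds$images)

  # ad2: factor 10, 30 -> 300, class proportions exact
  out <- expand_dataset(ds, augmentation_plan("ad2", seed = 9))
  expect_equal(length(out$images), 300L)
  expect_equal(as.vector(table(out$labels)), rep(100L, 3))
  expect_equal(nrow(out$manifest), 300L)
  expect_true(all(c("source_id", "operator_chain", "seed") %in%
                    names(out$manifest)))

  out2 <- expand_dataset(ds, augmentation_plan("ad2", seed = 9))
  expect_identical(out$manifest, out2$manifest)
  expect_identical(out$images, out2$images)

  ad1 <- expand_dataset(ds, augmentation_plan("ad1", seed = 1))
  expect_equal(length(ad1$images), 120L)
  ad1b <- expand_dataset(ds, augmentation_plan("ad1", seed = 2))
  expect_false(identical(ad1$images, ad1b$images))

  empty <- labeled_image_set(list(), integer(0), c("a", "b"))
  expect_error(expand_dataset(empty, augmentation_plan("ad2")), "empty")
})
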