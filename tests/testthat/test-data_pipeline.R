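test_that("PNM images round-trip through disk at 8-bit precision", {
  im <- toy_image(10, 14)
  path <- tempfile(fileext = ".ppm")
  write_pnm(im, path)
  back <- read_pnm(path)
  expect_equal(dim(back), dim(im))
  expect_lt(max(abs(back - im)), 1 / 255)

  # plain-text P3/P2 with comments and grayscale replication
  p3 <- tempfile(fileext = ".ppm")
  writeLines(c("P3", "# comment", "2 2", "255",
               "255 0 0  0 255 0", "0 0 255  255 255 255"), p3)
  im3 <- read_pnm(p3)
  expect_equal(im3[1, 1, ], c(1, 0, 0))
  expect_equal(im3[2, 2, ], c(1, 1, 1))
  p2 <- tempfile(fileext = ".pgm")
  writeLines(c("P2", "2 1", "255", "0 255"), p2)
  im2 <- read_pnm(p2)
  expect_equal(im2[1, 1, ], c(0, 0, 0))
  expect_equal(im2[1, 2, ], c(1, 1, 1))

  bad <- tempfile(); writeLines("not an image", bad)
  expect_error(read_pnm(bad), "PNM")
})

test_that("labeled_image_set validates its invariants", {
  ims <- list(toy_image(4, 4), toy_image(4, 4, 2))
  expect_error(labeled_image_set(ims, c(0L), c("a", "b")), "equal length")
  expect_error(labeled_image_set(ims, c(0L, 2L), c("a", "b")), "0-based")
  expect_error(labeled_image_set(ims, c(0L, 1L), c("a", "a")), "unique")
  s <- labeled_image_set(ims, c(0L, 1L), c("a", "b"))
  expect_s3_class(s, "leafcnn_image_set")
  expect_equal(length(s), 2L)
})

test_that("load_image_folder assigns alphabetical 0-based class ids", {
  root <- tempfile()
  # create b before a: vocabulary must still be alphabetical
  write_toy_tree(root, classes = c("b", "a"), per_class = 3)
  s <- load_image_folder(root)
  expect_equal(s$class_names, c("a", "b"))
  expect_equal(length(s$images), 6L)
  expect_equal(sort(unique(s$labels)), c(0L, 1L))
  expect_equal(sum(s$labels == 0L), 3L)

  # corrupt + non-image files are skipped with warnings
  writeLines("garbage", file.path(root, "a", "broken.ppm"))
  writeLines("notes", file.path(root, "a", "readme.txt"))
  expect_warning(expect_warning(s2 <- load_image_folder(root),
                                "undecodable"), "non-image")
  expect_equal(length(s2$images), 6L)

  expect_error(load_image_folder(tempfile()), "directory")
})

test_that("folder write/reload preserves labels and manifests", {
  ds <- generate_leaf_dataset(3, 4, image_size = c(16, 16, 3), seed = 8)
  # class names species01..species03 are already alphabetical
  root <- tempfile()
  write_image_folder(ds, root)
  expect_true(file.exists(file.path(root, "manifest.tsv")))
  back <- load_image_folder(root)
  expect_equal(back$class_names, ds$class_names)
  expect_equal(back$labels, ds$labels)
  expect_lt(max(abs(back$images[[5]] - ds$images[[5]])), 1 / 255)
})

test_that("resize is bicubic, exact at fixed point, and replicates gray", {
  ds <- labeled_image_set(list(toy_image(32, 32), toy_image(16, 16, 2)),
                          c(0L, 1L), c("a", "b"))
  out <- resize_images(ds, c(16, 16, 3))
  expect_true(all(vapply(out$images, function(i) all(dim(i) == c(16, 16, 3)),
                         logical(1))))
  # no-op on an already-target-size image
  expect_identical(out$images[[2]], ds$images[[2]])

  gray <- matrix(runif(64), 8, 8)
  arr <- leafcnn:::as_leaf_image(gray)
  expect_equal(arr[, , 1], arr[, , 3])

  # downsizing a smooth gradient stays close to the analytic gradient
  g <- array(rep(seq(0, 1, length.out = 32), times = 32), c(32, 32, 3))
  small <- leafcnn:::resize_image(g, 16, 16)
  expect_lt(max(abs(small[, 8, 1] - seq(0, 1, length.out = 32)[seq(1, 32, 2)])), 0.06)
})

test_that("stratified split partitions every class at round(0.8 n)", {
  ds <- generate_leaf_dataset(3, 10, image_size = c(8, 8, 3), seed = 3)
  sp <- stratified_split(ds, 0.8, seed = 1)
  expect_equal(length(sp$train$images), 24L)
  expect_equal(length(sp$test$images), 6L)
  expect_equal(as.vector(table(sp$train$labels)), rep(8L, 3))
  expect_equal(as.vector(table(sp$test$labels)), rep(2L, 3))
  # partition: disjoint ids, union = all ids
  expect_length(intersect(sp$train$manifest$id, sp$test$manifest$id), 0)
  expect_setequal(c(sp$train$manifest$id, sp$test$manifest$id), ds$manifest$id)

  sp2 <- stratified_split(ds, 0.8, seed = 1)
  expect_identical(sp$train$manifest$id, sp2$train$manifest$id)
  sp3 <- stratified_split(ds, 0.8, seed = 2)
  expect_false(identical(sp$train$manifest$id, sp3$train$manifest$id))

  # the published dataset size: 38,400 images at 80-20 -> 30,720 / 7,680
  labels <- rep(0:1, each = 19200)
  tr <- leafcnn:::split_indices(labels, 0.8, seed = 1)
  expect_equal(length(tr), 30720L)
  expect_equal(38400L - length(tr), 7680L)

  one <- labeled_image_set(list(toy_image(4, 4), toy_image(4, 4), toy_image(4, 4)),
                           c(0L, 0L, 1L), c("a", "b"))
  expect_error(stratified_split(one, 0.8, 1), ">= 2")
})
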