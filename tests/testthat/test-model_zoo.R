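test_that("make_model_spec builds the published architectures", {
  s1 <- make_model_spec("N1", num_classes = 9)
  convs <- Filter(function(l) l$kind == "conv2d", s1$layers)
  expect_equal(vapply(convs, function(l) l$num_filters, integer(1)), c(8L, 16L, 32L))
  expect_true(all(vapply(convs, function(l) all(l$filter_size == c(3L, 3L)), logical(1))))
  kinds <- vapply(s1$layers, `[[`, character(1), "kind")
  expect_equal(kinds, c("conv2d", "batchnorm", "relu", "maxpool",
                        "conv2d", "batchnorm", "relu", "maxpool",
                        "conv2d", "batchnorm", "relu",
                        "fully_connected", "softmax", "classification"))
  expect_equal(s1$input_size, c(256L, 256L, 3L))

  s3 <- make_model_spec("N3", num_classes = 9)
  convs3 <- Filter(function(l) l$kind == "conv2d", s3$layers)
  expect_equal(lapply(convs3, `[[`, "filter_size"),
               list(c(7L, 7L), c(5L, 5L), c(3L, 3L)))
  expect_equal(vapply(convs3, function(l) l$num_filters, integer(1)), c(8L, 16L, 32L))

  pools <- Filter(function(l) l$kind == "maxpool", s1$layers)
  expect_true(all(vapply(pools, function(l) l$stride == 2L && l$window == 2L,
                         logical(1))))
  fc <- Filter(function(l) l$kind == "fully_connected", s1$layers)[[1]]
  expect_equal(fc$out_units, 9L)

  expect_error(make_model_spec("N1", num_classes = 1), "num_classes")
  expect_error(make_model_spec("N9", num_classes = 9))
  expect_error(make_model_spec("N1", 9, input_size = c(30, 30, 3)), "divisible")
})

test_that("count_parameters matches the closed-form layer enumeration", {
  # frozen from the per-layer closed form:
  # 224 + 16 + 1168 + 32 + 4640 + 64 + (64*64*32*9 + 9) = 1,185,801
  expect_equal(count_parameters(make_model_spec("N1", 9)), 1185801)

  # cross-checks against the printed size ratios (29.7/14.8 and 14.8/14.8 MB)
  n1 <- count_parameters(make_model_spec("N1", 9))
  n2 <- count_parameters(make_model_spec("N2", 9))
  n3 <- count_parameters(make_model_spec("N3", 9))
  expect_gt(n2 / n1, 1.95); expect_lt(n2 / n1, 2.05)
  expect_gt(n3 / n1, 0.99); expect_lt(n3 / n1, 1.01)

  # degenerate spec: no conv layers, FC 4 -> 2 gives 4*2 + 2 = 10
  tiny <- structure(list(name = "N1", input_size = c(1L, 4L, 1L),
                         num_classes = 2L,
                         layers = list(list(kind = "fully_connected",
                                            out_units = 2L),
                                       list(kind = "softmax"),
                                       list(kind = "classification"))),
                    class = "leafcnn_model_spec")
  expect_equal(count_parameters(tiny), 10)

  # FC monotonicity: doubling classes strictly increases the count
  expect_gt(count_parameters(make_model_spec("N1", 18)), n1)
})

test_that("size_reduction_percent reproduces the published compactness", {
  expect_equal(size_reduction_percent(14.8, 202), 92.67)
  expect_equal(size_reduction_percent(29.7, 202), 85.29)
  expect_equal(size_reduction_percent(5, 5), 0)
  expect_error(size_reduction_percent(1, 0), "reference_size")
  expect_warning(out <- size_reduction_percent(300, 202), "larger")
  expect_lt(out, 0)
})

test_that("built networks produce seeded, normalized softmax outputs", {
  spec <- make_model_spec("N1", 9, input_size = c(64, 64, 3))
  net1 <- build_network(spec, seed = 42)
  net2 <- build_network(spec, seed = 42)
  expect_identical(net1$params, net2$params)
  net3 <- build_network(spec, seed = 43)
  expect_false(identical(net1$params, net3$params))

  set.seed(5)
  x <- array(runif(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  probs <- predict_classes(net1, x)$probabilities
  expect_equal(dim(probs), c(4L, 9L))
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-6)

  expect_error(predict_classes(net1, array(0, c(32, 32, 3, 2))), "shape")
})

test_that("N3 feature map before the FC layer is 64x64x32 at 256 input", {
  spec <- make_model_spec("N3", 9)
  shapes <- leafcnn:::layer_shapes(spec)
  fc_at <- which(vapply(spec$layers, `[[`, character(1), "kind") ==
                   "fully_connected")
  pre <- shapes[[fc_at]]$input
  expect_equal(c(pre$h, pre$w, pre$c), c(64, 64, 32))
})

test_that("model specs round-trip through JSON", {
  spec <- make_model_spec("N2", 5, input_size = c(64, 64, 3))
  path <- tempfile(fileext = ".json")
  write_model_spec(spec, path)
  back <- read_model_spec(path)
  expect_equal(back$name, spec$name)
  expect_equal(back$input_size, spec$input_size)
  expect_equal(back$num_classes, spec$num_classes)
  expect_equal(count_parameters(back), count_parameters(spec))
})
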