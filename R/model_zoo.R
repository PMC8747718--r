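#' Declarative layer and model specifications
#'
#' The three compact networks N1, N2 and N3 share one topology: three
#' conv/batch-norm/ReLU blocks, the first two followed by 2x2 stride-2 max
#' pooling, then a fully connected layer, softmax, and a classification
#' (cross-entropy) head. They differ only in conv filter sizes and counts:
#'
#' * N1: 3x3/8, 3x3/16, 3x3/32
#' * N2: 3x3/16, 3x3/32, 3x3/64
#' * N3: 7x7/8, 5x5/16, 3x3/32
#'
#' Convolutions use stride 1 with "same" zero padding, so spatial size halves
#' only at the two pools (e.g. 256 -> 128 -> 64). `alexnet_ref` is an
#' AlexNet-shaped stub (227x227x3 input) used purely as a size reference; its
#' pretrained weights are never needed.
#'
#' @param name one of `"N1"`, `"N2"`, `"N3"`, `"alexnet_ref"`.
#' @param num_classes number of output classes (>= 2).
#' @param input_size integer triple `(height, width, channels)`; defaults to
#'   `c(256, 256, 3)` for the N models and `c(227, 227, 3)` for `alexnet_ref`.
#' @return an object of class `leafcnn_model_spec`.
#' @examples
#' spec <- make_model_spec("N1", num_classes = 9)
#' count_parameters(spec)
#' @export
make_model_spec <- function(name = c("N1", "N2", "N3", "alexnet_ref"),
                            num_classes,
                            input_size = NULL) {
  name <- match.arg(name)
  if (!is_count(num_classes, min = 2))
    stop_leafcnn("num_classes must be an integer >= 2")
  if (is.null(input_size))
    input_size <- if (name == "alexnet_ref") c(227L, 227L, 3L) else c(256L, 256L, 3L)
  input_size <- as.integer(input_size)
  if (length(input_size) != 3 || any(input_size < 1))
    stop_leafcnn("input_size must be a positive (height, width, channels) triple")

  if (name == "alexnet_ref") {
    layers <- c(
      list(conv_layer(c(11, 11), 96, stride = 4, padding = 0), relu_layer(),
           pool_layer(window = 3, stride = 2),
           conv_layer(c(5, 5), 256, padding = 2), relu_layer(),
           pool_layer(window = 3, stride = 2),
           conv_layer(c(3, 3), 384, padding = 1), relu_layer(),
           conv_layer(c(3, 3), 384, padding = 1), relu_layer(),
           conv_layer(c(3, 3), 256, padding = 1), relu_layer(),
           pool_layer(window = 3, stride = 2),
           fc_layer(4096), relu_layer(), fc_layer(4096), relu_layer(),
           fc_layer(num_classes), softmax_layer(), classification_layer()))
  } else {
    if (any(input_size[1:2] %% 4 != 0))
      stop_leafcnn("input height/width must be divisible by 4 (two stride-2 pools)")
    conv_plan <- switch(name,
      N1 = list(list(c(3, 3), 8),  list(c(3, 3), 16), list(c(3, 3), 32)),
      N2 = list(list(c(3, 3), 16), list(c(3, 3), 32), list(c(3, 3), 64)),
      N3 = list(list(c(7, 7), 8),  list(c(5, 5), 16), list(c(3, 3), 32)))
    blocks <- lapply(seq_along(conv_plan), function(i) {
      p <- conv_plan[[i]]
      blk <- list(conv_layer(p[[1]], p[[2]]), batchnorm_layer(), relu_layer())
      if (i < 3) blk <- c(blk, list(pool_layer()))
      blk
    })
    layers <- c(do.call(c, blocks),
                list(fc_layer(num_classes), softmax_layer(),
                     classification_layer()))
  }
  structure(list(name = name, input_size = input_size,
                 num_classes = as.integer(num_classes), layers = layers),
            class = "leafcnn_model_spec")
}

conv_layer <- function(filter_size, num_filters, stride = 1L, padding = NULL) {
  filter_size <- as.integer(filter_size)
  if (is.null(padding)) padding <- (filter_size[1] - 1L) %/% 2L  # "same"
  list(kind = "conv2d", filter_size = filter_size,
       num_filters = as.integer(num_filters), stride = as.integer(stride),
       padding = as.integer(padding))
}
batchnorm_layer <- function() list(kind = "batchnorm")
relu_layer <- function() list(kind = "relu")
pool_layer <- function(window = 2L, stride = 2L)
  list(kind = "maxpool", window = as.integer(window), stride = as.integer(stride))
fc_layer <- function(out_units)
  list(kind = "fully_connected", out_units = as.integer(out_units))
softmax_layer <- function() list(kind = "softmax")
classification_layer <- function() list(kind = "classification")

#' @export
print.leafcnn_model_spec <- function(x, ...) {
  cat(sprintf("<leafcnn_model_spec %s: %dx%dx%d input, %d classes, %d layers>\n",
              x$name, x$input_size[1], x$input_size[2], x$input_size[3],
              x$num_classes, length(x$layers)))
  for (ly in x$layers) {
    desc <- switch(ly$kind,
      conv2d = sprintf("conv2d %dx%d, %d filters, stride %d, pad %d",
                       ly$filter_size[1], ly$filter_size[2], ly$num_filters,
                       ly$stride, ly$padding),
      maxpool = sprintf("maxpool %dx%d, stride %d", ly$window, ly$window, ly$stride),
      fully_connected = sprintf("fully_connected -> %d", ly$out_units),
      ly$kind)
    cat("  -", desc, "\n")
  }
  invisible(x)
}

# Walk the layer list tracking (h, w, channels-or-units); used by both the
# parameter counter and the network builder.
layer_shapes <- function(spec) {
  h <- spec$input_size[1]; w <- spec$input_size[2]; c <- spec$input_size[3]
  flat <- FALSE
  shapes <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    inshape <- list(h = h, w = w, c = c, flat = flat)
    if (ly$kind == "conv2d") {
      if (flat) stop_leafcnn("conv2d after flattening is not supported")
      h <- (h + 2 * ly$padding - ly$filter_size[1]) %/% ly$stride + 1L
      w <- (w + 2 * ly$padding - ly$filter_size[2]) %/% ly$stride + 1L
      c <- ly$num_filters
    } else if (ly$kind == "maxpool") {
      h <- (h - ly$window) %/% ly$stride + 1L
      w <- (w - ly$window) %/% ly$stride + 1L
    } else if (ly$kind == "fully_connected") {
      h <- 1L; w <- 1L; c <- ly$out_units; flat <- TRUE
    }
    shapes[[i]] <- list(input = inshape,
                        output = list(h = h, w = w, c = c, flat = flat))
  }
  shapes
}

#' Count trainable parameters of a model specification
#'
#' Closed-form accounting: a convolution contributes
#' `kh * kw * c_in * c_out + c_out`, batch normalization `2 * channels`
#' (scale and shift; running statistics are state, not parameters), a fully
#' connected layer `in_features * out_units + out_units`; pooling, ReLU,
#' softmax and the classification head contribute nothing.
#'
#' @param spec a `leafcnn_model_spec`.
#' @return total trainable parameter count (numeric scalar).
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "leafcnn_model_spec"))
  shapes <- layer_shapes(spec)
  total <- 0
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    inp <- shapes[[i]]$input
    total <- total + switch(ly$kind,
      conv2d = prod(ly$filter_size) * inp$c * ly$num_filters + ly$num_filters,
      batchnorm = 2 * inp$c,
      fully_connected = (inp$h * inp$w * inp$c) * ly$out_units + ly$out_units,
      0)
  }
  total
}

#' Model size estimate and compactness report
#'
#' @param spec a `leafcnn_model_spec`.
#' @param bytes_per_parameter storage per weight; default 4 (single precision).
#' @param reference_size_bytes optional reference model size for a
#'   size-reduction percentage (e.g. the published AlexNet 202 MB).
#' @return a `leafcnn_size_report` list with `trainable_parameters`,
#'   `bytes_per_parameter`, `estimated_bytes`, and when a reference is given,
#'   `reference_size_bytes` and `reduction_percent`.
#' @export
size_report <- function(spec, bytes_per_parameter = 4,
                        reference_size_bytes = NULL) {
  n <- count_parameters(spec)
  rep <- list(model = spec$name,
              trainable_parameters = n,
              bytes_per_parameter = bytes_per_parameter,
              estimated_bytes = n * bytes_per_parameter)
  if (!is.null(reference_size_bytes)) {
    rep$reference_size_bytes <- reference_size_bytes
    rep$reduction_percent <- size_reduction_percent(rep$estimated_bytes,
                                                    reference_size_bytes)
  }
  structure(rep, class = "leafcnn_size_report")
}

#' @export
print.leafcnn_size_report <- function(x, ...) {
  cat(sprintf("<size report %s: %s parameters, %.2f MB at %d B/param",
              x$model, format(x$trainable_parameters, big.mark = ","),
              x$estimated_bytes / 2^20, x$bytes_per_parameter))
  if (!is.null(x$reduction_percent))
    cat(sprintf(", %.2f%% smaller than reference", x$reduction_percent))
  cat(">\n")
  invisible(x)
}

#' Compactness: percentage size reduction relative to a reference model
#'
#' `100 * (1 - candidate / reference)`, reported to two decimals with the
#' fractional remainder truncated (the convention of the published figures:
#' 14.8 MB vs the 202 MB AlexNet reference is 92.6733... -> 92.67, and
#' 29.7 MB is 85.2970... -> 85.29). A candidate larger than the reference
#' yields a negative value (flagged with a warning).
#'
#' @param candidate_size,reference_size sizes in the same units (bytes or MB).
#' @return percentage reduction, to 2 decimals.
#' @export
size_reduction_percent <- function(candidate_size, reference_size) {
  if (!is.numeric(reference_size) || reference_size <= 0)
    stop_leafcnn("reference_size must be > 0")
  out <- trunc(100 * (1 - candidate_size / reference_size) * 100) / 100
  if (any(out < 0)) warning("candidate is larger than the reference model")
  out
}

#' Serialize / deserialize a model specification as JSON
#'
#' @param spec a `leafcnn_model_spec`.
#' @param path file path.
#' @return `read_model_spec()` returns a `leafcnn_model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "leafcnn_model_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  raw$layers <- lapply(raw$layers, function(ly) {
    ly <- lapply(ly, function(f) if (is.numeric(f)) as.integer(f) else f)
    ly
  })
  raw$input_size <- as.integer(raw$input_size)
  raw$num_classes <- as.integer(raw$num_classes)
  structure(raw, class = "leafcnn_model_spec")
}
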