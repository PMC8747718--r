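#' Image augmentation operators
#'
#' Seeded, composable operators realizing the two augmentation amalgamations:
#' `ad1` combines salt-and-pepper noise, Gaussian blur and a random affine map
#' (scaling 0.95-1.05 independently per axis, rotation -30 to 30 degrees)
#' into randomized per-image chains; `ad2` is a deterministic expansion into
#' the original plus four fixed rotations (45/135/225/315 degrees), horizontal
#' and vertical flips, and hue, saturation and contrast-equalization colour
#' transforms. All operators preserve image shape and the `[0, 1]` range.
#'
#' @name augmentation
NULL

#' Salt-and-pepper noise
#'
#' A seeded fraction `density` of pixel locations is set to pure black or
#' pure white (equal probability, all three channels); other pixels are
#' untouched.
#'
#' @param image `H x W x 3` numeric array in `[0, 1]`.
#' @param density fraction of pixels to corrupt, in `[0, 1]` (default 0.05).
#' @param seed integer seed.
#' @return the corrupted image.
#' @export
apply_salt_pepper <- function(image, density = 0.05, seed = 1L) {
  image <- as_leaf_image(image)
  if (!is.numeric(density) || density < 0 || density > 1)
    stop_leafcnn("density must be in [0, 1]")
  h <- dim(image)[1]; w <- dim(image)[2]
  with_rng(mix_seed(seed, 11L), {
    hit <- runif(h * w) < density
    val <- as.numeric(runif(h * w) < 0.5)  # 0 = pepper, 1 = salt
  })
  for (c in 1:3) {
    ch <- image[, , c]
    ch[hit] <- val[hit]
    image[, , c] <- ch
  }
  image
}

#' Gaussian blur
#'
#' Separable convolution with a normalized Gaussian kernel of standard
#' deviation `sigma` (radius `ceiling(3 * sigma)`), reflective borders.
#' Constant images are mapped to themselves and the image mean is preserved
#' up to border effects.
#'
#' @param image `H x W x 3` numeric array.
#' @param sigma kernel standard deviation in pixels (> 0; default 0.5).
#' @return the blurred image.
#' @export
apply_gaussian_blur <- function(image, sigma = 0.5) {
  image <- as_leaf_image(image)
  if (!is.numeric(sigma) || sigma <= 0) stop_leafcnn("sigma must be > 0")
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  h <- dim(image)[1]; w <- dim(image)[2]
  Bh <- blur_matrix(h, k)
  Bw <- t(blur_matrix(w, k))
  for (c in 1:3) image[, , c] <- clip01(Bh %*% image[, , c] %*% Bw)
  image
}

# Dense 1-D blur operator with reflective (mirror) boundary handling.
blur_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    js <- (i - r):(i + r)
    # reflect indices: 0 -> 1, -1 -> 2, n+1 -> n, ...
    js <- ifelse(js < 1, 1 - js, ifelse(js > n, 2 * n + 1 - js, js))
    js <- pmin(pmax(js, 1), n)
    for (k in seq_along(js)) M[i, js[k]] <- M[i, js[k]] + kernel[k]
  }
  M
}

#' Random affine transform
#'
#' Samples independent horizontal and vertical scale factors and one rotation
#' angle uniformly from the given ranges (seeded) and applies the map about
#' the image centre with bilinear interpolation on an unchanged canvas;
#' regions mapped from outside the source are filled black.
#'
#' @param image `H x W x 3` numeric array.
#' @param scale_range length-2 numeric, default `c(0.95, 1.05)`.
#' @param rotation_range_deg length-2 numeric, default `c(-30, 30)`.
#' @param seed integer seed.
#' @return the transformed image.
#' @export
random_affine <- function(image, scale_range = c(0.95, 1.05),
                          rotation_range_deg = c(-30, 30), seed = 1L) {
  image <- as_leaf_image(image)
  check_range <- function(r, what) {
    if (length(r) != 2 || !is.numeric(r) || anyNA(r) || r[1] > r[2])
      stop_leafcnn("malformed ", what, " range")
  }
  check_range(scale_range, "scale")
  check_range(rotation_range_deg, "rotation")
  with_rng(mix_seed(seed, 23L), {
    sx <- runif(1, scale_range[1], scale_range[2])
    sy <- runif(1, scale_range[1], scale_range[2])
    th <- runif(1, rotation_range_deg[1], rotation_range_deg[2])
  })
  if (sx == 1 && sy == 1 && th == 0) return(image)
  affine_warp(image, sx = sx, sy = sy, theta_deg = th)
}

#' Fixed rotation by 45/135/225/315 degrees
#'
#' Rotation about the centre with bilinear interpolation, unchanged canvas,
#' black fill outside the source footprint.
#'
#' @param image `H x W x 3` numeric array.
#' @param angle one of 45, 135, 225, 315 (degrees).
#' @return the rotated image.
#' @export
fixed_rotation <- function(image, angle) {
  if (!length(angle) == 1 || !angle %in% c(45, 135, 225, 315))
    stop_leafcnn("angle must be one of 45, 135, 225, 315")
  affine_warp(as_leaf_image(image), theta_deg = angle)
}

#' Horizontal or vertical flip
#'
#' Exact pixel reindexing: horizontal mirrors columns (left-right), vertical
#' mirrors rows (top-bottom). Both are involutions.
#'
#' @param image `H x W x 3` numeric array.
#' @param axis `"horizontal"` or `"vertical"`.
#' @return the flipped image.
#' @export
flip_image <- function(image, axis = c("horizontal", "vertical")) {
  image <- as_leaf_image(image)
  axis <- match.arg(axis)
  if (axis == "horizontal") image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
  else image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
}

#' Hue and saturation jitter
#'
#' Shifts hue cyclically on the `[0, 1)` wheel by `hue_delta` and multiplies
#' saturation by `saturation_factor` (clipped to `[0, 1]`), leaving value
#' untouched. `hue_delta = 0, saturation_factor = 1` is the identity.
#'
#' @param image `H x W x 3` numeric array.
#' @param hue_delta hue shift as a fraction of the wheel.
#' @param saturation_factor positive multiplier.
#' @return the recoloured image.
#' @export
color_jitter <- function(image, hue_delta = 0, saturation_factor = 1) {
  image <- as_leaf_image(image)
  if (!is.numeric(saturation_factor) || saturation_factor <= 0)
    stop_leafcnn("saturation_factor must be > 0")
  if (hue_delta == 0 && saturation_factor == 1) return(image)
  hsv <- rgb_to_hsv(image)
  hsv[, , 1] <- (hsv[, , 1] + hue_delta) %% 1
  hsv[, , 2] <- clip01(hsv[, , 2] * saturation_factor)
  hsv_to_rgb(hsv)
}

#' Contrast enhancement by histogram equalization
#'
#' Equalizes the HSV value channel over 256 bins while preserving hue and
#' saturation (chroma). Constant images are returned unchanged.
#'
#' @param image `H x W x 3` numeric array.
#' @return the contrast-equalized image.
#' @export
equalize_contrast <- function(image) {
  image <- as_leaf_image(image)
  hsv <- rgb_to_hsv(image)
  v <- hsv[, , 3]
  lev <- pmin(floor(v * 255), 255)  # 0..255 bins
  counts <- tabulate(lev + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(lev)
  cdf_min <- min(cdf[cdf > 0])
  if (cdf_min >= 1) return(image)  # single occupied bin: degenerate histogram
  mapped <- (cdf - cdf_min) / (1 - cdf_min)
  hsv[, , 3] <- matrix(mapped[lev + 1L], nrow(v), ncol(v))
  hsv_to_rgb(hsv)
}

#' Augmentation plans
#'
#' An `AugmentationPlan` is an ordered operator list plus an expansion factor
#' (augmented images emitted per source image, original included) and a seed.
#' `ad1` emits the original plus `expansion_factor - 1` randomized
#' noise/blur/affine chains (default factor 4); `ad2` is the deterministic
#' 10-way expansion: original, rotations by 45/135/225/315 degrees, horizontal
#' and vertical flips, hue jitter, saturation jitter, and contrast
#' equalization. The hue/saturation draws in `ad2` are seeded per image, so
#' the whole plan is reproducible from `seed`.
#'
#' @param name `"ad1"`, `"ad2"`, or `"none"` (pass-through, factor 1).
#' @param seed integer root seed for all per-image randomness.
#' @param expansion_factor images emitted per source image (`ad1` only;
#'   `ad2` is fixed at 10, `none` at 1).
#' @param sp_density salt-and-pepper density for `ad1` (default 0.05).
#' @param blur_sigma Gaussian blur sigma for `ad1` (default 0.5).
#' @return a `leafcnn_aug_plan`.
#' @export
augmentation_plan <- function(name = c("ad1", "ad2", "none"), seed = 1L,
                              expansion_factor = NULL,
                              sp_density = 0.05, blur_sigma = 0.5) {
  name <- match.arg(name)
  if (name == "ad1") {
    expansion_factor <- expansion_factor %||% 4L
    operators <- list(
      list(op = "salt_pepper", density = sp_density),
      list(op = "gaussian_blur", sigma = blur_sigma),
      list(op = "random_affine", scale = c(0.95, 1.05), rotation = c(-30, 30)))
  } else if (name == "ad2") {
    if (!is.null(expansion_factor) && expansion_factor != 10L)
      stop_leafcnn("ad2 is a fixed 10-way expansion")
    expansion_factor <- 10L
    operators <- list(
      list(op = "rotate", angle = 45), list(op = "rotate", angle = 135),
      list(op = "rotate", angle = 225), list(op = "rotate", angle = 315),
      list(op = "flip", axis = "horizontal"), list(op = "flip", axis = "vertical"),
      list(op = "hue", max_delta = 0.05),
      list(op = "saturation", range = c(0.7, 1.3)),
      list(op = "contrast_equalize"))
  } else {
    expansion_factor <- 1L
    operators <- list()
  }
  if (expansion_factor < 1) stop_leafcnn("expansion_factor must be >= 1")
  structure(list(name = name, operators = operators,
                 expansion_factor = as.integer(expansion_factor),
                 seed = as.integer(seed)),
            class = "leafcnn_aug_plan")
}

#' @export
print.leafcnn_aug_plan <- function(x, ...) {
  cat(sprintf("<augmentation plan %s: factor %d, %d operators, seed %d>\n",
              x$name, x$expansion_factor, length(x$operators), x$seed))
  invisible(x)
}

#' Serialize / deserialize an augmentation plan as JSON
#' @param plan a `leafcnn_aug_plan`.
#' @param path file path.
#' @export
write_aug_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_aug_plan
#' @export
read_aug_plan <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  raw$expansion_factor <- as.integer(raw$expansion_factor)
  raw$seed <- as.integer(raw$seed)
  structure(raw, class = "leafcnn_aug_plan")
}

# Apply one emitted-variant transform for image i of the dataset. Variant 1 is
# always the untouched original.
ad1_variant <- function(image, plan, img_seed) {
  image <- apply_salt_pepper(image, plan$operators[[1]]$density,
                             seed = mix_seed(img_seed, 1L))
  image <- apply_gaussian_blur(image, plan$operators[[2]]$sigma)
  random_affine(image, plan$operators[[3]]$scale, plan$operators[[3]]$rotation,
                seed = mix_seed(img_seed, 2L))
}

ad2_variant <- function(image, op, img_seed) {
  switch(op$op,
    rotate = fixed_rotation(image, op$angle),
    flip = flip_image(image, op$axis),
    hue = {
      d <- with_rng(mix_seed(img_seed, 3L),
                    runif(1, -op$max_delta, op$max_delta))
      color_jitter(image, hue_delta = d)
    },
    saturation = {
      f <- with_rng(mix_seed(img_seed, 4L),
                    runif(1, op$range[1], op$range[2]))
      color_jitter(image, saturation_factor = f)
    },
    contrast_equalize = equalize_contrast(image),
    stop_leafcnn("unknown ad2 operator: ", op$op))
}

#' Expand a dataset under an augmentation plan
#'
#' Emits `expansion_factor` images per source image (the original plus
#' augmented variants), inherits labels, and records
#' `(source id, operator chain, seed)` per emitted image in the manifest.
#' Deterministic given `plan$seed`; per-class proportions are preserved
#' exactly.
#'
#' @param dataset a nonempty `leafcnn_image_set`.
#' @param plan a `leafcnn_aug_plan`.
#' @return the expanded `leafcnn_image_set`.
#' @export
expand_dataset <- function(dataset, plan) {
  stopifnot(inherits(dataset, "leafcnn_image_set"),
            inherits(plan, "leafcnn_aug_plan"))
  n <- length(dataset$images)
  if (n == 0) stop_leafcnn("dataset is empty")
  if (plan$expansion_factor == 1L || length(plan$operators) == 0)
    return(dataset)
  images <- vector("list", n * plan$expansion_factor)
  labels <- integer(n * plan$expansion_factor)
  man <- vector("list", n * plan$expansion_factor)
  out <- 0L
  for (i in seq_len(n)) {
    src <- dataset$images[[i]]
    src_id <- dataset$manifest$id[i]
    img_seed <- mix_seed(plan$seed, i)
    for (v in seq_len(plan$expansion_factor)) {
      out <- out + 1L
      if (v == 1L) {
        images[[out]] <- src
        chain <- "original"
      } else if (plan$name == "ad1") {
        images[[out]] <- ad1_variant(src, plan, mix_seed(img_seed, v))
        chain <- "salt_pepper>gaussian_blur>random_affine"
      } else {
        op <- plan$operators[[v - 1L]]
        images[[out]] <- ad2_variant(src, op, img_seed)
        chain <- paste(unlist(op), collapse = ":")
      }
      labels[out] <- dataset$labels[i]
      man[[out]] <- data.frame(
        id = sprintf("%s_%s_v%02d", src_id, plan$name, v),
        class = dataset$class_names[dataset$labels[i] + 1L],
        source_id = src_id, operator_chain = chain,
        seed = img_seed, stringsAsFactors = FALSE)
    }
  }
  labeled_image_set(images, labels, dataset$class_names, do.call(rbind, man))
}
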