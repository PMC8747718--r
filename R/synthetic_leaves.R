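#' Procedural leaf image generator
#'
#' Renders leaf-like labeled RGB images so the whole pipeline (augmentation,
#' loading, training, evaluation) is testable without external datasets. Each
#' class is described by a `LeafClassRecipe`: a serrated superellipse blade
#' with a midrib and pinnate veins on a dark background, centred like typical
#' lab-bench leaf photographs. Classes differ in blade aspect ratio, margin
#' serration, vein count, base hue and texture noise; within-class variation
#' comes from seeded jitter of pose, scale and illumination. Disease mode
#' renders four classes sharing one species recipe — healthy leaves plus
#' brown-blob lesions (early blight), pale meandering trails (leaf miner) and
#' a radial displacement warp (leaf curl, YLCV-like) — so disease variants
#' differ from healthy leaves only inside lesion regions.
#'
#' @name synthetic_leaves
NULL

#' Leaf class recipe
#'
#' @param blade_aspect width-to-length ratio of the blade, in `(0, 1]`.
#' @param margin_serration serration amplitude fraction in `[0, 1]`.
#' @param vein_count number of pinnate vein pairs (>= 0).
#' @param base_hue hue on the `[0, 1)` wheel.
#' @param texture_noise amplitude of per-pixel value noise in `[0, 1]`.
#' @param lesion_mode `"none"`, `"blight_spots"`, `"miner_trails"`, or
#'   `"curl_warp"`.
#' @param serration_freq serration lobes around the margin.
#' @return a `leafcnn_recipe`.
#' @export
leaf_class_recipe <- function(blade_aspect = 0.55, margin_serration = 0.3,
                              vein_count = 7L, base_hue = 0.3,
                              texture_noise = 0.08,
                              lesion_mode = c("none", "blight_spots",
                                              "miner_trails", "curl_warp"),
                              serration_freq = 12L) {
  lesion_mode <- match.arg(lesion_mode)
  stopifnot(blade_aspect > 0, blade_aspect <= 1,
            margin_serration >= 0, margin_serration <= 1,
            vein_count >= 0, texture_noise >= 0, texture_noise <= 1)
  structure(list(blade_aspect = blade_aspect,
                 margin_serration = margin_serration,
                 vein_count = as.integer(vein_count),
                 base_hue = base_hue %% 1,
                 texture_noise = texture_noise,
                 lesion_mode = lesion_mode,
                 serration_freq = as.integer(serration_freq)),
            class = "leafcnn_recipe")
}

# Auto-generate pairwise distinct recipes. Species mode spreads hue evenly
# over the green-to-cyan band and varies shape/texture; disease mode uses one
# tomato-like recipe with the four lesion modes.
default_recipes <- function(num_classes, seed, disease_mode = FALSE) {
  if (disease_mode) {
    modes <- c("none", "blight_spots", "miner_trails", "curl_warp")
    return(lapply(modes, function(m)
      leaf_class_recipe(blade_aspect = 0.6, margin_serration = 0.35,
                        vein_count = 6L, base_hue = 0.31,
                        texture_noise = 0.06, lesion_mode = m,
                        serration_freq = 10L)))
  }
  with_rng(mix_seed(seed, 555L), {
    lapply(seq_len(num_classes), function(k) {
      leaf_class_recipe(
        blade_aspect = 0.35 + 0.6 * ((k * 7) %% num_classes) / num_classes,
        margin_serration = ((k * 3) %% 5) / 5,
        vein_count = 3L + ((k * 5) %% 9L),
        base_hue = 0.14 + 0.46 * (k - 1) / num_classes + runif(1, -0.005, 0.005),
        texture_noise = 0.03 + 0.12 * ((k * 11) %% 4) / 4,
        lesion_mode = "none",
        serration_freq = 8L + 2L * ((k * 13) %% 5L))
    })
  })
}

#' Render one leaf image from a recipe
#'
#' @param recipe a `leafcnn_recipe`.
#' @param image_size `(height, width, channels)` triple.
#' @param seed integer seed controlling pose, illumination, texture and
#'   lesion placement; identical seeds give identical images.
#' @return an `H x W x 3` numeric array in `[0, 1]`.
#' @export
generate_leaf_image <- function(recipe, image_size = c(256, 256, 3), seed = 1L) {
  stopifnot(inherits(recipe, "leafcnn_recipe"))
  h <- image_size[1]; w <- image_size[2]
  # base (pose/texture) draws are separated from lesion draws so that two
  # recipes differing only in lesion_mode render identical healthy tissue
  base <- with_rng(mix_seed(seed, 31L), list(
    phi = runif(1, -0.26, 0.26),
    s = runif(1, 0.82, 1.0),
    tx = runif(1, -0.06, 0.06),
    ty = runif(1, -0.06, 0.06),
    illum = runif(1, 0.85, 1.1),
    hue_jit = runif(1, -0.012, 0.012),
    noise = runif(h * w)))
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  half <- min(h, w) / 2
  x <- (rep(seq_len(w), each = h) - cx) / half
  y <- (rep(seq_len(h), times = w) - cy) / half
  # pose: translate then rotate into leaf coordinates
  xs <- x - base$tx; ys <- y - base$ty
  u <- cos(base$phi) * xs + sin(base$phi) * ys
  v <- -sin(base$phi) * xs + cos(base$phi) * ys
  if (recipe$lesion_mode == "curl_warp") {
    les <- with_rng(mix_seed(seed, 47L),
                    list(p1 = runif(1, 0, 2 * pi), p2 = runif(1, 0, 2 * pi)))
    g <- clip01(sqrt(u^2 + v^2) / 0.45 - 0.25)
    u2 <- u + 0.11 * sin(9 * v + les$p1) * g
    v2 <- v + 0.11 * sin(9 * u + les$p2) * g
    warp_moved <- g > 0
    u <- u2; v <- v2
  }
  a <- 0.8 * base$s
  b <- a * recipe$blade_aspect
  r <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  p <- 2.5
  R <- (abs(cos(th) / a)^p + abs(sin(th) / b)^p)^(-1 / p)
  Rs <- R * (1 + 0.12 * recipe$margin_serration *
               sin(recipe$serration_freq * th))
  inside <- r <= Rs
  t_rad <- pmin(r / Rs, 1)

  hue <- rep(recipe$base_hue + base$hue_jit, h * w)
  sat <- rep(0.35, h * w)
  val <- 0.10 + 0.04 * (base$noise - 0.5)  # background
  hue[!inside] <- 0.09
  # leaf tissue: radial value gradient plus texture noise
  sat[inside] <- 0.62 - 0.12 * t_rad[inside]
  val[inside] <- (0.32 + 0.48 * (1 - t_rad[inside])^0.7) * base$illum +
    recipe$texture_noise * (base$noise[inside] - 0.5)
  # midrib and pinnate veins (lighter than tissue)
  vein <- abs(v) < 0.014 & abs(u) < a & inside
  if (recipe$vein_count > 0) {
    beta <- 50 * pi / 180
    for (j in seq_len(recipe$vein_count)) {
      uj <- -0.7 * a + 1.4 * a * (j - 0.5) / recipe$vein_count
      for (sgn in c(-1, 1)) {
        du <- u - uj; dv <- v - sgn * 0
        # distance to a segment from (uj, 0) along direction (cos beta, sgn*sin beta)
        tproj <- pmin(pmax(du * cos(beta) + v * sgn * sin(beta), 0), 0.45 * b)
        dseg <- sqrt((du - tproj * cos(beta))^2 + (v - sgn * tproj * sin(beta))^2)
        vein <- vein | (dseg < 0.009 & inside & abs(v) < b)
      }
    }
  }
  val[vein] <- pmin(val[vein] + 0.22, 1)
  sat[vein] <- sat[vein] * 0.7

  if (recipe$lesion_mode == "blight_spots") {
    les <- with_rng(mix_seed(seed, 47L), list(
      nc = 5L,
      ucs = runif(5, -0.5, 0.5), vcs = runif(5, -0.5, 0.5),
      rads = runif(5, 0.16, 0.24)))
    for (k in seq_len(les$nc)) {
      uc <- les$ucs[k] * a; vc <- les$vcs[k] * b
      d <- sqrt((u - uc)^2 + (v - vc)^2)
      m <- d < les$rads[k] * a & inside
      if (!any(m)) next
      hue[m] <- 0.07
      sat[m] <- 0.78
      val[m] <- 0.30 + 0.12 * (d[m] / (les$rads[k] * a))
      rim <- d >= 0.8 * les$rads[k] * a & m
      val[rim] <- 0.18
    }
  } else if (recipe$lesion_mode == "miner_trails") {
    les <- with_rng(mix_seed(seed, 47L), list(
      n = 3L, u0 = runif(3, -0.4, 0.2), v0 = runif(3, -0.4, 0.4),
      psi = runif(3, 0, 2 * pi), phs = runif(3, 0, 2 * pi)))
    for (k in seq_len(les$n)) {
      tt <- seq(0, 1, length.out = 160)
      L <- 0.9 * a
      px <- les$u0[k] * a + tt * L * cos(les$psi[k]) -
        0.10 * sin(5 * pi * tt + les$phs[k]) * sin(les$psi[k])
      py <- les$v0[k] * b + tt * L * sin(les$psi[k]) +
        0.10 * sin(5 * pi * tt + les$phs[k]) * cos(les$psi[k])
      dmin <- rep(Inf, h * w)
      for (q in seq_along(tt))
        dmin <- pmin(dmin, (u - px[q])^2 + (v - py[q])^2)
      m <- dmin < 0.032^2 & inside
      sat[m] <- 0.12
      val[m] <- 0.88
    }
  }

  img <- hsv_to_rgb(array(c(hue, sat, clip01(val)), c(h, w, 3L)))
  clip01(img)
}

#' Generate a labeled synthetic leaf dataset
#'
#' `num_classes * per_class` images, balanced, each class from a distinct
#' auto-generated recipe (with `disease_mode = TRUE` exactly 4 classes:
#' `healthy`, `blight_spots`, `miner_trails`, `curl_warp`). All randomness is
#' expanded per image from the single root `seed`; the global RNG state is
#' untouched and identical calls produce identical images.
#'
#' @param num_classes number of classes (>= 2); forced to 4 in disease mode.
#' @param per_class images per class (>= 1).
#' @param image_size `(height, width, channels)` triple, default 256x256x3.
#' @param seed root seed.
#' @param disease_mode render tomato-disease classes instead of species.
#' @return a `leafcnn_image_set`.
#' @examples
#' ds <- generate_leaf_dataset(3, 4, image_size = c(32, 32, 3), seed = 1)
#' table(ds$labels)
#' @export
generate_leaf_dataset <- function(num_classes, per_class,
                                  image_size = c(256, 256, 3), seed = 1L,
                                  disease_mode = FALSE) {
  if (!is_count(num_classes, 2)) stop_leafcnn("num_classes must be >= 2")
  if (!is_count(per_class, 1)) stop_leafcnn("per_class must be >= 1")
  if (disease_mode) num_classes <- 4L
  recipes <- default_recipes(num_classes, seed, disease_mode)
  class_names <- if (disease_mode) {
    c("healthy", "blight_spots", "miner_trails", "curl_warp")
  } else {
    sprintf("species%02d", seq_len(num_classes))
  }
  n <- num_classes * per_class
  images <- vector("list", n)
  labels <- integer(n)
  ids <- character(n)
  i <- 0L
  for (k in seq_len(num_classes)) {
    for (j in seq_len(per_class)) {
      i <- i + 1L
      images[[i]] <- generate_leaf_image(recipes[[k]], image_size,
                                         seed = mix_seed(seed, k, j))
      labels[i] <- k - 1L
      ids[i] <- sprintf("%s_%03d", class_names[k], j)
    }
  }
  manifest <- data.frame(id = ids, class = class_names[labels + 1L],
                         source_id = "synthetic",
                         operator_chain = "generate_leaf_image",
                         seed = seed, stringsAsFactors = FALSE)
  labeled_image_set(images, labels, class_names, manifest)
}
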