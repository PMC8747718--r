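#' Labeled image sets
#'
#' The container moved between every pipeline stage: a list of `H x W x 3`
#' images, 0-based integer class labels, an ordered class-name vocabulary
#' (label `k` maps to `class_names[k + 1]`), and a per-image provenance
#' manifest (`data.frame` with at least an `id` column).
#'
#' @param images list of numeric `H x W x 3` arrays in `[0, 1]`.
#' @param labels integer vector of 0-based class ids, same length as `images`.
#' @param class_names character vector of unique class names.
#' @param manifest optional `data.frame` of per-image provenance.
#' @return a `leafcnn_image_set`.
#' @export
labeled_image_set <- function(images, labels, class_names, manifest = NULL) {
  if (length(images) != length(labels))
    stop_leafcnn("images and labels must have equal length")
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 0) || any(labels >= length(class_names)))
    stop_leafcnn("labels must be 0-based ids smaller than length(class_names)")
  if (anyDuplicated(class_names))
    stop_leafcnn("class_names must be unique")
  if (is.null(manifest)) {
    n <- length(images)
    manifest <- data.frame(id = sprintf("img%06d", seq_len(n)),
                           class = class_names[labels + 1L],
                           source_id = rep(NA_character_, n),
                           operator_chain = rep("", n),
                           seed = rep(NA_integer_, n),
                           stringsAsFactors = FALSE)
  }
  structure(list(images = images, labels = labels,
                 class_names = as.character(class_names),
                 manifest = manifest),
            class = "leafcnn_image_set")
}

#' @export
print.leafcnn_image_set <- function(x, ...) {
  d <- if (length(x$images)) dim(x$images[[1]]) else c(0, 0, 0)
  cat(sprintf("<leafcnn_image_set: %d images (%dx%dx%d), %d classes>\n",
              length(x$images), d[1], d[2], d[3], length(x$class_names)))
  print(table(factor(x$class_names[x$labels + 1L], levels = x$class_names)))
  invisible(x)
}

#' @export
length.leafcnn_image_set <- function(x) length(x$images)

subset_image_set <- function(set, idx) {
  labeled_image_set(set$images[idx], set$labels[idx], set$class_names,
                    set$manifest[idx, , drop = FALSE])
}

#' Load a class-per-folder image directory
#'
#' Each subdirectory of `root` is one class; the vocabulary is the
#' alphabetically sorted subdirectory names and class ids are assigned in that
#' order starting at 0. Files with extensions `.ppm`/`.pgm`/`.pnm` are decoded;
#' other files are skipped with a warning, as are files that fail to decode.
#'
#' @param root directory containing one subdirectory per class.
#' @return a `leafcnn_image_set`.
#' @export
load_image_folder <- function(root) {
  if (!dir.exists(root)) stop_leafcnn("no such directory: ", root)
  dirs <- sort(list.dirs(root, full.names = FALSE, recursive = FALSE),
               method = "radix")
  if (length(dirs) == 0) stop_leafcnn("no class subdirectories under ", root)
  images <- list(); labels <- integer(); ids <- character()
  for (k in seq_along(dirs)) {
    files <- sort(list.files(file.path(root, dirs[k]), full.names = TRUE),
                  method = "radix")
    for (f in files) {
      if (!grepl("\\.(ppm|pgm|pnm)$", f, ignore.case = TRUE)) {
        warning("skipping non-image file: ", f)
        next
      }
      img <- tryCatch(read_pnm(f), error = function(e) {
        warning("skipping undecodable file ", f, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(img)) next
      images[[length(images) + 1L]] <- img
      labels <- c(labels, k - 1L)
      ids <- c(ids, f)
    }
  }
  if (length(images) == 0) stop_leafcnn("no decodable images under ", root)
  manifest <- data.frame(id = ids, class = dirs[labels + 1L],
                         source_id = ids, operator_chain = "",
                         seed = NA_integer_, stringsAsFactors = FALSE)
  labeled_image_set(images, labels, dirs, manifest)
}

#' Write a labeled image set as a class-per-folder PPM tree
#'
#' Also writes `manifest.tsv` (image_path, class, source_path, operator_chain,
#' seed) at `root`.
#'
#' @param set a `leafcnn_image_set`.
#' @param root output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_image_folder <- function(set, root) {
  stopifnot(inherits(set, "leafcnn_image_set"))
  paths <- character(length(set$images))
  for (i in seq_along(set$images)) {
    cls <- set$class_names[set$labels[i] + 1L]
    dir.create(file.path(root, cls), recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(root, cls, sprintf("img%06d.ppm", i))
    write_pnm(set$images[[i]], paths[i])
  }
  man <- data.frame(image_path = paths,
                    class = set$class_names[set$labels + 1L],
                    source_path = set$manifest$source_id,
                    operator_chain = set$manifest$operator_chain,
                    seed = set$manifest$seed,
                    stringsAsFactors = FALSE)
  utils::write.table(man, file.path(root, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(root)
}

#' Resize all images in a set
#'
#' Bicubic (Keys cubic-convolution) resampling to `target[1] x target[2]`;
#' images already at the target size are returned pixel-identical.
#'
#' @param set a `leafcnn_image_set`.
#' @param target `(height, width, channels)` triple; channels must be 3.
#' @return the resized `leafcnn_image_set`.
#' @export
resize_images <- function(set, target) {
  stopifnot(inherits(set, "leafcnn_image_set"))
  if (target[1] < 1 || target[2] < 1)
    stop_leafcnn("target height/width must be positive")
  set$images <- lapply(set$images, resize_image, h = target[1], w = target[2])
  set
}

# Seeded per-class 80/20 index split; exposed separately so the arithmetic can
# be exercised on label vectors alone.
split_indices <- function(labels, train_fraction, seed) {
  train_idx <- integer(0)
  for (k in sort(unique(labels))) {
    idx <- which(labels == k)
    n <- length(idx)
    if (n < 2)
      stop_leafcnn("every class needs >= 2 members; class id ", k, " has ", n)
    n_train <- round(train_fraction * n)
    take <- with_rng(mix_seed(seed, 977L, k),
                     sample(idx, n_train, replace = FALSE))
    train_idx <- c(train_idx, take)
  }
  sort(train_idx)
}

#' Stratified train/test split
#'
#' Splits each class independently: `round(train_fraction * n_c)` images go to
#' the training set, the remainder to the test set, sampled without
#' replacement under a deterministic seed. This guarantees every class is
#' represented in the test set.
#'
#' @param set a `leafcnn_image_set` with at least 2 images per class.
#' @param train_fraction fraction of each class used for training (default 0.8).
#' @param seed integer seed.
#' @return `list(train = , test = )` of `leafcnn_image_set`s.
#' @export
stratified_split <- function(set, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(set, "leafcnn_image_set"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_leafcnn("train_fraction must be in (0, 1)")
  tr <- split_indices(set$labels, train_fraction, seed)
  te <- setdiff(seq_along(set$labels), tr)
  list(train = subset_image_set(set, tr), test = subset_image_set(set, te))
}

# Stack a list of images (all same size) into an (H, W, 3, N) batch tensor.
stack_images <- function(images) {
  d <- dim(images[[1]])
  out <- array(0, c(d, length(images)))
  for (i in seq_along(images)) out[, , , i] <- images[[i]]
  out
}
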