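#' In-memory image representation
#'
#' Images are numeric arrays of dimension `H x W x 3` with values in `[0, 1]`.
#' Row index runs down the image, column index across; channels are R, G, B.
#' These helpers validate, read and write images in the NetPBM formats
#' (binary `P6`/`P5` and plain-text `P3`/`P2`), the only image container the
#' package depends on.
#'
#' @param image numeric `H x W x 3` array.
#' @return `as_leaf_image()` returns the validated array.
#' @keywords internal
as_leaf_image <- function(image) {
  if (is.matrix(image)) image <- array(rep(image, 3L), c(dim(image), 3L))
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop_leafcnn("image must be an H x W x 3 numeric array")
  if (!is.numeric(image)) stop_leafcnn("image must be numeric")
  image
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Read a NetPBM image file
#'
#' Supports binary (`P6` colour, `P5` grayscale) and plain-text (`P3`, `P2`)
#' variants with maxval up to 255. Grayscale images are replicated to three
#' identical channels.
#'
#' @param path file path to a `.ppm`/`.pgm` file.
#' @return an `H x W x 3` numeric array in `[0, 1]`.
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    # whitespace/comment-tolerant token scanner over the header
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0) stop_leafcnn("unexpected end of PNM header: ", path)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0 || ch == "\n") break
        }
      } else if (!grepl("[ \t\r\n]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0 || grepl("[ \t\r\n#]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop_leafcnn("not a supported PNM file (P2/P3/P5/P6): ", path)
  w <- as.integer(tok()); h <- as.integer(tok()); maxval <- as.integer(tok())
  if (anyNA(c(w, h, maxval)) || w < 1 || h < 1 || maxval < 1 || maxval > 255)
    stop_leafcnn("malformed PNM header in ", path)
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- as.numeric(w) * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
  } else {
    scan(con, what = numeric(), n = n, quiet = TRUE)
  }
  if (length(vals) != n) stop_leafcnn("truncated PNM payload in ", path)
  # file is row-major, pixel-interleaved; convert to (H, W, 3) column-major
  px <- matrix(vals, nrow = nch)
  img <- array(0, c(h, w, 3L))
  for (c in 1:3) {
    ch <- px[min(c, nch), ]
    img[, , c] <- matrix(ch, nrow = h, ncol = w, byrow = TRUE)
  }
  img / maxval
}

#' Write an image as binary PPM (`P6`, maxval 255)
#'
#' @param image `H x W x 3` numeric array in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pnm <- function(image, path) {
  image <- as_leaf_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  bytes <- round(clip01(image) * 255)
  # interleave channels row-major
  px <- rbind(t(matrix(bytes[, , 1], h, w)) |> as.vector(),
              t(matrix(bytes[, , 2], h, w)) |> as.vector(),
              t(matrix(bytes[, , 3], h, w)) |> as.vector())
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  writeBin(as.raw(as.vector(px)), con)
  invisible(path)
}

# --- colour space -----------------------------------------------------------

# Vectorised RGB <-> HSV on [0,1] arrays; hue on the [0,1) wheel.
rgb_to_hsv <- function(image) {
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- matrix(0, nrow(mx), ncol(mx))
  nz <- d > 0
  hr <- nz & mx == r
  hg <- nz & !hr & mx == g
  hb <- nz & !hr & !hg
  h[hr] <- ((g[hr] - b[hr]) / d[hr]) %% 6
  h[hg] <- (b[hg] - r[hg]) / d[hg] + 2
  h[hb] <- (r[hb] - g[hb]) / d[hb] + 4
  h <- h / 6
  s <- ifelse(mx > 0, d / mx, 0)
  array(c(h, s, mx), dim(image))
}

hsv_to_rgb <- function(hsv) {
  h <- (hsv[, , 1] %% 1) * 6; s <- hsv[, , 2]; v <- hsv[, , 3]
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- g <- b <- v
  m <- i == 0; r[m] <- v[m]; g[m] <- t[m]; b[m] <- p[m]
  m <- i == 1; r[m] <- q[m]; g[m] <- v[m]; b[m] <- p[m]
  m <- i == 2; r[m] <- p[m]; g[m] <- v[m]; b[m] <- t[m]
  m <- i == 3; r[m] <- p[m]; g[m] <- q[m]; b[m] <- v[m]
  m <- i == 4; r[m] <- t[m]; g[m] <- p[m]; b[m] <- v[m]
  m <- i == 5; r[m] <- v[m]; g[m] <- p[m]; b[m] <- q[m]
  array(c(r, g, b), dim(hsv))
}

# --- resampling -------------------------------------------------------------

# Keys cubic-convolution kernel, a = -0.5 (the classic bicubic kernel).
cubic_kernel <- function(x) {
  x <- abs(x)
  a <- -0.5
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

# Dense (n_out x n_in) separable resampling operator with edge clamping.
resample_matrix <- function(n_in, n_out, kernel = cubic_kernel, support = 2) {
  if (n_in == n_out) return(diag(n_out))
  scale <- n_in / n_out
  centers <- (seq_len(n_out) - 0.5) * scale + 0.5  # source coords, 1-based
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- floor(centers[i]) - support + 1
    js <- lo:(lo + 2 * support - 1)
    w <- kernel(centers[i] - js)
    js <- pmin(pmax(js, 1), n_in)  # clamp at edges
    for (k in seq_along(js)) M[i, js[k]] <- M[i, js[k]] + w[k]
    M[i, ] <- M[i, ] / sum(M[i, ])
  }
  M
}

# Bicubic resize of one image to (h, w); identity when sizes already match.
resize_image <- function(image, h, w) {
  image <- as_leaf_image(image)
  d <- dim(image)
  if (d[1] == h && d[2] == w) return(image)
  Mh <- resample_matrix(d[1], h)
  Mw <- t(resample_matrix(d[2], w))
  out <- array(0, c(h, w, 3L))
  for (c in 1:3) out[, , c] <- clip01(Mh %*% image[, , c] %*% Mw)
  out
}

# Inverse-mapped affine resample about the image centre, bilinear sampling,
# zero (black) fill outside the source footprint. `sx`/`sy` scale columns/rows,
# `theta_deg` rotates counter-clockwise in conventional x/y coordinates.
affine_warp <- function(image, sx = 1, sy = 1, theta_deg = 0) {
  image <- as_leaf_image(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- theta_deg * pi / 180
  # output pixel centres, centred coordinates (x right, y up)
  xo <- rep((seq_len(w)) - cx, each = h)
  yo <- rep(cy - (seq_len(h)), times = w)
  # inverse map: undo rotation, then undo scaling
  xs <- ( cos(th) * xo + sin(th) * yo) / sx
  ys <- (-sin(th) * xo + cos(th) * yo) / sy
  ci <- xs + cx          # source column (real-valued)
  ri <- cy - ys          # source row
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  out <- array(0, dim(image))
  sample_ch <- function(ch, rr, cc) {
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    v <- numeric(length(rr))
    v[ok] <- ch[cbind(rr[ok], cc[ok])]
    v
  }
  for (c in 1:3) {
    ch <- image[, , c]
    v <- sample_ch(ch, r0,     c0)     * (1 - fr) * (1 - fc) +
         sample_ch(ch, r0 + 1, c0)     * fr       * (1 - fc) +
         sample_ch(ch, r0,     c0 + 1) * (1 - fr) * fc +
         sample_ch(ch, r0 + 1, c0 + 1) * fr       * fc
    out[, , c] <- matrix(v, h, w)
  }
  out
}
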