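# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: metrics by per-sample counting, ANOVA via stats::aov,
# blur by brute-force 2-D convolution.

# Per-sample brute-force macro metric oracle for 0-based label vectors.
oracle_macro_metrics <- function(truth, pred, C) {
  rec <- prec <- f1 <- acc <- numeric(C)
  n <- length(truth)
  for (c in 0:(C - 1)) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    tn <- n - tp - fp - fn
    rec[c + 1] <- if (tp + fn > 0) tp / (tp + fn) else 0
    prec[c + 1] <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1[c + 1] <- if (rec[c + 1] + prec[c + 1] > 0)
      2 * rec[c + 1] * prec[c + 1] / (rec[c + 1] + prec[c + 1]) else 0
    acc[c + 1] <- (tp + tn) / n
  }
  list(macro_recall = mean(rec), macro_precision = mean(prec),
       macro_f1 = mean(f1), mean_accuracy = mean(acc),
       overall = mean(truth == pred))
}

# stats::aov as the independent two-way ANOVA oracle.
oracle_anova <- function(df) {
  fit <- stats::aov(value ~ a * b, data = df)
  s <- summary(fit)[[1]]
  list(ss = s[["Sum Sq"]], df = s[["Df"]], f = s[["F value"]][1:3],
       p = s[["Pr(>F)"]][1:3])
}

# Brute-force separable Gaussian blur with mirrored borders.
oracle_blur <- function(im, sigma) {
  r <- ceiling(3 * sigma)
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  n1 <- dim(im)[1]; n2 <- dim(im)[2]
  refl <- function(j, n) ifelse(j < 1, 1 - j, ifelse(j > n, 2 * n + 1 - j, j))
  out <- im
  for (c in 1:3) {
    tmp <- matrix(0, n1, n2)
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
      s <- 0
      for (a in -r:r) for (b in -r:r)
        s <- s + k[a + r + 1] * k[b + r + 1] * im[refl(i + a, n1), refl(j + b, n2), c]
      tmp[i, j] <- s
    }
    out[, , c] <- tmp
  }
  out
}

# Small flat test image with reproducible content.
toy_image <- function(h = 16, w = 16, seed = 1) {
  set.seed(seed)
  array(runif(h * w * 3), c(h, w, 3))
}

# Tiny on-disk class-per-folder tree of PPM images.
write_toy_tree <- function(root, classes = c("a", "b"), per_class = 3,
                           h = 8, w = 8, seed = 1) {
  i <- 0
  for (cl in classes) {
    dir.create(file.path(root, cl), recursive = TRUE, showWarnings = FALSE)
    for (j in seq_len(per_class)) {
      i <- i + 1
      write_pnm(toy_image(h, w, seed + i), file.path(root, cl, sprintf("%d.ppm", j)))
    }
  }
  root
}

# Balanced label shuffle: each true class receives every label equally often,
# so the permuted labels carry no learnable signal even at small n (a plain
# permutation leaves a contingency tilt that separable classes turn into
# above-chance accuracy).
balanced_shuffle <- function(labels, C, seed) {
  out <- labels
  set.seed(seed)
  for (k in 0:(C - 1)) {
    idx <- which(labels == k)
    out[idx] <- sample(rep(0:(C - 1), length.out = length(idx)))
  }
  out
}
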