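#' Training configuration
#'
#' Defaults follow the published regime: 2 epochs at learning rate 1e-4.
#' The optimizer is SGD with momentum 0.9 (the training toolbox default used
#' by the original experiments; the choice is recorded here so it can be
#' switched), batch size 32.
#'
#' @param epochs number of passes over the training set (>= 1).
#' @param learning_rate positive step size.
#' @param batch_size minibatch size (>= 1).
#' @param optimizer currently `"sgdm"` (SGD with momentum).
#' @param momentum momentum coefficient in `[0, 1)`.
#' @param seed integer seed controlling epoch shuffling.
#' @param log_every record one training-log row every this many iterations.
#' @return a `leafcnn_train_config`.
#' @export
train_config <- function(epochs = 2L, learning_rate = 1e-4, batch_size = 32L,
                         optimizer = "sgdm", momentum = 0.9, seed = 1L,
                         log_every = 1L) {
  if (!is_count(epochs, 1)) stop_leafcnn("epochs must be >= 1")
  if (!is.numeric(learning_rate) || learning_rate <= 0)
    stop_leafcnn("learning_rate must be > 0")
  if (!is_count(batch_size, 1)) stop_leafcnn("batch_size must be >= 1")
  if (!identical(optimizer, "sgdm")) stop_leafcnn("unsupported optimizer")
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 momentum = momentum, seed = as.integer(seed),
                 log_every = as.integer(log_every)),
            class = "leafcnn_train_config")
}

#' Train a network on a labeled image set
#'
#' Minimizes the multinomial cross-entropy with minibatch SGD (momentum),
#' with seeded per-epoch shuffling. Returns the trained network and a
#' training log: per-iteration training loss/accuracy and per-epoch
#' validation loss/accuracy (evaluation mode, i.e. batch-norm running
#' statistics). Fully reproducible given the config seed.
#'
#' @param network a `leafcnn_network` from [build_network()].
#' @param train_set,val_set `leafcnn_image_set`s whose vocabulary length
#'   matches the network's class count. `val_set` may be `NULL`.
#' @param config a `leafcnn_train_config`.
#' @return `list(model = trained leafcnn_network, log = leafcnn_train_log)`.
#' @export
train <- function(network, train_set, val_set = NULL, config = train_config()) {
  stopifnot(inherits(network, "leafcnn_network"),
            inherits(train_set, "leafcnn_image_set"),
            inherits(config, "leafcnn_train_config"))
  n_classes <- network$spec$num_classes
  if (length(train_set$class_names) != n_classes)
    stop_leafcnn("train set has ", length(train_set$class_names),
                 " classes but the network expects ", n_classes)
  if (!is.null(val_set) && length(val_set$class_names) != n_classes)
    stop_leafcnn("validation set class count mismatch")
  n <- length(train_set$images)
  if (n == 0) stop_leafcnn("empty training set")

  velocity <- lapply(network$params, function(p)
    if (is.null(p)) NULL else lapply(p, function(w) w * 0))
  it_rows <- list(); ep_rows <- list()
  iter <- 0L
  t0 <- proc.time()[["elapsed"]]
  for (ep in seq_len(config$epochs)) {
    ord <- with_rng(mix_seed(config$seed, 7001L, ep), sample.int(n))
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- stack_images(train_set$images[idx])
      yb <- train_set$labels[idx]
      fwd <- net_forward(network, xb, train = TRUE, labels = yb)
      network <- fwd$net  # batchnorm running statistics advanced
      grads <- net_backward(network, fwd, yb)
      for (i in seq_along(grads)) {
        if (is.null(grads[[i]])) next
        for (nm in names(grads[[i]])) {
          velocity[[i]][[nm]] <- config$momentum * velocity[[i]][[nm]] -
            config$learning_rate * grads[[i]][[nm]]
          network$params[[i]][[nm]] <- network$params[[i]][[nm]] +
            velocity[[i]][[nm]]
        }
      }
      iter <- iter + 1L
      if (iter %% config$log_every == 0L) {
        pred <- max.col(fwd$probs, ties.method = "first") - 1L
        it_rows[[length(it_rows) + 1L]] <- data.frame(
          epoch = ep, iteration = iter, loss = fwd$loss,
          accuracy = mean(pred == yb))
      }
    }
    if (!is.null(val_set) && length(val_set$images) > 0) {
      vp <- net_predict_probs(network, stack_images(val_set$images))
      vy <- val_set$labels
      vloss <- -mean(log(pmax(vp[cbind(seq_len(nrow(vp)), vy + 1L)], 1e-12)))
      vacc <- mean((max.col(vp, ties.method = "first") - 1L) == vy)
      ep_rows[[length(ep_rows) + 1L]] <- data.frame(
        epoch = ep, val_loss = vloss, val_accuracy = vacc)
    }
  }
  log <- structure(list(
    iterations = do.call(rbind, it_rows),
    epochs = if (length(ep_rows)) do.call(rbind, ep_rows) else NULL,
    wall_time_s = proc.time()[["elapsed"]] - t0),
    class = "leafcnn_train_log")
  list(model = network, log = log)
}

#' @export
print.leafcnn_train_log <- function(x, ...) {
  it <- x$iterations
  cat(sprintf("<training log: %d iterations, final loss %.4f, final acc %.3f>\n",
              nrow(it), it$loss[nrow(it)], it$accuracy[nrow(it)]))
  invisible(x)
}

#' Predict class labels and probabilities
#'
#' @param model a (trained) `leafcnn_network`.
#' @param images a `leafcnn_image_set`, a list of images, or an
#'   `(H, W, 3, N)` array matching the model input size.
#' @return `list(labels = 0-based predicted ids, probabilities = N x C
#'   matrix)`. Labels are the row-wise argmax; ties resolve to the lowest
#'   class id.
#' @export
predict_classes <- function(model, images) {
  stopifnot(inherits(model, "leafcnn_network"))
  x <- if (inherits(images, "leafcnn_image_set")) stack_images(images$images)
       else if (is.list(images)) stack_images(images)
       else images
  probs <- net_predict_probs(model, x)
  list(labels = max.col(probs, ties.method = "first") - 1L,
       probabilities = probs)
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS file holding the full network (spec, parameters,
#' batch-norm state) and round-trips through [predict_classes()].
#'
#' @param model a `leafcnn_network`.
#' @param path checkpoint path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "leafcnn_network"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "leafcnn_network")) stop_leafcnn("not a model checkpoint")
  model
}
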