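#' Experiment configuration
#'
#' Declarative description of one end-to-end run: generate or load data,
#' optionally augment, resize to the model input, split 80/20, train,
#' evaluate, and write all artifacts. Every source of randomness derives from
#' `seed`, so a config + seed pair fully reconstructs the run.
#'
#' @param model model name (`"N1"`, `"N2"`, `"N3"`).
#' @param data either a directory path of class-per-folder images or a list
#'   `list(num_classes =, per_class =, disease_mode =)` describing a
#'   synthetic dataset.
#' @param augmentation `"none"`, `"ad1"` or `"ad2"`.
#' @param input_size model input `(height, width, channels)`; default
#'   64x64x3, the desk-scale default (full 256x256 is opt-in).
#' @param train train configuration overrides (list passed to
#'   [train_config()]); `epochs`/`learning_rate` default to the published
#'   regime.
#' @param out_dir output directory, or `NULL` to skip writing artifacts.
#' @param seed integer root seed.
#' @return a `leafcnn_experiment_config`.
#' @export
experiment_config <- function(model = "N1",
                              data = list(num_classes = 9L, per_class = 100L,
                                          disease_mode = FALSE),
                              augmentation = "none",
                              input_size = c(64, 64, 3),
                              train = list(),
                              out_dir = NULL,
                              seed = 1L) {
  if (!model %in% c("N1", "N2", "N3"))
    stop_leafcnn("unregistered model: ", model, stage = "config")
  if (!augmentation %in% c("none", "ad1", "ad2"))
    stop_leafcnn("unregistered augmentation plan: ", augmentation,
                 stage = "config")
  tc <- do.call(train_config, c(train, list(seed = mix_seed(seed, 4L))))
  structure(list(model = model, data = data, augmentation = augmentation,
                 input_size = as.integer(input_size), train = tc,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "leafcnn_experiment_config")
}

with_stage <- function(stage, code) {
  tryCatch(code, error = function(e)
    stop_leafcnn(conditionMessage(e), stage = stage))
}

#' Run one end-to-end experiment
#'
#' Executes generate/load -> augment -> resize -> split -> train -> evaluate
#' and, when `out_dir` is set, writes the metric report (CSV + JSON), the
#' confusion matrix, the training log, a size report, and a manifest of all
#' seeds. Identical config + seed produce byte-identical metric reports.
#' Stage failures propagate with the stage name attached.
#'
#' @param config a `leafcnn_experiment_config`.
#' @return list with `metrics`, `confusion`, `model`, `log`, `size_report`,
#'   `split` and `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "leafcnn_experiment_config"))
  dataset <- with_stage("load", {
    if (is.character(config$data)) {
      load_image_folder(config$data)
    } else {
      generate_leaf_dataset(config$data$num_classes %||% 9L,
                            config$data$per_class %||% 100L,
                            image_size = config$input_size,
                            seed = mix_seed(config$seed, 1L),
                            disease_mode = isTRUE(config$data$disease_mode))
    }
  })
  dataset <- with_stage("augment", {
    plan <- augmentation_plan(config$augmentation,
                              seed = mix_seed(config$seed, 2L))
    expand_dataset(dataset, plan)
  })
  dataset <- with_stage("resize", resize_images(dataset, config$input_size))
  split <- with_stage("split",
                      stratified_split(dataset, 0.8, mix_seed(config$seed, 3L)))
  spec <- make_model_spec(config$model,
                          num_classes = length(dataset$class_names),
                          input_size = config$input_size)
  net <- build_network(spec, seed = mix_seed(config$seed, 5L))
  fit <- with_stage("train", train(net, split$train, split$test, config$train))
  res <- with_stage("evaluate", {
    pred <- predict_classes(fit$model, split$test)
    cm <- confusion_matrix(split$test$labels, pred$labels,
                           length(dataset$class_names), dataset$class_names)
    list(cm = cm, metrics = macro_metrics(cm))
  })
  srep <- size_report(spec, reference_size_bytes = 202 * 2^20)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_evaluation(res$metrics, res$cm, config$out_dir)
    if (!is.null(fit$log$iterations))
      write.csv(fit$log$iterations, file.path(config$out_dir, "training_log.csv"),
                row.names = FALSE)
    jsonlite::write_json(unclass(srep),
                         file.path(config$out_dir, "size_report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(model = config$model, augmentation = config$augmentation,
           input_size = config$input_size, seed = config$seed,
           derived_seeds = list(data = mix_seed(config$seed, 1L),
                                augmentation = mix_seed(config$seed, 2L),
                                split = mix_seed(config$seed, 3L),
                                train = config$train$seed,
                                init = mix_seed(config$seed, 5L))),
      file.path(config$out_dir, "run_manifest.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(metrics = res$metrics, confusion = res$cm, model = fit$model,
       log = fit$log, size_report = srep, split = split, config = config)
}

# ---------------------------------------------------------------------------
# Command-line interface. `leafcnn_cli(c(verb, "--key", "value", ...))`
# drives the same functions as the R API; the launcher script under
# inst/cli/leafcnn.R calls it with commandArgs(TRUE).

cli_args <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    key <- argv[i]
    if (!startsWith(key, "--")) stop_leafcnn("unexpected argument: ", key)
    key <- substring(key, 3)
    if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- argv[i + 1L]; i <- i + 2L
    }
  }
  out
}

cli_log <- function(...) message("[leafcnn] ", sprintf(...))

#' Command-line entry point
#'
#' Verbs: `generate-data`, `augment`, `split`, `train`, `evaluate`,
#' `validate`, `compare-sizes`, `anova`, `reproduce-tables`, `run`. All verbs
#' accept `--seed`; tabular outputs are written as CSV and JSON. See the
#' package README for examples.
#'
#' @param argv character vector of arguments (defaults to the process
#'   command line).
#' @return verb-dependent result, invisibly.
#' @export
leafcnn_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) stop_leafcnn("usage: leafcnn <verb> [--options]")
  verb <- argv[1]
  opt <- cli_args(argv[-1])
  seed <- as.integer(opt$seed %||% 1L)
  num <- function(x) as.numeric(x)
  res <- switch(verb,
    "generate-data" = {
      ds <- generate_leaf_dataset(as.integer(opt$classes %||% 9L),
                                  as.integer(opt[["per-class"]] %||% 100L),
                                  image_size = rep(as.integer(opt$size %||% 256L), 2) |> c(3L),
                                  seed = seed,
                                  disease_mode = isTRUE(opt$disease))
      write_image_folder(ds, opt$out %||% "leaf_data")
      cli_log("wrote %d images to %s", length(ds$images), opt$out %||% "leaf_data")
      invisible(ds)
    },
    "augment" = {
      ds <- load_image_folder(opt$data)
      plan <- augmentation_plan(opt$plan %||% "ad2", seed = seed)
      out <- expand_dataset(ds, plan)
      write_image_folder(out, opt$out %||% "augmented")
      cli_log("expanded %d -> %d images", length(ds$images), length(out$images))
      invisible(out)
    },
    "split" = {
      ds <- load_image_folder(opt$data)
      sp <- stratified_split(ds, num(opt$fraction %||% 0.8), seed)
      write_image_folder(sp$train, file.path(opt$out %||% "split", "train"))
      write_image_folder(sp$test, file.path(opt$out %||% "split", "test"))
      jsonlite::write_json(
        list(train = sp$train$manifest$id, test = sp$test$manifest$id),
        file.path(opt$out %||% "split", "split.json"), auto_unbox = TRUE)
      cli_log("split %d/%d", length(sp$train$images), length(sp$test$images))
      invisible(sp)
    },
    "train" = {
      ds <- load_image_folder(opt$data)
      size <- as.integer(opt$size %||% 64L)
      ds <- resize_images(ds, c(size, size, 3L))
      sp <- stratified_split(ds, 0.8, seed)
      spec <- make_model_spec(opt$model %||% "N1",
                              num_classes = length(ds$class_names),
                              input_size = c(size, size, 3L))
      cfg <- train_config(epochs = as.integer(opt$epochs %||% 2L),
                          learning_rate = num(opt$lr %||% 1e-4), seed = seed)
      fit <- train(build_network(spec, seed), sp$train, sp$test, cfg)
      save_model(fit$model, opt$out %||% "model.ckpt")
      write.csv(fit$log$iterations, paste0(opt$out %||% "model.ckpt", ".log.csv"),
                row.names = FALSE)
      cli_log("trained %s; checkpoint at %s", spec$name, opt$out %||% "model.ckpt")
      invisible(fit)
    },
    "evaluate" = ,
    "validate" = {
      model <- load_model(opt$model)
      ds <- load_image_folder(opt$data)
      ds <- resize_images(ds, model$spec$input_size)
      if (verb == "evaluate") {
        pred <- predict_classes(model, ds)
        cm <- confusion_matrix(ds$labels, pred$labels,
                               length(ds$class_names), ds$class_names)
        m <- macro_metrics(cm)
        write_evaluation(m, cm, opt$out %||% "evaluation")
        print(m)
        invisible(m)
      } else {
        tab <- per_class_validation_table(model, ds)
        write.csv(tab, opt$out %||% "validation.csv", row.names = FALSE)
        print(tab)
        invisible(tab)
      }
    },
    "compare-sizes" = {
      reps <- lapply(c("N1", "N2", "N3"), function(m)
        size_report(make_model_spec(m, as.integer(opt$classes %||% 9L)),
                    reference_size_bytes = 202 * 2^20))
      for (r in reps) print(r)
      jsonlite::write_json(lapply(reps, unclass),
                           opt$out %||% "size_reports.json",
                           auto_unbox = TRUE, digits = NA)
      invisible(reps)
    },
    "anova" = {
      an <- anova_from_fixture(opt$condition %||% "data")
      print(an)
      write_anova(an, opt$out %||% paste0("anova_", opt$condition %||% "data"))
      invisible(an)
    },
    "reproduce-tables" = {
      rep <- reproduce_printed_tables()
      cli_log("%d/%d published cells reproduced", sum(rep$pass), nrow(rep))
      if (!is.null(opt$out)) write.csv(rep, opt$out, row.names = FALSE)
      invisible(rep)
    },
    "run" = {
      cfg <- experiment_config(
        model = opt$model %||% "N1",
        data = if (!is.null(opt$data)) opt$data else
          list(num_classes = as.integer(opt$classes %||% 9L),
               per_class = as.integer(opt[["per-class"]] %||% 100L),
               disease_mode = isTRUE(opt$disease)),
        augmentation = opt$augmentation %||% "none",
        input_size = rep(as.integer(opt$size %||% 64L), 2) |> c(3L),
        out_dir = opt$out %||% "experiment",
        seed = seed)
      out <- run_experiment(cfg)
      print(out$metrics)
      invisible(out)
    },
    stop_leafcnn("unknown verb: ", verb))
  invisible(res)
}
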