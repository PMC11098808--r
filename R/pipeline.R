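#' End-to-end phantom pipeline configuration
#'
#' Aggregates the per-stage settings of a full run: generate phantoms,
#' augment, split, train, evaluate, summarize. One top-level seed fans
#' out to the stages at fixed offsets (+0 synth, +1 augment, +2 split,
#' +3 training shuffle, +4 weight init) so a single integer reproduces a
#' whole run.
#'
#' @param out_dir Output directory for every artifact.
#' @param seed Top-level integer seed.
#' @param phantom A [phantom_spec()] (its own seed is overridden by
#'   `seed`).
#' @param augment An [augment_policy()] (seed overridden likewise), or
#'   `NULL` to skip augmentation.
#' @param split A [split_config()] (seed overridden likewise).
#' @param training A [training_config()] (seed overridden likewise).
#' @param model A [resmini_config()]; `num_classes` must match the
#'   phantom class count.
#' @param leakage_safe If `TRUE`, split the originals first and augment
#'   only the training records; the default (`FALSE`) augments before
#'   splitting, reproducing the study design (which lets augmented
#'   copies reach the test set).
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 0L,
                       phantom = phantom_spec(),
                       augment = augment_policy(),
                       split = split_config(),
                       training = training_config(),
                       model = NULL,
                       leakage_safe = FALSE) {
  seed <- as.integer(seed)
  phantom$seed <- seed
  if (!is.null(augment)) augment$seed <- seed + 1L
  split$seed <- seed + 2L
  training$seed <- seed + 3L
  if (is.null(model))
    model <- resmini_config(input_height = phantom$image_height,
                            input_width = phantom$image_width,
                            num_classes = length(phantom$classes))
  if (model$num_classes != length(phantom$classes))
    stop("model num_classes must match phantom class count", call. = FALSE)
  structure(list(out_dir = out_dir, seed = seed, phantom = phantom,
                 augment = augment, split = split, training = training,
                 model = model, leakage_safe = isTRUE(leakage_safe)),
            class = "run_config")
}

#' Run the full phantom pipeline
#'
#' synth -> augment -> split -> train -> eval -> summary, writing every
#' artifact under `config$out_dir`: `manifest.csv`, `history.csv`,
#' `model.rds`, `confusion.csv`, `metrics.json`, `summary.json` and a
#' `provenance.json` recording the seeds and stage settings that
#' reproduce the run.
#'
#' @param config A [run_config()].
#' @param verbose Print a progress line every `verbose` epochs during
#'   training (0 = silent).
#' @return List with `manifest`, `model`, `history`, `evaluation`,
#'   `summary` and the artifact `paths`, invisibly.
#' @export
run_pipeline <- function(config, verbose = 0L) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(out, "images")

  mf <- generate_phantom_dataset(config$phantom, img_dir,
                                 file.path(out, "manifest.csv"))
  if (!is.null(config$augment)) {
    if (config$leakage_safe) {
      mf <- make_splits(mf, config$split)
      mf <- augment_training_only(mf, config$augment,
                                  file.path(img_dir, "augmented"))
    } else {
      mf <- augment_dataset(mf, config$augment,
                            file.path(img_dir, "augmented"))
      mf <- make_splits(mf, config$split)
    }
  } else {
    mf <- make_splits(mf, config$split)
  }
  write_manifest(mf, file.path(out, "manifest.csv"))

  model <- build_model(config$model, seed = config$seed + 4L)
  fit <- train(model,
               load_dataset(mf, "train"),
               load_dataset(mf, "val"),
               config$training, verbose = verbose)
  save_history(fit$history, file.path(out, "history.csv"))
  save_model(fit$model, file.path(out, "model.rds"))

  ev <- evaluate(fit$model, load_dataset(mf, "test"), mf$class_names)
  write_confusion_csv(ev$confusion, file.path(out, "confusion.csv"))
  jsonlite::write_json(
    list(accuracy = ev$metrics$accuracy,
         macro_recall = ev$metrics$macro_recall,
         macro_precision = ev$metrics$macro_precision,
         per_class_recall = as.numeric(ev$metrics$per_class_recall),
         per_class_precision = as.numeric(ev$metrics$per_class_precision),
         n_test = sum(ev$confusion)),
    file.path(out, "metrics.json"), auto_unbox = TRUE, digits = NA)

  summ <- count_parameters(layer_specs(config$model))
  rep <- comparison_report(
    c(resmini = summ$total_parameters,
      resnet18 = build_resnet18_baseline(config$model$num_classes)$total_parameters,
      bhcnet = bhcnet_total_parameters()),
    c(resmini = ev$metrics$accuracy, resnet18 = NA, bhcnet = NA))
  jsonlite::write_json(
    list(table = rep$table, ratio_percent = rep$ratio_percent,
         weighted_layer_count = summ$weighted_layer_count),
    file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)

  prov <- list(seed = config$seed,
               stage_seeds = list(synth = config$seed,
                                  augment = config$seed + 1L,
                                  split = config$seed + 2L,
                                  train_shuffle = config$seed + 3L,
                                  weight_init = config$seed + 4L),
               phantom = unclass(config$phantom),
               augment = if (is.null(config$augment)) NULL
                         else unclass(config$augment),
               split = unclass(config$split),
               training = unclass(config$training),
               model = unclass(config$model),
               leakage_safe = config$leakage_safe)
  prov$phantom$classes <- lapply(prov$phantom$classes, unclass)
  jsonlite::write_json(prov, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(manifest = mf, model = fit$model, history = fit$history,
                 evaluation = ev, summary = rep,
                 paths = file.path(out, c("manifest.csv", "history.csv",
                                          "model.rds", "confusion.csv",
                                          "metrics.json", "summary.json",
                                          "provenance.json"))))
}

#' Augment only the training records of a split manifest
#'
#' The leakage-safe variant of [augment_dataset()]: originals must
#' already carry split assignments; only `split == "train"` records are
#' augmented and the copies stay in the training set, so validation and
#' test sets contain no derived images.
#'
#' @param manifest A split-assigned [manifest()] of original records.
#' @param policy An [augment_policy()].
#' @param out_dir Directory for the augmented PNGs.
#' @param base_dir Directory that relative record paths resolve against.
#' @return The extended `slice_manifest`.
#' @export
augment_training_only <- function(manifest, policy = augment_policy(),
                                  out_dir, base_dir = NULL) {
  stopifnot(inherits(manifest, "slice_manifest"))
  rec <- manifest$records
  train_rec <- rec[rec$split == "train", , drop = FALSE]
  if (nrow(train_rec) == 0L)
    stop("no training records to augment", call. = FALSE)
  sub <- manifest(train_rec[, c("image_id", "path", "class_name",
                                "provenance", "source_id", "split")],
                  manifest$class_names, manifest$image_height,
                  manifest$image_width)
  sub$records$split <- "unassigned"
  aug <- augment_dataset(sub, policy, out_dir, base_dir)
  new_rec <- aug$records[aug$records$provenance == "augmented",
                         c("image_id", "path", "class_name", "provenance",
                           "source_id", "split")]
  new_rec$split <- "train"
  manifest(rbind(rec[, c("image_id", "path", "class_name", "provenance",
                         "source_id", "split")], new_rec),
           manifest$class_names, manifest$image_height,
           manifest$image_width)
}
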