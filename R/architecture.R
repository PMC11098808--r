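#' ResMini network configuration
#'
#' Describes the ResMini architecture symbolically: a stem Conv_BN_ReLU
#' (3x3, stride 1, padding 3) and 3x3/stride-2 max pool, four residual
#' modules whose widths double (`f, 2f, 4f, 8f`), global average pooling,
#' and a dense softmax head. The configuration is the single source of
#' truth for both model construction ([build_model()]) and closed-form
#' parameter counting ([count_parameters()]).
#'
#' @param input_channels Number of input image channels (1 for grayscale).
#' @param input_height,input_width Input slice size in pixels.
#' @param base_width Stem/first-module channel count `f`; module `i`
#'   outputs `f * 2^(i-1)` channels.
#' @param num_classes Number of target classes `K` (>= 2).
#' @param shortcut_policy `"projection_all"` places a 1x1 projection
#'   Conv_BN on every module shortcut; `"projection_on_downsample"` uses
#'   identity shortcuts where shape permits (module 1).
#' @param module_strides Integer stride (1 or 2) of the first convolution
#'   and the shortcut of each of the four modules.
#' @param count_bn_statistics If `TRUE`, batch-norm running mean/variance
#'   are included in parameter totals, matching the "total params"
#'   convention of deep-learning framework model summaries.
#' @return An object of class `resmini_config`.
#' @examples
#' cfg <- resmini_config()
#' weighted_layer_count(layer_specs(cfg))  # 10
#' @export
resmini_config <- function(input_channels = 1L,
                           input_height = 95L,
                           input_width = 79L,
                           base_width = 9L,
                           num_classes = 3L,
                           shortcut_policy = c("projection_all",
                                               "projection_on_downsample"),
                           module_strides = c(1L, 2L, 2L, 2L),
                           count_bn_statistics = TRUE) {
  shortcut_policy <- match.arg(shortcut_policy)
  base_width <- as.integer(base_width)
  num_classes <- as.integer(num_classes)
  input_channels <- as.integer(input_channels)
  module_strides <- as.integer(module_strides)
  if (is.na(base_width) || base_width < 1L)
    stop("base_width must be a positive integer", call. = FALSE)
  if (is.na(num_classes) || num_classes < 2L)
    stop("num_classes must be >= 2", call. = FALSE)
  if (input_channels < 1L)
    stop("input_channels must be >= 1", call. = FALSE)
  if (length(module_strides) != 4L || !all(module_strides %in% c(1L, 2L)))
    stop("module_strides must be four values in {1, 2}", call. = FALSE)
  structure(list(
    input_channels = input_channels,
    input_height = as.integer(input_height),
    input_width = as.integer(input_width),
    base_width = base_width,
    num_modules = 4L,
    num_classes = num_classes,
    shortcut_policy = shortcut_policy,
    module_strides = module_strides,
    count_bn_statistics = isTRUE(count_bn_statistics)
  ), class = "resmini_config")
}

#' @export
print.resmini_config <- function(x, ...) {
  cat("ResMini configuration\n")
  cat(sprintf("  input: %d x %d x %d (HxWxC)\n",
              x$input_height, x$input_width, x$input_channels))
  cat(sprintf("  base width f = %d; module widths %s\n", x$base_width,
              paste(x$base_width * 2L^(0:3), collapse = ", ")))
  cat(sprintf("  classes K = %d; shortcuts: %s\n",
              x$num_classes, x$shortcut_policy))
  invisible(x)
}

#' Read a network configuration from JSON or YAML
#'
#' The file holds keys mirroring the [resmini_config()] arguments
#' (`base_width`, `num_classes`, `input_height`, ...); unknown keys are
#' an error. YAML requires the `yaml` package.
#'
#' @param path A `.json`, `.yaml` or `.yml` file.
#' @return A [resmini_config()].
#' @export
read_resmini_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(resmini_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(resmini_config, vals)
}

layer_spec <- function(name, kind, in_channels = 0L, out_channels = 0L,
                       kernel_h = 0L, kernel_w = 0L, stride = 1L,
                       padding = 0L, has_bias = FALSE, path = "main") {
  list(name = name, kind = kind,
       in_channels = as.integer(in_channels),
       out_channels = as.integer(out_channels),
       kernel_h = as.integer(kernel_h), kernel_w = as.integer(kernel_w),
       stride = as.integer(stride), padding = as.integer(padding),
       has_bias = isTRUE(has_bias), path = path)
}

#' Symbolic layer plan of a ResMini network
#'
#' Expands a [resmini_config()] into the ordered list of layers:
#' stem Conv_BN_ReLU, max pool, four residual modules (two main-path
#' 3x3 Conv_BN_ReLU each, plus a 1x1 projection Conv_BN shortcut per the
#' shortcut policy, an add and an activation), global average pooling, a
#' dense layer with bias, and softmax. Convolutions followed by batch
#' norm carry no bias.
#'
#' @param config A [resmini_config()].
#' @return A list of layer specifications (class `resmini_plan`), each a
#'   list with fields `name`, `kind`, `in_channels`, `out_channels`,
#'   `kernel_h`, `kernel_w`, `stride`, `padding`, `has_bias`, `path`
#'   (`"main"` or `"shortcut"`).
#' @export
layer_specs <- function(config) {
  stopifnot(inherits(config, "resmini_config"))
  f <- config$base_width
  c0 <- config$input_channels
  K <- config$num_classes
  specs <- list(
    layer_spec("stem.conv", "conv2d", c0, f, 3L, 3L, 1L, 3L),
    layer_spec("stem.bn", "batchnorm", f, f),
    layer_spec("stem.relu", "activation", f, f),
    layer_spec("stem.maxpool", "maxpool", f, f, 3L, 3L, 2L, 1L)
  )
  in_ch <- f
  for (i in 1:4) {
    out_ch <- f * 2L^(i - 1L)
    s <- config$module_strides[i]
    pre <- sprintf("m%d", i)
    specs <- c(specs, list(
      layer_spec(paste0(pre, ".conv1"), "conv2d", in_ch, out_ch, 3L, 3L, s, 1L),
      layer_spec(paste0(pre, ".bn1"), "batchnorm", out_ch, out_ch),
      layer_spec(paste0(pre, ".relu1"), "activation", out_ch, out_ch),
      layer_spec(paste0(pre, ".conv2"), "conv2d", out_ch, out_ch, 3L, 3L, 1L, 1L),
      layer_spec(paste0(pre, ".bn2"), "batchnorm", out_ch, out_ch),
      layer_spec(paste0(pre, ".relu2"), "activation", out_ch, out_ch)
    ))
    project <- config$shortcut_policy == "projection_all" ||
      s != 1L || in_ch != out_ch
    if (project) {
      specs <- c(specs, list(
        layer_spec(paste0(pre, ".shortcut.conv"), "conv2d", in_ch, out_ch,
                   1L, 1L, s, 0L, path = "shortcut"),
        layer_spec(paste0(pre, ".shortcut.bn"), "batchnorm", out_ch, out_ch,
                   path = "shortcut")
      ))
    }
    specs <- c(specs, list(
      layer_spec(paste0(pre, ".add"), "add", out_ch, out_ch),
      layer_spec(paste0(pre, ".relu_out"), "activation", out_ch, out_ch)
    ))
    in_ch <- out_ch
  }
  specs <- c(specs, list(
    layer_spec("gap", "avgpool_global", in_ch, in_ch),
    layer_spec("dense", "dense", in_ch, K, has_bias = TRUE),
    layer_spec("softmax", "softmax", K, K)
  ))
  structure(specs, class = "resmini_plan")
}

params_of_spec <- function(spec, include_bn_statistics) {
  switch(spec$kind,
    conv2d = spec$kernel_h * spec$kernel_w * spec$in_channels *
      spec$out_channels + if (spec$has_bias) spec$out_channels else 0L,
    batchnorm = (if (include_bn_statistics) 4L else 2L) * spec$out_channels,
    dense = spec$in_channels * spec$out_channels + spec$out_channels,
    maxpool = 0L, avgpool_global = 0L, activation = 0L,
    softmax = 0L, add = 0L,
    stop(sprintf("unknown layer kind '%s'", spec$kind), call. = FALSE)
  )
}

#' Count parameters of a layer plan in closed form
#'
#' A convolution holds `kh * kw * c_in * c_out` weights (plus `c_out` if
#' biased); a batch-norm layer holds 2 trainable parameters per channel
#' (scale, shift) plus, when `include_bn_statistics`, 2 running statistics
#' per channel -- the convention used by framework "total params"
#' summaries. A dense layer holds `in * out + out`. Pooling, activations,
#' adds and softmax are parameter-free.
#'
#' @param specs A layer plan from [layer_specs()] (or any list of layer
#'   specifications with the same fields).
#' @param include_bn_statistics Count batch-norm running mean/variance?
#' @return A `model_summary`: list with `per_layer` (data frame of layer
#'   name, kind and parameter count), `total_parameters`, and
#'   `weighted_layer_count`.
#' @examples
#' summ <- count_parameters(layer_specs(resmini_config()))
#' summ$total_parameters
#' @export
count_parameters <- function(specs, include_bn_statistics = TRUE) {
  counts <- vapply(specs, params_of_spec, numeric(1),
                   include_bn_statistics = include_bn_statistics)
  per_layer <- data.frame(
    name = vapply(specs, `[[`, character(1), "name"),
    kind = vapply(specs, `[[`, character(1), "kind"),
    parameters = as.numeric(counts),
    stringsAsFactors = FALSE
  )
  structure(list(
    per_layer = per_layer,
    total_parameters = sum(counts),
    weighted_layer_count = weighted_layer_count(specs)
  ), class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  df <- x$per_layer[x$per_layer$parameters > 0, ]
  cat(sprintf("%-20s %-12s %12s\n", "layer", "kind", "parameters"))
  for (i in seq_len(nrow(df)))
    cat(sprintf("%-20s %-12s %12s\n", df$name[i], df$kind[i],
                format(df$parameters[i], big.mark = ",")))
  cat(sprintf("%-20s %-12s %12s\n", "total", "",
              format(x$total_parameters, big.mark = ",")))
  cat(sprintf("weighted layers: %d\n", x$weighted_layer_count))
  invisible(x)
}

#' Count weighted layers of a plan
#'
#' The network-depth convention behind names like "ResNet-18": main-path
#' convolutions and dense layers count; projection-shortcut convolutions,
#' batch norm, pooling and activations do not.
#'
#' @param specs A layer plan from [layer_specs()].
#' @return Integer count of weighted layers.
#' @export
weighted_layer_count <- function(specs) {
  sum(vapply(specs, function(s) {
    (s$kind == "conv2d" && s$path == "main") || s$kind == "dense"
  }, logical(1)))
}

#' Closed-form ResMini parameter total
#'
#' For `shortcut_policy = "projection_all"` with batch-norm statistics
#' counted, the total parameter count reduces to
#' `1195 f^2 + f (9 c0 + 184) + 8 f K + K` where `f` is the base width,
#' `c0` the input channel count and `K` the class count. Used as an
#' independent check against the per-layer sum.
#'
#' @param base_width,input_channels,num_classes As in [resmini_config()].
#' @return Numeric parameter total.
#' @export
resmini_parameter_formula <- function(base_width, input_channels = 1,
                                      num_classes = 3) {
  f <- base_width; c0 <- input_channels; K <- num_classes
  1195 * f^2 + f * (9 * c0 + 184) + 8 * f * K + K
}

#' Published parameter count of the BHCnet comparison network
#'
#' BHCnet is an externally defined small CNN used only as a
#' parameter-economy comparison point; its published total parameter
#' count is 196,595. The architecture itself is not reimplemented here.
#'
#' @return The published count, as a number.
#' @export
bhcnet_total_parameters <- function() 196595

#' Layer plan of a canonical 18-weighted-layer residual baseline
#'
#' The standard ResNet-18: 7x7/stride-2 stem (64 filters), 3x3/stride-2
#' max pool, four stages of two basic blocks (64, 128, 256, 512 channels;
#' stride 2 and a projection shortcut at the first block of stages 2-4),
#' global average pooling and a dense head. Used for parameter-economy
#' reporting only.
#'
#' @param num_classes Output class count (resizes the dense head).
#' @param input_channels Input channels (canonical: 3).
#' @return A layer plan as in [layer_specs()].
#' @export
resnet18_layer_specs <- function(num_classes = 3L, input_channels = 3L) {
  K <- as.integer(num_classes)
  if (is.na(K) || K < 2L) stop("num_classes must be >= 2", call. = FALSE)
  specs <- list(
    layer_spec("stem.conv", "conv2d", input_channels, 64L, 7L, 7L, 2L, 3L),
    layer_spec("stem.bn", "batchnorm", 64L, 64L),
    layer_spec("stem.relu", "activation", 64L, 64L),
    layer_spec("stem.maxpool", "maxpool", 64L, 64L, 3L, 3L, 2L, 1L)
  )
  widths <- c(64L, 128L, 256L, 512L)
  in_ch <- 64L
  for (stage in 1:4) {
    out_ch <- widths[stage]
    for (block in 1:2) {
      s <- if (stage > 1L && block == 1L) 2L else 1L
      pre <- sprintf("s%d.b%d", stage, block)
      specs <- c(specs, list(
        layer_spec(paste0(pre, ".conv1"), "conv2d", in_ch, out_ch, 3L, 3L, s, 1L),
        layer_spec(paste0(pre, ".bn1"), "batchnorm", out_ch, out_ch),
        layer_spec(paste0(pre, ".relu1"), "activation", out_ch, out_ch),
        layer_spec(paste0(pre, ".conv2"), "conv2d", out_ch, out_ch, 3L, 3L, 1L, 1L),
        layer_spec(paste0(pre, ".bn2"), "batchnorm", out_ch, out_ch)
      ))
      if (s != 1L || in_ch != out_ch) {
        specs <- c(specs, list(
          layer_spec(paste0(pre, ".shortcut.conv"), "conv2d", in_ch, out_ch,
                     1L, 1L, s, 0L, path = "shortcut"),
          layer_spec(paste0(pre, ".shortcut.bn"), "batchnorm", out_ch, out_ch,
                     path = "shortcut")
        ))
      }
      specs <- c(specs, list(
        layer_spec(paste0(pre, ".add"), "add", out_ch, out_ch),
        layer_spec(paste0(pre, ".relu_out"), "activation", out_ch, out_ch)
      ))
      in_ch <- out_ch
    }
  }
  specs <- c(specs, list(
    layer_spec("gap", "avgpool_global", 512L, 512L),
    layer_spec("dense", "dense", 512L, K, has_bias = TRUE),
    layer_spec("softmax", "softmax", K, K)
  ))
  structure(specs, class = "resmini_plan")
}

#' Parameter summary of the ResNet-18 baseline
#'
#' @inheritParams resnet18_layer_specs
#' @param include_bn_statistics Count batch-norm running statistics?
#' @return A `model_summary` as from [count_parameters()].
#' @export
build_resnet18_baseline <- function(num_classes = 3L, input_channels = 3L,
                                    include_bn_statistics = TRUE) {
  count_parameters(resnet18_layer_specs(num_classes, input_channels),
                   include_bn_statistics = include_bn_statistics)
}
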