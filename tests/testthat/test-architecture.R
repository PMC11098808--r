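test_that("layer plan matches the ResMini structure", {
  plan <- layer_specs(resmini_config())
  kinds <- vapply(plan, `[[`, character(1), "kind")
  names <- vapply(plan, `[[`, character(1), "name")
  expect_identical(names[1:4],
                   c("stem.conv", "stem.bn", "stem.relu", "stem.maxpool"))
  expect_identical(names[length(names)], "softmax")
  # two main convs per module plus one projection shortcut conv each
  expect_equal(sum(kinds == "conv2d"), 1 + 4 * 3)
  # stem conv exactly as printed: 3x3, stride 1, padding 3
  stem <- plan[[1]]
  expect_equal(c(stem$kernel_h, stem$kernel_w, stem$stride, stem$padding),
               c(3, 3, 1, 3))
  # max pool 3x3, stride 2, padding 1
  mp <- plan[[4]]
  expect_equal(c(mp$kernel_h, mp$stride, mp$padding), c(3, 2, 1))
  # width-doubling rule
  out_w <- vapply(plan[kinds == "conv2d" &
                         grepl("conv2$", names)], `[[`, numeric(1),
                  "out_channels")
  expect_equal(out_w, 9 * c(1, 2, 4, 8))
})

test_that("width-doubling holds for a minimal f=1 plan and K resizes the head", {
  plan1 <- layer_specs(resmini_config(base_width = 1))
  convs <- Filter(function(s) s$kind == "conv2d" && grepl("conv2$", s$name),
                  plan1)
  expect_equal(vapply(convs, `[[`, numeric(1), "out_channels"),
               c(1, 2, 4, 8))
  plan4 <- layer_specs(resmini_config(num_classes = 4))
  dense <- Filter(function(s) s$kind == "dense", plan4)[[1]]
  expect_equal(dense$out_channels, 4)
  expect_equal(dense$in_channels, 8 * 9)
})

test_that("invalid configurations are rejected", {
  expect_error(resmini_config(base_width = 0), "base_width")
  expect_error(resmini_config(num_classes = 1), "num_classes")
  expect_error(resmini_config(module_strides = c(1, 2, 3, 2)), "strides")
  expect_error(count_parameters(list(list(name = "x", kind = "wavelet"))),
               "unknown layer kind")
})

test_that("per-layer parameter counting follows the closed rules", {
  conv <- list(name = "c", kind = "conv2d", in_channels = 1L,
               out_channels = 8L, kernel_h = 3L, kernel_w = 3L,
               stride = 1L, padding = 1L, has_bias = FALSE, path = "main")
  expect_equal(count_parameters(list(conv))$total_parameters, 72)
  bn <- list(name = "b", kind = "batchnorm", in_channels = 8L,
             out_channels = 8L, path = "main")
  expect_equal(count_parameters(list(conv, bn))$total_parameters, 104)
  expect_equal(count_parameters(list(conv, bn),
                                include_bn_statistics = FALSE)$total_parameters,
               72 + 16)
  dense <- list(name = "d", kind = "dense", in_channels = 72L,
                out_channels = 3L, has_bias = TRUE, path = "main")
  expect_equal(count_parameters(list(dense))$total_parameters, 72 * 3 + 3)
})

test_that("closed-form total equals the per-layer sum across configurations", {
  for (f in c(1, 2, 4, 8, 9, 16)) {
    for (c0 in c(1, 3)) {
      for (K in c(3, 4)) {
        cfg <- resmini_config(base_width = f, input_channels = c0,
                              num_classes = K)
        expect_equal(count_parameters(layer_specs(cfg))$total_parameters,
                     resmini_parameter_formula(f, c0, K),
                     info = sprintf("f=%d c0=%d K=%d", f, c0, K))
      }
    }
  }
})

test_that("reference configuration counts 98,751 parameters and 10 layers", {
  summ <- count_parameters(layer_specs(resmini_config()))
  expect_equal(summ$total_parameters, 98751)
  expect_equal(summ$weighted_layer_count, 10)
  expect_equal(sum(summ$per_layer$parameters), summ$total_parameters)
  expect_true(all(summ$per_layer$parameters >= 0))
})

test_that("parameter totals increase strictly in base width and class count", {
  tot <- function(f, K) count_parameters(
    layer_specs(resmini_config(base_width = f,
                               num_classes = K)))$total_parameters
  f_tot <- vapply(c(1, 2, 4, 8, 9, 16), tot, numeric(1), K = 3)
  expect_true(all(diff(f_tot) > 0))
  k_tot <- vapply(2:6, function(K) tot(9, K), numeric(1))
  expect_true(all(diff(k_tot) > 0))
})

test_that("weighted-layer convention counts main convs and dense only", {
  expect_equal(weighted_layer_count(layer_specs(resmini_config())), 10)
  # a stem + dense plan alone is depth 2
  stem_dense <- list(
    list(name = "stem", kind = "conv2d", path = "main"),
    list(name = "dense", kind = "dense", path = "main"))
  expect_equal(weighted_layer_count(stem_dense), 2)
  expect_equal(weighted_layer_count(resnet18_layer_specs(3)), 18)
})

test_that("ResNet-18 baseline dwarfs ResMini in parameters", {
  base <- build_resnet18_baseline(3)
  expect_equal(base$weighted_layer_count, 18)
  # order of magnitude of the canonical 11.2M-parameter network
  expect_gt(base$total_parameters, 1e7)
  expect_lt(base$total_parameters, 1.3e7)
  resmini <- count_parameters(layer_specs(resmini_config()))
  expect_lte(resmini$total_parameters, base$total_parameters)
})

test_that("configurations load from JSON and YAML files", {
  jp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(base_width = 4, num_classes = 4), jp,
                       auto_unbox = TRUE)
  cfg <- read_resmini_config(jp)
  expect_equal(cfg$base_width, 4L)
  expect_equal(cfg$num_classes, 4L)
  yp <- tempfile(fileext = ".yaml")
  writeLines(c("base_width: 2", "num_classes: 3"), yp)
  cfg2 <- read_resmini_config(yp)
  expect_equal(cfg2$base_width, 2L)
  jsonlite::write_json(list(frobnicate = 1), jp, auto_unbox = TRUE)
  expect_error(read_resmini_config(jp), "unknown config keys")
  unlink(c(jp, yp))
})

test_that("shortcut policy controls the projection convolutions", {
  plan <- layer_specs(resmini_config(
    shortcut_policy = "projection_on_downsample"))
  sc <- Filter(function(s) s$path == "shortcut" && s$kind == "conv2d", plan)
  expect_equal(length(sc), 3)  # module 1 keeps the identity shortcut
  full <- layer_specs(resmini_config())
  sc_all <- Filter(function(s) s$path == "shortcut" && s$kind == "conv2d",
                   full)
  expect_equal(length(sc_all), 4)
})
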