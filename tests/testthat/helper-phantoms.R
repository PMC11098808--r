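# Shared fixture builders; everything is generated in code at test time.

# a phantom manifest on disk mirroring the study's pre-augmentation
# composition when per_class = c(65, 57, 33)
make_phantom_manifest <- function(dir, per_class = c(4L, 4L, 4L),
                                  seed = 1L, separation = 1,
                                  noise_sd = 0.02,
                                  height = 95L, width = 79L) {
  spec <- phantom_spec(samples_per_class = per_class, seed = seed,
                       separation = separation, noise_sd = noise_sd,
                       image_height = height, image_width = width)
  generate_phantom_dataset(spec, dir)
}

# stratified train/test index split of an in-memory phantom array set
split_arrays <- function(dat, test_per_class, seed = 1L) {
  set.seed(seed)
  classes <- sort(unique(dat$y))
  test_i <- unlist(lapply(classes, function(k) {
    sample(which(dat$y == k), test_per_class)
  }))
  train_i <- setdiff(seq_along(dat$y), test_i)
  list(train = list(x = dat$x[, , , train_i, drop = FALSE],
                    y = dat$y[train_i]),
       test = list(x = dat$x[, , , test_i, drop = FALSE],
                   y = dat$y[test_i]))
}

# age morphologies scaled down for small test slices (default 32 x 28)
small_morphologies <- function() {
  list(
    "age3-5" = class_morphology(c(0.44, 0.40), 3, 1.5, 0.55),
    "age7-12" = class_morphology(c(0.42, 0.38), 2, 3, 0.50),
    "adult" = class_morphology(c(0.39, 0.35), 1, 4.5, 0.45)
  )
}

# in-memory small phantom set used by training-contract tests
small_phantoms <- function(n_per_class, seed, noise_sd = 0.05,
                           separation = 1.5) {
  generate_phantom_arrays(phantom_spec(
    classes = small_morphologies(),
    samples_per_class = rep(n_per_class, 3), image_height = 32L,
    image_width = 28L, noise_sd = noise_sd, separation = separation,
    seed = seed))
}

# records data frame with given per-class sizes (no images behind it)
make_records <- function(class_sizes) {
  do.call(rbind, lapply(names(class_sizes), function(cl) {
    n <- class_sizes[[cl]]
    data.frame(image_id = sprintf("%s_%03d", cl, seq_len(n)),
               path = sprintf("%s_%03d.png", cl, seq_len(n)),
               class_name = cl, provenance = "original",
               source_id = sprintf("%s_%03d", cl, seq_len(n)),
               split = "unassigned", stringsAsFactors = FALSE)
  }))
}
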