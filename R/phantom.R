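#' Class morphology for brain-slice phantoms
#'
#' A phantom class is an elliptical "brain" of a given mean intensity
#' with a brighter cortical ring and a dark central ventricle disc. The
#' age signal of real data is mimicked qualitatively: older classes get
#' larger ventricles, thinner cortex and slightly smaller brains
#' (atrophy), which is exactly the kind of morphological contrast the
#' network must learn.
#'
#' @param brain_axes Ellipse semi-axes as fractions of image height and
#'   width.
#' @param cortical_ring_thickness Ring thickness in pixels.
#' @param ventricle_radius Central dark-disc radius in pixels; must fit
#'   inside the brain ellipse.
#' @param mean_intensity Brain tissue intensity in `[0, 1]`.
#' @return An object of class `class_morphology`.
#' @export
class_morphology <- function(brain_axes = c(0.42, 0.38),
                             cortical_ring_thickness = 5,
                             ventricle_radius = 7,
                             mean_intensity = 0.5) {
  structure(list(brain_axes = brain_axes,
                 cortical_ring_thickness = cortical_ring_thickness,
                 ventricle_radius = ventricle_radius,
                 mean_intensity = mean_intensity),
            class = "class_morphology")
}

default_age_morphologies <- function() {
  list(
    "age3-5" = class_morphology(c(0.44, 0.40), 7, 3, 0.55),
    "age7-12" = class_morphology(c(0.42, 0.38), 5, 7, 0.50),
    "adult" = class_morphology(c(0.39, 0.35), 3, 11, 0.45)
  )
}

#' Phantom dataset specification
#'
#' Defaults mirror the study's pre-augmentation material: 95 x 79
#' single-channel slices, three age classes with 65/57/33 samples (155
#' in total), moderate Gaussian noise. `separation` scales every class's
#' morphological difference from the across-class mean: 1 reproduces the
#' designed contrast, 0 makes all classes identically distributed (a
#' negative control for pipeline leakage).
#'
#' @param classes Named list of [class_morphology()] objects.
#' @param samples_per_class Integer vector aligned with `classes`.
#' @param image_height,image_width Slice size in pixels.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param separation Class-contrast scale factor, `>= 0`.
#' @param seed Integer seed; generation is fully deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(classes = default_age_morphologies(),
                         samples_per_class = c(65L, 57L, 33L),
                         image_height = 95L, image_width = 79L,
                         noise_sd = 0.05, separation = 1, seed = 0L) {
  if (length(samples_per_class) != length(classes))
    stop("samples_per_class must align with classes", call. = FALSE)
  if (any(samples_per_class < 1L))
    stop("each class needs at least one sample", call. = FALSE)
  if (noise_sd < 0 || separation < 0)
    stop("noise_sd and separation must be >= 0", call. = FALSE)
  if (is.null(names(classes)))
    names(classes) <- paste0("class", seq_along(classes))
  structure(list(classes = classes,
                 samples_per_class = as.integer(samples_per_class),
                 image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 noise_sd = noise_sd, separation = separation,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# morphology blended toward the across-class mean by the separation factor
effective_morphology <- function(spec, class_index) {
  ms <- spec$classes
  ref <- list(
    brain_axes = rowMeans(vapply(ms, `[[`, numeric(2), "brain_axes")),
    cortical_ring_thickness =
      mean(vapply(ms, `[[`, numeric(1), "cortical_ring_thickness")),
    ventricle_radius = mean(vapply(ms, `[[`, numeric(1),
                                   "ventricle_radius")),
    mean_intensity = mean(vapply(ms, `[[`, numeric(1), "mean_intensity"))
  )
  m <- ms[[class_index]]
  s <- spec$separation
  class_morphology(
    brain_axes = ref$brain_axes + s * (m$brain_axes - ref$brain_axes),
    cortical_ring_thickness = ref$cortical_ring_thickness +
      s * (m$cortical_ring_thickness - ref$cortical_ring_thickness),
    ventricle_radius = ref$ventricle_radius +
      s * (m$ventricle_radius - ref$ventricle_radius),
    mean_intensity = ref$mean_intensity +
      s * (m$mean_intensity - ref$mean_intensity)
  )
}

#' Render one phantom slice
#'
#' Deterministic geometry plus additive Gaussian noise from R's current
#' random stream, clipped to `[0, 1]`. Background is 0; the cortical
#' ring is brighter and the ventricle darker than the brain mean.
#'
#' @param morphology A [class_morphology()].
#' @param image_height,image_width Output size in pixels.
#' @param noise_sd Gaussian noise standard deviation (0 = noiseless).
#' @return A numeric matrix in `[0, 1]`.
#' @export
phantom_image <- function(morphology, image_height = 95L,
                          image_width = 79L, noise_sd = 0) {
  H <- image_height; W <- image_width
  ay <- morphology$brain_axes[1] * H
  ax <- morphology$brain_axes[2] * W
  if (morphology$ventricle_radius >= min(ay, ax))
    stop("ventricle does not fit inside the brain ellipse", call. = FALSE)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  d2 <- ((r - cy) / ay)^2 + ((cc - cx) / ax)^2
  img <- matrix(0, H, W)
  inside <- d2 <= 1
  img[inside] <- morphology$mean_intensity
  ring_frac <- morphology$cortical_ring_thickness / min(ay, ax)
  ring <- inside & sqrt(d2) >= 1 - ring_frac
  img[ring] <- pmin(1, morphology$mean_intensity * 1.6)
  vent <- (r - cy)^2 + (cc - cx)^2 <= morphology$ventricle_radius^2
  img[vent & inside] <- morphology$mean_intensity * 0.25
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(H * W, sd = noise_sd), H, W)
  pmin(pmax(img, 0), 1)
}

#' Render a phantom volume
#'
#' A stack of `depth` planes whose middle plane carries the designed
#' morphology at full intensity while outer planes fade out, so that
#' [extract_middle_axial_slice()] recovers the designed pattern.
#'
#' @param morphology A [class_morphology()].
#' @param depth Number of axial planes.
#' @param image_height,image_width Plane size in pixels.
#' @param noise_sd Per-plane Gaussian noise standard deviation.
#' @return A numeric array `(H, W, depth)`.
#' @export
phantom_volume <- function(morphology, depth, image_height = 95L,
                           image_width = 79L, noise_sd = 0) {
  stopifnot(depth >= 1L)
  base <- phantom_image(morphology, image_height, image_width, 0)
  mid <- depth %/% 2L + 1L
  vol <- array(0, c(image_height, image_width, depth))
  for (k in seq_len(depth)) {
    fade <- if (k == mid) 1 else exp(-abs(k - mid) / max(1, depth / 4))
    plane <- base * fade
    if (noise_sd > 0)
      plane <- pmin(pmax(plane + matrix(
        stats::rnorm(length(base), sd = noise_sd),
        image_height, image_width), 0), 1)
    vol[, , k] <- plane
  }
  vol
}

#' Generate a phantom dataset in memory
#'
#' Per-class phantom slices stacked into a model-ready batch;
#' deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `x` (array `(H, W, 1, N)`), `y` (0-based labels),
#'   `class_names`.
#' @export
generate_phantom_arrays <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  N <- sum(spec$samples_per_class)
  x <- array(0, c(spec$image_height, spec$image_width, 1L, N))
  y <- integer(N)
  n <- 0L
  for (ci in seq_along(spec$classes)) {
    morph <- effective_morphology(spec, ci)
    for (s in seq_len(spec$samples_per_class[ci])) {
      n <- n + 1L
      x[, , 1L, n] <- phantom_image(morph, spec$image_height,
                                    spec$image_width, spec$noise_sd)
      y[n] <- ci - 1L
    }
  }
  list(x = x, y = y, class_names = names(spec$classes))
}

#' Generate a phantom dataset on disk
#'
#' Writes one PNG per sample plus a manifest CSV; file contents are
#' identical across runs with the same spec (the 8-bit quantization is
#' deterministic).
#'
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory (created if needed).
#' @param manifest_path Manifest CSV path (default
#'   `file.path(out_dir, "manifest.csv")`).
#' @return The [manifest()], invisibly; PNGs and the CSV are on disk.
#' @export
generate_phantom_dataset <- function(spec, out_dir,
                                     manifest_path = file.path(out_dir,
                                                               "manifest.csv")) {
  stopifnot(inherits(spec, "phantom_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dat <- generate_phantom_arrays(spec)
  class_names <- dat$class_names
  N <- length(dat$y)
  rows <- vector("list", N)
  for (i in seq_len(N)) {
    cl <- class_names[dat$y[i] + 1L]
    id <- sprintf("%s_%03d", cl, sum(dat$y[seq_len(i)] == dat$y[i]))
    path <- file.path(out_dir, paste0(id, ".png"))
    write_slice_png(dat$x[, , 1L, i], path)
    rows[[i]] <- data.frame(image_id = id, path = path, class_name = cl,
                            provenance = "original", source_id = id,
                            split = "unassigned", stringsAsFactors = FALSE)
  }
  mf <- manifest(do.call(rbind, rows), class_names,
                 spec$image_height, spec$image_width)
  write_manifest(mf, manifest_path)
  invisible(mf)
}
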