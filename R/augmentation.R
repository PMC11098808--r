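#' Augmentation policy
#'
#' Describes the dataset-doubling augmentation: each original image gets
#' `copies_per_image` augmented variants, each produced by a random
#' integer-pixel offset (uniform in `[-max_offset_fraction * dim,
#' +max_offset_fraction * dim]` per axis) followed, when `flip`, by a
#' horizontal flip. With the default single copy per image the dataset
#' size exactly doubles.
#'
#' @param max_offset_fraction Maximum offset per axis as a fraction of
#'   the image dimension; must satisfy `0 <= f < 0.5`.
#' @param flip Apply a horizontal flip to every augmented copy?
#' @param copies_per_image Augmented variants per original.
#' @param fill_value Intensity written into vacated pixels (0 = the dark
#'   background of brain slices).
#' @param seed Integer seed making augmentation deterministic.
#' @return An object of class `augment_policy`.
#' @export
augment_policy <- function(max_offset_fraction = 0.1, flip = TRUE,
                           copies_per_image = 1L, fill_value = 0,
                           seed = 0L) {
  if (max_offset_fraction < 0 || max_offset_fraction >= 0.5)
    stop("max_offset_fraction must be in [0, 0.5)", call. = FALSE)
  if (copies_per_image < 1L)
    stop("copies_per_image must be >= 1", call. = FALSE)
  structure(list(max_offset_fraction = max_offset_fraction,
                 flip = isTRUE(flip),
                 copies_per_image = as.integer(copies_per_image),
                 fill_value = fill_value,
                 seed = as.integer(seed)),
            class = "augment_policy")
}

#' Translate an image by whole pixels
#'
#' Shifts content right by `dx` columns and down by `dy` rows (negative
#' values shift left/up); vacated pixels receive `fill_value`. Shape is
#' preserved.
#'
#' @param image A 2D numeric matrix.
#' @param dx,dy Integer offsets in pixels; must be smaller in magnitude
#'   than the image width/height.
#' @param fill_value Intensity for vacated pixels.
#' @return The translated matrix.
#' @export
offset_image <- function(image, dx, dy, fill_value = 0) {
  stopifnot(is.matrix(image))
  h <- nrow(image); w <- ncol(image)
  dx <- as.integer(dx); dy <- as.integer(dy)
  if (abs(dx) >= w || abs(dy) >= h)
    stop("offset exceeds image bounds", call. = FALSE)
  out <- matrix(fill_value, h, w)
  src_rows <- max(1L, 1L - dy):min(h, h - dy)
  src_cols <- max(1L, 1L - dx):min(w, w - dx)
  out[src_rows + dy, src_cols + dx] <- image[src_rows, src_cols]
  out
}

#' Flip an image about its vertical midline
#'
#' Reverses column order; applying it twice is the identity.
#'
#' @param image A 2D numeric matrix.
#' @return The mirrored matrix.
#' @export
horizontal_flip <- function(image) {
  stopifnot(is.matrix(image))
  image[, rev(seq_len(ncol(image))), drop = FALSE]
}

# one augmented variant per the policy; rng must already be seeded
augment_once <- function(image, policy) {
  h <- nrow(image); w <- ncol(image)
  mx <- floor(policy$max_offset_fraction * w)
  my <- floor(policy$max_offset_fraction * h)
  dx <- if (mx > 0) sample(seq.int(-mx, mx), 1L) else 0L
  dy <- if (my > 0) sample(seq.int(-my, my), 1L) else 0L
  out <- offset_image(image, dx, dy, policy$fill_value)
  if (policy$flip) out <- horizontal_flip(out)
  out
}

#' Augment every original image of a manifest
#'
#' Reads each original record's PNG, produces `copies_per_image`
#' offset-and-flip variants ([offset_image()], [horizontal_flip()]),
#' writes them to `out_dir` and returns the manifest extended with the
#' augmented records (provenance `"augmented"`, `source_id` pointing at
#' the original, label copied). With the default policy the record count
#' exactly doubles and per-class counts double with it. Deterministic
#' given `policy$seed`.
#'
#' @param manifest A [manifest()] whose records are all originals (a
#'   record that is already augmented is an error).
#' @param policy An [augment_policy()].
#' @param out_dir Directory for the augmented PNGs (created if needed).
#' @param base_dir Directory that relative record paths resolve against.
#' @return The extended `slice_manifest`.
#' @export
augment_dataset <- function(manifest, policy = augment_policy(),
                            out_dir, base_dir = NULL) {
  stopifnot(inherits(manifest, "slice_manifest"),
            inherits(policy, "augment_policy"))
  rec <- manifest$records
  if (any(rec$provenance != "original"))
    stop("augment_dataset expects only original records", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(policy$seed)
  new_rows <- vector("list", nrow(rec) * policy$copies_per_image)
  k <- 0L
  for (i in seq_len(nrow(rec))) {
    p <- rec$path[i]
    if (!is.null(base_dir) && !file.exists(p)) p <- file.path(base_dir, p)
    img <- read_slice_png(p)
    for (copy in seq_len(policy$copies_per_image)) {
      aug <- augment_once(img, policy)
      id <- sprintf("%s_aug%d", rec$image_id[i], copy)
      path <- file.path(out_dir, paste0(id, ".png"))
      write_slice_png(aug, path)
      k <- k + 1L
      new_rows[[k]] <- data.frame(
        image_id = id, path = path, class_name = rec$class_name[i],
        provenance = "augmented", source_id = rec$image_id[i],
        split = "unassigned", stringsAsFactors = FALSE)
    }
  }
  all_rec <- rbind(rec[, c("image_id", "path", "class_name", "provenance",
                           "source_id", "split")],
                   do.call(rbind, new_rows))
  manifest(all_rec, manifest$class_names, manifest$image_height,
           manifest$image_width)
}
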