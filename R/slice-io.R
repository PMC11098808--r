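#' Extract the 2D axial middle slice of a volume
#'
#' Returns the plane at 0-based index `floor(D / 2)` along the axial
#' axis, i.e. slice `D %/% 2 + 1` in R's 1-based indexing. For 4D input
#' (e.g. an fMRI series) the first time frame is taken before slicing.
#'
#' @param volume A 3D or 4D numeric array (or an object coercible to one,
#'   such as an `RNifti` image).
#' @param axial_axis Which of the three spatial axes is
#'   superior-inferior; defaults to the third, the usual NIfTI layout.
#' @return A 2D matrix: the two non-axial spatial dimensions, in order.
#' @examples
#' v <- array(rep(0:9, each = 16), c(4, 4, 10))
#' unique(as.vector(extract_middle_axial_slice(v)))  # 5 = floor(10/2)
#' @export
extract_middle_axial_slice <- function(volume, axial_axis = 3L) {
  volume <- unclass(volume)
  d <- dim(volume)
  if (is.null(d) || length(d) < 3L)
    stop("volume must have at least 3 axes", call. = FALSE)
  if (length(d) > 4L)
    stop("volume must be 3D or 4D", call. = FALSE)
  if (length(d) == 4L) {
    volume <- volume[, , , 1L, drop = FALSE]
    dim(volume) <- d[1:3]
    d <- d[1:3]
  }
  if (!(axial_axis %in% 1:3))
    stop("axial_axis must be 1, 2 or 3", call. = FALSE)
  if (d[axial_axis] < 1L)
    stop("axial axis has zero extent", call. = FALSE)
  mid <- d[axial_axis] %/% 2L + 1L
  idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx[[axial_axis]] <- mid
  out <- do.call(`[`, c(list(volume), idx, list(drop = FALSE)))
  dim(out) <- d[-axial_axis]
  out
}

#' Min-max normalize image intensities to [0, 1]
#'
#' Per-image rescaling; a constant image maps to all zeros (documented
#' convention). Idempotent on images already spanning `[0, 1]`.
#'
#' @param image A numeric matrix or array with finite values.
#' @return The rescaled image, same shape.
#' @export
normalize_intensity <- function(image) {
  if (any(!is.finite(image)))
    stop("image contains non-finite pixels", call. = FALSE)
  rng <- range(image)
  if (rng[1] == rng[2]) {
    image[] <- 0
    return(image)
  }
  (image - rng[1]) / (rng[2] - rng[1])
}

#' Construct a slice-dataset manifest
#'
#' A manifest lists every labeled slice image of a dataset: identifier,
#' file path, class, provenance (`original` or `augmented` with a
#' `source_id` back-reference), and split assignment. Class labels are
#' 0-based indices into `class_names`.
#'
#' @param records Data frame with columns `image_id`, `path`,
#'   `class_name`, `provenance`, `source_id`, `split` (missing
#'   `provenance`/`source_id`/`split` columns are filled with defaults).
#' @param class_names Ordered character vector of unique class names.
#' @param image_height,image_width Slice size in pixels.
#' @return An object of class `slice_manifest`.
#' @export
manifest <- function(records, class_names,
                     image_height = 95L, image_width = 79L) {
  if (anyDuplicated(class_names))
    stop("class_names must be unique", call. = FALSE)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"provenance" %in% names(records)) records$provenance <- "original"
  if (!"source_id" %in% names(records)) records$source_id <- records$image_id
  if (!"split" %in% names(records)) records$split <- "unassigned"
  needed <- c("image_id", "path", "class_name", "provenance", "source_id",
              "split")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("manifest records lack columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records <- records[, needed]
  if (anyDuplicated(records$image_id))
    stop("duplicate image_id in manifest", call. = FALSE)
  bad <- setdiff(unique(records$class_name), class_names)
  if (length(bad))
    stop("unknown class_name: ", paste(bad, collapse = ", "), call. = FALSE)
  bad_prov <- setdiff(unique(records$provenance), c("original", "augmented"))
  if (length(bad_prov))
    stop("provenance must be 'original' or 'augmented'", call. = FALSE)
  bad_split <- setdiff(unique(records$split),
                       c("unassigned", "train", "val", "test"))
  if (length(bad_split))
    stop("split must be unassigned/train/val/test", call. = FALSE)
  aug <- records$provenance == "augmented"
  if (any(!records$source_id[aug] %in% records$image_id[!aug]))
    stop("augmented records must reference an existing original",
         call. = FALSE)
  records$label <- match(records$class_name, class_names) - 1L
  structure(list(class_names = as.character(class_names),
                 records = records,
                 image_height = as.integer(image_height),
                 image_width = as.integer(image_width)),
            class = "slice_manifest")
}

#' @export
print.slice_manifest <- function(x, ...) {
  cat(sprintf("Slice manifest: %d records, %d x %d px\n",
              nrow(x$records), x$image_height, x$image_width))
  tab <- table(factor(x$records$class_name, levels = x$class_names),
               factor(x$records$provenance,
                      levels = c("original", "augmented")))
  print(tab)
  invisible(x)
}

#' Read / write a manifest CSV
#'
#' The on-disk form is a CSV with columns `image_id`, `path`,
#' `class_name`, `provenance`, `source_id`, `split`, preceded by two
#' comment lines carrying the ordered class list and the image size so
#' the round trip is lossless.
#'
#' @param manifest A [manifest()] object.
#' @param path CSV file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the restored `slice_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "slice_manifest"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# class_names: ", paste(manifest$class_names, collapse = ",")),
    paste0("# image_size: ", manifest$image_height, "x",
           manifest$image_width)
  ), con)
  cols <- c("image_id", "path", "class_name", "provenance", "source_id",
            "split")
  utils::write.csv(manifest$records[, cols], con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop("manifest not found: ", path, call. = FALSE)
  header <- readLines(path, n = 2L)
  if (!grepl("^# class_names: ", header[1]) ||
      !grepl("^# image_size: ", header[2]))
    stop("not a manifest CSV (missing header comments): ", path,
         call. = FALSE)
  class_names <- strsplit(sub("^# class_names: ", "", header[1]), ",")[[1]]
  size <- as.integer(strsplit(sub("^# image_size: ", "", header[2]),
                              "x")[[1]])
  records <- utils::read.csv(path, comment.char = "#",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
  manifest(records, class_names, size[1], size[2])
}

#' Read a volume and export its middle axial slice as PNG
#'
#' Reads a NIfTI volume, extracts the middle axial slice
#' ([extract_middle_axial_slice()]), min-max normalizes it and writes it
#' as an 8-bit grayscale PNG.
#'
#' @param nifti_path Input `.nii` / `.nii.gz` file.
#' @param png_path Output PNG path.
#' @param axial_axis Axial axis index (see
#'   [extract_middle_axial_slice()]).
#' @return The slice matrix, invisibly.
#' @export
export_middle_slice <- function(nifti_path, png_path, axial_axis = 3L) {
  vol <- RNifti::readNifti(nifti_path)
  slice <- normalize_intensity(
    extract_middle_axial_slice(as.array(vol), axial_axis))
  write_slice_png(slice, png_path)
  invisible(slice)
}

#' Read / write a grayscale slice PNG
#'
#' Slices are stored as 8-bit grayscale PNG; intensities are quantized to
#' 256 levels on write and returned in `[0, 1]` on read.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param path PNG file path.
#' @return `write_slice_png` returns `path` invisibly; `read_slice_png`
#'   returns the image matrix.
#' @export
write_slice_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' @rdname write_slice_png
#' @export
read_slice_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Load manifest images as a model-ready batch
#'
#' Reads every (optionally split-filtered) record's PNG into an
#' `(H, W, 1, N)` array plus its 0-based label vector.
#'
#' @param manifest A [manifest()] object whose `path` entries point to
#'   existing PNG files.
#' @param split Optional split filter (`"train"`, `"val"`, `"test"`).
#' @param base_dir Directory that relative record paths resolve against.
#' @return List with `x` (array `(H, W, 1, N)`), `y` (integer labels) and
#'   `image_id`.
#' @export
load_dataset <- function(manifest, split = NULL, base_dir = NULL) {
  stopifnot(inherits(manifest, "slice_manifest"))
  rec <- manifest$records
  if (!is.null(split)) rec <- rec[rec$split %in% split, , drop = FALSE]
  n <- nrow(rec)
  if (n == 0L) stop("no records selected", call. = FALSE)
  x <- array(0, c(manifest$image_height, manifest$image_width, 1L, n))
  for (i in seq_len(n)) {
    p <- rec$path[i]
    if (!is.null(base_dir) && !file.exists(p)) p <- file.path(base_dir, p)
    img <- read_slice_png(p)
    if (!all(dim(img) == c(manifest$image_height, manifest$image_width)))
      stop(sprintf("image %s is %dx%d, manifest says %dx%d",
                   rec$image_id[i], dim(img)[1], dim(img)[2],
                   manifest$image_height, manifest$image_width),
           call. = FALSE)
    x[, , 1L, i] <- img
  }
  list(x = x, y = rec$label, image_id = rec$image_id)
}
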