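#' Split configuration
#'
#' The study design: an 8:2 stratified train/test split, then a further
#' 8:2 train/validation split of the training portion. Per class the
#' smaller part receives exactly `floor(fraction * n_c)` records
#' (floor-per-class rounding), chosen by a seeded shuffle.
#'
#' @param test_fraction Fraction of each class sent to the test set.
#' @param val_fraction_of_train Fraction of each class's remaining
#'   training records sent to the validation set.
#' @param seed Integer seed; fixes the split completely.
#' @return An object of class `split_config`.
#' @export
split_config <- function(test_fraction = 0.2, val_fraction_of_train = 0.2,
                         seed = 0L) {
  if (test_fraction <= 0 || test_fraction >= 1 ||
      val_fraction_of_train <= 0 || val_fraction_of_train >= 1)
    stop("fractions must lie in (0, 1)", call. = FALSE)
  structure(list(test_fraction = test_fraction,
                 val_fraction_of_train = val_fraction_of_train,
                 seed = as.integer(seed)),
            class = "split_config")
}

#' Stratified two-way split of labeled records
#'
#' For each class with `n_c` records, `floor(fraction * n_c)` records go
#' to part B via a seeded shuffle; the rest stay in part A. The parts are
#' disjoint and exhaustive.
#'
#' @param records Data frame with a `class_name` column.
#' @param fraction Per-class fraction assigned to part B.
#' @param seed Integer seed.
#' @return List with data frames `a` and `b`.
#' @export
stratified_split <- function(records, fraction, seed) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  classes <- unique(records$class_name)
  counts <- table(records$class_name)
  if (any(counts == 0L) || nrow(records) == 0L)
    stop("every class must have at least one record", call. = FALSE)
  set.seed(seed)
  b_idx <- integer(0)
  for (cl in classes) {
    idx <- which(records$class_name == cl)
    n_b <- floor(fraction * length(idx))
    if (n_b > 0L)
      b_idx <- c(b_idx, sample(idx, n_b))
  }
  list(a = records[setdiff(seq_len(nrow(records)), b_idx), , drop = FALSE],
       b = records[sort(b_idx), , drop = FALSE])
}

#' Assign train/val/test splits to a manifest
#'
#' Applies [stratified_split()] twice -- first carving out the test set,
#' then the validation set from the remaining training records -- and
#' writes the assignment into the manifest's `split` column.
#' Deterministic given `config$seed`.
#'
#' @param manifest A [manifest()] with all records unassigned.
#' @param config A [split_config()].
#' @return The manifest with `split` filled in.
#' @export
make_splits <- function(manifest, config = split_config()) {
  stopifnot(inherits(manifest, "slice_manifest"),
            inherits(config, "split_config"))
  rec <- manifest$records
  if (any(rec$split != "unassigned"))
    stop("manifest already has split assignments", call. = FALSE)
  s1 <- stratified_split(rec, config$test_fraction, config$seed)
  s2 <- stratified_split(s1$a, config$val_fraction_of_train,
                         config$seed + 1L)
  rec$split[rec$image_id %in% s1$b$image_id] <- "test"
  rec$split[rec$image_id %in% s2$b$image_id] <- "val"
  rec$split[rec$image_id %in% s2$a$image_id] <- "train"
  manifest(rec, manifest$class_names, manifest$image_height,
           manifest$image_width)
}
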