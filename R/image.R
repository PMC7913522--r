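#' Construct an MR image object
#'
#' An `mri_image` holds one grayscale 2-D scan as a numeric matrix of
#' intensities on the 16-bit scale (0--65535), together with its identifier,
#' an acquisition-group label (the unit of disjointness for train/test
#' splits), an optional body-part label, and -- for synthetic images -- the
#' distortion severity that produced it.
#'
#' @param id Character scalar, unique within a dataset.
#' @param pixels Numeric matrix, `h x w`, all values finite and `>= 0`.
#'   Height and width must both be at least 8.
#' @param group_id Character scalar naming the acquisition experiment
#'   (e.g. patient x body-part). Defaults to `id`.
#' @param body_part Optional character scalar (may be `""`).
#' @param severity Optional non-negative real; `NULL` for real scans.
#' @return An object of class `mri_image`.
#' @export
mri_image <- function(id, pixels, group_id = id, body_part = "", severity = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_mriqa("`id` must be a non-empty string")
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_mriqa(sprintf("image '%s': `pixels` must be a numeric matrix", id))
  if (nrow(pixels) < 8L || ncol(pixels) < 8L)
    stop_mriqa(sprintf("image '%s': dimensions must be at least 8 x 8", id))
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop_mriqa(sprintf("image '%s': intensities must be finite and non-negative", id))
  if (!is.null(severity)) {
    assert_scalar_number(severity, "severity")
    if (severity < 0) stop_mriqa("`severity` must be >= 0")
  }
  structure(
    list(id = id, pixels = pixels, group_id = as.character(group_id),
         body_part = as.character(body_part), severity = severity),
    class = "mri_image")
}

#' @export
print.mri_image <- function(x, ...) {
  cat(sprintf("<mri_image '%s'> %d x %d, group '%s'%s%s\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$group_id,
              if (nzchar(x$body_part)) paste0(", ", x$body_part) else "",
              if (!is.null(x$severity)) sprintf(", severity %.3g", x$severity) else ""))
  invisible(x)
}

#' @export
dim.mri_image <- function(x) dim(x$pixels)

#' Assemble an annotated dataset
#'
#' Binds a list of [mri_image()] objects to a table of subjective quality
#' records (one mean opinion score per image) into the canonical in-memory
#' dataset used throughout the package. Every record must resolve to exactly
#' one image and vice versa, and the dataset must contain at least two
#' distinct acquisition groups so grouped train/test splits are possible.
#'
#' @param images List of [mri_image()] objects.
#' @param records Data frame with columns `image_id` and `mos`
#'   (as returned by [read_mos_table()]); an optional `group_id` column
#'   overrides the group labels carried by the images.
#' @param name Dataset name.
#' @return An object of class `mriqa_dataset`.
#' @export
assemble_dataset <- function(images, records, name = "dataset") {
  if (!length(images)) stop_mriqa("`images` must be a non-empty list")
  ok <- vapply(images, inherits, logical(1), "mri_image")
  if (!all(ok)) stop_mriqa("all elements of `images` must be mri_image objects")
  ids <- vapply(images, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop_mriqa("duplicate image ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  records <- as.data.frame(records)
  if (!all(c("image_id", "mos") %in% names(records)))
    stop_mriqa("`records` must have columns image_id and mos")
  missing_rec <- setdiff(ids, records$image_id)
  extra_rec <- setdiff(records$image_id, ids)
  if (length(missing_rec) || length(extra_rec))
    stop_mriqa("images and records do not match 1-1; ",
               if (length(missing_rec)) paste0("images without record: ",
                 paste(missing_rec, collapse = ", "), "; ") else "",
               if (length(extra_rec)) paste0("records without image: ",
                 paste(extra_rec, collapse = ", ")) else "")
  if (anyDuplicated(records$image_id))
    stop_mriqa("duplicate image_id in records")
  if (any(records$mos < 1 | records$mos > 5))
    stop_mriqa("MOS values must lie in [1, 5]")
  names(images) <- ids
  if ("group_id" %in% names(records)) {
    gid <- records$group_id[match(ids, records$image_id)]
    use <- !is.na(gid) & nzchar(gid)
    for (i in which(use)) images[[i]]$group_id <- gid[i]
  }
  ds <- new_dataset(images, records[, c("image_id", "mos")], name)
  if (length(dataset_groups(ds)) < 2L)
    stop_mriqa("dataset must contain at least 2 distinct group_id values")
  ds
}

# Internal constructor without the >= 2 groups invariant (needed for the
# test side of grouped splits, which may legitimately hold a single group).
new_dataset <- function(images, records, name) {
  rownames(records) <- NULL
  structure(list(images = images, records = records, name = name),
            class = "mriqa_dataset")
}

#' @export
print.mriqa_dataset <- function(x, ...) {
  cat(sprintf("<mriqa_dataset '%s'> %d images, %d groups, MOS range [%.2f, %.2f]\n",
              x$name, length(x$images), length(dataset_groups(x)),
              min(x$records$mos), max(x$records$mos)))
  invisible(x)
}

#' @export
length.mriqa_dataset <- function(x) length(x$images)

#' Dataset accessors
#'
#' `dataset_groups()` returns the sorted distinct acquisition-group labels,
#' `dataset_mos()` the MOS vector named by image id, and `dataset_ids()` the
#' image ids in storage order.
#'
#' @param ds An `mriqa_dataset`.
#' @return Character or numeric vectors as described.
#' @export
dataset_groups <- function(ds) {
  sort(unique(vapply(ds$images, `[[`, character(1), "group_id")))
}

#' @rdname dataset_groups
#' @export
dataset_ids <- function(ds) names(ds$images)

#' @rdname dataset_groups
#' @export
dataset_mos <- function(ds) {
  m <- ds$records$mos[match(names(ds$images), ds$records$image_id)]
  names(m) <- names(ds$images)
  m
}

# Subset a dataset to the given image ids (internal; keeps record order
# aligned with image order, bypasses the two-group invariant).
subset_dataset <- function(ds, ids, name = ds$name) {
  stopifnot(all(ids %in% names(ds$images)))
  recs <- ds$records[match(ids, ds$records$image_id), , drop = FALSE]
  new_dataset(ds$images[ids], recs, name)
}
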