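#' Read a grayscale MR image
#'
#' Reads a single-channel 16-bit image from PNG, TIFF, or DICOM. Pixel
#' values are loaded losslessly onto the 16-bit scale (0--65535). Colour
#' (multi-channel) inputs are rejected: source MR images are single-channel.
#' When the file carries no grouping metadata, the acquisition group
#' defaults to the filename stem before the first underscore.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, or `.dcm`/`.dicom` file.
#' @return An [mri_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_mriqa("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = read_png16(path),
    tif = ,
    tiff = read_tiff16(path),
    dcm = ,
    dicom = read_dicom(path),
    stop_mriqa("unsupported image format '", ext, "' for ", path,
               " (expected PNG, TIFF, or DICOM)"))
  stem <- tools::file_path_sans_ext(basename(path))
  gid <- attr(px, "group_id")
  bp <- attr(px, "body_part")
  attributes(px) <- list(dim = dim(px))
  mri_image(id = stem, pixels = px,
            group_id = if (is.null(gid)) default_group_id(stem) else gid,
            body_part = if (is.null(bp)) "" else bp)
}

default_group_id <- function(stem) sub("_.*$", "", stem)

read_png16 <- function(path) {
  x <- tryCatch(png::readPNG(path, info = TRUE),
                error = function(e) stop_mriqa("cannot read PNG ", path, ": ",
                                               conditionMessage(e)))
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] > 1L)
      stop_mriqa("colour (multi-channel) PNG rejected: ", path,
                 " -- MR images are single-channel")
    x <- x[, , 1L]
  }
  # readPNG scales to [0,1] by (2^depth - 1); map back to the 16-bit scale.
  round(x * 65535)
}

read_tiff16 <- function(path) {
  x <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                error = function(e) stop_mriqa("cannot read TIFF ", path, ": ",
                                               conditionMessage(e)))
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] > 1L)
      stop_mriqa("colour (multi-channel) TIFF rejected: ", path,
                 " -- MR images are single-channel")
    x <- x[, , 1L]
  }
  storage.mode(x) <- "double"
  x
}

#' Write a grayscale MR image
#'
#' Writes 16-bit grayscale PNG, TIFF, or DICOM depending on the file
#' extension. Intensities are rounded to integers and clipped to
#' [0, 65535]; a write followed by [read_image()] is bit-exact.
#'
#' @param img An [mri_image()] or a numeric matrix.
#' @param path Output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  px <- if (inherits(img, "mri_image")) img$pixels else img
  px <- pmin(pmax(round(px), 0), 65535)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = write_png16(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px / 65535, path, bits.per.sample = 16L),
    dcm = ,
    dicom = write_dicom(px, path,
                        id = if (inherits(img, "mri_image")) img$id else "image"),
    stop_mriqa("unsupported image format '", ext, "'"))
  invisible(path)
}

#' Read a subjective-score (MOS) table
#'
#' Parses a UTF-8 CSV with header columns `image_id,mos` and optional
#' `group_id` and `body_part`. MOS values must lie in [1, 5]; offending
#' rows are reported by number.
#'
#' @param path CSV path.
#' @return Data frame with one quality record per row, in input order.
#' @export
read_mos_table <- function(path) {
  if (!file.exists(path)) stop_mriqa("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("image_id", "mos") %in% names(tab)))
    stop_mriqa("MOS table must have header columns image_id and mos: ", path)
  tab$image_id <- as.character(tab$image_id)
  tab$mos <- as.numeric(tab$mos)
  bad <- which(!is.finite(tab$mos) | tab$mos < 1 | tab$mos > 5)
  if (length(bad))
    stop_mriqa("MOS outside [1, 5] at row", if (length(bad) > 1) "s", " ",
               paste(bad, collapse = ", "), " of ", path)
  dup <- unique(tab$image_id[duplicated(tab$image_id)])
  if (length(dup))
    stop_mriqa("duplicate image_id in MOS table: ", paste(dup, collapse = ", "))
  keep <- intersect(c("image_id", "mos", "group_id", "body_part"), names(tab))
  tab <- tab[, keep, drop = FALSE]
  for (col in intersect(c("group_id", "body_part"), names(tab))) {
    tab[[col]] <- as.character(tab[[col]])
    tab[[col]][is.na(tab[[col]])] <- ""
  }
  tab
}

#' Write a subjective-score (MOS) table
#'
#' Inverse of [read_mos_table()]; always writes the four-column dialect
#' `image_id,mos,group_id,body_part`.
#'
#' @param records Data frame with at least `image_id` and `mos` columns,
#'   or an `mriqa_dataset` (whose records and group labels are used).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mos_table <- function(records, path) {
  if (inherits(records, "mriqa_dataset")) {
    ds <- records
    records <- data.frame(
      image_id = dataset_ids(ds),
      mos = unname(dataset_mos(ds)),
      group_id = vapply(ds$images, `[[`, character(1), "group_id"),
      body_part = vapply(ds$images, `[[`, character(1), "body_part"),
      stringsAsFactors = FALSE)
  }
  if (!"group_id" %in% names(records)) records$group_id <- records$image_id
  if (!"body_part" %in% names(records)) records$body_part <- ""
  utils::write.csv(records[, c("image_id", "mos", "group_id", "body_part")],
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Load an image folder plus MOS table as a dataset
#'
#' Reads every PNG/TIFF/DICOM image in `dir`, attaches the records of the
#' MOS CSV, and assembles the annotated dataset. Group labels in the CSV
#' take precedence over filename-derived defaults.
#'
#' @param dir Directory of images.
#' @param mos_csv Path to the MOS table (default `mos.csv` inside `dir`).
#' @param name Dataset name (default: basename of `dir`).
#' @return An `mriqa_dataset`.
#' @export
read_dataset <- function(dir, mos_csv = file.path(dir, "mos.csv"),
                         name = basename(dir)) {
  files <- list.files(dir, pattern = "\\.(png|tif|tiff|dcm|dicom)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (!length(files)) stop_mriqa("no images found in ", dir)
  images <- lapply(files, read_image)
  assemble_dataset(images, read_mos_table(mos_csv), name = name)
}

#' Write a dataset as an image folder plus MOS table
#'
#' Writes each image as 16-bit PNG into `dir` together with `mos.csv` in
#' the package's table dialect, the format produced by the `generate`
#' CLI subcommand.
#'
#' @param ds An `mriqa_dataset`.
#' @param dir Output directory (created if missing).
#' @param format `"png"` or `"tiff"`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (img in ds$images)
    write_image(img, file.path(dir, paste0(img$id, ".", format)))
  write_mos_table(ds, file.path(dir, "mos.csv"))
  invisible(dir)
}
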