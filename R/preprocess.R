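#' Replicate a single-channel MR image into three channels
#'
#' Pretrained recognition backbones expect three-channel inputs, so the
#' single 16-bit channel is scaled to [0, 1] (division by 65535) and
#' replicated into three identical channels.
#'
#' @param img An [mri_image()].
#' @return A `network_input`: list with `pixels` (`h x w x 3` array),
#'   `source_id`, and `angle_deg` (0 for unaugmented inputs).
#' @export
to_three_channels <- function(img) {
  if (!inherits(img, "mri_image")) stop_mriqa("`img` must be an mri_image")
  ch <- img$pixels / 65535
  structure(list(pixels = array(ch, dim = c(dim(ch), 3L)),
                 source_id = img$id, angle_deg = 0),
            class = "network_input")
}

#' @export
print.network_input <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<network_input '%s'> %d x %d x %d, angle %g deg\n",
              x$source_id, d[1], d[2], d[3], x$angle_deg))
  invisible(x)
}

#' Resize a network input for a backbone
#'
#' Direct (aspect-ratio-ignoring) bilinear resize to `side x side`, applied
#' identically to each channel. A resize to the current size is the
#' identity.
#'
#' @param x A `network_input` (from [to_three_channels()]).
#' @param side Target side length in pixels (`>= 8`).
#' @return A `network_input` of size `side x side x 3`.
#' @export
resize_for_backbone <- function(x, side) {
  if (!inherits(x, "network_input")) stop_mriqa("`x` must be a network_input")
  assert_scalar_number(side, "side")
  if (side < 8) stop_mriqa("`side` must be at least 8")
  d <- dim(x$pixels)
  if (d[1] == side && d[2] == side) return(x)
  out <- array(0, dim = c(side, side, 3L))
  for (c in 1:3)
    out[, , c] <- EBImage::resize(x$pixels[, , c], w = side, h = side,
                                  filter = "bilinear")
  x$pixels <- out
  x
}

#' Rotation augmentation of a dataset
#'
#' Every image is rotated about its centre to the angles
#' `step, 2*step, ..., 360` degrees (bilinear interpolation, zero fill
#' outside the support), so the dataset grows by the factor `360/step` and
#' the full-turn copy retains an unrotated view of each source image.
#' Rotated copies inherit the MOS and acquisition group of their source.
#' Intended for training folds only.
#'
#' @param ds An `mriqa_dataset`.
#' @param step_deg Angular step in degrees; must divide 360.
#' @return The augmented `mriqa_dataset`.
#' @export
rotation_augment <- function(ds, step_deg = 3) {
  assert_scalar_number(step_deg, "step_deg")
  if (step_deg <= 0 || step_deg > 360) stop_mriqa("`step_deg` must be in (0, 360]")
  n_ang <- 360 / step_deg
  if (abs(n_ang - round(n_ang)) > 1e-9)
    stop_mriqa("360 must be an integer multiple of `step_deg`")
  n_ang <- round(n_ang)
  angles <- step_deg * seq_len(n_ang)
  images <- vector("list", length(ds$images) * n_ang)
  ids <- character(length(images))
  mos <- numeric(length(images))
  src_mos <- dataset_mos(ds)
  k <- 0L
  for (img in ds$images) {
    for (a in angles) {
      k <- k + 1L
      px <- if (a %% 360 == 0) img$pixels
            else pmin(pmax(EBImage::rotate(img$pixels, a, filter = "bilinear",
                                           output.dim = dim(img$pixels),
                                           bg.col = 0), 0), 65535)
      rid <- sprintf("%s_rot%g", img$id, a)
      images[[k]] <- mri_image(rid, px, group_id = img$group_id,
                               body_part = img$body_part,
                               severity = img$severity)
      ids[k] <- rid
      mos[k] <- src_mos[[img$id]]
    }
  }
  names(images) <- ids
  new_dataset(images,
              data.frame(image_id = ids, mos = mos, stringsAsFactors = FALSE),
              paste0(ds$name, "_aug"))
}
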