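#' Fusion presets
#'
#' Named backbone combinations used throughout the package. `R50GR18`
#' fuses ResNet-50, GoogLeNet, and ResNet-18; `MR50` fuses MobileNet-V2 and
#' ResNet-50. The `R18GR50M` label is read from its abbreviation
#' (ResNet-18, GoogLeNet, ResNet-50, MobileNet-V2); the alternative
#' three-network reading is registered as `R50GM` (ResNet-50, GoogLeNet,
#' MobileNet-V2).
#'
#' @return Named list of character vectors of backbone names.
#' @export
fusion_presets <- function() {
  list(
    R50GR18 = c("ResNet-50", "GoogLeNet", "ResNet-18"),
    R18GR50M = c("ResNet-18", "GoogLeNet", "ResNet-50", "MobileNet-V2"),
    R50GM = c("ResNet-50", "GoogLeNet", "MobileNet-V2"),
    MR50 = c("MobileNet-V2", "ResNet-50"))
}

#' Build a fusion network
#'
#' Adapts each backbone (truncated at global average pooling), joins them at
#' a feature-concatenation layer, and appends the shared regression head:
#' one fully connected unit mapping the concatenated features to a single
#' quality score. All backbones receive the same input image, resized to
#' each backbone's own input side. Head weights are drawn from a seeded
#' small-variance normal and the bias starts at mid-scale MOS (3.0).
#'
#' @param specs A preset name (see [fusion_presets()]), a character vector
#'   of registered backbone names, or a list of `backbone_spec`s, in fusion
#'   order.
#' @param seed Master seed for weight initialization.
#' @return A `fusion_network` with elements `backbones`, `head`
#'   (`w`, `b`), and `total_feature_width`.
#' @export
build_fusion <- function(specs, seed = 1L) {
  if (is.character(specs) && length(specs) == 1L &&
      specs %in% names(fusion_presets()))
    specs <- fusion_presets()[[specs]]
  if (is.character(specs)) specs <- lapply(specs, lookup_backbone)
  if (inherits(specs, "backbone_spec")) specs <- list(specs)
  if (!length(specs)) stop_mriqa("`specs` must name at least one backbone")
  backbones <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (is.character(sp)) sp <- lookup_backbone(sp)
    backbones[[i]] <- adapt_backbone(
      sp, seed = if (is.null(sp$seed)) child_seed(seed, i) else sp$seed)
  }
  widths <- vapply(backbones, `[[`, integer(1), "feature_width")
  total <- sum(widths)
  head <- with_seed(child_seed(seed, 999L),
                    list(w = stats::rnorm(total, sd = 0.01), b = 3.0))
  structure(list(backbones = backbones, head = head,
                 total_feature_width = total, widths = widths, seed = seed),
            class = "fusion_network")
}

#' @export
print.fusion_network <- function(x, ...) {
  cat(sprintf("<fusion_network> %d backbone(s): %s; %d concatenated features\n",
              length(x$backbones),
              paste(vapply(x$backbones, `[[`, character(1), "name"),
                    collapse = " + "),
              x$total_feature_width))
  invisible(x)
}

# Column ranges of each backbone's features inside the concatenated vector.
fusion_slices <- function(net) {
  ends <- cumsum(net$widths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(seq.int, starts, ends)
}

as_network_inputs <- function(batch) {
  if (inherits(batch, "mriqa_dataset")) batch <- batch$images
  if (inherits(batch, "network_input") || inherits(batch, "mri_image"))
    batch <- list(batch)
  lapply(batch, function(x) {
    if (inherits(x, "mri_image")) to_three_channels(x)
    else if (inherits(x, "network_input")) x
    else stop_mriqa("batch elements must be mri_image or network_input")
  })
}

#' Forward pass of a fusion network
#'
#' Runs a batch through all backbones and the regression head, returning
#' one quality score and one concatenated pooled-feature row per input.
#' Inference is deterministic for fixed weights.
#'
#' @param net A `fusion_network`.
#' @param batch A list of `network_input`/[mri_image()] objects, a single
#'   such object, or an `mriqa_dataset`.
#' @return List with `scores` (numeric, named by source id) and `features`
#'   (matrix, one row per input, `total_feature_width` columns).
#' @export
forward <- function(net, batch) {
  if (!inherits(net, "fusion_network")) stop_mriqa("`net` must be a fusion_network")
  inputs <- as_network_inputs(batch)
  if (!length(inputs)) stop_mriqa("`batch` must be non-empty")
  n <- length(inputs)
  feats <- matrix(NA_real_, n, net$total_feature_width)
  ids <- unname(vapply(inputs, `[[`, character(1), "source_id"))
  for (i in seq_len(n)) {
    f <- unlist(lapply(net$backbones, function(bb)
      backbone_forward(bb, input_matrix(inputs[[i]], bb))$out))
    feats[i, ] <- f
  }
  scores <- as.numeric(feats %*% net$head$w) + net$head$b
  names(scores) <- ids
  rownames(feats) <- ids
  list(scores = scores, features = feats)
}

# ---- checkpoints -----------------------------------------------------------

#' Save or load a fusion-network checkpoint
#'
#' Checkpoints are self-describing JSON: schema version, the backbone
#' specifications, all convolution weights, and the head. `load_checkpoint`
#' rebuilds the geometry from the specs and restores the weights.
#'
#' @param net A `fusion_network`.
#' @param path Checkpoint path (`.json`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `fusion_network`.
#' @export
save_checkpoint <- function(net, path) {
  spec_list <- lapply(net$backbones, function(bb) {
    sp <- bb$spec
    list(name = sp$name, input_side = sp$input_side,
         feature_width = sp$feature_width, weights = sp$weights,
         seed = bb$seed, channels = sp$channels)
  })
  weights <- lapply(net$backbones, function(bb)
    lapply(bb$layers, function(l)
      if (l$type == "conv") list(W = l$W_mat, b = l$b) else NULL))
  obj <- list(schema = "mriqa-checkpoint-1", seed = net$seed,
              specs = spec_list, head = net$head, weights = weights)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$schema, "mriqa-checkpoint-1"))
    stop_mriqa("not an mriqa checkpoint: ", path)
  specs <- lapply(obj$specs, function(s)
    backbone_spec(s$name, s$input_side, s$feature_width, weights = s$weights,
                  seed = s$seed, channels = unlist(s$channels)))
  net <- build_fusion(specs, seed = obj$seed)
  for (b in seq_along(net$backbones)) {
    for (li in seq_along(net$backbones[[b]]$layers)) {
      l <- net$backbones[[b]]$layers[[li]]
      if (l$type != "conv") next
      w <- obj$weights[[b]][[li]]
      net$backbones[[b]]$layers[[li]]$W_mat <-
        matrix(unlist(w$W), nrow = 9L * l$cin, ncol = l$cout)
      net$backbones[[b]]$layers[[li]]$b <- as.numeric(unlist(w$b))
    }
  }
  net$head <- list(w = as.numeric(obj$head$w), b = as.numeric(obj$head$b))
  net
}
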