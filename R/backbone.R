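# Convolutional backbone engine.
#
# Backbones are stacks of 3x3 same-padding convolutions, ReLU, 2x2 average
# pooling, terminated by global average pooling (GAP). Convolution is
# implemented as im2col (a precomputed gather-index per layer) followed by a
# BLAS matrix product; the backward pass scatters back with rowsum(). All
# spatial geometry is fixed per backbone, so the gather indices are built
# once at construction time.

# Registry of backbone architectures known to the package. The seven
# ImageNet recognition networks are registered with their canonical pooled
# feature widths and input sides; materializing them with random weights
# builds a schematic (depth-reduced) conv stack with the same interface.
.registry <- new.env(parent = emptyenv())

register_backbone <- function(spec) {
  assign(spec$name, spec, envir = .registry)
  invisible(spec)
}

#' Backbone specification
#'
#' Describes one backbone to be adapted for quality regression: its name,
#' the side length of its square input, the length of its pooled feature
#' vector, and the weight source.
#'
#' @param name Backbone name.
#' @param input_side Input side length in pixels (`>= 8`).
#' @param feature_width Length of the global-average-pooled feature vector.
#' @param weights `"pretrained"` (ImageNet weights, an optional external
#'   input) or `"random"` (seeded initialization).
#' @param seed Seed for random initialization (`NULL`: derived at fusion
#'   build time).
#' @param channels Integer vector of per-stage channel counts; the last
#'   entry must equal `feature_width`. `NULL` selects a default stack.
#' @return A `backbone_spec`.
#' @export
backbone_spec <- function(name, input_side, feature_width,
                          weights = c("random", "pretrained"),
                          seed = NULL, channels = NULL) {
  weights <- match.arg(weights)
  if (feature_width < 1) stop_mriqa("`feature_width` must be >= 1")
  if (input_side < 8) stop_mriqa("`input_side` must be >= 8")
  if (!is.null(channels) && channels[length(channels)] != feature_width)
    stop_mriqa("last element of `channels` must equal `feature_width`")
  structure(list(name = name, input_side = as.integer(input_side),
                 feature_width = as.integer(feature_width),
                 weights = weights, seed = seed, channels = channels),
            class = "backbone_spec")
}

# Canonical ImageNet architectures: pooled feature width and input side.
local({
  tab <- list(
    list("DenseNet-201", 224L, 1920L),
    list("GoogLeNet",    224L, 1024L),
    list("Inception-v3", 299L, 2048L),
    list("MobileNet-V2", 224L, 1280L),
    list("ResNet-101",   224L, 2048L),
    list("ResNet-18",    224L,  512L),
    list("ResNet-50",    224L, 2048L))
  for (e in tab)
    register_backbone(backbone_spec(e[[1]], e[[2]], e[[3]], weights = "random"))
})

#' List registered backbones
#'
#' @return Character vector of backbone names currently in the registry.
#' @export
registered_backbones <- function() sort(ls(.registry))

lookup_backbone <- function(name) {
  if (!exists(name, envir = .registry))
    stop_mriqa("unknown backbone '", name, "'; registered: ",
               paste(registered_backbones(), collapse = ", "))
  get(name, envir = .registry)
}

#' Register a tiny test backbone
#'
#' Registers and returns a small convolutional backbone (three conv stages
#' with 2x2 average pooling, ending in global average pooling of the given
#' width) with 64-pixel inputs. These make the whole pipeline runnable at
#' desk scale without pretrained weights.
#'
#' @param width Pooled feature width (`>= 4`).
#' @param seed Seed for the weight initialization.
#' @return The registered `backbone_spec`.
#' @export
tiny_backbone <- function(width, seed = 1L) {
  if (width < 4) stop_mriqa("`width` must be >= 4")
  spec <- backbone_spec(sprintf("tiny%dw_s%d", width, seed),
                        input_side = 64L, feature_width = as.integer(width),
                        weights = "random", seed = as.integer(seed),
                        channels = c(8L, 16L, as.integer(width)))
  register_backbone(spec)
}

# ---- geometry --------------------------------------------------------------

# Gather indices for a 3x3 same-padding convolution over an H x W image with
# cin channels. The input is stored as an (H*W + 1) x cin matrix whose last
# row is a zero sentinel standing in for out-of-support neighbours; indices
# address its column-major flattening. Column order: offsets within channel,
# channels outer.
conv_indices <- function(H, W, cin) {
  HW <- H * W
  r <- rep(seq_len(H), W)
  cc <- rep(seq_len(W), each = H)
  nb <- matrix(0L, HW, 9L)
  o <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    o <- o + 1L
    rr <- r + dr; ccc <- cc + dc
    ok <- rr >= 1L & rr <= H & ccc >= 1L & ccc <= W
    nb[, o] <- ifelse(ok, rr + (ccc - 1L) * H, HW + 1L)
  }
  idx <- matrix(0L, HW, 9L * cin)
  for (ch in seq_len(cin))
    idx[, ((ch - 1L) * 9L + 1L):(ch * 9L)] <- nb + (ch - 1L) * (HW + 1L)
  idx
}

# 2x2/stride-2 average pooling; odd trailing rows/columns are dropped.
pool_indices <- function(H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  r <- rep(seq_len(H2), W2)
  cc <- rep(seq_len(W2), each = H2)
  p <- function(dr, dc) (2L * r - 1L + dr) + (2L * cc - 2L + dc) * H
  cbind(p(0L, 0L), p(1L, 0L), p(0L, 1L), p(1L, 1L))
}

# ---- construction ----------------------------------------------------------

he_init <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))

#' Adapt a backbone for quality regression
#'
#' Materializes a registered backbone truncated at its global-average-
#' pooling output: every layer after GAP (the 1000-class fully connected
#' classifier, softmax, and classification output of the recognition
#' networks) is absent, so a forward pass emits the pooled feature vector.
#' With `weights = "random"` a seeded He-normal initialization is used;
#' `"pretrained"` requires externally supplied ImageNet weights, which are
#' optional inputs and are not bundled with the package.
#'
#' @param spec A `backbone_spec` or registered backbone name.
#' @param seed Seed overriding `spec$seed` for random initialization.
#' @return An `mriqa_backbone` whose forward pass yields
#'   `spec$feature_width` features.
#' @export
adapt_backbone <- function(spec, seed = NULL) {
  if (is.character(spec)) spec <- lookup_backbone(spec)
  if (!inherits(spec, "backbone_spec")) stop_mriqa("`spec` must be a backbone_spec")
  if (spec$weights == "pretrained")
    stop_mriqa("pretrained ImageNet weights for '", spec$name, "' are an ",
               "optional external input and are not bundled; supply them or ",
               "use weights = 'random'")
  seed <- if (!is.null(seed)) seed else if (!is.null(spec$seed)) spec$seed else 1L
  channels <- spec$channels
  if (is.null(channels)) {
    # schematic stand-in stack for the named recognition architectures
    channels <- c(8L, 16L, 32L, spec$feature_width)
  }
  n_stage <- length(channels)
  side <- spec$input_side
  layers <- list()
  H <- side; cin <- 3L
  with_seed(seed, {
    for (i in seq_len(n_stage)) {
      cout <- channels[i]
      layers[[length(layers) + 1L]] <- list(
        type = "conv", cin = cin, cout = cout, H = H, W = H,
        idx = conv_indices(H, H, cin),
        W_mat = matrix(he_init(9L * cin, 9L * cin * cout), 9L * cin, cout),
        b = numeric(cout))
      layers[[length(layers) + 1L]] <- list(type = "relu")
      if (i < n_stage) {
        layers[[length(layers) + 1L]] <- list(type = "pool", H = H, W = H,
                                              P = pool_indices(H, H))
        H <- H %/% 2L
      } else {
        layers[[length(layers) + 1L]] <- list(type = "gap", hw = H * H)
      }
      cin <- cout
    }
  })
  structure(list(name = spec$name, input_side = side,
                 feature_width = spec$feature_width, seed = seed,
                 spec = spec, layers = layers),
            class = "mriqa_backbone")
}

#' @export
print.mriqa_backbone <- function(x, ...) {
  n_conv <- sum(vapply(x$layers, function(l) l$type == "conv", logical(1)))
  cat(sprintf("<mriqa_backbone '%s'> input %dx%d, %d conv stages, %d pooled features\n",
              x$name, x$input_side, x$input_side, n_conv, x$feature_width))
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------

# x: (H*W) x 3 matrix of the resized three-channel input.
backbone_forward <- function(bb, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(bb$layers)) else NULL
  for (li in seq_along(bb$layers)) {
    l <- bb$layers[[li]]
    if (l$type == "conv") {
      xa <- rbind(x, 0)
      xcol <- matrix(xa[as.vector(l$idx)], nrow = l$H * l$W)
      x <- xcol %*% l$W_mat
      x <- x + rep(l$b, each = nrow(x))
      if (keep_cache) caches[[li]] <- xcol
    } else if (l$type == "relu") {
      mask <- x > 0
      x <- x * mask
      if (keep_cache) caches[[li]] <- mask
    } else if (l$type == "pool") {
      x <- (x[l$P[, 1L], , drop = FALSE] + x[l$P[, 2L], , drop = FALSE] +
            x[l$P[, 3L], , drop = FALSE] + x[l$P[, 4L], , drop = FALSE]) / 4
    } else {  # gap
      x <- colMeans(x)
    }
  }
  list(out = x, caches = caches)
}

# dfeat: gradient w.r.t. the pooled feature vector. Returns a list of
# conv-layer gradients indexed like bb$layers (NULL for parameter-free
# layers); input gradients are not propagated past the first conv layer.
backbone_backward <- function(bb, caches, dfeat) {
  grads <- vector("list", length(bb$layers))
  first_conv <- which(vapply(bb$layers, function(l) l$type == "conv",
                             logical(1)))[1L]
  dy <- dfeat
  for (li in rev(seq_along(bb$layers))) {
    l <- bb$layers[[li]]
    if (l$type == "gap") {
      dy <- matrix(rep(dy, each = l$hw), nrow = l$hw) / l$hw
    } else if (l$type == "pool") {
      dx <- matrix(0, l$H * l$W, ncol(dy))
      q <- dy / 4
      dx[l$P[, 1L], ] <- q; dx[l$P[, 2L], ] <- q
      dx[l$P[, 3L], ] <- q; dx[l$P[, 4L], ] <- q
      dy <- dx
    } else if (l$type == "relu") {
      dy <- dy * caches[[li]]
    } else {  # conv
      xcol <- caches[[li]]
      grads[[li]] <- list(dW = crossprod(xcol, dy), db = colSums(dy))
      if (li == first_conv) break
      dxcol <- tcrossprod(dy, l$W_mat)
      acc <- rowsum(as.vector(dxcol), group = as.vector(l$idx))
      dxa <- matrix(0, (l$H * l$W + 1L), l$cin)
      dxa[as.integer(rownames(acc))] <- acc
      dy <- dxa[seq_len(l$H * l$W), , drop = FALSE]
    }
  }
  grads
}

# Flatten a network_input (resized to the backbone's side) into the
# (H*W) x 3 matrix layout the engine uses.
input_matrix <- function(x, bb) {
  x <- resize_for_backbone(x, bb$input_side)
  matrix(x$pixels, ncol = 3L)
}
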