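#' Generate a random soft-tissue-like phantom
#'
#' Deterministically (given `seed`) draws 5--12 smoothly shaded ellipses of
#' varying intensity, orientation, and size on a black background, then
#' normalizes the result to span the full 16-bit range. The phantoms stand
#' in for anatomy so the quality-assessment pipeline can be exercised
#' without clinical data.
#'
#' @param seed Integer seed; identical seeds give bit-identical phantoms.
#' @param side Image side length in pixels (`>= 32`).
#' @return An [mri_image()] with `severity = 0`.
#' @export
make_phantom <- function(seed, side = 64) {
  assert_scalar_number(side, "side")
  if (side < 32) stop_mriqa("`side` must be at least 32")
  with_seed(seed, {
    n_ell <- sample(5:12, 1L)
    xs <- matrix(rep(seq_len(side), side), side, side)          # row coord
    ys <- matrix(rep(seq_len(side), each = side), side, side)   # col coord
    px <- matrix(0, side, side)
    for (i in seq_len(n_ell)) {
      cx <- stats::runif(1, 0.15, 0.85) * side
      cy <- stats::runif(1, 0.15, 0.85) * side
      a <- stats::runif(1, 0.06, 0.30) * side
      b <- stats::runif(1, 0.06, 0.30) * side
      th <- stats::runif(1, 0, pi)
      amp <- stats::runif(1, 0.25, 1)
      u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
      v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
      rho2 <- (u / a)^2 + (v / b)^2
      px <- px + amp * pmax(1 - rho2, 0)  # smooth paraboloid shading
    }
    px <- px - min(px)
    px <- round(px / max(px) * 65535)
    mri_image(sprintf("phantom%d", seed), px, severity = 0)
  })
}

#' Apply a severity-graded distortion to an MR image
#'
#' Three schematic degradations emulate how parallel-imaging echo
#' reduction, noise, and smoothing degrade MR scans:
#' \describe{
#'   \item{`undersample_ghost`}{zeroes `floor(severity * h)` randomly chosen
#'     non-DC phase-encoding lines of the 2-D Fourier transform and
#'     reconstructs the magnitude image, producing ghosting/ringing;}
#'   \item{`rician_noise`}{replaces the image by the magnitude of the
#'     complex signal plus Gaussian noise of standard deviation
#'     `severity * 0.12 * 65535` in both quadratures, the characteristic
#'     MR magnitude-noise model;}
#'   \item{`gaussian_blur`}{Gaussian smoothing with standard deviation
#'     `severity * 4` pixels.}
#' }
#' Severity 0 always returns a pixel-identical copy. Results are clipped to
#' the 16-bit range, and any randomness is drawn reproducibly from `seed`.
#'
#' @param img An [mri_image()].
#' @param kind One of `"undersample_ghost"`, `"rician_noise"`,
#'   `"gaussian_blur"`.
#' @param severity Real in [0, 1].
#' @param seed Integer seed for the distortion's random draws.
#' @return The distorted [mri_image()] with `severity` recorded; for
#'   `undersample_ghost` the attribute `"kspace_lines_zeroed"` lists the
#'   zeroed frequency-line indices.
#' @export
apply_distortion <- function(img, kind, severity, seed = 1L) {
  if (!inherits(img, "mri_image")) stop_mriqa("`img` must be an mri_image")
  kinds <- c("undersample_ghost", "rician_noise", "gaussian_blur")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds)
    stop_mriqa("unknown distortion kind; expected one of: ",
               paste(kinds, collapse = ", "))
  assert_scalar_number(severity, "severity")
  if (severity < 0 || severity > 1) stop_mriqa("`severity` must be in [0, 1]")
  out <- img
  out$severity <- severity
  if (severity == 0) return(out)
  px <- img$pixels
  h <- nrow(px)
  if (kind == "undersample_ghost") {
    n_zero <- min(floor(severity * h), h - 1L)
    if (n_zero > 0) {
      lines <- with_seed(seed, sample(2:h, n_zero))  # never the DC line
      ksp <- stats::fft(px)
      ksp[lines, ] <- 0
      rec <- Mod(stats::fft(ksp, inverse = TRUE)) / length(px)
      out$pixels <- pmin(pmax(rec, 0), 65535)
      attr(out$pixels, "kspace_lines_zeroed") <- sort(lines)
    }
  } else if (kind == "rician_noise") {
    sigma <- severity * 0.12 * 65535
    noisy <- with_seed(seed, {
      n1 <- matrix(stats::rnorm(length(px), sd = sigma), nrow = h)
      n2 <- matrix(stats::rnorm(length(px), sd = sigma), nrow = h)
      sqrt((px + n1)^2 + n2^2)
    })
    out$pixels <- pmin(noisy, 65535)
  } else {  # gaussian_blur
    out$pixels <- pmin(pmax(EBImage::gblur(px, sigma = severity * 4), 0), 65535)
  }
  out
}

#' Pseudo mean opinion score of a synthetic severity
#'
#' Linear map `mos = 5 - 4 * severity`, strictly decreasing from 5 (pristine)
#' to 1 (worst). A known monotone ground truth is what makes
#' parameter-recovery tests of the whole pipeline possible.
#'
#' @param severity Real (vector) in [0, 1].
#' @return MOS value(s) in [1, 5].
#' @export
pseudo_mos <- function(severity) {
  if (!is.numeric(severity) || any(!is.finite(severity)) ||
      any(severity < 0 | severity > 1))
    stop_mriqa("`severity` must lie in [0, 1]")
  5 - 4 * severity
}

#' Benchmark generator configuration
#'
#' Defaults mirror the structure of a 240-image clinical benchmark: 30
#' acquisition groups, two slices per group, and four severity levels. The
#' default severity ladder `c(0, 0.2, 0.6, 1)` maps a parallel-imaging
#' acceleration series losing 30/40/60/80% of the echo signal onto [0, 1]
#' relative to its best acquisition (`(loss - 30) / 50`).
#'
#' @param n_groups Number of acquisition groups (`>= 2`).
#' @param images_per_group Phantoms per group (`>= 1`).
#' @param severity_levels Ascending severities in [0, 1], first one 0.
#' @param image_side Phantom side length in pixels.
#' @param seed Master seed; all randomness derives from it.
#' @param distortion `"composite"` (undersampling ghosting plus
#'   severity-scaled Rician noise and blur, emulating an acceleration
#'   series) or one of the single kinds of [apply_distortion()].
#' @return A validated `benchmark_config` list.
#' @export
benchmark_config <- function(n_groups = 30L, images_per_group = 2L,
                             severity_levels = c(0, 0.2, 0.6, 1),
                             image_side = 64L, seed = 1L,
                             distortion = "composite") {
  if (n_groups < 2L) stop_mriqa("`n_groups` must be >= 2")
  if (images_per_group < 1L) stop_mriqa("`images_per_group` must be >= 1")
  if (is.unsorted(severity_levels, strictly = TRUE) ||
      severity_levels[1] != 0 ||
      any(severity_levels < 0 | severity_levels > 1))
    stop_mriqa("`severity_levels` must be strictly ascending in [0, 1] and start at 0")
  if (!distortion %in% c("composite", "undersample_ghost", "rician_noise",
                         "gaussian_blur"))
    stop_mriqa("unknown `distortion`")
  structure(list(n_groups = as.integer(n_groups),
                 images_per_group = as.integer(images_per_group),
                 severity_levels = severity_levels,
                 image_side = as.integer(image_side),
                 seed = as.integer(seed), distortion = distortion),
            class = "benchmark_config")
}

#' Generate a synthetic MR-phantom benchmark
#'
#' Produces `n_groups * images_per_group * length(severity_levels)` images:
#' each phantom is degraded at every severity level, all versions of one
#' phantom share its acquisition group, and each image receives a pseudo-MOS
#' `5 - 4*severity` plus a small seeded uniform jitter (+/- 0.2, clipped to
#' [1, 5]) standing in for radiologist averaging noise. Fully reproducible
#' from `cfg$seed` via per-image child seeds.
#'
#' @param cfg A [benchmark_config()].
#' @return An `mriqa_dataset`.
#' @export
generate_benchmark <- function(cfg) {
  if (!inherits(cfg, "benchmark_config"))
    stop_mriqa("`cfg` must be a benchmark_config")
  n_total <- cfg$n_groups * cfg$images_per_group * length(cfg$severity_levels)
  images <- vector("list", n_total)
  ids <- character(n_total)
  mos <- numeric(n_total)
  k <- 0L
  for (g in seq_len(cfg$n_groups)) {
    gid <- sprintf("g%03d", g)
    for (j in seq_len(cfg$images_per_group)) {
      base_seed <- child_seed(cfg$seed, (g - 1L) * cfg$images_per_group + j)
      phantom <- make_phantom(base_seed, cfg$image_side)
      for (l in seq_along(cfg$severity_levels)) {
        k <- k + 1L
        s <- cfg$severity_levels[l]
        img <- distort_for_benchmark(phantom, s, cfg$distortion,
                                     child_seed(base_seed, l))
        img$id <- sprintf("%s_p%d_s%02d", gid, j, l)
        img$group_id <- gid
        jit <- with_seed(child_seed(base_seed, 100L + l),
                         stats::runif(1, -0.2, 0.2))
        images[[k]] <- img
        ids[k] <- img$id
        mos[k] <- min(max(pseudo_mos(s) + jit, 1), 5)
      }
    }
  }
  names(images) <- ids
  new_dataset(images,
              data.frame(image_id = ids, mos = mos, stringsAsFactors = FALSE),
              sprintf("synthetic_%d", cfg$seed))
}

distort_for_benchmark <- function(phantom, s, distortion, seed) {
  if (distortion != "composite")
    return(apply_distortion(phantom, distortion, s, seed))
  # Acceleration-like composite: ghosting at full severity, with the noise
  # amplification and resolution loss that accompany it at reduced strength.
  img <- apply_distortion(phantom, "undersample_ghost", s, seed)
  img <- apply_distortion(img, "rician_noise", 0.5 * s, child_seed(seed, 1L))
  img <- apply_distortion(img, "gaussian_blur", 0.3 * s, child_seed(seed, 2L))
  img$severity <- s
  img
}
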