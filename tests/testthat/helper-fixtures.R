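# Programmatic fixtures shared across the suite; nothing is stored on disk.

random_pixels <- function(side = 32, seed = 1) {
  set.seed(seed)
  matrix(sample(0:65535, side * side, replace = TRUE), side, side)
}

# Small annotated dataset of white-noise images: cheap, many groups.
toy_dataset <- function(n_groups = 10, per_group = 4, side = 8, seed = 1,
                        name = "toy") {
  set.seed(seed)
  imgs <- list(); ids <- character(0); mos <- numeric(0)
  for (g in seq_len(n_groups)) {
    gid <- sprintf("g%02d", g)
    for (j in seq_len(per_group)) {
      id <- sprintf("%s_%d", gid, j)
      imgs[[id]] <- mri_image(id, matrix(runif(side^2, 0, 65535), side, side),
                              group_id = gid)
      ids <- c(ids, id)
      mos <- c(mos, runif(1, 1, 5))
    }
  }
  assemble_dataset(imgs, data.frame(image_id = ids, mos = mos), name = name)
}

# Small phantom benchmark used where real quality signal is needed.
small_benchmark <- function(n_groups = 6, levels = c(0, 0.5, 1), seed = 1,
                            side = 64) {
  generate_benchmark(benchmark_config(
    n_groups = n_groups, images_per_group = 1L, severity_levels = levels,
    image_side = side, seed = seed))
}

tiny_fusion <- function(widths = c(8L, 16L), seed = 5L) {
  build_fusion(lapply(seq_along(widths),
                      function(i) tiny_backbone(widths[i], seed = i)),
               seed = seed)
}
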