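test_that("16-bit PNG and TIFF round trips are bit-exact", {
  px <- random_pixels(64, seed = 42)
  img <- mri_image("g1_scan", px)
  d <- withr::local_tempdir()
  for (ext in c("png", "tiff")) {
    path <- file.path(d, paste0("g1_scan.", ext))
    write_image(img, path)
    back <- read_image(path)
    expect_identical(back$pixels, px + 0, label = ext)
    expect_identical(back$group_id, "g1")
  }
})

test_that("edge-case images read correctly", {
  d <- withr::local_tempdir()
  # all-zero image has intensity sum 0
  zero <- matrix(0, 64, 64)
  write_image(zero, file.path(d, "z_0.tiff"))
  expect_equal(sum(read_image(file.path(d, "z_0.tiff"))$pixels), 0)
  # full-scale constant survives the 16-bit PNG path
  write_image(matrix(65535, 16, 16), file.path(d, "f_1.png"))
  expect_true(all(read_image(file.path(d, "f_1.png"))$pixels == 65535))
  # colour input is rejected
  rgb_path <- file.path(d, "c_1.png")
  png::writePNG(array(runif(16 * 16 * 3), dim = c(16, 16, 3)), rgb_path)
  expect_error(read_image(rgb_path), "single-channel")
  expect_error(read_image(file.path(d, "absent.png")), "not found")
  writeLines("not an image", file.path(d, "bad.bmp"))
  expect_error(read_image(file.path(d, "bad.bmp")), "unsupported")
})

test_that("DICOM round trip is exact and metadata is honoured", {
  px <- random_pixels(32, seed = 7)
  d <- withr::local_tempdir()
  path <- file.path(d, "scan_001.dcm")
  mriqa:::write_dicom(px, path, group_id = "patient9", body_part = "KNEE")
  back <- read_image(path)
  expect_identical(back$pixels, px + 0)
  expect_identical(back$group_id, "patient9")
  expect_identical(back$body_part, "KNEE")
})

test_that("an independent DICOM reader agrees with ours", {
  # pydicom, from the same toolchain, decodes the files we write
  px <- random_pixels(24, seed = 9)
  d <- withr::local_tempdir()
  path <- file.path(d, "x.dcm")
  mriqa:::write_dicom(px, path, group_id = "p1")
  out <- system2("python", c("-c", shQuote(paste0(
    "import pydicom; d = pydicom.dcmread('", path, "'); ",
    "print(d.Rows, d.Columns, d.PatientID, int(d.pixel_array.sum()))"))),
    stdout = TRUE)
  expect_identical(out, paste("24 24 p1", sum(px)))
})

test_that("MOS tables parse, validate, and round-trip", {
  d <- withr::local_tempdir()
  path <- file.path(d, "mos.csv")
  writeLines(c("image_id,mos,group_id", "a,1.0,g1", "b,3.2,g1", "c,5.0,g2"),
             path)
  tab <- read_mos_table(path)
  expect_equal(tab$image_id, c("a", "b", "c"))
  expect_equal(tab$mos, c(1.0, 3.2, 5.0))

  writeLines(c("image_id,mos", "a,2.0", "b,5.1"), path)
  expect_error(read_mos_table(path), "row.* 2")
  writeLines(c("image_id,mos", "a,2.0", "a,3.0"), path)
  expect_error(read_mos_table(path), "duplicate")

  recs <- data.frame(image_id = c("x", "y"), mos = c(2.5, 4.75),
                     group_id = c("g1", "g2"), body_part = c("knee", ""))
  write_mos_table(recs, path)
  back <- read_mos_table(path)
  expect_equal(back, recs)
})

test_that("dataset assembly validates the image/record correspondence", {
  imgs <- list(mri_image("a", random_pixels(8, 1), group_id = "g1"),
               mri_image("b", random_pixels(8, 2), group_id = "g2"))
  recs <- data.frame(image_id = c("a", "b"), mos = c(2, 4))
  ds <- assemble_dataset(imgs, recs)
  expect_s3_class(ds, "mriqa_dataset")
  expect_length(ds, 2)
  expect_error(assemble_dataset(imgs, recs[1, ]), "b")
  expect_error(
    assemble_dataset(imgs[1], data.frame(image_id = "a", mos = 3)),
    "2 distinct group_id")
  expect_error(
    assemble_dataset(imgs, data.frame(image_id = c("a", "b"), mos = c(0.5, 3))),
    "\\[1, 5\\]")
})

test_that("dataset assembly is order-insensitive", {
  ds <- toy_dataset(n_groups = 3, per_group = 2, seed = 11)
  perm <- rev(seq_along(ds$images))
  ds2 <- assemble_dataset(unname(ds$images[perm]),
                          ds$records[sample(nrow(ds$records)), ],
                          name = ds$name)
  ids <- sort(dataset_ids(ds))
  expect_identical(sort(dataset_ids(ds2)), ids)
  expect_equal(dataset_mos(ds2)[ids], dataset_mos(ds)[ids])
  expect_identical(dataset_groups(ds2), dataset_groups(ds))
})

test_that("a generated folder reloads as the same dataset", {
  ds <- small_benchmark(n_groups = 2, levels = c(0, 1), seed = 3, side = 32)
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  back <- read_dataset(d)
  ids <- dataset_ids(ds)
  expect_setequal(dataset_ids(back), ids)
  expect_equal(unname(dataset_mos(back)[ids]), unname(dataset_mos(ds)[ids]))
  expect_equal(as.vector(back$images[[ids[2]]]$pixels),
               as.vector(round(ds$images[[ids[2]]]$pixels)))
  expect_identical(vapply(back$images[ids], `[[`, character(1), "group_id"),
                   vapply(ds$images[ids], `[[`, character(1), "group_id"))
})
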