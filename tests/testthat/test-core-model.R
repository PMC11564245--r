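test_that("nucleus tables round-trip through CSV exactly", {
  nuc <- nucleus_table(
    nucleus_id = 1:3, x = c(1.25, 10.5, 100.125), y = c(2.5, 20.75, 200),
    area_px = c(40, 55, 62), mfi_venus = c(0.51, 0.02, 0.49),
    mfi_cherry = c(0.01, 0.52, 0.5),
    phase = c("G1G0", "S", "G2"), zone = c("MC", "AFC", "Tip"),
    retina_id = "r1", edu = c(FALSE, TRUE, FALSE)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_nucleus_table(nuc, path)
  back <- read_nucleus_table(path)
  expect_equal(back, nuc)
})

test_that("generator truth tables survive a write/read cycle unchanged", {
  ds <- generate_retina(small_retina_cfg(seed = 1), render = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_nucleus_table(ds$nuclei, path)
  expect_equal(read_nucleus_table(path), ds$nuclei)
})

test_that("malformed nucleus CSVs are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("retina_id,nucleus_id,x,y,area_px,mfi_venus,mfi_cherry",
               "r1,7,1,1,40,0.5,0.1", "r1,7,2,2,41,0.4,0.2"), path)
  expect_error(read_nucleus_table(path), "duplicate nucleus_id.*7")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("retina_id,nucleus_id,x,y", "r1,1,1,1"), path2)
  expect_error(read_nucleus_table(path2), "missing required column.*area_px")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("retina_id,nucleus_id,x,y,area_px,mfi_venus,mfi_cherry,phase,zone",
               "r1,1,1,1,40,0.5,0.1,G7,MC"), path3)
  expect_error(read_nucleus_table(path3), "unknown phase")
})

test_that("G2M is accepted on input as an alias for G2", {
  nuc <- nucleus_table(1, 1, 1, 40, 0.5, 0.5, phase = "G2M")
  expect_identical(nuc$phase, "G2")
})

test_that("zone annotations round-trip through GeoJSON", {
  square <- cbind(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  anns <- list(
    zone_annotation("MC", polygons = list(square)),
    zone_annotation("AFC", polygons = list(square + 20, square + 40)),
    zone_annotation("Tip", nucleus_ids = c(4L, 9L))
  )
  path <- withr::local_tempfile(fileext = ".geojson")
  write_zone_annotations(anns, path)
  back <- read_zone_annotations(path)
  expect_length(back, 3)
  expect_identical(back[[1]]$zone_name, "MC")
  expect_equal(back[[1]]$polygons[[1]], square)
  expect_length(back[[2]]$polygons, 2)
  expect_identical(back[[3]]$zone_name, "Tip")
  expect_identical(back[[3]]$nucleus_ids, c(4L, 9L))
  expect_length(back[[3]]$polygons, 0)
})

test_that("annotation construction enforces the zone vocabulary and ring validity", {
  square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_error(zone_annotation("Vein2", polygons = list(square)),
               "unknown zone.*PA.*Ven")
  expect_error(zone_annotation("MC", polygons = list(square[1:2, ])),
               ">= 3")
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(zone_annotation("MC", polygons = list(bowtie)),
               "self-intersecting")
  # Tip carries IDs, never polygons
  expect_error(zone_annotation("Tip", polygons = list(square)),
               "nucleus IDs, not polygons")
  # explicitly closed rings are normalized to open ones
  closed <- rbind(square, square[1, ])
  ann <- zone_annotation("MC", polygons = list(closed))
  expect_equal(nrow(ann$polygons[[1]]), 4)
})

test_that("validate_dataset reports violations without raising", {
  ds <- generate_retina(small_retina_cfg(seed = 3), render = FALSE)
  expect_identical(validate_dataset(ds), character(0))

  bad <- ds
  bad$annotations <- c(bad$annotations,
                       list(zone_annotation("Tip", nucleus_ids = 999999L)))
  v <- validate_dataset(bad)
  expect_length(grep("absent nucleus", v), 1)

  ds2 <- retina_dataset("r", channels = list(a = matrix(0, 4, 4),
                                             b = matrix(0, 5, 5)))
  expect_match(validate_dataset(ds2), "share one shape")

  # malformed-but-parsable nuclei: reported, not raised
  ds3 <- retina_dataset("r", nuclei = data.frame(nucleus_id = c(1, 1),
                                                 x = 0, y = 0, area_px = 10,
                                                 mfi_venus = -1, mfi_cherry = 0))
  v3 <- validate_dataset(ds3)
  expect_true(any(grepl("duplicate", v3)) && any(grepl("invalid MFI", v3)))
})

test_that("multichannel TIFFs round-trip through write/read", {
  ch <- list(erg = matrix(runif(64 * 64), 64, 64),
             venus = matrix(runif(64 * 64), 64, 64) * 0.5,
             cherry = matrix(0.25, 64, 64))
  path <- withr::local_tempfile(fileext = ".tif")
  write_channels_tiff(ch, path)
  back <- read_channels_tiff(path, c("erg", "venus", "cherry"))
  expect_named(back, c("erg", "venus", "cherry"))
  # 16-bit quantization: agreement to 1/65535
  expect_lt(max(abs(back$erg - ch$erg)), 1 / 65535)
  expect_lt(max(abs(back$venus - ch$venus)), 1 / 65535)
})
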