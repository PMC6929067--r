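test_that("phantom generation is deterministic and honors the ground truth contract", {
  spec <- tinySpec(nSlices = 3L, regions = list(c(1, 2, 20, 60, 0)),
                   sigma = 0.1, seed = 9L)
  v1 <- generatePhantom(spec)
  v2 <- generatePhantom(spec)
  expect_identical(slices(v1), slices(v2))
  expect_identical(trueILM(v1), trueILM(v2))

  # the truth mask is exactly the requested extent, no blurring
  m <- mapGrid(trueMap(v1))
  expect_identical(which(m == 1, arr.ind = TRUE),
                   which(outer(1:3 <= 2, 1:128 %in% 20:60) == 1, arr.ind = TRUE))

  # no regions -> all-zero map; full-coverage region -> all ones
  expect_true(all(mapGrid(trueMap(generatePhantom(tinySpec()))) == 0))
  full <- tinySpec(regions = list(c(1, 2, 1, 128, 0)))
  expect_true(all(mapGrid(trueMap(generatePhantom(full))) == 1))
})

test_that("a flat noiseless spec yields a constant true ILM at the baseline row", {
  vol <- generatePhantom(flatSpec(nSlices = 2L))
  expect_true(all(trueILM(vol) == 70))
})

test_that("intensity ordering ERM > tissue > vitreous holds on generated pixels", {
  spec <- tinySpec(nSlices = 2L, regions = list(c(1, 2, 10, 118, 0)),
                   sigma = 0.1, seed = 4L)
  vol <- generatePhantom(spec)
  ilm <- trueILM(vol)
  erm <- tis <- vit <- c()
  for (s in 1:2) {
    img <- slices(vol)[[s]]
    for (cc in seq_len(ncol(img))) {
      r <- ilm[s, cc]
      tis <- c(tis, img[r:(r + 10), cc])
      vit <- c(vit, img[1:(r - 5), cc])
      if (mapGrid(trueMap(vol))[s, cc] == 1)
        erm <- c(erm, img[(r - 2):(r - 1), cc])
    }
  }
  expect_gt(mean(erm), mean(tis))
  expect_gt(mean(tis), mean(vit))
})

test_that("invalid phantom geometry is rejected naming the offending field", {
  expect_error(phantomSpec(ilmBaselineRow = 150, retinaThickness = 60),
               "ilmBaselineRow")
  expect_error(phantomSpec(ermRegions = list(c(1, 99, 10, 20, 0))),
               "slice range")
  expect_error(phantomSpec(ermRegions = list(c(1, 2, 10, 500, 0))),
               "column range")
  expect_error(phantomSpec(tissueLevel = 10, vitreousLevel = 25),
               "intensity ordering")
})

test_that("write/load round trip is pixel-identical and the manifest regenerates the volume", {
  spec <- tinySpec(nSlices = 3L, regions = list(c(1, 3, 40, 80, 2)),
                   sigma = 0.1, seed = 21L)
  vol <- generatePhantom(spec)
  dir <- withr::local_tempdir()
  manifest <- writePhantom(vol, dir)
  expect_length(manifest$files, 3L)
  expect_true(all(file.exists(file.path(dir, unlist(manifest$files)))))

  loaded <- loadVolume(dir)
  expect_equal(slices(loaded), slices(vol))
  expect_equal(mapGrid(loadMap(file.path(dir, "true_map.png"))),
               mapGrid(trueMap(vol)))

  spec2 <- readPhantomSpec(file.path(dir, "manifest.json"))
  vol2 <- generatePhantom(spec2)
  expect_identical(slices(vol2), slices(vol))
})
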