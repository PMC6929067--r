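test_that("buildMap stacks per-slice vectors in order and rejects ragged input", {
  m <- buildMap(list(c(0, 0, 0, 1), c(0, 0, 1, 1), c(0, 0, 0, 0)))
  expect_equal(dim(mapGrid(m)), c(3L, 4L))
  expect_equal(sum(mapGrid(m)), 3)
  expect_equal(provenance(m), "raw")
  expect_equal(mapGrid(m)[2, ], c(0, 0, 1, 1))     # row i round-trips slice i
  expect_true(all(mapGrid(buildMap(list(rep(0, 4), rep(0, 4)))) == 0))
  expect_error(buildMap(list(c(0, 1), c(0, 1, 0))), "ragged")
})

test_that("component labeling honors the 4/8 connectivity choice", {
  mask <- matrix(0, 5, 5)
  mask[2, 2] <- 1; mask[3, 3] <- 1          # diagonal neighbors
  expect_equal(max(labelComponents(mask, 8L)), 1L)
  expect_equal(max(labelComponents(mask, 4L)), 2L)

  set.seed(10)
  rnd <- matrix(rbinom(30 * 40, 1, 0.4), 30, 40)
  lab <- labelComponents(rnd, 8L)
  expect_equal(sum(lab > 0), sum(rnd))       # labels exactly the foreground
})

test_that("area filtering removes small islands and keeps large regions", {
  grid <- matrix(0, 20, 30)
  grid[3:4, 3] <- 1                          # 2-px island
  grid[10:14, 10:19] <- 1                    # 50-px region
  out <- mapGrid(refineMap(grid, postprocessParams(minArea = 10)))
  expect_equal(sum(out[3:4, 3]), 0)
  expect_equal(sum(out[10:14, 10:19]), 50)
})

test_that("closing fills interior holes and (0,0) parameters are the identity", {
  grid <- matrix(0, 20, 20)
  grid[5:12, 5:12] <- 1
  grid[8, 8] <- 0                            # 1-px interior hole
  out <- mapGrid(refineMap(grid, postprocessParams(closingRadius = 2)))
  expect_equal(out[8, 8], 1)

  expect_equal(mapGrid(refineMap(grid, postprocessParams(0, 0))), grid)
})

test_that("refinement is idempotent and stays inside the dilation envelope", {
  set.seed(3)
  for (trial in 1:5) {
    grid <- matrix(rbinom(32 * 48, 1, 0.15), 32, 48)
    p <- postprocessParams(minArea = sample(0:8, 1),
                           closingRadius = sample(0:3, 1))
    once <- refineMap(grid, p)
    twice <- refineMap(once, p)
    expect_equal(mapGrid(twice), mapGrid(once))

    # no positives beyond the closing-radius dilation of the area-filtered mask
    survivors <- mapGrid(refineMap(grid, postprocessParams(p$minArea, 0L)))
    if (p$closingRadius > 0) {
      pad <- 2L * p$closingRadius
      kern <- EBImage::makeBrush(2L * p$closingRadius + 1L, "disc")
      envel <- EBImage::dilate(ermmap:::padZero(survivors, pad), kern)
      envel <- envel[(pad + 1):(pad + 32), (pad + 1):(pad + 48)]
    } else envel <- survivors
    expect_true(all(mapGrid(once) <= envel))
  }
})

test_that("the post-processing optimizer dominates the identity transform", {
  set.seed(14)
  truth <- matrix(0, 32, 64)
  truth[8:24, 10:40] <- 1
  noisyPred <- function() {
    g <- truth
    flip <- matrix(rbinom(length(g), 1, 0.06), nrow(g))  # speckle-like errors
    (g + flip) %% 2
  }
  raws <- lapply(1:3, function(i) buildMap(noisyPred()))
  truths <- lapply(1:3, function(i) truth)
  best <- optimizePostprocess(raws, truths)
  diceOf <- function(maps) mean(vapply(seq_along(maps), function(i)
    computeMetrics(confusionCounts(maps[[i]], truth))$dice, numeric(1)))
  refined <- lapply(raws, refineMap, params = best)
  expect_gte(diceOf(refined), diceOf(raws))
})

test_that("optimizer degenerate grids behave as specified", {
  truth <- matrix(0, 8, 8); truth[3:6, 3:6] <- 1
  perfect <- buildMap(truth)
  # single candidate returned verbatim
  single <- optimizePostprocess(list(perfect), list(truth),
                                minAreaGrid = 5L, closingRadiusGrid = 2L)
  expect_equal(single$minArea, 5L)
  expect_equal(single$closingRadius, 2L)
  # identity grid on perfect maps keeps Dice 1
  id <- optimizePostprocess(list(perfect), list(truth),
                            minAreaGrid = 0L, closingRadiusGrid = 0L)
  expect_equal(attr(id, "scores")$meanDice, 1)
  # all-negative ground truth cannot drive a Dice optimization
  expect_error(optimizePostprocess(list(perfect), list(matrix(0, 8, 8))),
               "specificity")
})
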