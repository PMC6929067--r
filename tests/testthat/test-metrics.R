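test_that("confusion counts match enumerated toys", {
  m <- matrix(c(1, 1, 0, 0), 2, 2)
  cc <- confusionCounts(m, m)
  expect_equal(cc, list(TP = 2L, FP = 0L, TN = 2L, FN = 0L),
               ignore_attr = TRUE)
  cc2 <- confusionCounts(1 - m, m)
  expect_equal(cc2$TP, 0L); expect_equal(cc2$TN, 0L)

  pred <- rbind(c(1, 0), c(1, 0))
  truth <- rbind(c(1, 1), c(0, 0))
  cc3 <- confusionCounts(pred, truth)
  expect_equal(cc3, list(TP = 1L, FP = 1L, TN = 1L, FN = 1L),
               ignore_attr = TRUE)
  expect_error(confusionCounts(matrix(0, 2, 2), matrix(0, 3, 2)),
               "shape mismatch")
})

test_that("metric formulas reproduce hand-computed values", {
  r <- computeMetrics(list(TP = 1, FP = 1, TN = 1, FN = 1))
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$specificity, 0.5)
  expect_equal(r$dice, 0.5)
  expect_equal(r$jaccard, 1 / 3)
})

test_that("the Dice-Jaccard identity reproduces the printed coefficient pairs", {
  expect_equal(round(diceToJaccard(0.754), 3), 0.605)
  expect_equal(round(diceToJaccard(0.882), 3), 0.789)
})

test_that("jaccard == dice/(2-dice) and dice >= jaccard on random confusions", {
  set.seed(123)
  for (i in 1:1000) {
    cc <- as.list(stats::setNames(sample(0:50, 4, replace = TRUE),
                                  c("TP", "FP", "TN", "FN")))
    r <- computeMetrics(cc)
    if (!is.na(r$dice)) {
      expect_equal(r$jaccard, r$dice / (2 - r$dice), tolerance = 1e-12)
      expect_gte(r$dice, r$jaccard)
    }
  }
})

test_that("metrics on a self-comparison are all 1 when both classes are present", {
  set.seed(5)
  m <- matrix(rbinom(64, 1, 0.3), 8, 8)
  r <- computeMetrics(confusionCounts(m, m))
  expect_equal(unlist(r[c("sensitivity", "specificity", "dice", "jaccard")]),
               c(1, 1, 1, 1), ignore_attr = TRUE)
})

test_that("positives-free volumes mark sensitivity/dice/jaccard undefined", {
  r <- computeMetrics(list(TP = 0, FP = 3, TN = 97, FN = 0))
  expect_true(is.na(r$sensitivity))
  expect_true(is.na(r$dice))
  expect_true(is.na(r$jaccard))
  expect_equal(r$specificity, 0.97)
})

test_that("aggregation uses sample sd and skips undefined metrics per class", {
  reports <- rbind(
    cbind(computeMetrics(list(TP = 30, FP = 10, TN = 55, FN = 10), "v1", "postprocess"),
          class = "ERM"),
    cbind(computeMetrics(list(TP = 40, FP = 5, TN = 50, FN = 5), "v2", "postprocess"),
          class = "ERM"),
    cbind(computeMetrics(list(TP = 0, FP = 2, TN = 98, FN = 0), "v3", "postprocess"),
          class = "non-ERM"))
  # hand-check: dice values 2*30/(60+20)=0.75 and 80/90
  agg <- aggregateMetrics(reports)
  d <- agg[agg$class == "ERM" & agg$metric == "dice", ]
  expect_equal(d$mean, mean(c(0.75, 8 / 9)))
  expect_equal(d$sd, stats::sd(c(0.75, 8 / 9)))
  expect_equal(d$n, 2L)

  nonErm <- agg[agg$class == "non-ERM", ]
  expect_identical(sort(nonErm$metric), "specificity")   # only specificity defined
  expect_equal(nonErm$sd, 0)                             # single volume
  expect_equal(nonErm$n, 1L)

  # two volumes with dice 0.6 / 0.8 -> mean 0.7, sample sd ~0.1414
  r2 <- rbind(
    cbind(computeMetrics(list(TP = 30, FP = 10, TN = 50, FN = 10), "a", "s"), class = "ERM"),
    cbind(computeMetrics(list(TP = 40, FP = 5, TN = 50, FN = 5), "b", "s"), class = "ERM"))
  r2$dice <- c(0.6, 0.8)
  a2 <- aggregateMetrics(r2)
  d2 <- a2[a2$metric == "dice", ]
  expect_equal(d2$mean, 0.7)
  expect_equal(round(d2$sd, 4), 0.1414)
})
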