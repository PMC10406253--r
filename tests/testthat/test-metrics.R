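test_that("confusion counts follow each objective's positive class", {
  truth <- c(rep("noise", 10), rep("rsn", 5), rep("soz", 2))
  cc1 <- confusion(truth, truth, "noise_removal")
  expect_equal(cc1[c("tp", "tn", "fp", "fn")],
               list(tp = 7L, tn = 10L, fp = 0L, fn = 0L))
  cc2 <- confusion(truth, truth, "soz_identification")
  expect_equal(cc2[c("tp", "tn", "fp", "fn")],
               list(tp = 2L, tn = 15L, fp = 0L, fn = 0L))

  cc3 <- confusion(rep("soz", 4), rep("noise", 4), "soz_identification")
  expect_equal(cc3$fp, 4L)
  expect_equal(cc3$tp, 0L)

  expect_error(confusion(c("soz", "rsn"), "soz"), "length")

  # counts conservation
  set.seed(8)
  for (i in 1:20) {
    p <- sample(c("noise", "rsn", "soz"), 30, replace = TRUE)
    t <- sample(c("noise", "rsn", "soz"), 30, replace = TRUE)
    for (obj in c("noise_removal", "soz_identification")) {
      cc <- confusion(p, t, obj)
      expect_identical(cc$tp + cc$tn + cc$fp + cc$fn, 30L)
    }
  }
})

test_that("swapping prediction and truth swaps fp and fn, fixing accuracy", {
  set.seed(9)
  p <- sample(c("noise", "rsn", "soz"), 40, replace = TRUE)
  t <- sample(c("noise", "rsn", "soz"), 40, replace = TRUE)
  a <- confusion(p, t, "soz_identification")
  b <- confusion(t, p, "soz_identification")
  expect_identical(a$fp, b$fn)
  expect_identical(a$fn, b$fp)
  expect_equal(metric_set(a)$accuracy, metric_set(b)$accuracy)
})

test_that("derived metrics match hand-computed values and mark undefined cases", {
  # the 16-of-22 true-positive composition of a screening report
  ms <- metric_set(list(tp = 16, tn = 0, fp = 6, fn = 0))
  expect_equal(ms$precision, 16 / 22)
  expect_equal(ms$sensitivity, 1)

  ms2 <- metric_set(list(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_true(is.na(ms2$precision))
  expect_equal(ms2$specificity, 1.0)
  expect_equal(ms2$accuracy, 1.0)

  perfect <- metric_set(confusion(c("soz", "rsn", "noise"),
                                  c("soz", "rsn", "noise"), "noise_removal"))
  expect_equal(unlist(perfect), c(accuracy = 1, precision = 1,
                                  sensitivity = 1, specificity = 1))
})

test_that("aggregation reports mean, sample sd and usable-subject counts", {
  two <- rbind(metric_set(list(tp = 8, tn = 0, fp = 2, fn = 0)),
               metric_set(list(tp = 9, tn = 0, fp = 1, fn = 0)))
  agg <- aggregate_metrics(two)
  prec <- agg[agg$metric == "precision", ]
  expect_equal(prec$mean, 0.85)
  expect_equal(prec$sd, sd(c(0.8, 0.9)))
  expect_identical(prec$n_used, 2L)
  # specificity undefined in both rows (tn + fp... fp > 0 so defined);
  # sensitivity identical in both -> sd 0
  expect_equal(agg[agg$metric == "sensitivity", "sd"], 0)

  one <- metric_set(list(tp = 1, tn = 1, fp = 0, fn = 0))
  agg1 <- aggregate_metrics(one)
  expect_true(is.na(agg1$sd[1]))
  # undefined entries are excluded from aggregation
  mixed <- rbind(metric_set(list(tp = 0, tn = 5, fp = 0, fn = 0)),
                 metric_set(list(tp = 4, tn = 4, fp = 2, fn = 0)))
  aggm <- aggregate_metrics(mixed)
  expect_identical(aggm[aggm$metric == "precision", "n_used"], 1L)
  expect_equal(aggm[aggm$metric == "precision", "mean"], 4 / 6)
})

test_that("the literal SOZ true-positive reading is available but not default", {
  p <- c("rsn", "soz", "noise")
  t <- c("rsn", "rsn", "soz")
  strict <- confusion(p, t, "soz_identification")
  literal <- confusion(p, t, "soz_identification", literal_soz_tp = TRUE)
  expect_identical(strict$tp, 0L)
  expect_identical(literal$tp, 2L)   # agreement on non-noise counts as TP
})
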