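disk3d <- function(dims, ctr, r, value, base = array(0, dims), slice = 1L) {
  x <- matrix(seq_len(dims[1]), dims[1], dims[2])
  y <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  m <- (x - ctr[1])^2 + (y - ctr[2])^2 <= r^2
  sl <- base[, , slice]
  sl[m] <- value
  base[, , slice] <- sl
  base
}

test_that("bullseye score rewards nested concentric activation", {
  dims <- c(32, 32, 3)
  vol <- disk3d(dims, c(16, 16), 6, 3, slice = 2L)
  vol <- disk3d(dims, c(16, 16), 3, 6, base = vol, slice = 2L)
  expect_equal(bullseye_score(vol), 1.0)

  # uniform blob with no high-threshold core
  flat <- disk3d(dims, c(16, 16), 6, 3, slice = 2L)
  expect_equal(bullseye_score(flat), 0)

  # disjoint blobs at the two thresholds: centroid factor halves the score
  apart <- disk3d(dims, c(9, 9), 5, 3, slice = 2L)
  apart <- disk3d(dims, c(24, 24), 3, 6, base = apart, slice = 2L)
  expect_lte(bullseye_score(apart), 0.5)

  expect_equal(bullseye_score(array(0, dims)), 0)
})

test_that("template overlap is a maximum Dice with sane edge cases", {
  dims <- c(16, 16, 2)
  tmpl <- array(FALSE, dims); tmpl[4:9, 4:9, 1] <- TRUE
  vol <- array(0, dims); vol[4:9, 4:9, 1] <- 5
  expect_equal(as.numeric(rsn_template_overlap(vol, list(a = tmpl))), 1.0)

  far <- array(0, dims); far[12:14, 12:14, 2] <- 5
  expect_equal(as.numeric(rsn_template_overlap(far, list(a = tmpl))), 0.0)

  # equal-size half-overlapping masks have Dice 0.5
  half <- array(0, dims); half[4:9, 7:12, 1] <- 5
  got <- rsn_template_overlap(half, list(a = tmpl))
  expect_equal(as.numeric(got), 0.5)
  expect_identical(attr(got, "best_template"), "a")

  expect_warning(out <- rsn_template_overlap(vol, list()), "no RSN templates")
  expect_equal(as.numeric(out), 0)
})

test_that("rule assignment gates on frequency, template overlap and markers", {
  cfg <- ic_config()
  f <- function(freq, overlap, bull, gini = 0.4) {
    data.frame(bullseye_score = bull, gray_matter_fraction = 0.9,
               rsn_template_overlap = overlap, dominant_freq_hz = freq,
               gini_activelet = gini, gini_sine_mp = 0.9)
  }
  expect_identical(rule_assign(f(0.1, 0.0, 0.9), cfg), "soz")
  expect_identical(rule_assign(f(0.02, 0.0, 0.9), cfg), "rsn")   # frequency gate
  expect_identical(rule_assign(f(0.1, 0.8, 0.9), cfg), "rsn")    # RSN-overlap gate
  expect_identical(rule_assign(f(0.1, 0.0, 0.1), cfg), "rsn")    # no spatial/sparsity marker
  expect_identical(rule_assign(f(0.1, 0.0, 0.1, gini = 0.8), cfg), "soz")
})

test_that("white-matter-noise override needs the right subtype and sparsity", {
  cfg <- ic_config()
  tf <- function(ga, gs = 0) {
    structure(list(gini_activelet = ga, gini_sine_mp = gs,
                   dominant_freq_hz = 0.1, windows_used = 2L),
              class = "temporal_features")
  }
  expect_equal(wm_noise_override("white_matter", tf(0.80), cfg),
               list(reclassify = TRUE, override = "activelet_gini"))
  expect_equal(wm_noise_override("white_matter", tf(0.60, 0.5), cfg),
               list(reclassify = FALSE, override = "none"))
  expect_equal(wm_noise_override("boundary", tf(0.99), cfg),
               list(reclassify = FALSE, override = "none"))
  # the printed sine threshold exceeds 1, so only a lowered threshold
  # lets the sine arm fire
  cfg072 <- ic_config(gini_sine_threshold = 0.72)
  expect_equal(wm_noise_override("white_matter", tf(0.6, 0.9), cfg072),
               list(reclassify = TRUE, override = "sine_gini"))
  expect_false(wm_noise_override("white_matter", tf(0.6, 0.9), cfg)$reclassify)
})

test_that("override monotonicity: raising the wavelet Gini never undoes SOZ", {
  cfg <- ic_config()
  tfv <- function(ga) structure(list(gini_activelet = ga, gini_sine_mp = 0,
                                     dominant_freq_hz = 0.1, windows_used = 1L),
                                class = "temporal_features")
  flips <- vapply(seq(0.76, 0.99, by = 0.01), function(ga) {
    wm_noise_override("white_matter", tfv(ga), cfg)$reclassify
  }, logical(1))
  expect_true(all(flips))
})

test_that("mixture assignment separates well-separated feature clouds", {
  sim <- sim_clouds(1)
  got <- ml_cluster_assign(sim$features)
  expect_gte(mean(got == sim$truth), 0.95)
})

test_that("mixture assignment handles degenerate inputs conservatively", {
  one <- data.frame(bullseye_score = 1.0, gray_matter_fraction = 0.9,
                    rsn_template_overlap = 0, dominant_freq_hz = 0.1,
                    gini_activelet = 0.9, gini_sine_mp = 0.8)
  expect_identical(ml_cluster_assign(one), "soz")   # rule fallback on 1 IC
  same <- one[rep(1, 8), ]
  expect_identical(ml_cluster_assign(same), rep("rsn", 8))
})

test_that("subject classification is exhaustive, exclusive and accurate", {
  subj <- phantom_subject_fixture(5)
  labels <- classify_subject(subj$dec, subj$templates)
  expect_identical(nrow(labels), subj$dec$n_ics)
  expect_true(all(labels$category %in% c("noise", "rsn", "soz")))
  expect_identical(sort(labels$ic_index), subj$truth$ic_index)
  # label-consistency invariant: subtype outside noise only via override
  bad <- labels$noise_subtype != "none" & labels$category != "noise" &
    labels$override_applied == "none"
  expect_false(any(bad))
  ev <- evaluate_labels(labels, subj$truth)
  expect_gte(ev$soz_identification$metrics$sensitivity, 0.8)
  expect_gte(ev$noise_removal$metrics$sensitivity, 0.85)
  empty <- ic_decomposition(array(0, c(4, 4, 2, 0)), matrix(0, 16, 0), 2)
  expect_error(classify_subject(empty), "empty")
})
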