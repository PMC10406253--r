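mock_contours <- function(nx = 20, ny = 20) {
  periph <- matrix(FALSE, nx, ny); periph[3:18, 3:18] <- TRUE
  wm <- matrix(FALSE, nx, ny); wm[8:13, 8:13] <- TRUE
  ves <- matrix(FALSE, nx, ny); ves[15:16, 15:16] <- TRUE
  list(periphery = periph, white_matter = wm, vessels = ves,
       gray_matter = periph & !wm & !ves, empty = FALSE)
}

cluster_from <- function(xy, slice = 1L) {
  xy <- xy[order(xy[, 1], xy[, 2]), , drop = FALSE]
  list(voxels = xy, core = xy, border = xy[0, , drop = FALSE],
       size = nrow(xy), slice_index = slice)
}

test_that("slice statistics normalise overlaps by cluster size", {
  ct <- mock_contours()
  # cluster fully inside the white-matter mask
  wm_xy <- which(ct$white_matter, arr.ind = TRUE)[1:10, ]
  st <- slice_stats(list(cluster_from(wm_xy)), ct, 4L)
  expect_equal(st$pct_wm_overlap, 100)
  expect_equal(st$outside_brain_fraction, 0)
  expect_equal(st$slice_index, 4L)

  # no clusters: zeroed statistics
  st0 <- slice_stats(list(), ct, 2L)
  expect_equal(st0$n_clusters, 0L)
  expect_equal(st0$largest_cluster_size, 0L)
  expect_equal(st0$crescent_score, 0)
})

test_that("crescent score is the in-band fraction of the largest cluster", {
  ct <- mock_contours()
  band <- ct$periphery &
    !sozica:::as_logical_mask(EBImage::erode(ct$periphery,
                                             EBImage::makeBrush(5, "disc")))
  in_band <- which(band, arr.ind = TRUE)[1:4, ]
  interior <- which(ct$gray_matter & !band, arr.ind = TRUE)[1:6, ]
  st <- slice_stats(list(cluster_from(rbind(in_band, interior))), ct, 1L)
  expect_equal(st$crescent_score, 0.4)
})

test_that("slice noise rules fire in the documented order", {
  cfg <- ic_config()
  base <- data.frame(slice_index = 1L, n_clusters = 1L,
                     largest_cluster_size = 50L, pct_boundary_overlap = 0,
                     pct_wm_overlap = 0, pct_vessel_overlap = 0,
                     outside_brain_fraction = 0, crescent_score = 0)
  expect_equal(classify_slice(base, cfg), list(is_noise = FALSE, subtype = "none"))

  wm <- base; wm$pct_wm_overlap <- 90
  expect_equal(classify_slice(wm, cfg),
               list(is_noise = TRUE, subtype = "white_matter"))

  out <- wm; out$outside_brain_fraction <- 0.9   # earlier rule wins
  expect_equal(classify_slice(out, cfg),
               list(is_noise = TRUE, subtype = "boundary"))

  many <- base; many$n_clusters <- 40L; many$largest_cluster_size <- 5L
  expect_equal(classify_slice(many, cfg),
               list(is_noise = TRUE, subtype = "small_clusters"))

  # many clusters but one large: the small-clusters rule must not fire
  mixed <- many; mixed$largest_cluster_size <- 50L
  expect_false(classify_slice(mixed, cfg)$is_noise)
})

test_that("IC noise call needs a strict top-k majority", {
  cfg <- ic_config()
  mk <- function(n_noise, n_total = 10) {
    do.call(rbind, lapply(seq_len(n_total), function(i) {
      data.frame(slice_index = i, n_clusters = 1L,
                 largest_cluster_size = 100L - i,
                 pct_boundary_overlap = 0,
                 pct_wm_overlap = if (i <= n_noise) 90 else 0,
                 pct_vessel_overlap = 0, outside_brain_fraction = 0,
                 crescent_score = 0)
    }))
  }
  r6 <- classify_ic_noise(mk(6), cfg)
  expect_true(r6$is_noise)
  expect_identical(r6$subtype, "white_matter")
  r5 <- classify_ic_noise(mk(5), cfg)
  expect_false(r5$is_noise)
  expect_identical(r5$subtype, "none")
})

test_that("only the top-k largest informative slices enter the vote", {
  cfg <- ic_config()
  # 10 large clean slices followed by 20 small noisy slices
  clean <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(slice_index = i, n_clusters = 1L,
               largest_cluster_size = 200L, pct_boundary_overlap = 0,
               pct_wm_overlap = 0, pct_vessel_overlap = 0,
               outside_brain_fraction = 0, crescent_score = 0)
  }))
  noisy <- do.call(rbind, lapply(11:30, function(i) {
    data.frame(slice_index = i, n_clusters = 1L,
               largest_cluster_size = 5L, pct_boundary_overlap = 0,
               pct_wm_overlap = 100, pct_vessel_overlap = 0,
               outside_brain_fraction = 0, crescent_score = 0)
  }))
  r <- classify_ic_noise(rbind(clean, noisy), cfg)
  expect_false(r$is_noise)
  # decision is invariant to row order
  set.seed(1)
  perm <- rbind(clean, noisy)[sample.int(30), ]
  expect_equal(classify_ic_noise(perm, cfg), r)
})

test_that("slices without clusters never make an IC noisy", {
  cfg <- ic_config()
  empty <- do.call(rbind, lapply(1:12, function(i) {
    data.frame(slice_index = i, n_clusters = 0L,
               largest_cluster_size = 0L, pct_boundary_overlap = 0,
               pct_wm_overlap = 0, pct_vessel_overlap = 0,
               outside_brain_fraction = 0, crescent_score = 0)
  }))
  r <- classify_ic_noise(empty, cfg)
  expect_false(r$is_noise)
})
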