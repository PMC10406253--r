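test_that("binarize_slice keeps both activation signs, boundary inclusive", {
  z <- matrix(0, 4, 4)
  expect_false(any(binarize_slice(z, 2)))
  expect_true(all(binarize_slice(matrix(2, 4, 4), 2)))
  m <- matrix(c(3, -3, 1, -1), 2, 2)
  expect_equal(binarize_slice(m, 2), matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_error(binarize_slice(matrix(c(1, NA, 1, 1), 2, 2), 2), "non-finite")
})

test_that("density scan finds the expected clusters on constructed masks", {
  # single isolated voxel below the density requirement
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_length(detect_clusters(m, 1.5, 2), 0)

  # a filled 5x5 square is one cluster of 25
  m <- matrix(FALSE, 12, 12); m[3:7, 3:7] <- TRUE
  cl <- detect_clusters(m, 1.5, 3)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$size, 25L)
  expect_identical(canonical_partition(list(cl[[1]]$voxels)),
                   canonical_partition(brute_force_clusters(m, 1.5, 3)))

  # two 3x3 squares separated by 10 voxels stay separate
  m <- matrix(FALSE, 20, 20); m[2:4, 2:4] <- TRUE; m[15:17, 15:17] <- TRUE
  cl <- detect_clusters(m, 1.5, 3)
  expect_length(cl, 2)
  expect_equal(sort(vapply(cl, function(x) x$size, integer(1))), c(9L, 9L))

  # empty mask is an empty collection, not an error
  expect_length(detect_clusters(matrix(FALSE, 4, 4), 1.5, 3), 0)
})

test_that("cluster structure satisfies core/border invariants", {
  m <- matrix(FALSE, 12, 12); m[3:7, 3:7] <- TRUE; m[3, 9] <- TRUE
  cl <- detect_clusters(m, 1.5, 3)
  for (c1 in cl) {
    expect_identical(nrow(c1$core) + nrow(c1$border), c1$size)
    # core and border are disjoint
    joint <- rbind(c1$core, c1$border)
    expect_identical(nrow(unique(joint)), nrow(joint))
  }
})

test_that("partition matches the brute-force oracle on random small masks", {
  set.seed(42)
  for (i in 1:120) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    m <- matrix(stats::runif(nx * ny) < stats::runif(1, 0.2, 0.8), nx, ny)
    eps <- sample(c(1, 1.5, 2), 1); vm <- sample(1:4, 1)
    got <- canonical_partition(
      lapply(detect_clusters(m, eps, vm), function(cl) cl$voxels))
    want <- canonical_partition(brute_force_clusters(m, eps, vm))
    expect_identical(got, want,
      info = sprintf("mask %d (eps=%.1f, v_min=%d)", i, eps, vm))
  }
})

test_that("decreasing v_min never removes a core point", {
  set.seed(7)
  for (i in 1:25) {
    m <- matrix(stats::runif(49) < 0.55, 7, 7)
    core_at <- function(vm) {
      cl <- detect_clusters(m, 1.5, vm)
      canonical_partition(lapply(cl, function(x) x$core))
    }
    hi <- unlist(strsplit(core_at(4), ";"))
    lo <- unlist(strsplit(core_at(2), ";"))
    expect_true(all(hi %in% lo))
  }
})

test_that("largest_cluster breaks size ties by lowest (x, y) coordinate", {
  m <- matrix(FALSE, 20, 20)
  m[10:12, 2:4] <- TRUE    # tie cluster, lexicographically later
  m[2:4, 6:8] <- TRUE      # tie cluster, lowest minimal coordinate
  big <- largest_cluster(detect_clusters(m, 1.5, 3))
  expect_identical(big$size, 9L)
  expect_identical(min(big$voxels[, 1]), 2L)
  expect_null(largest_cluster(list()))
  # plain maximum when sizes differ
  m2 <- matrix(FALSE, 20, 20); m2[2:4, 2:4] <- TRUE; m2[8:12, 8:12] <- TRUE
  expect_identical(largest_cluster(detect_clusters(m2, 1.5, 3))$size, 25L)
})
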