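NOISE_SUBTYPES <- c("boundary", "white_matter", "vessel", "small_clusters")

#' Per-slice noise statistics
#'
#' Stage-1 statistics of the noise classifier for one slice: cluster
#' count, largest-cluster size, and the percentage overlap of the largest
#' cluster with the brain-boundary band, white matter and vessels
#' (normalised by cluster size), plus the fraction of all cluster voxels
#' outside the filled periphery and the crescent score (fraction of
#' largest-cluster voxels inside a 2-voxel band along the inner
#' periphery).
#'
#' @param clusters Cluster list for the slice ([detect_clusters()]).
#' @param slice_contours Per-slice contour set ([extract_contours()]).
#' @param slice_index Slice index (1-based).
#' @return One-row data frame with columns `slice_index`, `n_clusters`,
#'   `largest_cluster_size`, `pct_boundary_overlap`, `pct_wm_overlap`,
#'   `pct_vessel_overlap`, `outside_brain_fraction`, `crescent_score`.
#' @export
slice_stats <- function(clusters, slice_contours, slice_index) {
  zero <- data.frame(
    slice_index = as.integer(slice_index), n_clusters = 0L,
    largest_cluster_size = 0L, pct_boundary_overlap = 0,
    pct_wm_overlap = 0, pct_vessel_overlap = 0,
    outside_brain_fraction = 0, crescent_score = 0
  )
  if (length(clusters) == 0) return(zero)
  periph <- slice_contours$periphery
  nx <- nrow(periph); ny <- ncol(periph)
  big <- largest_cluster(clusters)
  big_idx <- (big$voxels[, 2] - 1L) * nx + big$voxels[, 1]
  n_big <- length(big_idx)
  band <- periphery_band(periph)

  all_idx <- unlist(lapply(clusters, function(cl) {
    (cl$voxels[, 2] - 1L) * nrow(periph) + cl$voxels[, 1]
  }))
  outside <- if (any(periph)) mean(!periph[all_idx]) else 1

  data.frame(
    slice_index = as.integer(slice_index),
    n_clusters = length(clusters),
    largest_cluster_size = as.integer(n_big),
    pct_boundary_overlap = 100 * mean(band[big_idx] | !periph[big_idx]),
    pct_wm_overlap = 100 * mean(slice_contours$white_matter[big_idx]),
    pct_vessel_overlap = 100 * mean(slice_contours$vessels[big_idx]),
    outside_brain_fraction = outside,
    crescent_score = mean(band[big_idx])
  )
}

## 2-voxel band just inside the filled periphery
periphery_band <- function(periph) {
  if (!any(periph)) return(periph)
  eroded <- as_logical_mask(
    EBImage::erode(periph, EBImage::makeBrush(5, shape = "disc")))
  periph & !eroded
}

#' Stage-1 slice noise decision
#'
#' Applies the noise-marker rules in a fixed order and reports the first
#' that fires: cluster mass outside the brain (boundary), high
#' white-matter overlap, high vessel overlap, crescent shape along the
#' boundary, many small clusters.
#'
#' @param stats One-row data frame from [slice_stats()].
#' @param config An [ic_config()].
#' @return List `(is_noise, subtype)`; subtype is `"none"` when clean.
#' @export
classify_slice <- function(stats, config = ic_config()) {
  if (stats$n_clusters == 0) return(list(is_noise = FALSE, subtype = "none"))
  if (stats$outside_brain_fraction > config$theta_outside) {
    return(list(is_noise = TRUE, subtype = "boundary"))
  }
  if (stats$pct_wm_overlap > config$theta_wm) {
    return(list(is_noise = TRUE, subtype = "white_matter"))
  }
  if (stats$pct_vessel_overlap > config$theta_vessel) {
    return(list(is_noise = TRUE, subtype = "vessel"))
  }
  if (stats$crescent_score > config$theta_crescent) {
    return(list(is_noise = TRUE, subtype = "boundary"))
  }
  if (stats$n_clusters > config$theta_many &&
      stats$largest_cluster_size < config$theta_small) {
    return(list(is_noise = TRUE, subtype = "small_clusters"))
  }
  list(is_noise = FALSE, subtype = "none")
}

#' Stage-2 IC noise decision (top-k slice majority)
#'
#' Sorts the informative slices (those holding at least one cluster) by
#' decreasing largest-cluster size (stable, slice-index tie-break),
#' classifies the top `top_k` (fewer if the IC has fewer informative
#' slices), and calls the IC noise when strictly more than half of the
#' selected slices are noise. The reported subtype is the modal subtype
#' among the noise slices, ties resolved in the fixed rule order.
#'
#' @param per_slice Data frame of per-slice statistics (rows from
#'   [slice_stats()]).
#' @param config An [ic_config()].
#' @return List `(is_noise, subtype, n_selected, n_noise)`.
#' @export
classify_ic_noise <- function(per_slice, config = ic_config()) {
  stopifnot(nrow(per_slice) >= 1)
  informative <- per_slice[per_slice$n_clusters > 0, , drop = FALSE]
  pool <- if (nrow(informative) > 0) informative else per_slice
  o <- order(-pool$largest_cluster_size, pool$slice_index)
  sel <- pool[o, , drop = FALSE]
  sel <- utils::head(sel, config$top_k)
  calls <- lapply(seq_len(nrow(sel)), function(i) {
    classify_slice(sel[i, , drop = FALSE], config)
  })
  is_noise_slice <- vapply(calls, `[[`, logical(1), "is_noise")
  n_noise <- sum(is_noise_slice)
  is_noise <- n_noise > nrow(sel) / 2
  subtype <- "none"
  if (is_noise) {
    subs <- vapply(calls[is_noise_slice], `[[`, character(1), "subtype")
    tab <- table(factor(subs, levels = NOISE_SUBTYPES))
    subtype <- NOISE_SUBTYPES[which.max(tab)]   # ties -> fixed rule order
  }
  list(is_noise = is_noise, subtype = subtype,
       n_selected = nrow(sel), n_noise = as.integer(n_noise))
}

#' Per-slice noise statistics for a whole IC
#'
#' @param clusters_by_slice List of per-slice cluster lists
#'   ([detect_clusters_volume()]).
#' @param contours An `"anatomy_contours"` ([subject_contours()]).
#' @return Data frame with one row per slice.
#' @export
ic_slice_stats <- function(clusters_by_slice, contours) {
  do.call(rbind, lapply(seq_along(clusters_by_slice), function(s) {
    slice_stats(clusters_by_slice[[s]], contours$slices[[s]], s)
  }))
}
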