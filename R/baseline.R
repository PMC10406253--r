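#' Count large voxel clusters of an IC
#'
#' Number of detected clusters, pooled over all slices, whose size
#' strictly exceeds `min_px` voxels. With the default 135-pixel bar this
#' is the cluster-count feature of the shallow-learning baseline.
#'
#' @param vol 3D numeric array, the IC z-score map.
#' @param min_px Size a cluster must strictly exceed to be counted.
#' @param config An [ic_config()].
#' @param clusters_by_slice Optional precomputed cluster cache.
#' @return Integer count.
#' @export
count_large_clusters <- function(vol, min_px = 135, config = ic_config(),
                                 clusters_by_slice = NULL) {
  stopifnot(min_px >= 1)
  if (is.null(clusters_by_slice)) {
    clusters_by_slice <- detect_clusters_volume(vol, config)
  }
  as.integer(sum(vapply(clusters_by_slice, function(cl) {
    sum(vapply(cl, function(c1) c1$size > min_px, logical(1)))
  }, numeric(1))))
}

#' Left–right asymmetry of an IC map
#'
#' Mean absolute difference between each suprathreshold voxel's z-score
#' and that of its contralateral (x-mirrored) counterpart. A perfectly
#' mirror-symmetric map scores 0; the measure is invariant under
#' reflection of the map.
#'
#' @param vol 3D numeric array with even x-dimension (the midline falls
#'   between the two central sagittal planes); for odd `nx` supply
#'   `midline`, the number of columns in the left half.
#' @param z_threshold Binarization threshold selecting the voxels scored.
#' @param midline Optional left-half width for odd grids.
#' @return Nonnegative scalar.
#' @export
asymmetry <- function(vol, z_threshold = 2, midline = NULL) {
  nx <- dim(vol)[1]
  if (is.null(midline)) {
    if (nx %% 2 != 0) {
      stop("odd x-dimension: supply `midline` explicitly")
    }
  }
  mirrored <- vol[rev(seq_len(nx)), , , drop = FALSE]
  active <- abs(vol) >= z_threshold
  if (!any(active)) return(0)
  mean(abs(vol[active] - mirrored[active]))
}

#' Baseline feature vector of one IC
#'
#' The four features of the shallow-learning (LS-SVM) comparison:
#' number of clusters larger than 135 voxels, left–right asymmetry,
#' wavelet-domain (activelet-style) sparsity and sine-dictionary
#' sparsity, both as Gini indices. Intended for export to any external
#' classifier.
#'
#' @param vol 3D numeric array, the IC map.
#' @param tc Numeric vector, the IC time course.
#' @param tr_seconds Repetition time (s).
#' @param config An [ic_config()].
#' @return One-row data frame: `n_large_clusters`, `asymmetry`,
#'   `gini_activelet`, `gini_sine`.
#' @export
baseline_vector <- function(vol, tc, tr_seconds, config = ic_config()) {
  tf <- temporal_features(tc, tr_seconds, config)
  data.frame(
    n_large_clusters = count_large_clusters(
      vol, config$hunyadi_min_cluster_px, config),
    asymmetry = asymmetry(vol, config$z_threshold),
    gini_activelet = tf$gini_activelet,
    gini_sine = tf$gini_sine_mp
  )
}

#' Baseline feature table for a whole decomposition
#'
#' @param dec An `"ic_decomposition"`.
#' @param config An [ic_config()].
#' @return Data frame with `ic_index` (0-based) and the four features.
#' @export
baseline_table <- function(dec, config = ic_config()) {
  rows <- lapply(seq_len(dec$n_ics), function(i) {
    cbind(ic_index = i - 1L,
          baseline_vector(dec$maps[, , , i], dec$mix[, i],
                          dec$tr_seconds, config))
  })
  do.call(rbind, rows)
}
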