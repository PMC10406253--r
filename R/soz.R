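#' Bullseye score of an IC map
#'
#' Quantifies the concentric nested-activation SOZ marker. The IC is
#' binarized at `z_threshold` and at twice that value; on the slice
#' holding the overall largest low-threshold cluster, the score is the
#' fraction of high-threshold largest-cluster voxels enclosed by (the
#' filled hull of) the low-threshold largest cluster, multiplied by 1
#' when the two cluster centroids lie within 3 voxels and by 0.5
#' otherwise. No low-threshold cluster, or no high-threshold core, gives
#' 0.
#'
#' @param vol 3D numeric array, the IC z-score map.
#' @param config An [ic_config()].
#' @param clusters_by_slice Optional precomputed
#'   [detect_clusters_volume()] result at `config$z_threshold`.
#' @return Scalar in `[0, 1]`.
#' @export
bullseye_score <- function(vol, config = ic_config(),
                           clusters_by_slice = NULL) {
  if (is.null(clusters_by_slice)) {
    clusters_by_slice <- detect_clusters_volume(vol, config)
  }
  sizes <- vapply(clusters_by_slice, function(cl) {
    if (length(cl) == 0) 0L else cl[[1]]$size
  }, integer(1))
  if (max(sizes) == 0) return(0)
  s <- which.max(sizes)
  low <- largest_cluster(clusters_by_slice[[s]])
  hi_clusters <- detect_clusters(
    binarize_slice(vol[, , s], 2 * config$z_threshold),
    eps = config$eps, v_min = config$v_min, metric = config$metric,
    slice_index = s)
  hi <- largest_cluster(hi_clusters)
  if (is.null(hi)) return(0)
  nx <- dim(vol)[1]; ny <- dim(vol)[2]
  low_hull <- as_logical_mask(EBImage::fillHull(cluster_mask(low, nx, ny)))
  frac <- mean(low_hull[cbind(hi$voxels[, 1], hi$voxels[, 2])])
  c_low <- colMeans(low$voxels)
  c_hi <- colMeans(hi$voxels)
  centred <- sqrt(sum((c_low - c_hi)^2)) <= 3
  frac * if (centred) 1 else 0.5
}

#' Maximum Dice overlap with RSN templates
#'
#' @param vol 3D numeric array, the IC z-score map.
#' @param templates Named list of 3D logical template masks on the same
#'   grid (empty list gives 0 with a warning).
#' @param z_threshold Binarization threshold for the IC mask.
#' @return Scalar in `[0, 1]`, plus attribute `best_template`.
#' @export
rsn_template_overlap <- function(vol, templates, z_threshold = 2) {
  if (length(templates) == 0) {
    warning("no RSN templates supplied; overlap set to 0")
    return(structure(0, best_template = NA_character_))
  }
  mask <- abs(vol) >= z_threshold
  n_mask <- sum(mask)
  dices <- vapply(templates, function(tm) {
    stopifnot(all(dim(tm) == dim(vol)))
    inter <- sum(mask & tm)
    denom <- n_mask + sum(tm)
    if (denom == 0) 0 else 2 * inter / denom
  }, numeric(1))
  structure(max(dices), best_template = names(dices)[which.max(dices)])
}

#' SOZ feature vector of one non-noise IC
#'
#' @param vol 3D numeric array, the IC map.
#' @param tc Numeric vector, the IC BOLD time course.
#' @param tr_seconds Repetition time (s).
#' @param contours An `"anatomy_contours"` for the subject.
#' @param templates Named list of RSN template masks.
#' @param config An [ic_config()].
#' @param clusters_by_slice Optional precomputed cluster cache.
#' @return One-row data frame: `bullseye_score`, `gray_matter_fraction`,
#'   `rsn_template_overlap`, `dominant_freq_hz`, `gini_activelet`,
#'   `gini_sine_mp`.
#' @export
soz_features <- function(vol, tc, tr_seconds, contours, templates,
                         config = ic_config(), clusters_by_slice = NULL) {
  tf <- temporal_features(tc, tr_seconds, config)
  if (is.null(clusters_by_slice)) {
    clusters_by_slice <- detect_clusters_volume(vol, config)
  }
  ## spatial features are computed on the cluster-filtered map: isolated
  ## suprathreshold noise voxels (no density support) carry no anatomy
  ## and would dilute the Dice and gray-matter terms
  filt <- array(0, dim(vol))
  for (s in seq_along(clusters_by_slice)) {
    for (cl in clusters_by_slice[[s]]) {
      filt[, , s][cbind(cl$voxels[, 1], cl$voxels[, 2])] <- vol[, , s][
        cbind(cl$voxels[, 1], cl$voxels[, 2])]
    }
  }
  mask <- abs(filt) >= config$z_threshold
  gm <- vapply(seq_len(dim(vol)[3]), function(s) {
    sum(mask[, , s] & contours$slices[[s]]$gray_matter)
  }, numeric(1))
  n_act <- sum(mask)
  data.frame(
    bullseye_score = bullseye_score(vol, config, clusters_by_slice),
    gray_matter_fraction = if (n_act == 0) 0 else sum(gm) / n_act,
    rsn_template_overlap = as.numeric(
      rsn_template_overlap(filt, templates, config$z_threshold)),
    dominant_freq_hz = tf$dominant_freq_hz,
    gini_activelet = tf$gini_activelet,
    gini_sine_mp = tf$gini_sine_mp
  )
}

#' Rule-based RSN/SOZ assignment
#'
#' An IC is SOZ when its dominant frequency exceeds the SOZ frequency
#' marker, it does not overlap an RSN template, and it carries either the
#' bullseye spatial marker or sparse (high-Gini) BOLD activity; otherwise
#' it is an RSN.
#'
#' @param features One-row data frame from [soz_features()].
#' @param config An [ic_config()].
#' @return `"soz"` or `"rsn"`.
#' @export
rule_assign <- function(features, config = ic_config()) {
  soz <- features$dominant_freq_hz > config$soz_freq_hz &&
    features$rsn_template_overlap < config$rsn_overlap_max &&
    (features$bullseye_score >= config$bullseye_min ||
       features$gini_activelet > config$gini_activelet_threshold)
  if (soz) "soz" else "rsn"
}

SOZ_VOTE_FEATURES <- c("dominant_freq_hz", "gini_activelet", "bullseye_score")

#' Maximum-likelihood RSN/SOZ cluster assignment
#'
#' Standardizes the subject's feature vectors and fits a two-component
#' diagonal-covariance Gaussian mixture by maximum likelihood; the
#' component whose mean is higher on the majority of the SOZ-leaning
#' features (dominant frequency, wavelet Gini, bullseye score) is
#' labelled SOZ and ICs are assigned by maximum posterior. Degenerate
#' inputs (single IC, identical features, non-convergence, tied
#' component vote) fall back to [rule_assign()] — or, for identical
#' features, to the conservative all-RSN call.
#'
#' @param features Data frame, one row per non-noise IC.
#' @param config An [ic_config()].
#' @return Character vector of `"rsn"` / `"soz"`, one per row.
#' @importFrom mclust Mclust mclustBIC
#' @export
ml_cluster_assign <- function(features, config = ic_config()) {
  stopifnot(nrow(features) >= 1)
  rule_fallback <- function() {
    vapply(seq_len(nrow(features)), function(i) {
      rule_assign(features[i, , drop = FALSE], config)
    }, character(1))
  }
  if (nrow(features) == 1) return(rule_fallback())
  x <- as.matrix(features[, c("bullseye_score", "gray_matter_fraction",
                              "rsn_template_overlap", "dominant_freq_hz",
                              "gini_activelet", "gini_sine_mp")])
  if (all(apply(x, 2, function(col) diff(range(col)) < 1e-12))) {
    return(rep("rsn", nrow(features)))   # conservative degenerate call
  }
  z <- apply(x, 2, function(col) {
    s <- stats::sd(col)
    if (s < 1e-12) rep(0, length(col)) else (col - mean(col)) / s
  })
  fit <- NULL
  for (model in c("VVI", "EEI")) {   # variable then pooled diagonal covariance
    fit <- try(suppressWarnings(
      Mclust(z, G = 2, modelNames = model, verbose = FALSE)),
      silent = TRUE)
    if (!inherits(fit, "try-error") && !is.null(fit)) break
  }
  if (inherits(fit, "try-error") || is.null(fit)) {
    warning("mixture fit did not converge; using rule-based assignment")
    return(rule_fallback())
  }
  mu <- fit$parameters$mean      # features x components
  vote <- sum(sign(mu[SOZ_VOTE_FEATURES, 2] - mu[SOZ_VOTE_FEATURES, 1]))
  if (vote == 0) {
    warning("tied component vote; using rule-based assignment")
    return(rule_fallback())
  }
  soz_comp <- if (vote > 0) 2L else 1L
  ifelse(fit$classification == soz_comp, "soz", "rsn")
}

#' White-matter-noise override
#'
#' An IC called white-matter noise by the spatial stage is reclassified
#' as SOZ when its BOLD signal is sparse: wavelet-domain Gini index above
#' `gini_activelet_threshold`, or sine-dictionary matching-pursuit Gini
#' above `gini_sine_threshold`. The override is restricted to the
#' white-matter subtype.
#'
#' @param subtype Noise subtype of the IC.
#' @param tf A `"temporal_features"` object for the IC.
#' @param config An [ic_config()].
#' @return List `(reclassify, override)`; `override` is
#'   `"activelet_gini"`, `"sine_gini"` or `"none"`.
#' @export
wm_noise_override <- function(subtype, tf, config = ic_config()) {
  if (!identical(subtype, "white_matter")) {
    return(list(reclassify = FALSE, override = "none"))
  }
  if (tf$gini_activelet > config$gini_activelet_threshold) {
    return(list(reclassify = TRUE, override = "activelet_gini"))
  }
  if (tf$gini_sine_mp > config$gini_sine_threshold) {
    return(list(reclassify = TRUE, override = "sine_gini"))
  }
  list(reclassify = FALSE, override = "none")
}

#' Classify every IC of a subject
#'
#' Full waterfall: anatomy contours from cluster-free reference slices,
#' per-slice density clustering, the two-stage noise classifier, the
#' white-matter-noise sparsity override, then RSN/SOZ assignment of the
#' surviving ICs (maximum-likelihood clustering or rules, per
#' `config$soz_method`). Exactly one label per IC.
#'
#' @param dec An `"ic_decomposition"`.
#' @param templates Named list of RSN template masks; `NULL` builds the
#'   schematic templates for the decomposition's grid.
#' @param config An [ic_config()].
#' @return Data frame of labels (one row per IC): `ic_index` (0-based),
#'   `category`, `noise_subtype`, `override_applied`, and numeric
#'   evidence columns.
#' @export
classify_subject <- function(dec, templates = NULL, config = ic_config()) {
  stopifnot(inherits(dec, "ic_decomposition"))
  if (dec$n_ics == 0) stop("empty decomposition")
  nyq <- 1 / (2 * dec$tr_seconds)
  if (config$mp_band_hz[2] > nyq + 1e-12) {
    stop("matching-pursuit band exceeds the Nyquist frequency ", nyq, " Hz")
  }
  if (is.null(templates)) templates <- generate_templates(dec$dims)
  contours <- subject_contours(dec, config)

  n <- dec$n_ics
  labels <- data.frame(
    ic_index = seq_len(n) - 1L,
    category = rep(NA_character_, n),
    noise_subtype = "none",
    override_applied = "none",
    largest_cluster_size = 0L,
    n_noise_slices = 0L,
    bullseye_score = NA_real_,
    rsn_template_overlap = NA_real_,
    dominant_freq_hz = NA_real_,
    gini_activelet = NA_real_,
    gini_sine_mp = NA_real_,
    stringsAsFactors = FALSE
  )

  pending <- list()  # non-noise ICs awaiting second-level assignment
  for (i in seq_len(n)) {
    vol <- dec$maps[, , , i]
    clusters <- detect_clusters_volume(vol, config)
    stats_df <- ic_slice_stats(clusters, contours)
    labels$largest_cluster_size[i] <- max(stats_df$largest_cluster_size)
    call <- classify_ic_noise(stats_df, config)
    labels$n_noise_slices[i] <- call$n_noise
    if (call$is_noise) {
      labels$category[i] <- "noise"
      labels$noise_subtype[i] <- call$subtype
      if (call$subtype == "white_matter") {
        tf <- temporal_features(dec$mix[, i], dec$tr_seconds, config)
        labels$gini_activelet[i] <- tf$gini_activelet
        labels$gini_sine_mp[i] <- tf$gini_sine_mp
        labels$dominant_freq_hz[i] <- tf$dominant_freq_hz
        ov <- wm_noise_override(call$subtype, tf, config)
        if (ov$reclassify) {
          labels$category[i] <- "soz"
          labels$override_applied[i] <- ov$override
        }
      }
    } else {
      f <- soz_features(vol, dec$mix[, i], dec$tr_seconds, contours,
                        templates, config, clusters_by_slice = clusters)
      labels$bullseye_score[i] <- f$bullseye_score
      labels$rsn_template_overlap[i] <- f$rsn_template_overlap
      labels$dominant_freq_hz[i] <- f$dominant_freq_hz
      labels$gini_activelet[i] <- f$gini_activelet
      labels$gini_sine_mp[i] <- f$gini_sine_mp
      pending[[length(pending) + 1]] <- list(i = i, f = f)
    }
  }

  if (length(pending) > 0) {
    feats <- do.call(rbind, lapply(pending, `[[`, "f"))
    cls <- if (config$soz_method == "ml") {
      ml_cluster_assign(feats, config)
    } else {
      vapply(seq_len(nrow(feats)), function(k) {
        rule_assign(feats[k, , drop = FALSE], config)
      }, character(1))
    }
    for (k in seq_along(pending)) {
      labels$category[pending[[k]]$i] <- cls[k]
    }
  }
  stopifnot(!anyNA(labels$category))
  labels
}
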