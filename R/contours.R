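#' Cluster-free reference slice
#'
#' Builds a background-intensity image for one slice index from the
#' corresponding slices of every IC of a subject: the element-wise median
#' suppresses activation clusters (which sit at different locations in
#' different ICs), and any residual suprathreshold blob is in-painted
#' with the median of a surrounding annulus of background voxels.
#'
#' @param slices List of numeric matrices (the same slice index across
#'   ICs), at least one.
#' @param z_threshold Absolute deviation from the slice median above
#'   which a voxel is treated as residual cluster and in-painted.
#' @return Numeric matrix, the cluster-free reference slice.
#' @export
make_reference_slice <- function(slices, z_threshold = 2) {
  stopifnot(length(slices) >= 1)
  dims <- dim(slices[[1]])
  ref <- if (length(slices) == 1) {
    slices[[1]]
  } else {
    flat <- vapply(slices, as.numeric, numeric(prod(dims)))
    matrix(matrixStats::rowMedians(flat), dims[1], dims[2])
  }
  med0 <- stats::median(ref)
  act <- abs(ref - med0) >= z_threshold
  if (!any(act)) return(ref)
  lab <- EBImage::bwlabel(act)
  kern <- EBImage::makeBrush(5, shape = "box")
  for (id in seq_len(max(lab))) {
    comp <- lab == id
    ring <- EBImage::dilate(comp, kern) & !act
    bg <- if (any(ring)) stats::median(ref[ring]) else med0
    ref[comp] <- bg
  }
  ref
}

#' Sobel gradient magnitude
#'
#' Horizontal and vertical 3x3 Sobel kernels combined as the Euclidean
#' norm; image borders use edge replication.
#'
#' @param ref_slice Numeric matrix.
#' @return Nonnegative numeric matrix of the same dimensions.
#' @export
detect_edges <- function(ref_slice) {
  stopifnot(is.matrix(ref_slice), all(is.finite(ref_slice)))
  nx <- nrow(ref_slice); ny <- ncol(ref_slice)
  pad <- matrix(0, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- ref_slice
  pad[1, ] <- pad[2, ]; pad[nx + 2, ] <- pad[nx + 1, ]
  pad[, 1] <- pad[, 2]; pad[, ny + 2] <- pad[, ny + 1]
  p <- function(dx, dy) pad[(2 + dx):(nx + 1 + dx), (2 + dy):(ny + 1 + dy)]
  gx <- (p(1, -1) + 2 * p(1, 0) + p(1, 1)) -
        (p(-1, -1) + 2 * p(-1, 0) + p(-1, 1))
  gy <- (p(-1, 1) + 2 * p(0, 1) + p(1, 1)) -
        (p(-1, -1) + 2 * p(0, -1) + p(1, -1))
  sqrt(gx^2 + gy^2)
}

empty_slice_contours <- function(dims) {
  list(periphery = matrix(FALSE, dims[1], dims[2]),
       white_matter = matrix(FALSE, dims[1], dims[2]),
       vessels = matrix(FALSE, dims[1], dims[2]),
       gray_matter = matrix(FALSE, dims[1], dims[2]),
       periphery_contour = NULL, wm_contours = list(),
       vessel_contours = list(), empty = TRUE)
}

as_logical_mask <- function(img) {
  m <- as.matrix(img)
  storage.mode(m) <- "logical"
  m
}

#' Extract anatomy contours from one reference slice
#'
#' The Sobel gradient is thresholded at a quantile of its nonzero values,
#' morphologically closed, and the closed contour whose filled region
#' contains all other contours becomes the brain periphery. Inside the
#' periphery, voxel intensities are split into three natural-break
#' classes (deterministic 3-class k-means seeded at intensity quantiles):
#' the brightest class traced into closed contours gives the white
#' matter; low-intensity contours strictly inside the periphery give
#' vessel candidates, kept only in the basal central region (central
#' third of the periphery bounding box) and discarded when enclosed
#' within a white-matter contour (CSF). Slices with no closed contour
#' (outside the brain) return an empty marker, not an error.
#'
#' @param gradient Gradient magnitude from [detect_edges()].
#' @param ref_slice The reference slice the gradient came from.
#' @param config An [ic_config()] (uses `gradient_quantile`).
#' @return A per-slice contour set: filled logical masks `periphery`,
#'   `white_matter`, `vessels`, `gray_matter` (periphery minus the other
#'   two), traced contours, and an `empty` flag.
#' @export
extract_contours <- function(gradient, ref_slice, config = ic_config()) {
  stopifnot(all(dim(gradient) == dim(ref_slice)))
  dims <- dim(ref_slice)
  gz <- gradient[gradient > 1e-12]
  if (length(gz) < 8) return(empty_slice_contours(dims))
  ## adaptive edge threshold: try descending gradient quantiles and keep
  ## the highest one whose strongest component actually closes (its fill
  ## clearly exceeds its outline); a fixed quantile cannot serve both
  ## noisy references (noise floor dominates the quantile) and clean
  ## ones (the quantile guts the contour)
  qs <- sort(unique(c(0.9, config$gradient_quantile, 0.5)),
             decreasing = TRUE)
  best <- NULL
  best_area <- 0
  for (q in qs) {
    edge <- gradient >= stats::quantile(gz, q)
    edge <- as_logical_mask(
      EBImage::closing(edge, EBImage::makeBrush(3, "box")))
    lab <- EBImage::bwlabel(edge)
    n_comp <- max(lab)
    if (n_comp == 0) next
    filled <- lapply(seq_len(n_comp), function(id) {
      as_logical_mask(EBImage::fillHull(lab == id))
    })
    areas <- vapply(filled, sum, numeric(1))
    peri_id <- which.max(areas)
    outline_px <- sum(lab == peri_id)
    closed <- areas[peri_id] >= 25 && areas[peri_id] >= 1.4 * outline_px
    if (closed && areas[peri_id] > best_area) {
      best <- filled[[peri_id]]
      best_area <- areas[peri_id]
    }
  }
  if (is.null(best)) return(empty_slice_contours(dims))
  ## the Sobel edge band straddles the true boundary; shrink the filled
  ## contour by the outer half of the band
  periphery <- as_logical_mask(
    EBImage::erode(best, EBImage::makeBrush(5, "disc")))
  if (sum(periphery) < 25) return(empty_slice_contours(dims))

  ## intensity statistics exclude the residual boundary ring
  inside <- as_logical_mask(
    EBImage::erode(periphery, EBImage::makeBrush(5, "disc")))
  if (sum(inside) < 25) inside <- periphery
  vals <- ref_slice[inside]
  ## natural-break intensity anchors inside the brain: the bulk
  ## (median), the bright tail (white matter) and the dark floor
  ## (vessels are rare dark outliers, so the floor is a low quantile)
  med <- stats::median(vals)
  hi <- stats::quantile(vals, 0.97, names = FALSE)
  lo <- stats::quantile(vals, 0.002, names = FALSE)

  ## white matter: bright regions, only when a bright class is genuinely
  ## separated from the bulk intensity
  wm <- matrix(FALSE, dims[1], dims[2])
  if (hi > 1.25 * max(med, 1e-9)) {
    wm_cand <- inside & ref_slice > (med + hi) / 2
    wlab <- EBImage::bwlabel(wm_cand)
    for (id in seq_len(max(wlab))) {
      comp <- wlab == id
      if (sum(comp) >= 4) wm <- wm | comp
    }
  }

  ## vessels: dark outlier regions in the basal central region, excluding
  ## CSF (dark regions enclosed in a white-matter contour)
  vessels <- matrix(FALSE, dims[1], dims[2])
  if (lo < 0.4 * max(med, 1e-9)) {
    dark <- inside & ref_slice < lo + 0.5 * (med - lo)
    xs <- which(rowSums(periphery) > 0)
    ys <- which(colSums(periphery) > 0)
    cx <- range(xs); cy <- range(ys)
    x_ok <- c(cx[1] + diff(cx) / 3, cx[2] - diff(cx) / 3)
    y_ok <- c(cy[1] + diff(cy) / 3, cy[2] - diff(cy) / 3)
    ## CSF: dark spots sitting within the white-matter region itself
    wm_zone <- if (any(wm)) {
      as_logical_mask(EBImage::dilate(wm, EBImage::makeBrush(3, "box")))
    } else {
      wm
    }
    dlab <- EBImage::bwlabel(dark)
    for (id in seq_len(max(dlab))) {
      comp <- dlab == id
      if (sum(comp) < 2) next
      cc <- which(comp, arr.ind = TRUE)
      ctr <- colMeans(cc)
      central <- ctr[1] >= x_ok[1] && ctr[1] <= x_ok[2] &&
                 ctr[2] >= y_ok[1] && ctr[2] <= y_ok[2]
      in_wm <- mean(wm_zone[comp]) > 0.5
      if (central && !in_wm) vessels <- vessels | comp
    }
  }

  wm <- wm & periphery
  vessels <- vessels & periphery & !wm
  list(
    periphery = periphery,
    white_matter = wm,
    vessels = vessels,
    gray_matter = periphery & !wm & !vessels,
    periphery_contour = trace_contour(periphery),
    wm_contours = trace_contours(wm),
    vessel_contours = trace_contours(vessels),
    empty = FALSE
  )
}

trace_contour <- function(mask) {
  if (!any(mask)) return(NULL)
  oc <- EBImage::ocontour(EBImage::bwlabel(mask))
  if (length(oc) == 0) return(NULL)
  oc[[1]] + 1L   # EBImage contours are 0-based
}

trace_contours <- function(mask) {
  if (!any(mask)) return(list())
  oc <- EBImage::ocontour(EBImage::bwlabel(mask))
  lapply(oc, function(p) p + 1L)
}

#' Anatomy contours for a whole subject
#'
#' Builds cluster-free reference slices from all ICs of a decomposition,
#' detects edges and extracts periphery / white-matter / vessel masks for
#' every slice.
#'
#' @param dec An `ic_decomposition` (see [load_decomposition()]).
#' @param config An [ic_config()].
#' @return Object of class `"anatomy_contours"`: a list with `slices`
#'   (per-slice contour sets), `reference` (3D array of reference
#'   slices) and `dims`.
#' @export
subject_contours <- function(dec, config = ic_config()) {
  dims <- dec$dims
  ref <- array(0, dims)
  slices <- vector("list", dims[3])
  for (s in seq_len(dims[3])) {
    sl <- lapply(seq_len(dec$n_ics), function(i) dec$maps[, , s, i])
    ref[, , s] <- make_reference_slice(sl, config$z_threshold)
    slices[[s]] <- extract_contours(detect_edges(ref[, , s]), ref[, , s],
                                    config)
  }
  structure(list(slices = slices, reference = ref, dims = dims),
            class = "anatomy_contours")
}
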