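#' Binarize one IC slice
#'
#' Retains both activation and deactivation: a voxel is active when its
#' absolute z-score reaches `z_threshold` (boundary inclusive).
#'
#' @param slice Numeric matrix, one axial slice of an IC z-score map.
#' @param z_threshold Nonnegative scalar.
#' @return Logical matrix of the same dimensions.
#' @export
binarize_slice <- function(slice, z_threshold) {
  stopifnot(is.matrix(slice), is.numeric(slice), z_threshold >= 0)
  if (!all(is.finite(slice))) stop("slice contains non-finite values")
  abs(slice) >= z_threshold
}

## Integer lattice offsets within distance eps of the origin, origin excluded.
neighbour_offsets <- function(eps, metric = "euclidean") {
  r <- floor(eps)
  if (metric == "manhattan" || metric == "chebyshev") r <- floor(eps)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  d <- switch(metric,
    euclidean = sqrt(g$dx^2 + g$dy^2),
    manhattan = abs(g$dx) + abs(g$dy),
    chebyshev = pmax(abs(g$dx), abs(g$dy))
  )
  keep <- d <= eps & !(g$dx == 0 & g$dy == 0)
  data.frame(dx = g$dx[keep], dy = g$dy[keep], d = d[keep])
}

## Shift a logical/numeric matrix by (dx, dy), padding with `fill`.
shift_mat <- function(m, dx, dy, fill = FALSE) {
  nx <- nrow(m); ny <- ncol(m)
  out <- matrix(fill, nx, ny)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  if (length(xs) > 0 && length(ys) > 0) {
    out[xs, ys] <- m[xs - dx, ys - dy]
  }
  out
}

#' Density-based voxel cluster detection in one slice
#'
#' Scans a binary activation mask with an epsilon-neighbourhood density
#' rule. A voxel with strictly more than `v_min` active voxels in its
#' epsilon-neighbourhood is a core point; an active non-core voxel within
#' epsilon of a core point is a border point and joins the cluster of the
#' nearest core point (ties broken towards the core point with the lowest
#' (x, y) lexicographic coordinate); all other active voxels are ignored.
#' Core points within epsilon of one another share a cluster.
#'
#' @param mask Logical matrix (active voxels `TRUE`).
#' @param eps Neighbourhood radius in voxel units.
#' @param v_min Minimum neighbour count (strict).
#' @param metric Distance metric name.
#' @param slice_index Slice index recorded on each cluster (1-based).
#' @return A list of clusters, each a list with elements `voxels`, `core`,
#'   `border` (two-column integer matrices of (x, y) coordinates), `size`
#'   and `slice_index`. Clusters are ordered by decreasing size, ties by
#'   lowest minimal (x, y) coordinate. Empty masks give an empty list.
#' @export
detect_clusters <- function(mask, eps, v_min, metric = "euclidean",
                            slice_index = 1L) {
  stopifnot(is.matrix(mask), is.logical(mask), eps > 0, v_min >= 1)
  if (!any(mask)) return(list())
  nx <- nrow(mask); ny <- ncol(mask)
  offs <- neighbour_offsets(eps, metric)
  n_off <- nrow(offs)

  counts <- matrix(0L, nx, ny)
  for (i in seq_len(n_off)) {
    counts <- counts + shift_mat(mask, offs$dx[i], offs$dy[i])
  }
  core <- mask & counts > v_min
  if (!any(core)) return(list())

  core_idx <- which(core)                       # column-major linear indices
  core_id <- matrix(0L, nx, ny)
  core_id[core_idx] <- seq_along(core_idx)

  ## Union core points that lie within eps of each other.
  edges <- NULL
  for (i in seq_len(n_off)) {
    nb <- shift_mat(core, offs$dx[i], offs$dy[i])
    both <- which(core & nb)
    if (length(both) > 0) {
      from <- core_id[both]
      ## neighbour position: shift by (dx, dy) means source voxel is at -off
      src <- both - offs$dx[i] - offs$dy[i] * nx
      to <- core_id[src]
      edges <- rbind(edges, cbind(from, to))
    }
  }
  n_core <- length(core_idx)
  if (is.null(edges)) {
    comp <- seq_len(n_core)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n_core - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_len(n_core)]
  }

  ## Border points: active, not core, within eps of a core point; assigned
  ## to the nearest core point, lexicographic (x, y) tie-break.
  border_cluster <- matrix(0L, nx, ny)
  border_dist <- matrix(Inf, nx, ny)
  border_core_src <- matrix(NA_integer_, nx, ny)
  candidate <- mask & !core
  ## lexicographic key of the core voxel reachable through each offset
  for (i in order(offs$d)) {
    dx <- offs$dx[i]; dy <- offs$dy[i]; d <- offs$d[i]
    nb_core <- shift_mat(core, dx, dy)
    hit <- which(candidate & nb_core)
    if (length(hit) == 0) next
    src <- hit - dx - dy * nx
    better <- d < border_dist[hit]
    if (d > 0) {
      ## equal distance: prefer the core with lower (x, y) lexicographic key
      eq <- d == border_dist[hit]
      if (any(eq)) {
        cur_key <- core_key(border_core_src[hit[eq]], nx)
        new_key <- core_key(src[eq], nx)
        better[eq] <- new_key < cur_key
      }
    }
    upd <- hit[better]
    if (length(upd) > 0) {
      border_dist[upd] <- d
      border_cluster[upd] <- comp[core_id[src[better]]]
      border_core_src[upd] <- src[better]
    }
  }

  assemble_clusters(core_idx, comp, border_cluster, nx, ny, slice_index)
}

## lexicographic (x, y) order key of a linear (column-major) index
core_key <- function(lin, nx) {
  x <- ((lin - 1L) %% nx) + 1L
  y <- ((lin - 1L) %/% nx) + 1L
  x * (2^20) + y
}

assemble_clusters <- function(core_idx, comp, border_cluster, nx, ny,
                              slice_index) {
  ids <- sort(unique(comp))
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    cidx <- core_idx[comp == id]
    bidx <- which(border_cluster == id)
    core_xy <- cbind(x = ((cidx - 1L) %% nx) + 1L,
                     y = ((cidx - 1L) %/% nx) + 1L)
    border_xy <- cbind(x = ((bidx - 1L) %% nx) + 1L,
                       y = ((bidx - 1L) %/% nx) + 1L)
    vox <- rbind(core_xy, border_xy)
    o <- order(vox[, 1], vox[, 2])
    out[[k]] <- list(
      voxels = vox[o, , drop = FALSE],
      core = core_xy[order(core_xy[, 1], core_xy[, 2]), , drop = FALSE],
      border = border_xy[order(border_xy[, 1], border_xy[, 2]), ,
                         drop = FALSE],
      size = nrow(vox),
      slice_index = as.integer(slice_index)
    )
  }
  ## deterministic ordering: size descending, then lowest minimal (x, y)
  keys <- vapply(out, function(cl) min(core_key(
    (cl$voxels[, 2] - 1L) * nx + cl$voxels[, 1], nx)), numeric(1))
  sizes <- vapply(out, function(cl) cl$size, numeric(1))
  out[order(-sizes, keys)]
}

#' Largest voxel cluster
#'
#' @param clusters List of clusters as returned by [detect_clusters()].
#' @return The cluster with maximal size (ties: lowest minimal (x, y)
#'   lexicographic coordinate), or `NULL` for an empty list.
#' @export
largest_cluster <- function(clusters) {
  if (length(clusters) == 0) return(NULL)
  clusters[[1]]   # detect_clusters orders by size then coordinate
}

## logical mask of a cluster's voxels on an nx-by-ny grid
cluster_mask <- function(cluster, nx, ny) {
  m <- matrix(FALSE, nx, ny)
  m[cbind(cluster$voxels[, 1], cluster$voxels[, 2])] <- TRUE
  m
}

#' Detect clusters on every slice of an IC volume
#'
#' Convenience wrapper binarizing each slice at `config$z_threshold` and
#' running [detect_clusters()].
#'
#' @param vol 3D numeric array (x, y, slice).
#' @param config An [ic_config()].
#' @return A list (one element per slice) of cluster lists.
#' @export
detect_clusters_volume <- function(vol, config = ic_config()) {
  stopifnot(length(dim(vol)) == 3)
  lapply(seq_len(dim(vol)[3]), function(s) {
    detect_clusters(binarize_slice(vol[, , s], config$z_threshold),
                    eps = config$eps, v_min = config$v_min,
                    metric = config$metric, slice_index = s)
  })
}
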