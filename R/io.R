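#' Build an IC decomposition object
#'
#' In-memory container for one subject's ICA decomposition: a 4D array of
#' IC spatial z-score maps (x, y, slice, IC) and the aligned T x N mixing
#' matrix of BOLD time courses.
#'
#' @param maps 4D numeric array `(nx, ny, nslices, n_ics)`.
#' @param mix Numeric matrix, rows = time points, columns = ICs.
#' @param tr_seconds Repetition time in seconds.
#' @param subject_id Opaque subject identifier.
#' @return Object of class `"ic_decomposition"`.
#' @export
ic_decomposition <- function(maps, mix, tr_seconds, subject_id = "subject") {
  stopifnot(length(dim(maps)) == 4, is.matrix(mix), tr_seconds > 0)
  if (dim(maps)[4] != ncol(mix)) {
    stop("alignment error: ", dim(maps)[4], " IC maps but ", ncol(mix),
         " mixing-matrix columns")
  }
  bad <- which(apply(maps, 4, function(v) any(!is.finite(v))))
  if (length(bad) > 0) {
    stop("non-finite voxels in IC map(s): ",
         paste(bad - 1L, collapse = ", "), " (0-based)")
  }
  if (any(!is.finite(mix))) stop("non-finite values in mixing matrix")
  structure(list(
    maps = maps, mix = mix, tr_seconds = tr_seconds,
    subject_id = subject_id,
    dims = dim(maps)[1:3], n_ics = dim(maps)[4], t_len = nrow(mix)
  ), class = "ic_decomposition")
}

#' @export
print.ic_decomposition <- function(x, ...) {
  cat(sprintf(
    "IC decomposition '%s': %d ICs on a %d x %d x %d grid, T = %d, TR = %g s\n",
    x$subject_id, x$n_ics, x$dims[1], x$dims[2], x$dims[3], x$t_len,
    x$tr_seconds))
  invisible(x)
}

#' Load an ICA decomposition from disk
#'
#' Reads the MELODIC-style layout: a 4D NIfTI of IC z-score maps (one 3D
#' volume per IC) plus a whitespace-delimited T x N mixing matrix (rows =
#' time, columns = ICs).
#'
#' @param ic_maps_path Path to the 4D NIfTI (.nii or .nii.gz).
#' @param mix_path Path to the plain-text mixing matrix.
#' @param tr_seconds Repetition time in seconds.
#' @param subject_id Subject identifier stored on the object.
#' @return An `"ic_decomposition"`.
#' @export
load_decomposition <- function(ic_maps_path, mix_path, tr_seconds,
                               subject_id = basename(ic_maps_path)) {
  if (!file.exists(ic_maps_path)) stop("IC map file not found: ", ic_maps_path)
  if (!file.exists(mix_path)) stop("mixing matrix not found: ", mix_path)
  img <- RNifti::readNifti(ic_maps_path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) == 3) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 4) {
    stop("expected a 4D NIfTI, got ", length(dim(arr)), " dimensions")
  }
  mix <- as.matrix(utils::read.table(mix_path))
  dimnames(mix) <- NULL
  ic_decomposition(arr, mix, tr_seconds, subject_id)
}

#' Write an IC decomposition to disk
#'
#' Writes the layout consumed by [load_decomposition()]: a 4D NIfTI of IC
#' maps (double precision, so phantom round-trips are bit-exact) and a
#' whitespace-delimited mixing matrix.
#'
#' @param dec An `"ic_decomposition"`.
#' @param ic_maps_path,mix_path Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_decomposition <- function(dec, ic_maps_path, mix_path) {
  stopifnot(inherits(dec, "ic_decomposition"))
  RNifti::writeNifti(dec$maps, ic_maps_path, datatype = "double")
  utils::write.table(dec$mix, mix_path, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(ic_maps_path, mix_path))
}

LABEL_COLUMNS <- c("ic_index", "category", "noise_subtype",
                   "override_applied")

#' Write / read IC labels
#'
#' Labels are a data frame with one row per IC: `ic_index` (0-based, the
#' MELODIC convention), `category` (`noise`/`rsn`/`soz`), `noise_subtype`
#' (`none`/`boundary`/`white_matter`/`vessel`/`small_clusters`),
#' `override_applied` (`none`/`activelet_gini`/`sine_gini`) and any
#' numeric evidence columns. Written as CSV with a deterministic column
#' order (the four label columns first, evidence columns sorted by name).
#'
#' @param labels Data frame of labels, non-empty.
#' @param path Output CSV path.
#' @return `write_labels()` returns `path` invisibly; `read_labels()`
#'   returns the data frame.
#' @export
write_labels <- function(labels, path) {
  if (!is.data.frame(labels) || nrow(labels) == 0) {
    stop("labels must be a non-empty data frame")
  }
  missing_cols <- setdiff(LABEL_COLUMNS, names(labels))
  if (length(missing_cols) > 0) {
    stop("labels missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  evidence <- sort(setdiff(names(labels), LABEL_COLUMNS))
  out <- labels[, c(LABEL_COLUMNS, evidence), drop = FALSE]
  ok <- try(utils::write.csv(out, path, row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop("failed to write labels to ", path, ": ", attr(ok, "condition")$message)
  }
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
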