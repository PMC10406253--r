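pkg_version <- function() {
  as.character(utils::packageVersion("sozica"))
}

write_manifest <- function(path, config, inputs, seed, counts) {
  manifest <- list(
    version = pkg_version(),
    seed = seed,
    inputs = inputs,
    config = unclass(config),
    counts = counts
  )
  stopifnot(counts$total == counts$noise + counts$rsn + counts$soz)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a phantom subject on disk
#'
#' Writes the decomposition layout ([write_decomposition()]) plus the
#' ground-truth label CSV and a run manifest into `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param spec A [phantom_spec()].
#' @return Invisibly, a named list of the written paths.
#' @export
run_phantom <- function(out_dir, spec = phantom_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subj <- generate_subject(spec)
  paths <- list(
    ic_maps = file.path(out_dir, "ic_maps.nii.gz"),
    mix = file.path(out_dir, "melodic_mix.txt"),
    truth = file.path(out_dir, "truth_labels.csv"),
    manifest = file.path(out_dir, "phantom_manifest.json")
  )
  write_decomposition(subj$dec, paths$ic_maps, paths$mix)
  truth <- subj$truth
  truth$override_applied <- "none"
  write_labels(truth, paths$truth)
  counts <- list(total = nrow(truth),
                 noise = sum(truth$category == "noise"),
                 rsn = sum(truth$category == "rsn"),
                 soz = sum(truth$category == "soz"))
  write_manifest(paths$manifest, ic_config(), list(spec = unclass(spec)),
                 spec$seed, counts)
  invisible(paths)
}

#' Classify a decomposition from disk
#'
#' Loads the MELODIC-style layout, runs the full waterfall classifier,
#' and writes the label CSV, a per-IC evidence table and a run manifest.
#'
#' @param ic_maps_path,mix_path Input paths ([load_decomposition()]).
#' @param tr_seconds Repetition time (s).
#' @param out_dir Output directory (created if missing).
#' @param config An [ic_config()].
#' @param templates_dir Optional directory of NIfTI template masks
#'   (filenames become network labels); `NULL` uses the schematic
#'   templates for the data's grid.
#' @return Invisibly, a named list of the written paths.
#' @export
run_classify <- function(ic_maps_path, mix_path, tr_seconds, out_dir,
                         config = ic_config(), templates_dir = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dec <- load_decomposition(ic_maps_path, mix_path, tr_seconds)
  templates <- if (is.null(templates_dir)) {
    NULL
  } else {
    load_templates(templates_dir, dec$dims)
  }
  labels <- classify_subject(dec, templates, config)
  paths <- list(
    labels = file.path(out_dir, "labels.csv"),
    manifest = file.path(out_dir, "run_manifest.json")
  )
  write_labels(labels, paths$labels)
  counts <- list(total = nrow(labels),
                 noise = sum(labels$category == "noise"),
                 rsn = sum(labels$category == "rsn"),
                 soz = sum(labels$category == "soz"))
  write_manifest(paths$manifest, config,
                 list(ic_maps = ic_maps_path, mix = mix_path,
                      tr_seconds = tr_seconds),
                 NA, counts)
  invisible(paths)
}

#' Load RSN template masks from a directory of NIfTI files
#'
#' @param dir Directory holding `<network>.nii` / `<network>.nii.gz`
#'   binary masks on the data grid.
#' @param dims Expected grid, checked per template.
#' @return Named list of 3D logical arrays.
#' @export
load_templates <- function(dir, dims) {
  files <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  if (length(files) == 0) stop("no NIfTI templates found in ", dir)
  out <- lapply(files, function(f) {
    arr <- array(as.numeric(RNifti::readNifti(f)) > 0.5, dim = dims)
    arr
  })
  names(out) <- sub("\\.nii(\\.gz)?$", "", basename(files))
  out
}

#' Evaluate label files
#'
#' Scores a predicted-label CSV against a truth CSV on both objectives
#' and writes the metric report (CSV and JSON).
#'
#' @param labels_path,truth_path Label CSVs ([write_labels()] layout).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the metrics data frame (one row per objective).
#' @export
run_eval <- function(labels_path, truth_path, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pred <- read_labels(labels_path)
  truth <- read_labels(truth_path)
  if (nrow(pred) != nrow(truth) ||
      !setequal(pred$ic_index, truth$ic_index)) {
    stop("label files disagree on the IC set (", nrow(pred), " vs ",
         nrow(truth), " ICs)")
  }
  ev <- evaluate_labels(pred, truth)
  rows <- do.call(rbind, lapply(names(ev), function(obj) {
    cbind(objective = obj, ev[[obj]]$metrics,
          as.data.frame(ev[[obj]]$counts[c("tp", "tn", "fp", "fn")]))
  }))
  utils::write.csv(rows, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(rows, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rows)
}

#' Run the phantom recovery study
#'
#' Generates `n_subjects` phantom subjects (seeds `seed_base + 1 ..
#' seed_base + n_subjects`), classifies each with the supplied
#' configuration, scores both objectives per subject and aggregates
#' across subjects. This is the package's headline experiment.
#'
#' @param n_subjects Number of phantom subjects.
#' @param seed_base Integer; subject k uses seed `seed_base + k`.
#' @param spec_args Named list of overrides passed to [phantom_spec()].
#' @param config An [ic_config()].
#' @return List with `per_subject` (metrics per subject and objective),
#'   `aggregate` (per-objective mean/sd table), and `soz_counts`
#'   (predicted SOZ ICs per subject).
#' @export
phantom_study <- function(n_subjects = 10, seed_base = 0L,
                          spec_args = list(), config = ic_config()) {
  per_subject <- list()
  soz_counts <- integer(n_subjects)
  total_ics <- 0L
  for (k in seq_len(n_subjects)) {
    spec <- do.call(phantom_spec,
                    c(list(seed = as.integer(seed_base + k)), spec_args))
    subj <- generate_subject(spec)
    labels <- classify_subject(subj$dec, subj$templates, config)
    ev <- evaluate_labels(labels, subj$truth)
    soz_counts[k] <- sum(labels$category == "soz")
    total_ics <- total_ics + nrow(labels)
    for (obj in names(ev)) {
      per_subject[[length(per_subject) + 1]] <-
        cbind(subject = k, objective = obj, ev[[obj]]$metrics)
    }
  }
  per_subject <- do.call(rbind, per_subject)
  agg <- do.call(rbind, lapply(unique(per_subject$objective), function(o) {
    cbind(objective = o,
          aggregate_metrics(per_subject[per_subject$objective == o, ]))
  }))
  list(per_subject = per_subject, aggregate = agg,
       soz_counts = soz_counts, total_ics = total_ics)
}
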