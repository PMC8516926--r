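# On-disk artifact plumbing: cohort manifests, TSV matrices and result
# tables.  Conventions: tab-separated values with a header row; matrix files
# are purely numeric with parcel ids as column names; all time indices are
# written 0-based (documented in each writer) and converted to R's 1-based
# indexing on read.

new_cohort_store <- function(subjects, parcels, tr_seconds) {
  stopifnot_scalar_positive(tr_seconds, "tr_seconds")
  R <- nrow(parcels)
  for (id in names(subjects)) {
    s <- subjects[[id]]
    if (ncol(s$cortex) != R) {
      stop(sprintf("shape error: subject '%s' has %d parcels, expected %d",
                   id, ncol(s$cortex), R), call. = FALSE)
    }
    if (!is.null(colnames(s$cortex)) &&
        !identical(colnames(s$cortex), parcels$parcel_id)) {
      stop(sprintf("shape error: subject '%s' parcel ordering differs from sidecar", id),
           call. = FALSE)
    }
  }
  structure(list(subjects = subjects, parcels = parcels, tr_seconds = tr_seconds),
            class = "cohort_store")
}

#' @export
print.cohort_store <- function(x, ...) {
  Tn <- nrow(x$subjects[[1]]$cortex)
  cat(sprintf("cohort_store: %d subjects, %d parcels, %d time points, TR = %.3f s\n",
              length(x$subjects), nrow(x$parcels), Tn, x$tr_seconds))
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a cohort to disk
#'
#' Writes one cortical matrix TSV and one subcortical TSV per subject, a
#' shared parcel-metadata sidecar, optional ground truth, and a YAML
#' manifest consumable by [load_cohort()].  Ground-truth and event indices
#' are written 0-based.
#'
#' @param cohort a `cohort_store`.
#' @param out_dir output directory (created if needed).
#' @param truth optional per-subject ground truth from [generate_cohort()].
#' @return path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, out_dir, truth = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  write_tsv(cohort$parcels, file.path(out_dir, "parcels.tsv"))
  subjects <- lapply(names(cohort$subjects), function(id) {
    s <- cohort$subjects[[id]]
    cmat <- as.data.frame(s$cortex)
    names(cmat) <- cohort$parcels$parcel_id
    write_tsv(cmat, file.path(out_dir, paste0(id, "_cortex.tsv")))
    write_tsv(s$subcort, file.path(out_dir, paste0(id, "_subcortical.tsv")))
    list(id = id, cortex = paste0(id, "_cortex.tsv"),
         subcortical = paste0(id, "_subcortical.tsv"))
  })
  if (!is.null(truth)) {
    ev <- truth_events(truth)
    if (!is.null(ev)) {
      ev$t0 <- ev$t0 - 1L  # indices on disk are 0-based
      write_tsv(ev, file.path(out_dir, "ground_truth_events.tsv"))
    }
  }
  manifest <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(tr_seconds = cohort$tr_seconds, parcels = "parcels.tsv",
                        subjects = subjects), manifest)
  invisible(manifest)
}

#' Load a cohort from a manifest
#'
#' Reads the YAML manifest written by [write_cohort()] (or hand-authored in
#' the same layout), validates that every referenced file exists and that
#' all subjects share the same parcel count and ordering.
#'
#' @param manifest_path path to the manifest.
#' @return a `cohort_store`.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path, call. = FALSE)
  m <- yaml::read_yaml(manifest_path)
  root <- dirname(manifest_path)
  resolve <- function(p) if (startsWith(p, "/")) p else file.path(root, p)
  parcels <- read_tsv(resolve(m$parcels))
  subjects <- list()
  for (s in m$subjects) {
    for (field in c("cortex", "subcortical")) {
      p <- resolve(s[[field]])
      if (!file.exists(p)) {
        stop(sprintf("load error: subject '%s' is missing file '%s'", s$id, s[[field]]),
             call. = FALSE)
      }
    }
    cmat <- as.matrix(read_tsv(resolve(s$cortex)))
    subcort <- read_tsv(resolve(s$subcortical))
    subjects[[s$id]] <- list(cortex = cmat, subcort = subcort)
  }
  new_cohort_store(subjects, parcels, m$tr_seconds)
}

# ---------------------------------------------------------------------------
# Result writers/readers.  write_results() dispatches on class; each format
# round-trips exactly for integer fields and to full stored precision for
# reals (numbers serialised with 17 significant digits).

fmt_num <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Write a pipeline result to disk
#'
#' Generic writer with methods for phasic event sets, energy landscapes,
#' wave fits and event-locked responses.  Layouts are delimited tables with
#' a JSON metadata sidecar where the object carries parameters; all time
#' indices are written 0-based.
#'
#' @param result a pipeline output object.
#' @param out_dir directory to write into (created if needed).
#' @return the main file path written, invisibly.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("unwritable output directory", call. = FALSE)
  UseMethod("write_results")
}

#' @export
write_results.phasic_events <- function(result, out_dir) {
  ev <- result$events
  ev$t0 <- ev$t0 - 1L  # 0-based on disk
  path <- file.path(out_dir, "events.tsv")
  write_tsv(fmt_num(ev), path)
  meta <- result[setdiff(names(result), "events")]
  jsonlite::write_json(meta, file.path(out_dir, "events_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phasic event set written by [write_results()]
#' @param dir directory containing `events.tsv` and `events_meta.json`.
#' @return a `phasic_events` object.
#' @export
read_events <- function(dir) {
  ev <- read_tsv(file.path(dir, "events.tsv"))
  ev$t0 <- as.integer(ev$t0) + 1L
  meta <- jsonlite::read_json(file.path(dir, "events_meta.json"), simplifyVector = TRUE)
  for (nm in c("accel_sd", "sustain_sd", "sustain_window", "boundary")) {
    meta[[nm]] <- as.numeric(meta[[nm]])
  }
  meta$series_lengths <- lapply(meta$series_lengths, as.integer)
  structure(c(list(events = ev), meta), class = "phasic_events")
}

#' @export
write_results.energy_landscape <- function(result, out_dir) {
  grid <- expand.grid(lag = result$lags, msd = result$msd_grid)
  grid <- grid[order(grid$lag, grid$msd), ]
  df <- data.frame(condition = result$condition, lag = grid$lag, msd = grid$msd,
                   P = as.vector(t(result$P)), E = as.vector(t(result$E)),
                   flagged = as.integer(as.vector(t(result$flagged))),
                   n = result$n)
  path <- file.path(out_dir, paste0("landscape_", gsub("[^A-Za-z0-9]+", "_", result$condition), ".tsv"))
  write_tsv(fmt_num(df), path)
  invisible(path)
}

#' Read an energy landscape written by [write_results()]
#' @param path the landscape TSV path.
#' @return an `energy_landscape` object.
#' @export
read_landscape <- function(path) {
  df <- read_tsv(path)
  df$P <- as.numeric(df$P); df$E <- as.numeric(df$E)
  lags <- sort(unique(df$lag)); grid <- sort(unique(df$msd))
  shape <- function(col) {
    m <- matrix(col[order(df$lag, df$msd)], length(lags), length(grid), byrow = TRUE)
    dimnames(m) <- list(lag = lags, msd = grid)
    m
  }
  structure(list(P = shape(df$P), E = shape(df$E),
                 flagged = shape(df$flagged) > 0,
                 msd_grid = grid, lags = lags, n = df$n[1],
                 condition = df$condition[1],
                 bandwidth = NA_real_),
            class = "energy_landscape")
}

#' @export
write_results.wave_fit <- function(result, out_dir) {
  df <- data.frame(parcel_id = result$parcel_id, ttp_s = result$time_to_peak_s,
                   y_mm = result$y_mm)
  path <- file.path(out_dir, "wave_fit.tsv")
  write_tsv(fmt_num(df), path)
  jsonlite::write_json(list(velocity_m_per_s = result$velocity_m_per_s,
                            direction_sign = result$direction_sign,
                            fit_r2 = result$fit_r2,
                            slope_s_per_mm = result$slope_s_per_mm),
                       file.path(out_dir, "wave_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_results.event_locked_response <- function(result, out_dir) {
  df <- data.frame(lag = result$lags, mean = result$mean, sem = result$sem)
  if (!is.null(result$null_ci)) {
    df$null_low <- result$null_ci[, 1]
    df$null_high <- result$null_ci[, 2]
  }
  path <- file.path(out_dir, paste0("response_", result$label, ".tsv"))
  write_tsv(fmt_num(df), path)
  invisible(path)
}

#' Read an event-locked response written by [write_results()]
#' @param path the response TSV path.
#' @return an `event_locked_response` object.
#' @export
read_response <- function(path) {
  df <- read_tsv(path)
  label <- sub("^response_", "", sub("\\.tsv$", "", basename(path)))
  out <- list(lags = as.integer(df$lag), mean = as.numeric(df$mean),
              sem = as.numeric(df$sem), label = label, null_ci = NULL)
  if ("null_low" %in% names(df)) {
    out$null_ci <- cbind(low = as.numeric(df$null_low), high = as.numeric(df$null_high))
  }
  structure(out, class = "event_locked_response")
}

#' Mean ROI time series from voxel data in a NIfTI mask
#'
#' Convenience extractor for users starting from voxel-level NIfTI images;
#' the pipeline proper starts from parcellated matrices.
#'
#' @param bold_path path to a 4D NIfTI BOLD image.
#' @param mask_path path to a 3D NIfTI mask (non-zero voxels define the ROI).
#' @return numeric vector: the mean over mask voxels at each time point.
#' @export
nifti_roi_mean <- function(bold_path, mask_path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("the 'RNifti' package is required for NIfTI input", call. = FALSE)
  }
  bold <- RNifti::readNifti(bold_path)
  mask <- RNifti::readNifti(mask_path)
  d <- dim(bold)
  vox <- which(mask != 0)
  mat <- matrix(bold, prod(d[1:3]), d[4])
  colMeans(mat[vox, , drop = FALSE])
}
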