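# Persistence and rendering: runs are written as a directory of plain-text
# artefacts (full-precision CSV field matrices, 0/1 mask matrices, a YAML
# config, JSON metadata and metrics) plus optional PNG renders.

write_matrix_exact <- function(M, path) {
  # %.17g round-trips doubles exactly through as.numeric()
  lines <- apply(M, 1, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

read_matrix_exact <- function(path) {
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  do.call(rbind, lapply(rows, as.numeric))
}

#' Save a run (and optionally its metrics) to a directory
#'
#' Layout: `config.yaml` (resolved configuration), `meta.json` (seed, model,
#' times, config hash), `snapshots/NNN/` with one full-precision CSV per
#' field plus the three masks, and `metrics.json` / `metrics.csv` when
#' metrics are supplied. Field CSVs round-trip bit-identically through
#' [load_run_fields()].
#'
#' @param run A `ds_run`.
#' @param out_path Output directory (created).
#' @param metrics Optional `pattern_metrics` (or list of them, one per
#'   snapshot).
#' @param snapshots Indices of snapshots to write (default: final only).
#' @return `out_path`, invisibly.
#' @export
save_outputs <- function(run, out_path, metrics = NULL, snapshots = NULL) {
  ok <- dir.create(out_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_path)) stop("cannot create output directory: ", out_path)
  cfgp <- file.path(out_path, "config.yaml")
  save_config(run$config, cfgp)
  if (is.null(snapshots)) snapshots <- length(run$snapshots)
  for (si in snapshots) {
    sd <- file.path(out_path, "snapshots", sprintf("%03d", si))
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    snap <- run$snapshots[[si]]
    for (nm in names(snap$fields))
      write_matrix_exact(snap$fields[[nm]],
                         file.path(sd, paste0("field_", nm, ".csv")))
    for (nm in c("omega", "committed", "crescent"))
      write_mask_csv(snap$masks[[nm]], file.path(sd, paste0(nm, ".csv")))
  }
  meta <- list(model = run$model, variant = run$variant, seed = run$seed,
               times = run$times, nsteps = run$nsteps,
               snapshots_written = snapshots,
               config_hash = unname(tools::md5sum(cfgp)),
               package_version = as.character(utils::packageVersion("dotstripe")))
  jsonlite::write_json(meta, file.path(out_path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(metrics)) {
    if (inherits(metrics, "pattern_metrics")) metrics <- list(metrics)
    rows <- do.call(rbind, lapply(metrics, metrics_row))
    utils::write.csv(rows, file.path(out_path, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lapply(metrics, function(m)
      m[setdiff(names(m), "dot_points")]),
      file.path(out_path, "metrics.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(out_path)
}

#' Read field matrices back from a saved snapshot
#'
#' @param out_path Directory written by [save_outputs()].
#' @param snapshot Snapshot index.
#' @return Named list of field matrices.
#' @export
load_run_fields <- function(out_path, snapshot) {
  sd <- file.path(out_path, "snapshots", sprintf("%03d", snapshot))
  files <- list.files(sd, pattern = "^field_.*\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no fields found under ", sd)
  out <- lapply(files, read_matrix_exact)
  names(out) <- sub("^field_(.*)\\.csv$", "\\1", basename(files))
  out
}

#' Render a snapshot to PNG
#'
#' @param run A `ds_run`.
#' @param path Output PNG path.
#' @param field,snapshot As in [plot.ds_run()].
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
render_png <- function(run, path, field = NULL, snapshot = NULL,
                       width = 800, height = 400) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot(run, field = field, snapshot = snapshot)
  invisible(path)
}
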