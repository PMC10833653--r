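#' Read an ROI time-series table
#'
#' Rectangular TSV/CSV with a header row of ROI ids and one row per volume.
#' Missing or non-numeric cells are rejected with the offending location.
#'
#' @param path file path.
#' @param tr_seconds sampling interval to attach.
#' @param subject_id id to attach (default: file name without extension).
#' @return a [roi_timeseries()].
#' @export
read_timeseries <- function(path, tr_seconds = 0.8, subject_id = NULL) {
  dt <- data.table::fread(path, header = TRUE, sep = "auto")
  M <- as.matrix(dt)
  if (!is.numeric(M)) {
    bad <- which(!vapply(dt, is.numeric, logical(1)))
    stop(sprintf("non-numeric column(s) in %s: %s", path,
                 paste(names(dt)[bad], collapse = ", ")))
  }
  if (anyNA(M)) {
    ij <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value in %s at row %d, column '%s'",
                 path, ij[1], colnames(M)[ij[2]]))
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  roi_timeseries(M, tr_seconds = tr_seconds, subject_id = subject_id)
}

#' Write an ROI time-series table
#'
#' @param ts a [roi_timeseries()].
#' @param path output TSV path.
#' @export
write_timeseries <- function(ts, path) {
  M <- ts$data
  colnames(M) <- paste0("ROI", seq_len(ncol(M)))
  data.table::fwrite(as.data.frame(M), path, sep = "\t")
  invisible(path)
}

#' Read an atlas membership table
#'
#' Columns `roi_id`, `hemisphere` (L/R) and `rsn` (one of the seven
#' canonical RSN acronyms); every ROI appears exactly once.
#'
#' @param path CSV/TSV path.
#' @param R expected ROI count (optional check).
#' @return validated data.frame.
#' @export
read_membership <- function(path, R = NULL) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  need <- c("roi_id", "hemisphere", "rsn")
  if (!all(need %in% names(df)))
    stop(sprintf("membership table must have columns: %s",
                 paste(need, collapse = ", ")))
  if (anyDuplicated(df$roi_id))
    stop(sprintf("duplicate roi_id: %s",
                 df$roi_id[anyDuplicated(df$roi_id)]))
  if (!all(df$hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R'")
  bad <- setdiff(unique(df$rsn), rsn_labels())
  if (length(bad) > 0)
    stop(sprintf("unknown RSN label(s) %s; allowed: %s",
                 paste(bad, collapse = ", "),
                 paste(rsn_labels(), collapse = ", ")))
  if (!is.null(R) && nrow(df) != R)
    stop(sprintf("membership has %d ROIs, expected %d", nrow(df), R))
  df[need]
}

#' Write a synthetic cohort to disk
#'
#' Per-subject, per-scale time-series TSVs, a cohort CSV (subject id, group,
#' label, score), a JSON ground-truth file (per-subject latent epoch
#' states), and per-scale membership CSVs.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sc in names(cohort$timeseries)) {
    scdir <- file.path(dir, sc)
    dir.create(scdir, showWarnings = FALSE)
    for (i in seq_along(cohort$timeseries[[sc]])) {
      ts <- cohort$timeseries[[sc]][[i]]
      write_timeseries(ts, file.path(scdir, paste0(ts$subject_id, ".tsv")))
    }
    data.table::fwrite(cohort$membership[[sc]],
                       file.path(dir, paste0("membership_", sc, ".csv")))
  }
  data.table::fwrite(cohort$subjects, file.path(dir, "subjects.csv"))
  gt <- list(states = stats::setNames(cohort$states, cohort$subjects$subject_id),
             epoch_volumes = cohort$spec$epoch_volumes,
             burnin_volumes = cohort$spec$burnin_volumes)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

run_manifest <- function(config, seed, extra = list()) {
  c(list(package = "dfcnstate",
         version = as.character(utils::packageVersion("dfcnstate")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed,
         config_hash = digest_config(config)),
    extra)
}

# tiny structural hash (no external digest dependency): serialize + sum
digest_config <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw) * seq_along(raw)) %% .Machine$integer.max)
}
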