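# CSV schemas:
#   trial:    t,pos_x,pos_y,pos_z,acc_x,acc_y,acc_z   (SI units)
#   manifest: subject_id,group,trial_index,file,trigger_time,end_time,
#             vabs_com,vabs_dl,vabs_soc

trial_csv_cols <- c("t", "pos_x", "pos_y", "pos_z", "acc_x", "acc_y", "acc_z")
manifest_cols <- c("subject_id", "group", "trial_index", "file",
                   "trigger_time", "end_time", "vabs_com", "vabs_dl",
                   "vabs_soc")

# Write a data.frame with numeric columns rounded to 6 significant digits so
# repeated runs produce byte-identical files.
write_csv_num <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = 6L)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write one trial recording to CSV
#'
#' @param rec a [trial_recording].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_trial_csv <- function(rec, path) {
  stopifnot(inherits(rec, "trial_recording"))
  df <- data.frame(t = rec$t,
                   pos_x = rec$pos[, 1L], pos_y = rec$pos[, 2L],
                   pos_z = rec$pos[, 3L],
                   acc_x = rec$acc[, 1L], acc_y = rec$acc[, 2L],
                   acc_z = rec$acc[, 3L])
  write_csv_num(df, path)
}

#' Write a simulated cohort to disk
#'
#' Writes one trial CSV per recording under `dir/trials/` and a manifest CSV
#' referencing them.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "trials"), recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  for (i in seq_along(cohort$trials)) {
    rec <- cohort$trials[[i]]
    rel <- file.path("trials",
                     sprintf("%s_t%02d.csv", rec$subject_id, rec$trial_index))
    write_trial_csv(rec, file.path(dir, rel))
    manifest$file[manifest$subject_id == rec$subject_id &
                    manifest$trial_index == rec$trial_index] <- rel
  }
  path <- file.path(dir, "manifest.csv")
  write_csv_num(manifest[, manifest_cols], path)
  invisible(path)
}

#' Read a cohort back from a manifest
#'
#' Parses header-keyed CSVs (column order is irrelevant), validates the
#' schema and the time base, and rebuilds [trial_recording] objects.
#'
#' @param manifest_path path to a manifest CSV.
#' @param sample_rate optional override; by default inferred from the time
#'   vector of each trial.
#' @return A list with `trials` and `manifest`.
#' @export
read_trials <- function(manifest_path, sample_rate = NULL) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(manifest_cols, c("vabs_com", "vabs_dl", "vabs_soc")),
                     names(manifest))
  if (length(missing) > 0L)
    stop("manifest lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(manifest) == 0L) stop("no trials in manifest", call. = FALSE)
  base <- dirname(manifest_path)
  trials <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    fp <- file.path(base, row$file)
    if (!file.exists(fp))
      stop(sprintf("manifest row %d: trial file not found: %s", i, row$file),
           call. = FALSE)
    df <- utils::read.csv(fp, stringsAsFactors = FALSE)
    miss <- setdiff(trial_csv_cols, names(df))
    if (length(miss) > 0L)
      stop(sprintf("%s: missing columns: %s", row$file,
                   paste(miss, collapse = ", ")), call. = FALSE)
    t <- df$t
    if (any(diff(t) <= 0))
      stop(sprintf("%s: time vector not strictly increasing", row$file),
           call. = FALSE)
    sr <- if (is.null(sample_rate)) 1 / stats::median(diff(t)) else sample_rate
    trials[[i]] <- trial_recording(
      subject_id = row$subject_id, group_label = row$group,
      trial_index = row$trial_index, sample_rate = sr, t = t,
      pos = as.matrix(df[, c("pos_x", "pos_y", "pos_z")]),
      acc = as.matrix(df[, c("acc_x", "acc_y", "acc_z")]),
      trigger_time = row$trigger_time, end_time = row$end_time)
  }
  list(trials = trials, manifest = manifest)
}

#' Write a feature table to CSV
#' @param features feature table from [extract_cohort_features()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_feature_table <- function(features, path) write_csv_num(features, path)

#' Read a feature table CSV
#' @param path feature table CSV written by [write_feature_table()].
#' @return A data.frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
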