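# Tidy delimited trial layout: tab-separated, first header line = column
# names, second header line = units, then data rows at full double precision.
# A JSON sidecar (<stem>.json) carries subject metadata, the generating
# config, and -- for synthetic trials -- the ground truth.

trial_columns <- function() {
  c("time", paste0("emg_", required_muscles),
    "ankle_angle", "mtp_angle", "arch_length", "ankle_moment", "grf_vertical")
}

trial_units <- function() {
  c("s", rep("mvc", length(required_muscles)),
    "rad", "rad", "m", "N.m/kg", "N")
}

#' Write a trial to the tidy delimited time-series layout
#'
#' One clock column plus one column per signal; the first header line holds
#' column names, the second holds units. Values are written at full double
#' precision so a written trial round-trips bit-identically. A JSON sidecar
#' `<stem>.json` records subject mass, speed, stride duration, sample rate,
#' and optionally the generating config and ground truth.
#'
#' @param trial a `synthetic_trial` (or an equally shaped bundle).
#' @param path output file path (e.g. `trial.tsv`).
#' @param ground_truth optional `ground_truth` to embed in the sidecar.
#' @param config optional [trial_config()] to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, ground_truth = NULL, config = NULL) {
  cols <- c(list(trial$time),
            trial$envelopes[required_muscles],
            list(trial$ankle_angle, trial$mtp_angle, trial$arch_length,
                 trial$ankle_moment, trial$grf_vertical))
  mat <- do.call(cbind, lapply(cols, as.numeric))
  colnames(mat) <- trial_columns()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(trial_columns(), collapse = "\t"), con)
  writeLines(paste(trial_units(), collapse = "\t"), con)
  body <- apply(mat, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(body, con)
  sidecar <- list(subject_mass = trial$subject_mass, speed = trial$speed,
                  stride_duration = trial$stride_duration,
                  sample_rate = trial$sample_rate)
  if (!is.null(config)) sidecar$config <- unclass(config)
  if (!is.null(ground_truth)) sidecar$ground_truth <- unclass(ground_truth)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a trial written in the tidy delimited layout
#'
#' Validates the schema (all required columns present, units parseable) and
#' returns an in-memory bundle shaped like a `synthetic_trial`. A clock column
#' in milliseconds is converted to seconds. Metadata are taken from the JSON
#' sidecar when present.
#'
#' @param path trial file path.
#' @return a `synthetic_trial`; attribute `"ground_truth"` carries the
#'   sidecar's ground truth when present.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  hdr <- readLines(path, n = 2L)
  if (length(hdr) < 2L)
    stop("schema error: file lacks the two header lines (names, units)",
         call. = FALSE)
  nms <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]]
  units <- strsplit(hdr[2], "\t", fixed = TRUE)[[1]]
  miss <- setdiff(trial_columns(), nms)
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(units) != length(nms) || any(!nzchar(units)))
    stop("schema error: units header must give a unit for every column",
         call. = FALSE)
  dat <- utils::read.table(path, sep = "\t", skip = 2L, header = FALSE,
                           col.names = nms, colClasses = "numeric")
  tu <- units[match("time", nms)]
  time <- switch(tu,
                 s = dat$time,
                 ms = dat$time / 1000,
                 stop("schema error: unsupported time unit '", tu, "'",
                      call. = FALSE))
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  fs <- if (!is.null(meta$sample_rate)) meta$sample_rate else
    1 / stats::median(diff(time))
  envs <- lapply(required_muscles, function(m) dat[[paste0("emg_", m)]])
  names(envs) <- required_muscles
  trial <- structure(list(
    time = time,
    envelopes = envs,
    ankle_angle = dat$ankle_angle,
    mtp_angle = dat$mtp_angle,
    arch_length = dat$arch_length,
    ankle_moment = dat$ankle_moment,
    grf_vertical = dat$grf_vertical,
    sample_rate = fs,
    subject_mass = if (!is.null(meta$subject_mass)) meta$subject_mass else NA_real_,
    speed = if (!is.null(meta$speed)) meta$speed else NA_real_,
    stride_duration = if (!is.null(meta$stride_duration)) meta$stride_duration
    else NA_real_,
    units = stats::setNames(units, nms)
  ), class = "synthetic_trial")
  if (!is.null(meta$ground_truth))
    attr(trial, "ground_truth") <- meta$ground_truth
  trial
}

#' Read a muscle-parameter config (YAML or JSON)
#'
#' Accepts either a top-level list of muscle records or a `muscles` field
#' holding one; each record needs `name`, `pcsa`, `pennation`, `r_ankle`,
#' `r_mtp`. The result is validated by [make_muscle_set()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `muscle_set`.
#' @export
read_muscle_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported muscle config format: .", ext, call. = FALSE)
  if (!is.null(raw$muscles)) raw <- raw$muscles
  tab <- if (is.data.frame(raw)) raw else
    do.call(rbind, lapply(raw, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  make_muscle_set(tab)
}

#' Write the tables and JSON summaries of a pipeline run
#'
#' Emits `fit.tsv` (subject, speed, EMD, scaling factor, R^2), `metrics.tsv`
#' (peak Push-off power and work per source waveform), `overestimates.tsv`,
#' `waveforms.tsv` (the decomposition on the stride grid), and
#' `provenance.json`; plus `sensitivity.json` when the run included the Monte
#' Carlo analysis.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  fit <- report$fit
  wt(data.frame(subject = fit$subject_id, speed = fit$speed,
                emd_s = fit$emd, scaling_N_per_kg_cm2 = fit$scaling,
                r_squared = fit$r_squared), "fit.tsv")
  wt(report$metrics, "metrics.tsv")
  wt(report$overestimates, "overestimates.tsv")
  d <- report$decomposition
  wf <- data.frame(pct_stride = stride_pct(d$p_ank_model),
                   p_ank_id = wf_values(d$inverse_dynamics),
                   p_ank_model = wf_values(d$p_ank_model),
                   p_fdhl_ank = wf_values(d$p_fdhl_ank),
                   p_fdhl_foot = wf_values(d$p_fdhl_foot),
                   p_fdhl = wf_values(d$p_fdhl),
                   p_mtu_min = wf_values(d$p_mtu_min),
                   p_mtu = wf_values(d$p_mtu))
  wt(wf, "waveforms.tsv")
  if (!is.null(report$sensitivity)) {
    s <- report$sensitivity
    jsonlite::write_json(
      list(nominal_work = s$nominal_work, min_work = s$min_work,
           max_work = s$max_work, max_relative_change = s$max_relative_change,
           n_samples = length(s$work_samples), n_excluded = s$n_excluded,
           seed = s$seed, units = s$units),
      file.path(dir, "sensitivity.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(data.frame(work = s$work_samples),
                       file.path(dir, "sensitivity_samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
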