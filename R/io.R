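# Readers and writers for the plain-text interchange formats: trace files
# (TSV: time_s, v_pos0...) with a JSON metadata sidecar, YAML geometry
# configs, sensilla CSV tables, and run manifests. Decimal commas (as
# sometimes found in exported tables) are normalized to "." on read.

.read_delim_checked <- function(path, required, delim = "\t") {
  if (!file.exists(path)) stop_validation("File not found: %s", path)
  df <- tryCatch(
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE,
                      locale = readr::locale(decimal_mark = ".")),
    error = function(e) stop_validation("Cannot parse %s: %s", path,
                                        conditionMessage(e))
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_validation("%s is missing required column(s): %s.",
                    path, paste(missing_cols, collapse = ", "))
  }
  df
}

#' Write an EAG recording to a trace file + metadata sidecar
#'
#' Produces `<prefix>.tsv` (columns `time_s`, `v_pos0`, ...,
#' `v_pos{N-1}`, voltages in mV), `<prefix>.meta.json` (onset, duration,
#' rate, odorant, individual, species, control file reference) and, when
#' controls are present, `<prefix>.control.tsv`.
#'
#' @param recording An [eag_recording()].
#' @param prefix Output path prefix (no extension).
#' @return The prefix, invisibly.
#' @export
write_recording <- function(recording, prefix) {
  if (!inherits(recording, "eag_recording")) {
    stop_validation("`recording` must be an `eag_recording`.")
  }
  n <- ncol(recording$traces)
  tb <- tibble::as_tibble(recording$traces,
                          .name_repair = ~ paste0("v_pos", seq_len(n) - 1L))
  tb <- dplyr::bind_cols(tibble::tibble(time_s = recording$time_s), tb)
  readr::write_tsv(tb, paste0(prefix, ".tsv"), progress = FALSE)
  ctrl_file <- NULL
  if (!is.null(recording$control_traces)) {
    ctrl <- Reduce(`+`, recording$control_traces) /
      length(recording$control_traces)
    cb <- tibble::as_tibble(ctrl,
                            .name_repair = ~ paste0("v_pos", seq_len(n) - 1L))
    cb <- dplyr::bind_cols(tibble::tibble(time_s = recording$time_s), cb)
    ctrl_file <- paste0(basename(prefix), ".control.tsv")
    readr::write_tsv(cb, paste0(prefix, ".control.tsv"), progress = FALSE)
  }
  meta <- list(
    sampling_rate_hz = recording$sampling_rate_hz,
    stimulus_onset_s = recording$stimulus_onset_s,
    stimulus_duration_s = recording$stimulus_duration_s,
    odorant = recording$odorant,
    individual = recording$individual,
    species = recording$species,
    n_positions = n,
    control_file = ctrl_file
  )
  jsonlite::write_json(meta, paste0(prefix, ".meta.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(prefix)
}

#' Read an EAG recording written by [write_recording()]
#'
#' @param prefix Path prefix (or the `.tsv` path itself).
#' @return An [eag_recording()].
#' @export
read_recording <- function(prefix) {
  prefix <- sub("\\.tsv$", "", prefix)
  meta_path <- paste0(prefix, ".meta.json")
  if (!file.exists(meta_path)) {
    stop_validation("Metadata sidecar not found: %s", meta_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  vcols <- paste0("v_pos", seq_len(meta$n_positions) - 1L)
  df <- .read_delim_checked(paste0(prefix, ".tsv"), c("time_s", vcols))
  if (any(!is.finite(as.matrix(df[vcols])))) {
    stop_validation("%s contains non-finite voltages.", paste0(prefix, ".tsv"))
  }
  if (any(diff(df$time_s) <= 0)) {
    stop_validation("%s: time_s is not strictly increasing.",
                    paste0(prefix, ".tsv"))
  }
  ctrl <- NULL
  if (!is.null(meta$control_file) && !is.na(meta$control_file)) {
    cpath <- file.path(dirname(paste0(prefix, ".tsv")), meta$control_file)
    cdf <- .read_delim_checked(cpath, c("time_s", vcols))
    ctrl <- as.matrix(cdf[vcols])
  }
  eag_recording(
    traces = as.matrix(df[vcols]),
    time_s = df$time_s,
    sampling_rate_hz = meta$sampling_rate_hz,
    stimulus_onset_s = meta$stimulus_onset_s,
    stimulus_duration_s = meta$stimulus_duration_s,
    control_traces = ctrl,
    odorant = meta$odorant %||% NA_character_,
    individual = meta$individual %||% NA_character_,
    species = meta$species %||% NA_character_
  )
}

#' Read a funiculus geometry config (YAML/JSON)
#'
#' Expected keys: `species`, `length_mm`, `width_mm`, `thickness_mm`,
#' optional `positions_norm` and `sigma`.
#'
#' @param path Path to the config file.
#' @return A [funiculus_geometry()].
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop_validation("File not found: %s", path)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_validation(
                    "Cannot parse geometry config %s: %s", path,
                    conditionMessage(e)))
  for (key in c("length_mm", "width_mm", "thickness_mm")) {
    if (is.null(cfg[[key]])) {
      stop_validation("Geometry config %s is missing `%s`.", path, key)
    }
  }
  pos <- cfg$positions_norm
  funiculus_geometry(
    length_mm = cfg$length_mm,
    width_mm = cfg$width_mm,
    thickness_mm = cfg$thickness_mm,
    n_positions = if (is.null(pos)) 4L else length(pos),
    positions_norm = pos,
    sigma = cfg$sigma %||% 10,
    species = cfg$species
  )
}

#' Write a funiculus geometry config
#'
#' @param geom A [funiculus_geometry()].
#' @param path Output YAML path.
#' @export
write_geometry <- function(geom, path) {
  yaml::write_yaml(
    list(species = geom$species, length_mm = geom$length_mm,
         width_mm = geom$width_mm, thickness_mm = geom$thickness_mm,
         positions_norm = geom$positions_norm, sigma = geom$sigma),
    path, precision = 15)
  invisible(path)
}

#' Read a sensilla annotation CSV
#'
#' Columns: `x_norm`, `y_norm`, `type` (trichoid|basiconic|clavate|
#' coeloconic) and optionally `individual`, `species`.
#'
#' @param path CSV path.
#' @param face_area_mm2 Optional lateral-face area.
#' @return A [sensilla_map()].
#' @export
read_sensilla <- function(path, face_area_mm2 = NULL) {
  df <- .read_delim_checked(path, c("x_norm", "y_norm", "type"), delim = ",")
  sensilla_map(df, face_area_mm2 = face_area_mm2)
}

#' Write a sensilla map to CSV
#'
#' @param map A [sensilla_map()].
#' @param path Output CSV path.
#' @export
write_sensilla <- function(map, path) {
  readr::write_csv(tibble::as_tibble(map), path, progress = FALSE)
  invisible(path)
}

#' Write a tidy table to delimited text
#'
#' @param x Data frame.
#' @param path Output path (`.csv` writes comma-separated, anything else
#'   tab-separated).
#' @export
write_table <- function(x, path) {
  if (grepl("\\.csv$", path)) readr::write_csv(x, path, progress = FALSE)
  else readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Run manifest for reproducible command-line runs
#'
#' Records the command, input paths with MD5 content hashes, the
#' parameter set, the seed and the package version, so a run can be
#' reproduced or audited.
#'
#' @param command Command name.
#' @param inputs Character vector of input paths.
#' @param params Named list of parameters.
#' @param seed Seed used (or `NULL`).
#' @param path Optional output path; when given the manifest JSON is
#'   written there.
#' @return The manifest (list), invisibly when written.
#' @export
run_manifest <- function(command, inputs = character(0), params = list(),
                         seed = NULL, path = NULL) {
  hashes <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(inputs))
  } else list()
  manifest <- list(
    command = command,
    inputs = hashes,
    params = params,
    seed = seed,
    tool = "olfactomap",
    version = as.character(utils::packageVersion("olfactomap")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                         digits = NA)
    return(invisible(manifest))
  }
  manifest
}
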