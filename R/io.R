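#' Write / read a valve trajectory as CSV
#'
#' Columns: `time_s`, `c_leaflet1..3`, `dcdt_leaflet1..3`, `pvoa_cm2`.
#'
#' @param trajectory a [integrate_valve()] result.
#' @param path output CSV path.
#' @return (write) the path, invisibly; (read) a data.frame.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  df <- data.frame(
    time_s = trajectory$time,
    c_leaflet1 = trajectory$c[, 1], c_leaflet2 = trajectory$c[, 2],
    c_leaflet3 = trajectory$c[, 3],
    dcdt_leaflet1 = trajectory$dcdt[, 1], dcdt_leaflet2 = trajectory$dcdt[, 2],
    dcdt_leaflet3 = trajectory$dcdt[, 3],
    pvoa_cm2 = trajectory$pvoa_cm2
  )
  utils::write.csv(format(df, digits = 17, scientific = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path)
}

#' Export a valve surface mesh as a Wavefront OBJ triangle list
#'
#' @param geometry a [build_valve_geometry()] object.
#' @param path OBJ path.
#' @param configuration which node configuration to export: `"closed"`,
#'   `"open"`, or a length-3 vector of leaflet openings `c` (linear
#'   mapping) for an intermediate shape.
#' @return the path, invisibly.
#' @export
write_mesh_obj <- function(geometry, path, configuration = "closed") {
  v <- if (identical(configuration, "closed")) {
    geometry$x_close
  } else if (identical(configuration, "open")) {
    geometry$x_open
  } else {
    leaflet_kinematics(geometry, valve_mapping("linear"),
                       configuration)$position
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("f %d %d %d", geometry$tri[, 1], geometry$tri[, 2],
                     geometry$tri[, 3]), con)
  invisible(path)
}

#' Write / read a source panel set as CSV
#'
#' Columns: `cx, cy, cz, nx, ny, nz, area`.
#'
#' @param panels a [build_canonical_aorta()] panel set.
#' @param path CSV path.
#' @return (write) the path, invisibly; (read) a `source_panels` object
#'   (geometry only).
#' @export
write_panels_csv <- function(panels, path) {
  df <- data.frame(cx = panels$centroid[, 1], cy = panels$centroid[, 2],
                   cz = panels$centroid[, 3], nx = panels$normal[, 1],
                   ny = panels$normal[, 2], nz = panels$normal[, 3],
                   area = panels$area)
  utils::write.csv(format(df, digits = 17, scientific = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panels_csv
#' @export
read_panels_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(centroid = as.matrix(df[, c("cx", "cy", "cz")]),
                 normal = as.matrix(df[, c("nx", "ny", "nz")]),
                 area = df$area),
            class = "source_panels")
}

#' Write / read an acceleration record as CSV
#'
#' Columns: `time_s`, `accel_mps2`.
#'
#' @param record an [acoustic_record()].
#' @param path CSV path.
#' @param fs sampling rate when reading (inferred from the time column if
#'   omitted).
#' @return (write) the path, invisibly; (read) an [acoustic_record()].
#' @export
write_record_csv <- function(record, path) {
  df <- data.frame(time_s = record$time, accel_mps2 = record$a)
  utils::write.csv(format(df, digits = 17, scientific = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_record_csv
#' @export
read_record_csv <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  if (is.null(fs)) fs <- round(1 / stats::median(diff(df$time_s)))
  acoustic_record(df$accel_mps2, fs)
}

#' Export an acoustic record as a WAV file
#'
#' Minimal 16-bit PCM RIFF writer. The signal is peak-normalized (audition
#' only; not analysis-grade -- absolute amplitude is not preserved).
#'
#' @param record an [acoustic_record()].
#' @param path WAV path.
#' @param peak target peak amplitude in `(0, 1]`; default 0.95.
#' @return the path, invisibly.
#' @export
write_record_wav <- function(record, path, peak = 0.95) {
  stopifnot(peak > 0, peak <= 1)
  x <- record$a
  m <- max(abs(x))
  if (m > 0) x <- x / m * peak
  samples <- as.integer(round(x * 32767))
  fs <- as.integer(record$fs)
  n <- length(samples)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little") # byte rate
  writeBin(2L, con, size = 2, endian = "little")  # block align
  writeBin(16L, con, size = 2, endian = "little") # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(samples, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file written by [write_record_wav()]
#'
#' @param path WAV path.
#' @return an [acoustic_record()] with amplitudes in `[-1, 1]`.
#' @export
read_record_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("parse error: not a RIFF file")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("parse error: not a WAVE file")
  fs <- NULL
  repeat {
    tag <- readChar(con, 4)
    if (length(tag) == 0 || nchar(tag) < 4) stop("parse error: no data chunk")
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (tag == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1) stop("parse error: only PCM supported")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "raw", size - 8))
    } else if (tag == "data") {
      samples <- readBin(con, "integer", size / 2, size = 2,
                         endian = "little")
      return(acoustic_record(samples / 32767, fs))
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
}

#' Save / load a trained pipeline as JSON
#'
#' Persists the ensemble mean, retained right singular vectors, singular
#' values, LDA direction and threshold (everything [classify_signal()]
#' needs) in a single JSON container.
#'
#' @param pipeline a [train_pipeline()] object.
#' @param path JSON path.
#' @return (write) the path, invisibly; (read) a reduced `murmur_pipeline`
#'   usable by [classify_signal()].
#' @export
write_pipeline_json <- function(pipeline, path) {
  P <- pipeline$P_train
  obj <- list(
    a_bar = pipeline$a_bar,
    v = pipeline$basis$v[, seq_len(P), drop = FALSE],
    d = pipeline$basis$d[seq_len(P)],
    P_cv = pipeline$P_cv,
    P_train = P,
    w = pipeline$lda$w,
    threshold = pipeline$lda$threshold,
    classes = as.list(pipeline$lda$classes)
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_json
#' @export
read_pipeline_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lda <- structure(list(w = obj$w, threshold = obj$threshold,
                        classes = unlist(obj$classes)),
                   class = "lda_model")
  structure(list(a_bar = obj$a_bar,
                 basis = structure(list(v = as.matrix(obj$v), d = obj$d),
                                   class = "svd_basis"),
                 P_cv = obj$P_cv, P_train = obj$P_train, lda = lda),
            class = "murmur_pipeline")
}

#' Write / read a run configuration as YAML
#'
#' @param cfg a [default_config()] list.
#' @param path YAML path.
#' @return (write) the path, invisibly; (read) the `run_config` list.
#' @export
write_config_yaml <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Write a dataset manifest as JSON
#'
#' @param manifest a data.frame (e.g. from [generate_dataset()]).
#' @param path JSON path.
#' @return (write) the path, invisibly; (read) the manifest data.frame.
#' @export
write_manifest_json <- function(manifest, path) {
  jsonlite::write_json(manifest, path, digits = NA)
  invisible(path)
}

#' @rdname write_manifest_json
#' @export
read_manifest_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
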