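# Channel order is fixed across the package and the CSV dialect.
.vt_channels <- c("acc_ap", "acc_ml", "acc_vt", "gyr_sag", "gyr_fro", "gyr_hor")
.vt_meta_keys <- c("subject_id", "session", "site", "side", "sampling_rate_hz")

#' Sensor metadata for an IMU recording
#'
#' Describes one inertial measurement unit: where it is mounted (tibial
#' tuberosity or lateral femoral condyle), on which side, and at what
#' sampling rate. The default rate of 200 Hz matches the acquisition setup
#' the index was developed for.
#'
#' @param site Mounting site, `"tibia"` or `"femur"`.
#' @param side `"left"` or `"right"`.
#' @param sampling_rate_hz Sampling rate in Hz (positive; default 200).
#' @param subject_id Subject identifier (free text).
#' @param session_label Session label, e.g. `"day1"` / `"day2"`.
#' @return An object of class `imu_meta`.
#' @export
imu_meta <- function(site = c("tibia", "femur"), side = c("left", "right"),
                     sampling_rate_hz = 200, subject_id = "",
                     session_label = "day1") {
  site <- match.arg(site)
  side <- match.arg(side)
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a single positive number", call. = FALSE)
  }
  structure(
    list(site = site, side = side,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         subject_id = as.character(subject_id)[1L],
         session_label = as.character(session_label)[1L]),
    class = "imu_meta"
  )
}

#' Construct an IMU recording
#'
#' A synchronized 6-channel time series from one sensor: 3-axis acceleration
#' (anteroposterior, mediolateral, vertical; m/s^2) and 3-plane angular
#' velocity (sagittal, frontal, horizontal; deg/s), with explicit timestamps
#' so that dropped samples remain detectable.
#'
#' Hard requirements (errors): all seven sequences the same length, at least
#' two samples, finite strictly increasing timestamps. Soft conformance
#' (sampling regularity, sensor ranges) is reported by
#' [validate_recording()] as findings, not errors.
#'
#' @param time_s Timestamps in seconds, strictly increasing.
#' @param acc_ap,acc_ml,acc_vt Acceleration channels (m/s^2).
#' @param gyr_sag,gyr_fro,gyr_hor Angular-velocity channels (deg/s).
#' @param meta An [imu_meta()] object.
#' @return An object of class `imu_recording` with elements `meta` and
#'   `data` (a data frame with columns `time_s` and the six channels).
#' @export
imu_recording <- function(time_s, acc_ap, acc_ml, acc_vt,
                          gyr_sag, gyr_fro, gyr_hor, meta = imu_meta()) {
  if (!inherits(meta, "imu_meta")) stop("`meta` must be an `imu_meta` object", call. = FALSE)
  chans <- list(time_s = time_s, acc_ap = acc_ap, acc_ml = acc_ml,
                acc_vt = acc_vt, gyr_sag = gyr_sag, gyr_fro = gyr_fro,
                gyr_hor = gyr_hor)
  lens <- lengths(chans)
  if (length(unique(lens)) != 1L) {
    stop("all channels must have identical length (got ",
         paste(lens, collapse = ", "), ")", call. = FALSE)
  }
  if (lens[1L] < 2L) stop("a recording needs at least 2 samples", call. = FALSE)
  chans <- lapply(chans, as.numeric)
  if (anyNA(chans$time_s) || any(!is.finite(chans$time_s))) {
    stop("timestamps must be finite", call. = FALSE)
  }
  if (any(diff(chans$time_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  structure(list(meta = meta, data = as.data.frame(chans)),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  m <- x$meta
  n <- nrow(x$data)
  dur <- x$data$time_s[n] - x$data$time_s[1L]
  cat(sprintf("IMU recording: %s %s, subject '%s', session '%s'\n",
              m$side, m$site, m$subject_id, m$session_label))
  cat(sprintf("  %d samples over %.2f s at %g Hz\n", n, dur, m$sampling_rate_hz))
  invisible(x)
}

#' Validate an IMU recording against sensor and sampling conformance rules
#'
#' Checks sampling regularity (consecutive timestamp differences within
#' +/-1% of the nominal sampling interval) and the sensor measurement
#' ranges (+/-60 m/s^2 for acceleration, +/-2000 deg/s for angular
#' velocity). Violations are reported as findings -- the data may still be
#' usable -- never as exceptions.
#'
#' @param rec An [imu_recording()].
#' @param acc_range_ms2 Acceleration range limit (m/s^2).
#' @param gyr_range_degs Angular-velocity range limit (deg/s).
#' @param dt_tol Relative tolerance on the sampling interval.
#' @return A data frame of findings with columns `code`, `severity`,
#'   `message`, `first_index`, `last_index`; zero rows when conforming.
#' @export
validate_recording <- function(rec, acc_range_ms2 = 60,
                               gyr_range_degs = 2000, dt_tol = 0.01) {
  stopifnot(inherits(rec, "imu_recording"))
  findings <- list()
  add <- function(code, severity, message, idx) {
    findings[[length(findings) + 1L]] <<- data.frame(
      code = code, severity = severity, message = message,
      first_index = min(idx), last_index = max(idx),
      stringsAsFactors = FALSE)
  }
  dt_nom <- 1 / rec$meta$sampling_rate_hz
  dt <- diff(rec$data$time_s)
  bad <- which(abs(dt - dt_nom) > dt_tol * dt_nom)
  if (length(bad)) {
    add("irregular_sampling", "warning",
        sprintf("irregular sampling: %d interval(s) deviate more than %.0f%% from %.6g s",
                length(bad), 100 * dt_tol, dt_nom), c(bad, bad + 1L))
  }
  acc <- as.matrix(rec$data[, c("acc_ap", "acc_ml", "acc_vt")])
  over <- which(abs(acc) > acc_range_ms2, arr.ind = TRUE)
  if (nrow(over)) {
    add("acc_out_of_range", "warning",
        sprintf("out-of-range acceleration: %d sample(s) exceed +/-%g m/s^2",
                nrow(over), acc_range_ms2), over[, "row"])
  }
  gyr <- as.matrix(rec$data[, c("gyr_sag", "gyr_fro", "gyr_hor")])
  over <- which(abs(gyr) > gyr_range_degs, arr.ind = TRUE)
  if (nrow(over)) {
    add("gyr_out_of_range", "warning",
        sprintf("out-of-range angular velocity: %d sample(s) exceed +/-%g deg/s",
                nrow(over), gyr_range_degs), over[, "row"])
  }
  if (!length(findings)) {
    return(data.frame(code = character(), severity = character(),
                      message = character(), first_index = integer(),
                      last_index = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' Read an IMU recording from CSV
#'
#' The dialect is plain UTF-8 text: leading comment lines `#key=value` for
#' the metadata keys `subject_id`, `session`, `site`, `side`,
#' `sampling_rate_hz`, then the header row
#' `time_s,acc_ap,acc_ml,acc_vt,gyr_sag,gyr_fro,gyr_hor`, then one
#' comma-separated row per sample with `.` as decimal mark.
#'
#' Conformance findings from [validate_recording()] (irregular sampling,
#' out-of-range samples) are raised as warnings; the data are still
#' returned.
#'
#' @param path Path to the CSV file.
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  n_meta <- match(FALSE, is_meta, nomatch = length(lines) + 1L) - 1L
  meta_lines <- lines[seq_len(n_meta)]
  kv <- regmatches(meta_lines, regexec("^#([^=]+)=(.*)$", meta_lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) {
    stop("malformed header line: ", meta_lines[which(bad)[1L]], call. = FALSE)
  }
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  if (anyDuplicated(keys)) {
    stop("duplicate header key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(.vt_meta_keys, keys)
  if (length(missing)) {
    stop("missing header key(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  meta_vals <- as.list(vals)
  names(meta_vals) <- keys
  rate <- suppressWarnings(as.numeric(meta_vals$sampling_rate_hz))
  if (is.na(rate)) stop("non-numeric sampling_rate_hz in header", call. = FALSE)
  body <- lines[seq.int(n_meta + 1L, length(lines))]
  if (length(body) < 1L) stop("no data rows in ", path, call. = FALSE)
  header <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  expected <- c("time_s", .vt_channels)
  if (!identical(header, expected)) {
    stop("unexpected column header; expected '",
         paste(expected, collapse = ","), "'", call. = FALSE)
  }
  cells <- strsplit(body[-1L], ",", fixed = TRUE)
  ncell <- lengths(cells)
  if (any(ncell != 7L)) {
    stop("wrong number of fields at data row ", which(ncell != 7L)[1L],
         call. = FALSE)
  }
  mat <- matrix(unlist(cells, use.names = FALSE), ncol = 7L, byrow = TRUE)
  num <- suppressWarnings(matrix(as.numeric(mat), ncol = 7L))
  if (anyNA(num)) {
    bad <- which(is.na(num) & mat != "NA", arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-numeric value '%s' at data row %d, column '%s'",
                   mat[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                   expected[bad[1L, 2L]]), call. = FALSE)
    }
    stop("missing values in data rows", call. = FALSE)
  }
  meta <- imu_meta(site = meta_vals$site, side = meta_vals$side,
                   sampling_rate_hz = rate,
                   subject_id = meta_vals$subject_id,
                   session_label = meta_vals$session)
  rec <- imu_recording(num[, 1L], num[, 2L], num[, 3L], num[, 4L],
                       num[, 5L], num[, 6L], num[, 7L], meta = meta)
  findings <- validate_recording(rec)
  for (i in seq_len(nrow(findings))) warning(findings$message[i], call. = FALSE)
  rec
}

#' Write an IMU recording to CSV
#'
#' Inverse of [read_imu_csv()]; numeric cells are printed with 10
#' significant digits so a write/read round trip preserves values to better
#' than 9 significant digits, and a second write of the re-read recording is
#' byte-identical.
#'
#' @param rec An [imu_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  m <- rec$meta
  header <- c(
    paste0("#subject_id=", m$subject_id),
    paste0("#session=", m$session_label),
    paste0("#site=", m$site),
    paste0("#side=", m$side),
    paste0("#sampling_rate_hz=", sprintf("%.10g", m$sampling_rate_hz)),
    paste(c("time_s", .vt_channels), collapse = ",")
  )
  cols <- lapply(rec$data, function(v) sprintf("%.10g", v))
  rows <- do.call(paste, c(cols, sep = ","))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}
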