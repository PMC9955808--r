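# Reading and writing stretch-session recordings and feature tables.
#
# CSV dialects:
#   low-rate  (1000 Hz): time_s,angle_x_deg,angle_y_deg,force_n
#   high-rate (2000 Hz): time_s,semg_mv
# An optional leading comment line "# subject_id=..;trial_id=..;mas_label=.."
# carries session metadata. UTF-8, "." decimal, no thousands separators.

.LO_COLS <- c("time_s", "angle_x_deg", "angle_y_deg", "force_n")
.HI_COLS <- c("time_s", "semg_mv")

#' Construct a validated stretch-session recording
#'
#' A recording holds the raw multi-rate channels of one passive elbow-stretch
#' session: twin-axis goniometer angles and myometer force sampled at
#' `fs_lo` (1000 Hz by default) and surface EMG at `fs_hi` (2000 Hz).
#'
#' @param subject_id,trial_id Opaque identifier strings.
#' @param time_lo Sample times (s) of the 1000 Hz channels, strictly
#'   increasing, starting at 0.
#' @param angle_x,angle_y Goniometer x/y-plane angles (deg).
#' @param force Myometer resisting force (N).
#' @param time_hi Sample times (s) of the EMG channel.
#' @param semg Surface EMG (mV).
#' @param mas_label Optional MAS grade (see [mas_levels()]).
#' @param fs_lo,fs_hi Nominal sample rates (Hz) of the two time bases.
#' @return Object of class `stretch_recording`.
#' @export
stretch_recording <- function(subject_id, trial_id, time_lo, angle_x, angle_y,
                              force, time_hi, semg, mas_label = NULL,
                              fs_lo = 1000, fs_hi = 2000) {
  rec <- structure(
    list(subject_id = as.character(subject_id),
         trial_id = as.character(trial_id),
         time_lo = as.numeric(time_lo),
         angle_x = as.numeric(angle_x), angle_y = as.numeric(angle_y),
         force = as.numeric(force),
         time_hi = as.numeric(time_hi), semg = as.numeric(semg),
         mas_label = if (is.null(mas_label) || is.na(mas_label)) NA_character_
                     else as.character(as_mas(mas_label)),
         fs_lo = fs_lo, fs_hi = fs_hi),
    class = "stretch_recording")
  validate_recording(rec)
  rec
}

#' Validate the invariants of a stretch recording
#'
#' Checks equal channel lengths per time base, non-empty channels, and
#' strictly increasing time vectors that start at zero. Violations raise an
#' error naming the broken rule.
#'
#' @param rec A `stretch_recording`.
#' @return `rec`, invisibly.
#' @export
validate_recording <- function(rec) {
  n_lo <- length(rec$time_lo)
  if (n_lo == 0L) stop("recording format error: zero-length low-rate channels")
  for (ch in c("angle_x", "angle_y", "force")) {
    if (length(rec[[ch]]) != n_lo) {
      stop("recording format error: channel '", ch, "' has length ",
           length(rec[[ch]]), " but time_lo has length ", n_lo)
    }
  }
  if (length(rec$semg) == 0L) stop("recording format error: zero-length semg channel")
  if (length(rec$semg) != length(rec$time_hi)) {
    stop("recording format error: channel 'semg' has length ", length(rec$semg),
         " but time_hi has length ", length(rec$time_hi))
  }
  for (tv in c("time_lo", "time_hi")) {
    tt <- rec[[tv]]
    if (abs(tt[1]) > 1e-9) stop("recording format error: ", tv, " must start at 0")
    if (length(tt) > 1 && any(diff(tt) <= 0)) {
      stop("recording format error: ", tv, " must be strictly increasing")
    }
  }
  invisible(rec)
}

.read_meta_line <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- list()
  if (length(first) == 1L && startsWith(first, "#")) {
    body <- sub("^#\\s*", "", first)
    for (kv in strsplit(body, ";", fixed = TRUE)[[1]]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(parts) == 2) meta[[trimws(parts[1])]] <- trimws(parts[2])
    }
  }
  meta
}

.read_channel_csv <- function(path, expected_cols) {
  if (!file.exists(path)) stop("recording format error: file not found: ", path)
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  missing <- setdiff(expected_cols, names(df))
  if (length(missing)) {
    stop("recording format error: missing column(s) ",
         paste(missing, collapse = ", "), " in ", path)
  }
  df[expected_cols]
}

#' Read a session recording from its two CSV files
#'
#' @param path_lo Path to the low-rate CSV
#'   (`time_s,angle_x_deg,angle_y_deg,force_n`).
#' @param path_hi Path to the high-rate CSV (`time_s,semg_mv`).
#' @param subject_id,trial_id,mas_label Optional metadata overriding anything
#'   stored in the files' comment header.
#' @return A validated [stretch_recording()].
#' @export
read_recording <- function(path_lo, path_hi, subject_id = NULL,
                           trial_id = NULL, mas_label = NULL) {
  lo <- .read_channel_csv(path_lo, .LO_COLS)
  hi <- .read_channel_csv(path_hi, .HI_COLS)
  meta <- .read_meta_line(path_lo)
  pick <- function(arg, key) {
    if (!is.null(arg)) arg
    else if (!is.null(meta[[key]]) && nzchar(meta[[key]]) && meta[[key]] != "NA")
      meta[[key]] else NA_character_
  }
  stretch_recording(
    subject_id = pick(subject_id, "subject_id"),
    trial_id = pick(trial_id, "trial_id"),
    time_lo = lo$time_s, angle_x = lo$angle_x_deg, angle_y = lo$angle_y_deg,
    force = lo$force_n, time_hi = hi$time_s, semg = hi$semg_mv,
    mas_label = pick(mas_label, "mas_label"))
}

#' Write a session recording to its two CSV files
#'
#' Lossless to numeric round-trip tolerance (1e-9); session metadata
#' (identifiers and MAS label) is persisted in a comment header of the
#' low-rate file.
#'
#' @param rec A `stretch_recording`.
#' @param path_lo,path_hi Output paths for the two channel tables.
#' @return Paths, invisibly.
#' @export
write_recording <- function(rec, path_lo, path_hi) {
  validate_recording(rec)
  meta <- sprintf("# subject_id=%s;trial_id=%s;mas_label=%s",
                  rec$subject_id, rec$trial_id, rec$mas_label)
  lo <- data.frame(time_s = rec$time_lo, angle_x_deg = rec$angle_x,
                   angle_y_deg = rec$angle_y, force_n = rec$force)
  hi <- data.frame(time_s = rec$time_hi, semg_mv = rec$semg)
  .write_csv_with_header <- function(df, path, header) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(header, con)
    write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, quote = FALSE)
  }
  .write_csv_with_header(lo, path_lo, meta)
  .write_csv_with_header(hi, path_hi, NULL)
  invisible(c(path_lo, path_hi))
}

.FEATURE_META_COLS <- c("subject_id", "trial_id", "stretch_index", "speed", "mas_label")

#' Read / write a stretch-feature table
#'
#' The canonical feature CSV has columns `subject_id, trial_id,
#' stretch_index, speed, mas_label` followed by the 17 canonical feature
#' names of [feature_names()], in that order. `mas_label` may be empty for
#' prediction-mode tables; any unknown column is an error.
#'
#' @param path CSV path.
#' @return `read_feature_table()`: a data.frame in canonical column order.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table format error: file not found: ", path)
  df <- read.csv(path, check.names = FALSE, colClasses = NA)
  canonical <- c(.FEATURE_META_COLS, feature_names())
  unknown <- setdiff(names(df), canonical)
  if (length(unknown)) {
    stop("feature table format error: unknown column(s): ",
         paste(unknown, collapse = ", "))
  }
  missing <- setdiff(setdiff(canonical, "mas_label"), names(df))
  if (length(missing)) {
    stop("feature table format error: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"mas_label" %in% names(df)) df$mas_label <- NA_character_
  df$mas_label <- as.character(df$mas_label)
  df$mas_label[!is.na(df$mas_label) & df$mas_label == ""] <- NA_character_
  as_mas(df$mas_label)  # validate values
  df[canonical]
}

#' @rdname read_feature_table
#' @param table Feature data.frame with the canonical columns.
#' @return `write_feature_table()`: `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  canonical <- c(.FEATURE_META_COLS, feature_names())
  unknown <- setdiff(names(table), canonical)
  if (length(unknown)) {
    stop("feature table format error: unknown column(s): ",
         paste(unknown, collapse = ", "))
  }
  missing <- setdiff(setdiff(canonical, "mas_label"), names(table))
  if (length(missing)) {
    stop("feature table format error: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!"mas_label" %in% names(table)) table$mas_label <- NA_character_
  out <- table[canonical]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15, trim = TRUE,
                                                  scientific = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
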