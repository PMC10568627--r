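#' Read trial-epoched pupil traces
#'
#' Reads the package's epoch CSV dialect: a header block of comment lines
#' (`# dialect=1`, `# unit=area|diameter`, `# rate_hz=...`, `# missing=...`)
#' followed by columns `participant_id, block_id, trial_index, speech_type,
#' snr_db, t_s, pupil`. Times are seconds relative to sentence onset
#' (0 = onset). Missing samples are encoded by the header-declared sentinel
#' (default: an empty field) and mapped to `NA` on read; samples are never
#' rescaled or otherwise mutated at I/O time.
#'
#' Each trial is validated: timestamps must be uniform at `1/rate_hz` to
#' within 1e-9 s, and the epoch must cover at least `[-1.0, 4.5]` s so the
#' baseline and analysis windows exist. Failing trials are flagged, not
#' dropped: see [trace_flags()].
#'
#' @param path File path (or vector of paths, concatenated).
#' @param dialect_version Expected dialect version (only 1 exists).
#' @return A tibble of samples with attributes `unit`, `rate_hz`, `dialect`,
#'   `missing_sentinel`, and `flags` (per-trial usability).
#' @export
read_pupil_traces <- function(path, dialect_version = 1L) {
  out <- purrr::map(path, read_one_trace_file, dialect_version = dialect_version)
  traces <- dplyr::bind_rows(purrr::map(out, "data"))
  meta <- out[[1]]$meta
  units <- unique(purrr::map_chr(out, ~ .x$meta$unit))
  rates <- unique(purrr::map_dbl(out, ~ .x$meta$rate_hz))
  if (length(units) > 1 || length(rates) > 1) {
    stop_pupilgca("trace files disagree on unit or sampling rate")
  }
  flags <- validate_trials(traces, meta$rate_hz)
  attr(traces, "unit") <- meta$unit
  attr(traces, "rate_hz") <- meta$rate_hz
  attr(traces, "dialect") <- meta$dialect
  attr(traces, "missing_sentinel") <- meta$missing
  attr(traces, "flags") <- flags
  traces
}

read_one_trace_file <- function(path, dialect_version) {
  if (!file.exists(path)) stop_pupilgca(sprintf("no such file: %s", path))
  hdr <- character(0)
  con <- file(path, "r")
  on.exit(close(con), add = TRUE)
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  kv <- stringr::str_match(hdr, "^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$")
  meta <- setNames(as.list(trimws(kv[, 3])), kv[, 2])
  if (is.null(meta$dialect) || as.integer(meta$dialect) != dialect_version) {
    stop_pupilgca(sprintf(
      "unknown or missing dialect version in %s (expected %d)",
      path, dialect_version
    ))
  }
  if (is.null(meta$unit) || !meta$unit %in% c("area", "diameter")) {
    stop_pupilgca("header must declare unit=area or unit=diameter")
  }
  if (is.null(meta$rate_hz)) stop_pupilgca("header must declare rate_hz")
  meta$rate_hz <- as.numeric(meta$rate_hz)
  meta$dialect <- as.integer(meta$dialect)
  meta$missing <- meta$missing %||% ""
  sentinel <- if (nzchar(meta$missing)) c("", meta$missing) else ""
  dat <- readr::read_csv(
    path, comment = "#", na = sentinel, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      block_id = readr::col_character(),
      trial_index = readr::col_integer(),
      speech_type = readr::col_character(),
      # parsed via R's strtod for exact round-tripping of written values
      snr_db = readr::col_character(),
      t_s = readr::col_character(),
      pupil = readr::col_character()
    )
  )
  dat$snr_db <- as.numeric(dat$snr_db)
  dat$t_s <- as.numeric(dat$t_s)
  dat$pupil <- as.numeric(dat$pupil)
  list(data = dat, meta = meta)
}

# Per-trial structural validation; returns one row per trial.
validate_trials <- function(traces, rate_hz) {
  step <- 1 / rate_hz
  if (nrow(traces) == 0) {
    return(tibble(
      participant_id = character(), block_id = character(),
      trial_index = integer(), speech_type = character(),
      snr_db = double(), t_min = double(), t_max = double(),
      usable = logical(), reason = character()
    ))
  }
  traces |>
    group_by(.data$participant_id, .data$block_id, .data$trial_index,
             .data$speech_type, .data$snr_db) |>
    summarise(
      t_min = min(.data$t_s), t_max = max(.data$t_s),
      uniform = max(abs(diff(.data$t_s) - step)) <= 1e-9,
      .groups = "drop"
    ) |>
    mutate(
      usable = .data$uniform & .data$t_min <= -1.0 & .data$t_max >= 4.5,
      reason = dplyr::case_when(
        !.data$uniform ~ "non-uniform timestamps",
        .data$t_min > -1.0 ~ "insufficient baseline coverage",
        .data$t_max < 4.5 ~ "insufficient analysis-window coverage",
        TRUE ~ ""
      )
    ) |>
    select(-"uniform")
}

#' Per-trial usability flags attached by the reader
#'
#' @param traces A tibble from [read_pupil_traces()].
#' @return A tibble with one row per trial (`usable`, `reason`).
#' @export
trace_flags <- function(traces) {
  flags <- attr(traces, "flags")
  if (is.null(flags)) {
    flags <- validate_trials(traces, attr(traces, "rate_hz") %||%
                               infer_rate(traces))
  }
  flags
}

infer_rate <- function(traces) {
  d <- diff(sort(unique(traces$t_s)))
  round(1 / min(d[d > 1e-12]))
}

#' Write trial-epoched pupil traces
#'
#' Inverse of [read_pupil_traces()]: deterministic column order, full-precision
#' floating samples, missing samples restored to the sentinel, UTF-8, LF line
#' endings. Writing then reading is the identity on values and metadata;
#' write/read/write is byte-idempotent.
#'
#' @param traces Sample tibble (columns as documented in
#'   [read_pupil_traces()]); an empty tibble yields a header-only file.
#' @param path Output path.
#' @param unit `"area"` or `"diameter"`; defaults to the tibble's attribute.
#' @param rate_hz Sampling rate; defaults to the tibble's attribute.
#' @param missing_sentinel Field written for missing samples (default empty).
#' @return Invisibly, `path`.
#' @export
write_pupil_traces <- function(traces, path, unit = NULL, rate_hz = NULL,
                               missing_sentinel = "") {
  unit <- unit %||% attr(traces, "unit")
  rate_hz <- rate_hz %||% attr(traces, "rate_hz")
  if (is.null(unit) || is.null(rate_hz)) {
    stop_pupilgca("`unit` and `rate_hz` must be supplied or present as attributes")
  }
  cols <- c("participant_id", "block_id", "trial_index", "speech_type",
            "snr_db", "t_s", "pupil")
  missing_cols <- setdiff(cols, names(traces))
  if (nrow(traces) > 0 && length(missing_cols)) {
    stop_pupilgca(paste("traces missing columns:", paste(missing_cols, collapse = ", ")))
  }
  hdr <- c(
    "# dialect=1",
    paste0("# unit=", unit),
    paste0("# rate_hz=", format(rate_hz, digits = 15)),
    paste0("# missing=", missing_sentinel)
  )
  con <- file(path, open = "wb")
  writeLines(hdr, con, sep = "\n")
  close(con)
  if (nrow(traces) == 0) {
    cat(paste(cols, collapse = ","), "\n", sep = "", file = path, append = TRUE)
  } else {
    df <- as_tibble(traces)[, cols]
    # full-precision round-trip formatting for the floating columns
    df$snr_db <- sprintf("%.17g", df$snr_db)
    df$t_s <- sprintf("%.17g", df$t_s)
    df$pupil <- ifelse(is.na(df$pupil), NA_character_,
                       sprintf("%.17g", df$pupil))
    readr::write_csv(df, path, na = missing_sentinel, append = TRUE,
                     col_names = TRUE, eol = "\n")
  }
  invisible(path)
}

#' Read / write behavioral tables
#'
#' Plain CSV round trips for the per-trial table (`participant_id, block_id,
#' trial_index, speech_type, snr_db, familiarization, keywords_correct`) and
#' the per-block effort-rating table (`participant_id, block_id, speech_type,
#' snr_db, effort_rating`). Values are validated on read: keyword scores in
#' 0..5, ratings in 0..10.
#'
#' @param records A tibble of trial or rating records.
#' @param path CSV path.
#' @return `write_tables()` returns `path` invisibly; readers return tibbles.
#' @name behavioral-tables
NULL

#' @rdname behavioral-tables
#' @export
write_tables <- function(records, path) {
  readr::write_csv(as_tibble(records), path, eol = "\n")
  invisible(path)
}

#' @rdname behavioral-tables
#' @export
read_trial_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("keywords_correct" %in% names(x)) {
    bad <- !is.na(x$keywords_correct) &
      (x$keywords_correct < 0 | x$keywords_correct > 5)
    if (any(bad)) stop_pupilgca("keywords_correct outside 0..5")
  }
  x
}

#' @rdname behavioral-tables
#' @export
read_rating_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("effort_rating" %in% names(x)) {
    bad <- !is.na(x$effort_rating) & (x$effort_rating < 0 | x$effort_rating > 10)
    if (any(bad)) stop_pupilgca("effort_rating outside 0..10")
  }
  x
}

#' Write baseline-normalized dilation curves as a tidy long table
#'
#' One row per trace per analysis-grid point: `participant_id, block_id,
#' trial_index, speech_type, snr_db, t_s, erpd`. All traces must share an
#' identical analysis grid; mixed grids are rejected because downstream
#' growth-curve fits require a common basis.
#'
#' @param erpd_long Long tibble of dilation curves on the analysis grid.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_erpd_long <- function(erpd_long, path) {
  check_shared_grid(erpd_long)
  readr::write_csv(as_tibble(erpd_long), path, eol = "\n")
  invisible(path)
}

#' @rdname write_erpd_long
#' @export
read_erpd_long <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

check_shared_grid <- function(erpd_long) {
  keys <- intersect(
    c("participant_id", "block_id", "trial_index", "speech_type", "snr_db"),
    names(erpd_long)
  )
  counts <- erpd_long |>
    group_by(across(all_of(keys))) |>
    summarise(sig = paste(format(.data$t_s, digits = 15), collapse = ","),
              .groups = "drop")
  if (length(unique(counts$sig)) > 1) {
    stop_pupilgca("traces are not on a shared analysis grid")
  }
  invisible(TRUE)
}
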