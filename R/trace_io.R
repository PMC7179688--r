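# Canonical trace and attribute-table I/O.
#
# Trace dialect: comma-separated, header `time_s,position_mm,laser_on,session`,
# UTF-8, '.' decimal separator, time 0-based at experiment start. One file per
# fly; the fly id defaults to the file stem.

parse_error <- function(msg) abort(msg, class = "flyoperant_parse_error")

#' Construct a position trace
#'
#' A position trace is a tibble with one row per sample: `time_s` (uniform,
#' 0-based), `position_mm` along the chamber axis, `laser_on` (0/1) and
#' `session` (one of [protocol_sessions()], each a contiguous block in
#' protocol order). The fly id and sampling step are carried as attributes.
#'
#' @param time_s,position_mm,laser_on,session Sample columns.
#' @param fly_id Fly identifier.
#' @param chamber_length Chamber length used for validation, mm.
#' @param validate Run [validate_trace()] on the result.
#' @return A `fly_trace` tibble.
#' @export
fly_trace <- function(time_s, position_mm, laser_on, session,
                      fly_id = "fly", chamber_length = 48.7,
                      validate = TRUE) {
  tr <- tibble::tibble(
    time_s = as.double(time_s),
    position_mm = as.double(position_mm),
    laser_on = as.integer(laser_on),
    session = as.character(session)
  )
  attr(tr, "fly_id") <- fly_id
  attr(tr, "chamber_length") <- chamber_length
  attr(tr, "dt") <- if (nrow(tr) >= 2) tr$time_s[2] - tr$time_s[1] else NA_real_
  class(tr) <- c("fly_trace", class(tr))
  if (validate) validate_trace(tr)
  tr
}

#' Validate a position trace
#'
#' Checks column presence and types, strictly increasing uniform times,
#' binary laser values, positions within the chamber, known session labels
#' forming contiguous blocks in protocol order. Errors name the first
#' offending row and field.
#'
#' @param trace A `fly_trace` (or plain data frame with the four columns).
#' @return The trace, invisibly, if valid.
#' @export
validate_trace <- function(trace) {
  req <- c("time_s", "position_mm", "laser_on", "session")
  miss <- setdiff(req, names(trace))
  if (length(miss))
    parse_error(sprintf("trace is missing column(s): %s",
                        paste(miss, collapse = ", ")))
  n <- nrow(trace)
  if (n < 2) parse_error("trace must have at least 2 samples")
  bad <- which(!(trace$laser_on %in% c(0L, 1L)))
  if (length(bad))
    parse_error(sprintf("row %d: field `laser_on` has non-binary value %s",
                        bad[1], trace$laser_on[bad[1]]))
  d <- diff(trace$time_s)
  if (any(d <= 0))
    parse_error(sprintf("row %d: field `time_s` is not strictly increasing",
                        which(d <= 0)[1] + 1L))
  dt <- median(d)
  off <- which(abs(d - dt) > dt / 2)
  if (length(off))
    parse_error(sprintf("row %d: field `time_s` breaks uniform sampling",
                        off[1] + 1L))
  unknown <- which(!(trace$session %in% SESSIONS))
  if (length(unknown))
    parse_error(sprintf("row %d: field `session` has unknown label '%s'",
                        unknown[1], trace$session[unknown[1]]))
  r <- rle(trace$session)
  if (anyDuplicated(r$values))
    parse_error("field `session`: a session label appears in non-contiguous blocks")
  ord <- match(r$values, SESSIONS)
  if (is.unsorted(ord, strictly = TRUE))
    parse_error("field `session`: blocks are not in protocol order")
  L <- attr(trace, "chamber_length") %||% 48.7
  out <- which(trace$position_mm < -1e-9 | trace$position_mm > L + 1e-9)
  if (length(out))
    parse_error(sprintf("row %d: field `position_mm` outside [0, %.1f]",
                        out[1], L))
  invisible(trace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a position trace from CSV
#'
#' @param path Path to a trace CSV in the canonical dialect.
#' @param fly_id Fly identifier; defaults to the file stem.
#' @param chamber_length Chamber length for validation, mm.
#' @return A validated `fly_trace` tibble with session windows reconstructable
#'   via [session_windows()].
#' @export
read_trace <- function(path, fly_id = tools::file_path_sans_ext(basename(path)),
                       chamber_length = 48.7) {
  if (!file.exists(path)) parse_error(sprintf("no such trace file: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(),
    position_mm = readr::col_double(),
    laser_on = readr::col_double(),
    session = readr::col_character()
  ), progress = FALSE)
  fly_trace(df$time_s, df$position_mm, df$laser_on, df$session,
            fly_id = fly_id, chamber_length = chamber_length)
}

#' Write a position trace to canonical CSV
#'
#' The writer is canonicalizing: times and positions are fixed-format with
#' four decimals, so `write_trace(read_trace(f))` is byte-identical to a
#' canonical `f`.
#'
#' @param trace A `fly_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  validate_trace(trace)
  lines <- c(
    "time_s,position_mm,laser_on,session",
    sprintf("%.4f,%.4f,%d,%s", trace$time_s, trace$position_mm,
            trace$laser_on, trace$session)
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Session windows of a trace
#'
#' Half-open, non-overlapping sample windows, one per session block, ordered;
#' their union covers the trace.
#'
#' @param trace A `fly_trace`.
#' @return Tibble with `session`, `start_idx` (1-based, inclusive),
#'   `end_idx` (exclusive), `start_s`, `end_s`, `n_samples`.
#' @export
session_windows <- function(trace) {
  r <- rle(trace$session)
  end <- cumsum(r$lengths)
  start <- c(1L, head(end, -1) + 1L)
  dt <- attr(trace, "dt") %||% median(diff(trace$time_s))
  tibble::tibble(
    session = r$values,
    start_idx = start,
    end_idx = end + 1L,
    start_s = trace$time_s[start],
    end_s = trace$time_s[end] + dt,
    n_samples = r$lengths
  )
}

#' Read a fly attribute table
#'
#' One row per fly with `fly_id`, `group` (train/yoked/blank), `triplet_id`
#' and descriptive attributes. Rows with missing attributes are flagged, not
#' dropped — the curation step decides. Duplicate fly ids are an error; a
#' triplet missing a group member yields a warning and a `triplet_complete`
#' flag.
#'
#' @param path Path to the attribute CSV.
#' @return Tibble of fly records with `attribute_complete` and
#'   `triplet_complete` logical columns.
#' @export
read_attributes <- function(path) {
  if (!file.exists(path)) parse_error(sprintf("no such attribute file: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  fly_records(df)
}

#' Build validated fly records from a data frame
#'
#' @param df Data frame with at least `fly_id`, `group`, `triplet_id`.
#' @return Tibble of fly records (see [read_attributes()]).
#' @export
fly_records <- function(df) {
  req <- c("fly_id", "group", "triplet_id")
  miss <- setdiff(req, names(df))
  if (length(miss))
    parse_error(sprintf("attribute table is missing column(s): %s",
                        paste(miss, collapse = ", ")))
  if (anyDuplicated(df$fly_id)) {
    dup <- df$fly_id[duplicated(df$fly_id)][1]
    parse_error(sprintf("duplicate fly_id '%s' in attribute table", dup))
  }
  badg <- which(!(df$group %in% c("train", "yoked", "blank")))
  if (length(badg))
    parse_error(sprintf("row %d: field `group` must be train/yoked/blank, got '%s'",
                        badg[1], df$group[badg[1]]))
  out <- tibble::as_tibble(df)
  for (nm in c("genotype", "sex", "eclosion_date"))
    if (!nm %in% names(out)) out[[nm]] <- NA_character_
  if (!"procedure_error" %in% names(out)) out$procedure_error <- FALSE
  out$procedure_error <- as.logical(out$procedure_error) %in% TRUE
  attrs <- out[, c("genotype", "sex", "eclosion_date")]
  out$attribute_complete <- complete.cases(attrs) &
    !apply(attrs == "", 1, any, na.rm = TRUE)
  comp <- tapply(out$group, out$triplet_id,
                 function(g) setequal(g, c("train", "yoked", "blank")))
  out$triplet_complete <- unname(comp[out$triplet_id])
  if (any(!out$triplet_complete))
    warn(sprintf("%d triplet(s) are missing a group member",
                 sum(!comp)), class = "flyoperant_triplet_warning")
  out
}

#' Write a fly attribute table to CSV
#'
#' @param records Fly records tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attributes <- function(records, path) {
  keep <- intersect(
    c("fly_id", "group", "triplet_id", "genotype", "sex",
      "eclosion_date", "procedure_error"),
    names(records)
  )
  readr::write_csv(records[, keep], path, progress = FALSE)
  invisible(path)
}

#' Read a cohort of traces plus its attribute table
#'
#' Expects one `<fly_id>.csv` per fly in `dir` next to the attribute table.
#'
#' @param dir Directory of trace CSVs.
#' @param attributes Path to the attribute CSV (default
#'   `file.path(dir, "attributes.csv")`).
#' @param chamber_length Chamber length for validation, mm.
#' @return List with `traces` (named list of `fly_trace`) and `records`.
#' @export
read_cohort <- function(dir, attributes = file.path(dir, "attributes.csv"),
                        chamber_length = 48.7) {
  records <- read_attributes(attributes)
  traces <- lapply(records$fly_id, function(id) {
    read_trace(file.path(dir, paste0(id, ".csv")), fly_id = id,
               chamber_length = chamber_length)
  })
  names(traces) <- records$fly_id
  list(traces = traces, records = records)
}

#' Write a cohort of traces plus its attribute table
#'
#' @param cohort List with `traces` and `records`, as returned by
#'   [simulate_cohort()] or [read_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$traces))
    write_trace(cohort$traces[[id]], file.path(dir, paste0(id, ".csv")))
  write_attributes(cohort$records, file.path(dir, "attributes.csv"))
  invisible(dir)
}
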