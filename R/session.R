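#' @importFrom stats approx cor fft median pf pchisq quantile rnorm runif sd var
#' @importFrom utils read.csv write.csv
NULL

AREAS <- c("ACC", "HPC")
HEMISPHERES <- c("L", "R")
GROUPS <- c("control", "STZ")
OUTCOMES <- c("correct", "error")

# Delay-length boundary (s): < DELAY_SPLIT_S is "short", >= is "long".
DELAY_SPLIT_S <- 20

#' Construct a session recording
#'
#' Bundles the continuous multi-lead voltage traces of one behavioral
#' session with lead metadata, the animal's position trace and the trial
#' event log, and validates the invariants every downstream stage relies
#' on (shared time base, ordered non-overlapping trials, unique lead ids).
#'
#' Signals are quantized to 32-bit float on construction so that a session
#' round-trips bit-exactly through [write_session()] / [read_session()].
#'
#' @param signals numeric matrix, leads in rows, samples in columns
#'   (microvolts).
#' @param sample_rate sampling rate in Hz (1000 for the recordings this
#'   pipeline targets).
#' @param leads data.frame with columns `lead_id`, `subject_id`,
#'   `session_id`, `area` ("ACC"/"HPC"), `hemisphere` ("L"/"R"),
#'   `group` ("control"/"STZ").
#' @param positions data.frame with columns `t_s`, `x_cm`, `y_cm`;
#'   timestamps strictly increasing and inside the recording.
#' @param events data.frame with one row per trial: `trial_index`,
#'   `delay_start_s`, `trial_start_s`, `choice_time_s`, `return_time_s`,
#'   `outcome`. May have zero rows.
#' @return an object of class `session_recording`.
#' @export
session_recording <- function(signals, sample_rate, leads, positions, events) {
  if (!is.matrix(signals) || !is.numeric(signals)) {
    stop("`signals` must be a numeric matrix [n_leads x n_samples]", call. = FALSE)
  }
  stop_if_not_scalar_pos(sample_rate, "sample_rate")
  s <- structure(
    list(
      signals = as_f32(signals),
      sample_rate = as.numeric(sample_rate),
      leads = as.data.frame(leads, stringsAsFactors = FALSE),
      positions = as.data.frame(positions, stringsAsFactors = FALSE),
      events = as.data.frame(events, stringsAsFactors = FALSE)
    ),
    class = "session_recording"
  )
  validate_session(s)
  s
}

# Quantize to float32 so in-memory values equal their on-disk representation.
as_f32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
               numeric(), n = length(x), size = 4L, endian = "little")
  dim(y) <- d
  y
}

#' Validate a session recording's invariants
#'
#' @param s a `session_recording`.
#' @return `s`, invisibly; stops with a validation error naming the
#'   offending lead or trial otherwise.
#' @export
validate_session <- function(s) {
  leads <- s$leads
  need <- c("lead_id", "subject_id", "session_id", "area", "hemisphere", "group")
  miss <- setdiff(need, names(leads))
  if (length(miss)) stop("leads table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(leads$lead_id)) {
    stop("validation error: duplicate lead_id ",
         leads$lead_id[duplicated(leads$lead_id)][1], call. = FALSE)
  }
  if (nrow(leads) != nrow(s$signals)) {
    stop("validation error: ", nrow(leads), " lead rows for ",
         nrow(s$signals), " signal rows", call. = FALSE)
  }
  if (!all(leads$area %in% AREAS)) stop("validation error: unknown area", call. = FALSE)
  if (!all(leads$hemisphere %in% HEMISPHERES)) stop("validation error: unknown hemisphere", call. = FALSE)
  if (!all(leads$group %in% GROUPS)) stop("validation error: unknown group", call. = FALSE)

  dur <- ncol(s$signals) / s$sample_rate
  p <- s$positions
  if (nrow(p)) {
    if (any(diff(p$t_s) <= 0)) stop("validation error: position timestamps not strictly increasing", call. = FALSE)
    if (p$t_s[1] < 0 || p$t_s[nrow(p)] > dur) {
      stop("validation error: position timestamps outside [0, ", dur, "]", call. = FALSE)
    }
  }

  e <- s$events
  if (nrow(e)) {
    bad <- which(!(e$delay_start_s < e$trial_start_s &
                   e$trial_start_s < e$choice_time_s &
                   e$choice_time_s < e$return_time_s))
    if (length(bad)) {
      stop("validation error: trial ", e$trial_index[bad[1]],
           " violates delay_start < trial_start < choice_time < return_time",
           call. = FALSE)
    }
    if (nrow(e) > 1 && any(e$delay_start_s[-1] < e$return_time_s[-nrow(e)])) {
      stop("validation error: overlapping or unordered trials", call. = FALSE)
    }
    if (!all(e$outcome %in% OUTCOMES)) stop("validation error: unknown outcome", call. = FALSE)
  }
  invisible(s)
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %d leads x %d samples @ %g Hz (%.1f s), %d trials\n",
              nrow(x$signals), ncol(x$signals), x$sample_rate,
              ncol(x$signals) / x$sample_rate, nrow(x$events)))
  invisible(x)
}

# Fixed-format numeric CSV writing: %.17g survives a parse round trip
# exactly, and identical input always yields identical bytes.
write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write a session to a directory
#'
#' Layout: `signals.f32` (raw little-endian float32, lead-major: lead 1's
#' full trace, then lead 2's, ...), `signals.json` (shape/dtype/rate
#' sidecar), `leads.csv`, `positions.csv`, `events.csv`. Writing the same
#' session twice produces byte-identical directories.
#'
#' @param session a `session_recording`.
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("I/O error: cannot create directory ", path, call. = FALSE)
  }
  # lead-major: row-wise, so write the transpose of R's column-major layout
  con <- file(file.path(path, "signals.f32"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(t(session$signals)), con, size = 4L, endian = "little")
  sidecar <- list(
    n_leads = nrow(session$signals),
    n_samples = ncol(session$signals),
    sample_rate_hz = session$sample_rate,
    dtype = "float32",
    byte_order = "little",
    layout = "lead_major"
  )
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA),
             file.path(path, "signals.json"))
  write_csv_exact(session$leads, file.path(path, "leads.csv"))
  write_csv_exact(session$positions, file.path(path, "positions.csv"))
  write_csv_exact(session$events, file.path(path, "events.csv"))
  invisible(path)
}

#' Read a session from a directory written by [write_session()]
#'
#' @param path session directory.
#' @return a validated `session_recording`; a format error names any
#'   missing file.
#' @export
read_session <- function(path) {
  need <- c("signals.f32", "signals.json", "leads.csv", "positions.csv", "events.csv")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stop("format error: missing file ", f, " in ", path, call. = FALSE)
    }
  }
  sc <- jsonlite::fromJSON(file.path(path, "signals.json"))
  n <- sc$n_leads * sc$n_samples
  raw_sig <- readBin(file.path(path, "signals.f32"), numeric(), n = n,
                     size = 4L, endian = "little")
  if (length(raw_sig) != n) {
    stop("format error: signals.f32 holds ", length(raw_sig),
         " values, sidecar promises ", n, call. = FALSE)
  }
  signals <- matrix(raw_sig, nrow = sc$n_leads, ncol = sc$n_samples, byrow = TRUE)
  leads <- read.csv(file.path(path, "leads.csv"), stringsAsFactors = FALSE,
                    colClasses = "character")
  positions <- read.csv(file.path(path, "positions.csv"), stringsAsFactors = FALSE)
  events <- read.csv(file.path(path, "events.csv"), stringsAsFactors = FALSE)
  if (nrow(events) == 0) {
    events <- data.frame(trial_index = integer(), delay_start_s = numeric(),
                         trial_start_s = numeric(), choice_time_s = numeric(),
                         return_time_s = numeric(), outcome = character(),
                         stringsAsFactors = FALSE)
  } else {
    events$trial_index <- as.integer(events$trial_index)
  }
  session_recording(signals, sc$sample_rate_hz, leads, positions, events)
}

#' Build the per-trial table from an event log
#'
#' Adds the delay length and its category. Delays shorter than 20 s are
#' "short", delays of 20 s or more are "long" (the boundary itself is
#' assigned to "long" so the two categories partition all trials).
#'
#' @param events event data.frame as in [session_recording()].
#' @return data.frame with `trial_index`, `delay_s`, `delay_category`,
#'   `outcome` and the event times.
#' @export
build_trial_table <- function(events) {
  e <- as.data.frame(events, stringsAsFactors = FALSE)
  delay_s <- e$trial_start_s - e$delay_start_s
  data.frame(
    trial_index = e$trial_index,
    delay_s = delay_s,
    delay_category = ifelse(delay_s < DELAY_SPLIT_S, "short", "long"),
    outcome = e$outcome,
    delay_start_s = e$delay_start_s,
    trial_start_s = e$trial_start_s,
    choice_time_s = e$choice_time_s,
    return_time_s = e$return_time_s,
    stringsAsFactors = FALSE
  )
}

#' Standard 16-lead metadata table for one session
#'
#' Four leads per area per hemisphere, the standard montage of the
#' recordings this pipeline targets.
#'
#' @param subject_id,session_id,group identifying metadata.
#' @return a 16-row leads data.frame.
#' @export
standard_leads <- function(subject_id, session_id, group) {
  grid <- expand.grid(lead = 1:4, hemisphere = HEMISPHERES, area = AREAS,
                      stringsAsFactors = FALSE)
  data.frame(
    lead_id = sprintf("%s_%s_%s%d", session_id, grid$area, grid$hemisphere, grid$lead),
    subject_id = subject_id,
    session_id = session_id,
    area = grid$area,
    hemisphere = grid$hemisphere,
    group = group,
    stringsAsFactors = FALSE
  )
}
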