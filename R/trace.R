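#' Two-bead position trace with acquisition metadata
#'
#' Canonical container for a dumbbell recording: two synchronized bead
#' position series in nm plus the metadata the analysis needs (sample
#' interval, per-trap stiffness, molecule and condition labels).
#'
#' @param bead_a,bead_b Bead positions in nm, equal length >= 2, finite.
#' @param sample_interval Sampling interval in s (> 0).
#' @param trap_stiffness_a,trap_stiffness_b Trap stiffness, pN nm^-1.
#' @param molecule_id,condition Free-text labels.
#' @param source `"simulated"` or `"imported"`.
#' @return An object of class `trap_trace`.
#' @export
trap_trace <- function(bead_a, bead_b, sample_interval,
                       trap_stiffness_a = NA_real_,
                       trap_stiffness_b = NA_real_,
                       molecule_id = "unknown",
                       condition = "",
                       source = c("simulated", "imported")) {
  source <- match.arg(source)
  if (length(bead_a) != length(bead_b)) {
    stop("bead_a and bead_b must have equal length", call. = FALSE)
  }
  if (length(bead_a) < 2L) stop("trace must have at least 2 samples", call. = FALSE)
  if (any(!is.finite(bead_a)) || any(!is.finite(bead_b))) {
    stop("bead positions must be finite", call. = FALSE)
  }
  .check_scalar(sample_interval, "sample_interval", min = 0, strict_min = TRUE)
  structure(
    list(bead_a = as.numeric(bead_a), bead_b = as.numeric(bead_b),
         sample_interval = sample_interval,
         trap_stiffness_a = trap_stiffness_a,
         trap_stiffness_b = trap_stiffness_b,
         molecule_id = molecule_id, condition = condition, source = source),
    class = "trap_trace"
  )
}

#' @export
print.trap_trace <- function(x, ...) {
  cat(sprintf(
    "<trap_trace> %s | %s | %d samples @ %.6g kHz | traps %.3g/%.3g pN/nm | %s\n",
    x$molecule_id, x$condition, length(x$bead_a),
    1e-3 / x$sample_interval, x$trap_stiffness_a, x$trap_stiffness_b, x$source))
  invisible(x)
}

#' @export
length.trap_trace <- function(x) length(x$bead_a)

#' Time axis of a trace
#' @param trace A [trap_trace()].
#' @return Seconds from trace start, one per sample.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$bead_a) - 1L) * trace$sample_interval
}

#' Subset a trace by a time range
#' @param trace A [trap_trace()].
#' @param from,to Time range in s (half-open, `[from, to)`).
#' @return A new [trap_trace()] covering the requested range.
#' @export
trace_window <- function(trace, from, to) {
  tt <- trace_times(trace)
  keep <- tt >= from & tt < to
  if (sum(keep) < 2L) stop("time range selects fewer than 2 samples")
  trap_trace(trace$bead_a[keep], trace$bead_b[keep], trace$sample_interval,
             trace$trap_stiffness_a, trace$trap_stiffness_b,
             trace$molecule_id, trace$condition, trace$source)
}

.trace_header_keys <- c("sample_rate_hz", "trap_stiffness_a_pn_per_nm",
                        "trap_stiffness_b_pn_per_nm", "molecule_id",
                        "condition", "source", "seed")

#' Write / read a trace as TSV with a JSON metadata header
#'
#' The interchange format is a plain TSV (`time_s`, `bead_a_nm`, `bead_b_nm`,
#' positions printed to 1e-4 nm) preceded by a single `#`-prefixed JSON line
#' carrying `sample_rate_hz`, `trap_stiffness_a_pn_per_nm`,
#' `trap_stiffness_b_pn_per_nm`, `molecule_id`, `condition`, `source`, `seed`.
#'
#' @param trace A [trap_trace()].
#' @param path Output / input file path.
#' @param seed Seed recorded in the header (metadata only).
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [trap_trace()].
#' @export
write_trace <- function(trace, path, seed = NA) {
  meta <- list(
    sample_rate_hz = 1 / trace$sample_interval,
    trap_stiffness_a_pn_per_nm = trace$trap_stiffness_a,
    trap_stiffness_b_pn_per_nm = trace$trap_stiffness_b,
    molecule_id = trace$molecule_id,
    condition = trace$condition,
    source = trace$source,
    seed = seed
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null",
                                           na = "null", digits = NA)),
             con, sep = "\n")
  writeLines("time_s\tbead_a_nm\tbead_b_nm", con, sep = "\n")
  tt <- trace_times(trace)
  writeLines(sprintf("%.6f\t%.4f\t%.4f", tt, trace$bead_a, trace$bead_b),
             con, sep = "\n")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "#")) {
    stop("trace format error: missing '#' JSON metadata header (line 1)")
  }
  meta <- jsonlite::fromJSON(sub("^#\\s*", "", lines[1L]))
  for (key in c("sample_rate_hz", "molecule_id", "source")) {
    if (is.null(meta[[key]])) {
      stop(sprintf("trace format error: header missing key '%s' (line 1)", key))
    }
  }
  body <- lines[-(1:2)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    bad <- which(nf != 3L)[1L]
    stop(sprintf("trace format error: expected 3 columns, got %d (line %d)",
                 nf[bad], bad + 2L))
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 3L, byrow = TRUE)
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m[, 1]) | !is.finite(m[, 2]) | !is.finite(m[, 3]))[1L]
    stop(sprintf("trace format error: non-numeric value (line %d)", bad + 2L))
  }
  if (any(diff(m[, 1]) <= 0)) {
    bad <- which(diff(m[, 1]) <= 0)[1L]
    stop(sprintf("trace format error: non-monotone time (line %d)", bad + 3L))
  }
  stiff_a <- meta[["trap_stiffness_a_pn_per_nm"]]
  stiff_b <- meta[["trap_stiffness_b_pn_per_nm"]]
  trap_trace(m[, 2], m[, 3],
             sample_interval = 1 / meta$sample_rate_hz,
             trap_stiffness_a = if (is.null(stiff_a)) NA_real_ else stiff_a,
             trap_stiffness_b = if (is.null(stiff_b)) NA_real_ else stiff_b,
             molecule_id = meta$molecule_id,
             condition = if (is.null(meta$condition)) "" else meta$condition,
             source = meta$source)
}

#' Write / read a detected-event table as CSV
#'
#' Columns: `molecule_id`, `event_index`, `raw_start_s`, `raw_end_s`,
#' `refined_start_s`, `refined_end_s`, `duration_s`.
#'
#' @param events Event data.frame as returned by [refine_events()].
#' @param path File path.
#' @export
write_events <- function(events, path) {
  out <- data.frame(
    molecule_id = events$molecule_id,
    event_index = seq_len(nrow(events)),
    raw_start_s = events$raw_start, raw_end_s = events$raw_end,
    refined_start_s = events$refined_start, refined_end_s = events$refined_end,
    duration_s = events$duration
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(
    molecule_id = df$molecule_id,
    raw_start = df$raw_start_s, raw_end = df$raw_end_s,
    refined_start = df$refined_start_s, refined_end = df$refined_end_s,
    duration = df$duration_s
  )
}

#' Write / read a ground-truth event table as CSV
#'
#' Columns: `event_index`, `attach_time_s`, `substep2_time_s` (empty when the
#' event has no second substep), `detach_time_s`, `shift1_nm`, `shift2_nm`.
#'
#' @param truth Ground-truth data.frame from [simulate_dumbbell()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  out <- data.frame(
    event_index = truth$event_index,
    attach_time_s = truth$attach_time,
    substep2_time_s = ifelse(is.na(truth$substep2_time), "",
                             format(truth$substep2_time, digits = 10)),
    detach_time_s = truth$detach_time,
    shift1_nm = truth$applied_shift_1,
    shift2_nm = truth$applied_shift_2
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(
    event_index = df$event_index,
    attach_time = df$attach_time_s,
    substep2_time = suppressWarnings(as.numeric(df$substep2_time_s)),
    detach_time = df$detach_time_s,
    applied_shift_1 = df$shift1_nm,
    applied_shift_2 = df$shift2_nm
  )
}
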