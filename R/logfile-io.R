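# Pulse-log CSV schema. This project-defined schema stands in for the
# vendor's proprietary >300-parameter record: it carries exactly the fields
# the timing analysis needs.
.log_required <- c("fraction_id", "beam_id", "pulse_index", "timestamp_ms",
                   "target_charge_pC", "energy_level", "x_mm", "y_mm",
                   "is_low_charge")

.log_schema <- function(config) c(.log_required, leaf_columns(config$n_leaves))

#' Write a pulse log to CSV
#'
#' Columns are emitted in the canonical schema order and all continuous
#' fields are serialized with three fixed decimals (0.001 ms / 0.001 mm /
#' 0.001 pC), so that a write-read cycle is value-stable for records whose
#' fields are already at that precision (which simulator output is).
#'
#' @param records A pulse-log data frame (see [simulate_fraction()]).
#' @param path Output file path.
#' @param config A [machine_config()] (determines the leaf columns).
#' @return `path`, invisibly.
#' @export
write_pulse_log <- function(records, path, config = machine_config()) {
  schema <- .log_schema(config)
  missing <- setdiff(schema, names(records))
  if (length(missing))
    stop("records lack required column(s): ", paste(missing, collapse = ", "))
  out <- records[, schema, drop = FALSE]
  num <- setdiff(schema, c("fraction_id", "beam_id", "pulse_index",
                           "energy_level", "is_low_charge"))
  for (cn in num) out[[cn]] <- sprintf("%.3f", out[[cn]])
  out$is_low_charge <- ifelse(records$is_low_charge, "TRUE", "FALSE")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pulse log from CSV
#'
#' Restores the canonical column types, sorts rows by `pulse_index` within
#' each (fraction, beam) record, and enforces the log invariants: a missing
#' schema column raises an error naming the column, non-monotone timestamps
#' raise an error identifying the offending pulse, and charges above the
#' configured pulse cap produce a warning (not a failure).
#'
#' @param path CSV file path.
#' @param config A [machine_config()].
#' @return A pulse-log data frame.
#' @export
read_pulse_log <- function(path, config = machine_config()) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  schema <- .log_schema(config)
  missing <- setdiff(schema, names(d))
  if (length(missing))
    stop("log file is missing required column(s): ",
         paste(missing, collapse = ", "))
  d <- d[, schema, drop = FALSE]
  d$is_low_charge <- as.logical(d$is_low_charge)
  d <- d[order(d$fraction_id, d$beam_id, d$pulse_index), , drop = FALSE]
  row.names(d) <- NULL
  for (key in split(seq_len(nrow(d)), paste(d$fraction_id, d$beam_id))) {
    ts <- d$timestamp_ms[key]
    if (length(ts) > 1 && any(diff(ts) <= 0)) {
      i <- which(diff(ts) <= 0)[1]
      stop(sprintf(
        "non-monotone timestamps in record %s/%s at pulse_index %d",
        d$fraction_id[key[1]], d$beam_id[key[1]], d$pulse_index[key[i + 1]]))
    }
  }
  over <- d$target_charge_pC > config$max_pulse_charge + 1e-9
  if (any(over))
    warning(sprintf("%d pulse(s) exceed the configured charge cap (%.1f pC)",
                    sum(over), config$max_pulse_charge))
  d
}

#' Validate a pulse log against the schema invariants
#'
#' Pure reporting operation: the records are never modified. Checks
#' performed per (fraction, beam) record: contiguous `pulse_index` starting
#' at 1, strictly increasing timestamps, charges within the pulse cap
#' (warning severity), and low-charge-layer pulses carrying exactly the
#' configured low charge.
#'
#' @param records A pulse-log data frame.
#' @param config A [machine_config()].
#' @return A data frame of issues with columns `severity` (`"error"` or
#'   `"warning"`), `location`, `message`; zero rows iff all invariants hold.
#' @export
validate_pulse_log <- function(records, config = machine_config()) {
  issues <- list()
  add <- function(sev, loc, msg)
    issues[[length(issues) + 1]] <<- data.frame(severity = sev, location = loc,
                                                message = msg)
  missing <- setdiff(.log_schema(config), names(records))
  if (length(missing)) {
    add("error", "<header>",
        paste("missing column(s):", paste(missing, collapse = ", ")))
    return(do.call(rbind, issues))
  }
  for (key in split(seq_len(nrow(records)),
                    paste(records$fraction_id, records$beam_id, sep = "/"))) {
    r <- records[key, , drop = FALSE]
    loc <- paste(r$fraction_id[1], r$beam_id[1], sep = "/")
    pi_sorted <- sort(r$pulse_index)
    if (anyDuplicated(r$pulse_index))
      add("error", loc, "duplicated pulse_index")
    else if (!identical(as.integer(pi_sorted), seq_len(nrow(r))))
      add("error", loc, "pulse_index not contiguous from 1")
    ts <- r$timestamp_ms[order(r$pulse_index)]
    if (length(ts) > 1 && any(diff(ts) <= 0))
      add("error", loc, sprintf("non-increasing timestamp at pulse_index %d",
                                r$pulse_index[order(r$pulse_index)][which(diff(ts) <= 0)[1] + 1]))
    over <- r$target_charge_pC > config$max_pulse_charge + 1e-9
    if (any(over))
      add("warning", loc,
          sprintf("%d pulse(s) above the %.1f pC charge cap",
                  sum(over), config$max_pulse_charge))
    bad_low <- r$is_low_charge &
      abs(r$target_charge_pC - config$low_charge) > 1e-9
    if (any(bad_low))
      add("warning", loc,
          sprintf("%d low-charge-layer pulse(s) not at %.1f pC",
                  sum(bad_low), config$low_charge))
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(severity = character(0), location = character(0),
                  message = character(0))
}
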