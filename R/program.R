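#' Linear temperature programs
#'
#' A temperature program is an ordered sequence of linear scan segments, each
#' with a start and end temperature (K), a signed scan rate (K s^-1, negative
#' for cooling), and a role (`"first"`, `"cool"`, or `"reheat"`). Segment
#' boundaries must be contiguous in temperature, and the sign of the rate must
#' match the direction of each segment. The program starts at a temperature
#' low enough that all protein is native.
#'
#' `heat_cool_reheat()` is a convenience constructor for the canonical DSC
#' reheating experiment: heat from `t0` to the terminal temperature `t_prime`,
#' cool back to `t0` (at the same absolute rate unless `cool_rate` is given),
#' then reheat to `t_end` (default `t_prime`).
#'
#' @param segments A list of segments, each a list/row with `t_start`, `t_end`
#'   (K), `rate` (signed K s^-1) and `role`.
#' @return A tibble with class `dsc_program` (columns `t_start`, `t_end`,
#'   `rate`, `role`).
#' @examples
#' heat_cool_reheat(t0 = 293.15, t_prime = 343.15, rate = 1 / 60)
#' @export
temperature_program <- function(segments) {
  seg <- dplyr::bind_rows(lapply(segments, tibble::as_tibble))
  stopifnot(all(c("t_start", "t_end", "rate", "role") %in% names(seg)))
  check_temperature(seg$t_start, "t_start")
  check_temperature(seg$t_end, "t_end")
  if (any(seg$rate == 0)) abort("Scan rate must be non-zero.")
  if (any(sign(seg$t_end - seg$t_start) != sign(seg$rate))) {
    abort("sign(t_end - t_start) must equal sign(rate) in every segment.")
  }
  if (!all(seg$role %in% c("first", "cool", "reheat"))) {
    abort("Segment role must be one of 'first', 'cool', 'reheat'.")
  }
  if (nrow(seg) > 1) {
    gap <- abs(seg$t_start[-1] - seg$t_end[-nrow(seg)])
    if (any(gap > 1e-9)) abort("Segments must be contiguous in temperature.")
  }
  structure(seg, class = c("dsc_program", class(tibble::tibble())))
}

#' @rdname temperature_program
#' @param t0 Start (and cooling end) temperature (K).
#' @param t_prime Terminal temperature of the first heating (K).
#' @param rate Heating rate (K s^-1, positive).
#' @param t_end Terminal temperature of the reheat (K); default `t_prime`.
#' @param cool_rate Absolute cooling rate (K s^-1); default `rate`.
#' @param reheat If `FALSE`, only the first heating segment is produced.
#' @export
heat_cool_reheat <- function(t0, t_prime, rate, t_end = t_prime,
                             cool_rate = rate, reheat = TRUE) {
  stopifnot(rate > 0, cool_rate > 0, t_prime > t0)
  segs <- list(list(t_start = t0, t_end = t_prime, rate = rate, role = "first"))
  if (reheat) {
    segs <- c(segs, list(
      list(t_start = t_prime, t_end = t0, rate = -cool_rate, role = "cool"),
      list(t_start = t0, t_end = t_end, rate = rate, role = "reheat")))
  }
  temperature_program(segs)
}

#' DSC scan tables
#'
#' The package's tabular container for DSC data is a long tibble with one row
#' per recorded point and the scan metadata repeated along the scan:
#'
#' * `experiment` — experiment identifier (one first scan plus its reheats),
#' * `protein` — protein label,
#' * `role` — `"first"` or `"reheat"`,
#' * `scan_rate` — heating rate (K s^-1, positive),
#' * `t_prime` — terminal temperature (K) of the first run that preceded a
#'   reheat (`NA` for first scans),
#' * `temperature` — temperature (K),
#' * `cp` — apparent molar heat capacity (J mol^-1 K^-1).
#'
#' `dsc_scans()` validates such a table (≥ 10 finite points per scan,
#' strictly increasing temperature within each scan, reheats referencing an
#' experiment that has a first scan).
#'
#' @param data A data frame with the columns listed above.
#' @param check_links If `TRUE` (default), require that every reheat
#'   references an experiment with a first scan; single-scan tables read in
#'   isolation set this to `FALSE`.
#' @return The validated tibble with class `dsc_scans`.
#' @export
dsc_scans <- function(data, check_links = TRUE) {
  data <- as_tibble(data)
  needed <- c("experiment", "role", "scan_rate", "temperature", "cp")
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing columns: ", paste(missing, collapse = ", "), "."))
  }
  if (!"protein" %in% names(data)) data$protein <- NA_character_
  if (!"t_prime" %in% names(data)) data$t_prime <- NA_real_
  if (!all(data$role %in% c("first", "reheat"))) {
    abort("`role` must be 'first' or 'reheat'.")
  }
  if (any(!is.finite(data$temperature)) || any(!is.finite(data$cp))) {
    abort("Non-finite temperature or cp values.", class = "dscfit_parse_error")
  }
  if (any(data$scan_rate <= 0)) abort("Scan rates must be positive.")
  by_scan <- split(data, scan_key(data))
  for (sc in by_scan) {
    if (nrow(sc) < 10) {
      abort("Each scan needs at least 10 points.", class = "dscfit_parse_error")
    }
    if (any(diff(sc$temperature) <= 0)) {
      abort("Temperatures must be strictly increasing within a scan.",
            class = "dscfit_parse_error")
    }
  }
  if (any(data$role == "reheat" & !is.finite(data$t_prime))) {
    abort("Reheat scans must declare t_prime (terminal K of the first run).")
  }
  if (check_links) {
    reheats <- unique(data$experiment[data$role == "reheat"])
    firsts <- unique(data$experiment[data$role == "first"])
    if (!all(reheats %in% firsts)) {
      abort("Every reheat must reference an experiment with a first scan.")
    }
    # the declared t_prime normally coincides with (or lies below) the
    # recorded first-run maximum; the method itself has no such limitation,
    # so only warn
    for (e in reheats) {
      tmax_first <- max(data$temperature[data$experiment == e &
                                           data$role == "first"])
      tp <- unique(data$t_prime[data$experiment == e & data$role == "reheat"])
      if (any(tp > tmax_first + 1e-6)) {
        warn(sprintf(
          "Experiment '%s': reheat t_prime exceeds the recorded first-run maximum.", e),
          class = "dscfit_tprime_warning")
      }
    }
  }
  class(data) <- unique(c("dsc_scans", class(data)))
  data
}

# a scan is identified by (experiment, role, t_prime): one experiment may
# carry several reheats from different terminal temperatures
scan_key <- function(data) {
  interaction(data$experiment, data$role,
              ifelse(is.na(data$t_prime), "", format(data$t_prime)),
              drop = TRUE)
}

# one-row-per-scan summary used internally
scan_index <- function(data) {
  dplyr::summarise(
    dplyr::group_by(data, .data$experiment, .data$role, .data$t_prime),
    protein = .data$protein[1], scan_rate = .data$scan_rate[1],
    t_min = min(.data$temperature), t_max = max(.data$temperature),
    n = dplyr::n(), .groups = "drop")
}
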