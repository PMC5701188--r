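#' Read a DSC thermogram from delimited text
#'
#' Reads a two-column delimited scan (temperature, apparent heat capacity).
#' Tab or comma delimiters are autodetected; lines starting with `#` are
#' comments, and comment lines of the form `# key: value` carry scan metadata
#' (keys: `experiment`, `protein`, `role`, `scan_rate_C_per_min`, `t_prime_C`,
#' `temp_unit`, `cp_unit`). Explicit arguments override header metadata.
#' Temperatures default to degrees Celsius (instrument exports) and heat
#' capacities to kJ mol^-1 K^-1; both are converted to internal SI units
#' (K, J mol^-1 K^-1). Points are sorted by temperature (with a warning if the
#' file was unsorted) and duplicate temperatures are collapsed by their mean.
#'
#' @param path File path.
#' @param temp_unit `"celsius"` (default) or `"kelvin"`.
#' @param cp_unit `"kJ"` (default) or `"J"` per mol per K.
#' @param scan_rate Heating rate in K s^-1; overrides the header.
#' @param role `"first"` or `"reheat"`; overrides the header.
#' @param t_prime Terminal temperature (K) of the preceding first run, for
#'   reheats; overrides the header.
#' @param experiment,protein Metadata labels; override the header.
#' @return A single-scan [dsc_scans()] tibble.
#' @export
read_thermogram <- function(path, temp_unit = NULL, cp_unit = NULL,
                            scan_rate = NULL, role = NULL, t_prime = NULL,
                            experiment = NULL, protein = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^\\s*#", lines)
  meta <- list()
  for (h in sub("^\\s*#\\s*", "", lines[hdr])) {
    mm <- regmatches(h, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(mm) == 3) meta[[mm[2]]] <- trimws(mm[3])
  }
  body <- lines[!hdr]
  if (length(body) == 0) abort("No data rows.", class = "dscfit_parse_error")
  delim <- if (grepl("\t", body[1])) "\t" else if (grepl(",", body[1])) "," else "\\s+"
  fields <- strsplit(body, delim)
  if (any(lengths(fields) < 2)) {
    abort("Rows must have two delimited columns.", class = "dscfit_parse_error")
  }
  tvals <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1)))
  cvals <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  if (any(is.na(tvals)) || any(is.na(cvals))) {
    abort("Non-numeric data rows.", class = "dscfit_parse_error")
  }
  temp_unit <- temp_unit %||% meta$temp_unit %||% "celsius"
  cp_unit <- cp_unit %||% meta$cp_unit %||% "kJ"
  temp_unit <- match.arg(temp_unit, c("celsius", "kelvin"))
  cp_unit <- match.arg(cp_unit, c("kJ", "J"))
  if (temp_unit == "celsius") tvals <- tvals + 273.15
  if (cp_unit == "kJ") cvals <- cvals * 1e3

  if (is.unsorted(tvals)) {
    warn("Rows were not sorted by temperature; sorting.",
         class = "dscfit_unsorted_warning")
    ord <- order(tvals)
    tvals <- tvals[ord]; cvals <- cvals[ord]
  }
  if (anyDuplicated(tvals)) {
    cvals <- as.numeric(tapply(cvals, tvals, mean))
    tvals <- sort(unique(tvals))
  }
  if (length(tvals) < 10) {
    abort("A scan needs at least 10 points.", class = "dscfit_parse_error")
  }
  rate <- scan_rate %||%
    (if (!is.null(meta$scan_rate_C_per_min)) as.numeric(meta$scan_rate_C_per_min) / 60 else NULL)
  if (is.null(rate) || !is.finite(rate)) {
    abort("Scan rate metadata is required (argument or header scan_rate_C_per_min).",
          class = "dscfit_parse_error")
  }
  role <- role %||% meta$role %||% "first"
  tp <- t_prime %||%
    (if (!is.null(meta$t_prime_C)) as.numeric(meta$t_prime_C) + 273.15 else NA_real_)
  dsc_scans(tibble(
    experiment = experiment %||% meta$experiment %||% "exp1",
    protein = protein %||% meta$protein %||% NA_character_,
    role = role, scan_rate = rate,
    t_prime = if (role == "reheat") tp else NA_real_,
    temperature = tvals, cp = cvals), check_links = FALSE)
}

#' @rdname read_thermogram
#' @param data A single-scan [dsc_scans()] tibble to write.
#' @param delim Field delimiter (default tab).
#' @export
write_thermogram <- function(data, path, temp_unit = "celsius",
                             cp_unit = "kJ", delim = "\t") {
  idx <- scan_index(data)
  if (nrow(idx) != 1) abort("write_thermogram() writes exactly one scan.")
  temp_unit <- match.arg(temp_unit, c("celsius", "kelvin"))
  cp_unit <- match.arg(cp_unit, c("kJ", "J"))
  hdr <- c(
    paste0("# experiment: ", idx$experiment),
    if (!is.na(idx$protein)) paste0("# protein: ", idx$protein),
    paste0("# role: ", idx$role),
    paste0("# scan_rate_C_per_min: ",
           format(idx$scan_rate * 60, digits = 15)),
    if (!is.na(idx$t_prime)) paste0("# t_prime_C: ",
                                    format(idx$t_prime - 273.15, digits = 15)),
    paste0("# temp_unit: ", temp_unit),
    paste0("# cp_unit: ", cp_unit))
  tv <- data$temperature - if (temp_unit == "celsius") 273.15 else 0
  cv <- data$cp / if (cp_unit == "kJ") 1e3 else 1
  rows <- paste(format(tv, digits = 15, trim = TRUE),
                format(cv, digits = 15, trim = TRUE), sep = delim)
  readr::write_lines(c(hdr, rows), path)
  invisible(path)
}

#' Concentration normalization of a heat signal
#'
#' Converts a per-cell heat-capacity signal (J K^-1, buffer baseline already
#' subtracted) into apparent molar heat capacity by dividing by the number of
#' moles of protein in the cell.
#'
#' @param data A scan table whose `cp` column holds the per-cell signal.
#' @param concentration Protein concentration in mol L^-1.
#' @param cell_volume Calorimeter cell volume in L.
#' @return The table with `cp` in J mol^-1 K^-1; the division factor is
#'   recorded in the `"normalization_moles"` attribute.
#' @export
normalize_concentration <- function(data, concentration, cell_volume) {
  if (!is.finite(concentration) || concentration <= 0 ||
      !is.finite(cell_volume) || cell_volume <= 0) {
    abort("Concentration and cell volume must be positive.")
  }
  moles <- concentration * cell_volume
  data$cp <- data$cp / moles
  attr(data, "normalization_moles") <- moles
  data
}

#' Superimpose replicate experiments on their first runs
#'
#' DSC curves from independent protein batches are typically offset
#' vertically. This applies one additive offset per experiment, chosen by
#' least squares so that all first runs agree over a common pre-transition
#' reference window; the first experiment (sorted order) is the unshifted
#' reference. Each experiment's reheats receive the same offset as their
#' first run, which preserves the heat-capacity-difference information
#' carried by the first-to-reheat baseline shift.
#'
#' @param data A [dsc_scans()] table with >= 1 experiments of one protein at
#'   one scan rate.
#' @param window Numeric length-2: temperature range (K) inside the
#'   pre-transition region of all first runs.
#' @return The shifted table; offsets are stored in the `"offsets"` attribute.
#' @export
superimpose <- function(data, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  idx <- scan_index(data)
  if (length(unique(round(idx$scan_rate, 12))) > 1) {
    abort("Superimposition requires a single scan rate.")
  }
  firsts <- dplyr::filter(data, .data$role == "first")
  exps <- sort(unique(idx$experiment))
  in_window <- function(e) {
    d <- firsts[firsts$experiment == e &
                  firsts$temperature >= window[1] &
                  firsts$temperature <= window[2], ]
    if (nrow(d) < 2) {
      abort("Reference window does not overlap the first run of every experiment.")
    }
    d
  }
  ref <- in_window(exps[1])
  offsets <- stats::setNames(numeric(length(exps)), exps)
  for (e in exps[-1]) {
    d <- in_window(e)
    ref_cp <- stats::approx(ref$temperature, ref$cp, xout = d$temperature,
                            rule = 2)$y
    offsets[e] <- mean(ref_cp - d$cp)  # least-squares additive offset
  }
  data$cp <- data$cp + unname(offsets[data$experiment])
  attr(data, "offsets") <- offsets
  data
}

#' Subtract a reference scan
#'
#' Optional helper for two-series (e.g. sample minus buffer) subtraction; the
#' reference is interpolated onto the sample's temperature grid. Not part of
#' the fitting path, which assumes buffer subtraction was done upstream.
#'
#' @param data Sample scan table.
#' @param reference Reference scan table (columns `temperature`, `cp`).
#' @return `data` with the interpolated reference subtracted from `cp`.
#' @export
subtract_reference <- function(data, reference) {
  ref <- stats::approx(reference$temperature, reference$cp,
                       xout = data$temperature, rule = 2)$y
  data$cp <- data$cp - ref
  data
}

#' Read an experiment manifest
#'
#' A manifest is a YAML file listing scan files and their metadata:
#' ```yaml
#' scans:
#'   - file: first.tsv
#'     experiment: exp1
#'     role: first
#'     scan_rate_C_per_min: 1
#'   - file: reheat.tsv
#'     experiment: exp1
#'     role: reheat
#'     t_prime_C: 62
#' ```
#' Paths are resolved relative to the manifest location. Any metadata given in
#' the manifest overrides file headers.
#'
#' @param path Manifest path.
#' @return A combined [dsc_scans()] table.
#' @export
read_experiment_set <- function(path) {
  man <- yaml::read_yaml(path)
  if (is.null(man$scans)) abort("Manifest must contain a `scans:` list.")
  base <- dirname(path)
  scans <- lapply(man$scans, function(s) {
    read_thermogram(
      file.path(base, s$file),
      temp_unit = s$temp_unit, cp_unit = s$cp_unit,
      scan_rate = if (!is.null(s$scan_rate_C_per_min)) s$scan_rate_C_per_min / 60,
      role = s$role,
      t_prime = if (!is.null(s$t_prime_C)) s$t_prime_C + 273.15,
      experiment = s$experiment, protein = s$protein)
  })
  dsc_scans(dplyr::bind_rows(scans))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
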