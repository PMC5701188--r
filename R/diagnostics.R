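#' Residual statistics split by scan role
#'
#' After a global fit to first and reheated scans, splits the residuals into
#' the first-run group and the reheat group and summarises each by its signed
#' mean, mean absolute value, and standard deviation over each scan's full
#' recorded range. If the model explains both runs, the two groups should be
#' of the same magnitude; reheat residuals that are systematically biased or
#' much more scattered than first-run residuals indicate that the protein
#' refolded into something other than the native state during cooling.
#'
#' @param fit A [global_fit()] result including at least one reheat scan.
#' @return A `refold_report`: tibble with one row per group (`first`,
#'   `reheat`) and columns `mean`, `mean_abs`, `sd`, `n`, plus attributes
#'   `sd_ratio` (SD_reheat / SD_first) and `peak_height` (first-run excess
#'   peak amplitude, for the signal threshold).
#' @export
refold_statistics <- function(fit) {
  stopifnot(inherits(fit, "dsc_fit"))
  aug <- fit$fitted
  if (!any(aug$role == "reheat")) {
    abort("refold_statistics() needs at least one reheat scan in the fit.")
  }
  rep <- dplyr::summarise(
    dplyr::group_by(aug, group = .data$role),
    mean = mean(.data$.resid), mean_abs = mean(abs(.data$.resid)),
    sd = stats::sd(.data$.resid), n = dplyr::n(), .groups = "drop")
  first <- dplyr::filter(aug, .data$role == "first")
  pk <- tryCatch(find_peak(dplyr::rename(first, cp = ".fitted"))$height,
                 error = function(e) NA_real_)
  attr(rep, "sd_ratio") <- rep$sd[rep$group == "reheat"] /
    rep$sd[rep$group == "first"]
  attr(rep, "peak_height") <- pk
  class(rep) <- unique(c("refold_report", class(rep)))
  rep
}

#' Flag possible alternative refolding
#'
#' Raises a flag when the reheat residual group betrays a model that predicts
#' reheating much less precisely than the first run: either the reheat
#' group's absolute signed mean exceeds `signal_threshold` (default 5%) of
#' the first-run peak amplitude, or the ratio of reheat to first-run residual
#' SDs reaches `sd_ratio_threshold` (default 2).
#'
#' @param report A `refold_report` from [refold_statistics()].
#' @param signal_threshold Bias threshold as a fraction of the first-run peak
#'   amplitude.
#' @param sd_ratio_threshold SD-ratio threshold.
#' @return A list with `flag` (logical), `rationale` (character naming the
#'   triggering statistic), and the thresholds used.
#' @export
flag_alternative_refolding <- function(report, signal_threshold = 0.05,
                                       sd_ratio_threshold = 2) {
  stopifnot(inherits(report, "refold_report"))
  sd_ratio <- attr(report, "sd_ratio")
  peak <- attr(report, "peak_height")
  bias <- abs(report$mean[report$group == "reheat"])
  reasons <- character(0)
  if (is.finite(peak) && bias > signal_threshold * peak) {
    reasons <- c(reasons, sprintf(
      "reheat residual bias %.3g exceeds %.0f%% of the first-run peak amplitude %.3g",
      bias, 100 * signal_threshold, peak))
  }
  if (sd_ratio >= sd_ratio_threshold) {
    reasons <- c(reasons, sprintf(
      "reheat/first residual SD ratio %.2f >= %.2f", sd_ratio,
      sd_ratio_threshold))
  }
  list(flag = length(reasons) > 0,
       rationale = if (length(reasons)) paste(reasons, collapse = "; ")
                   else "reheat residuals match the first run",
       sd_ratio = sd_ratio, bias = bias,
       signal_threshold = signal_threshold,
       sd_ratio_threshold = sd_ratio_threshold)
}

#' Classify reversibility from a reheat at the post-transition foot
#'
#' The reliable reversibility test reheats from a first run terminated at the
#' foot of the peak, immediately after the transition. This compares the
#' baseline-corrected reheat peak to the first-run peak and estimates the
#' surviving native fraction as their height ratio (area ratio optionally).
#' A fraction of at least `rev_min` (default 0.99) indicates a fully
#' reversible transition (reversible two-state analysis applies); fractions
#' between `partial_min` (default 0.20) and `rev_min` indicate the partially
#' reversible three-state model; lower fractions indicate essentially
#' irreversible two-state behaviour.
#'
#' @param first,reheat Single-scan [dsc_scans()] tables recorded at the same
#'   scan rate, the reheat following a first run terminated at the
#'   post-transition foot.
#' @param method `"height"` (default) or `"area"`.
#' @param rev_min,partial_min Class boundaries on the native fraction.
#' @return A list with `class` (`"A"`, `"C"`, or `"B"`), `fraction`, and
#'   `method`.
#' @export
classify_reversibility <- function(first, reheat, method = c("height", "area"),
                                   rev_min = 0.99, partial_min = 0.20) {
  method <- match.arg(method)
  if (abs(first$scan_rate[1] - reheat$scan_rate[1]) > 1e-12) {
    abort("Reversibility classification requires identical scan rates.")
  }
  pk1 <- find_peak(first)
  pk2 <- tryCatch(find_peak(reheat), error = function(e) NULL)
  fraction <- if (is.null(pk2)) 0 else if (method == "height") {
    pk2$height / pk1$height
  } else {
    pk2$area / pk1$area
  }
  fraction <- min(max(fraction, 0), 1.5)  # noise can push slightly past 1
  cls <- if (fraction >= rev_min) "A" else if (fraction >= partial_min) "C" else "B"
  list(class = cls, fraction = min(fraction, 1), method = method)
}

#' Suggest informative terminal temperatures for reheating
#'
#' From a first-run thermogram, returns the three reheat planning points:
#' point III, the apparent peak temperature, where the reheat peak decline is
#' first measurable; point V, the post-transition foot (first temperature
#' after the peak where the excess signal falls below `foot_frac` of the peak
#' height), where the reversibility check is performed; and point IV, halfway
#' between III and V, the most sensitive point for discriminating the general
#' three-state model from its limiting cases.
#'
#' @param first A single-scan [dsc_scans()] table (a first run).
#' @param pre_window Optional length-2 pre-transition window (K) for the
#'   baseline fit; default the first 15% of the scan range.
#' @param foot_frac Foot threshold as a fraction of peak height.
#' @return A tibble with columns `point` (`"III"`, `"IV"`, `"V"`) and
#'   `temperature` (K).
#' @export
suggest_reheat_temperatures <- function(first, pre_window = NULL,
                                        foot_frac = 0.02) {
  pk <- find_peak(first, pre_window = pre_window, foot_frac = foot_frac)
  tibble(point = c("III", "IV", "V"),
         temperature = c(pk$tp, (pk$tp + pk$foot) / 2, pk$foot))
}
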