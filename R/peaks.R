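# Peak characterisation of a single heating scan.
#
# The baseline is a linear fit over the pre-transition window (by default the
# first `pre_frac` of the scan's temperature span); the peak is the largest
# local maximum of the baseline-subtracted signal. The peak must rise above
# the baseline noise (`snr` times the robust SD of the pre-window residuals,
# with an absolute floor) to count as detected. The post-transition foot is
# the first temperature after the peak where the excess signal falls below
# `foot_frac` of the peak height.
find_peak <- function(data, pre_window = NULL, pre_frac = 0.15,
                      foot_frac = 0.02, snr = 5) {
  Tg <- data$temperature
  cp <- data$cp
  if (is.null(pre_window)) {
    pre_window <- c(Tg[1], Tg[1] + pre_frac * (max(Tg) - min(Tg)))
  }
  pre <- Tg >= pre_window[1] & Tg <= pre_window[2]
  if (sum(pre) < 3) abort("Pre-transition window holds fewer than 3 points.")
  bl <- stats::lm.fit(cbind(1, Tg[pre]), cp[pre])$coefficients
  excess <- cp - (bl[1] + bl[2] * Tg)
  noise <- stats::mad(excess[pre])
  ipk <- which.max(excess)
  height <- excess[ipk]
  if (ipk %in% c(1L, length(Tg)) ||
      height < max(snr * noise, 1e-12 * max(abs(cp), 1))) {
    abort("No detectable peak above the baseline.",
          class = "dscfit_no_peak_error")
  }
  # the post-transition excess plateaus at ~dCp above the pre-baseline, so
  # the foot threshold is taken relative to that plateau, not to zero
  after <- seq(ipk, length(Tg))
  post_level <- max(stats::quantile(excess[after], 0.1), 0)
  foot_i <- after[which(excess[after] - post_level <
                          foot_frac * (height - post_level))[1]]
  foot <- if (is.na(foot_i)) Tg[length(Tg)] else Tg[foot_i]
  area <- sum(diff(Tg) * (excess[-1] + excess[-length(Tg)]) / 2)
  list(tp = Tg[ipk], height = height, area = area, foot = foot,
       baseline = c(b0 = unname(bl[1]), b1 = unname(bl[2])), noise = noise)
}
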