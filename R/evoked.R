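#' Construct a stimulus-evoked trace
#'
#' A uniformly- or irregularly-sampled recording with a known stimulus
#' time, tagged by modality: `"eag"` (electroantennogram, mV; responses are
#' downward deflections), `"dcfda"` (ROS-sensor fluorescence, arbitrary
#' units; responses are increases), or `"patch"` (whole-cell current, pA;
#' responses are downward/inward deflections).
#'
#' @param times Sample times in seconds, strictly increasing.
#' @param signal Signal values, same length as `times`.
#' @param stim_time Stimulus onset in seconds; must lie within the record.
#' @param modality `"eag"`, `"dcfda"`, or `"patch"`.
#' @param unit Unit label (defaults per modality).
#' @return An `evoked_trace` tibble (`time_s`, `signal`) with `stim_time`,
#'   `modality` and `unit` attributes.
#' @examples
#' evoked_trace(0:20, c(rep(0, 10), -0.4, -0.2, rep(0, 9)), stim_time = 10,
#'              modality = "eag")
#' @export
evoked_trace <- function(times, signal, stim_time,
                         modality = c("eag", "dcfda", "patch"),
                         unit = NULL) {
  modality <- match.arg(modality)
  if (!is.numeric(times) || !is.numeric(signal) ||
      length(times) != length(signal) || length(times) < 2) {
    ft_abort("`times` and `signal` must be numeric vectors of equal length >= 2.",
             "flytube_bad_trace")
  }
  if (any(diff(times) <= 0)) {
    ft_abort("`times` must be strictly increasing.", "flytube_bad_trace")
  }
  assert_scalar_number(stim_time, "stim_time")
  if (stim_time < times[1] || stim_time > times[length(times)]) {
    ft_abort("`stim_time` must lie within the record.", "flytube_bad_trace")
  }
  if (is.null(unit)) {
    unit <- switch(modality, eag = "mV", dcfda = "a.u.", patch = "pA")
  }
  structure(
    tibble::tibble(time_s = times, signal = signal),
    stim_time = stim_time, modality = modality, unit = unit,
    class = c("evoked_trace", class(tibble::tibble()))
  )
}

# response polarity by modality: EAG and whole-cell currents deflect
# downward (magnitude reported positive); DCFDA fluorescence rises
.modality_polarity <- function(modality) {
  switch(modality, eag = "down", patch = "down", dcfda = "up")
}

# default response window (s after stimulus): 10 s for a 500 ms odor puff
# EAG, full 120 s post-record for DCFDA, 30 s application epoch for patch
.default_response_window <- function(modality) {
  switch(modality, eag = 10, dcfda = 120, patch = 30)
}

#' Quantify a stimulus-evoked peak response
#'
#' Implements the peak-minus-baseline rule: the baseline is the mean signal
#' over the `baseline_s` seconds preceding the stimulus, and the amplitude
#' is the extremum of the response window minus that baseline, signed by
#' the modality's polarity and reported as a positive magnitude for
#' downward-deflecting modalities (EAG, whole-cell current). EAG responses
#' smaller than `exclude_below` (default 0.05 mV — no-response recordings)
#' are flagged as excluded with a machine-readable reason; they are
#' returned, not dropped, so exclusion is auditable.
#'
#' @param trace An [evoked_trace()].
#' @param baseline_s Baseline duration before the stimulus, seconds
#'   (default 5). Samples with `stim_time - baseline_s <= t < stim_time`
#'   are used; the window must be fully recorded.
#' @param response_window_s Response window length after the stimulus;
#'   default per modality (EAG 10 s, DCFDA 120 s, patch 30 s).
#' @param polarity `"auto"` (per modality), `"up"`, or `"down"`.
#' @param exclude_below Exclusion floor for EAG amplitudes, in mV.
#' @return A `peak_response`: one-row tibble with `modality`, `unit`,
#'   `baseline_mean`, `amplitude`, `peak_time_s`, `excluded`, `reason`.
#' @examples
#' tr <- evoked_trace(seq(0, 20, 0.5), rep(1.2, 41), stim_time = 10)
#' tr$signal[25] <- 1.2 - 2.8 # downward EAG deflection
#' quantify_peak(tr)$amplitude
#' @export
quantify_peak <- function(trace, baseline_s = 5, response_window_s = NULL,
                          polarity = c("auto", "up", "down"),
                          exclude_below = 0.05) {
  if (!inherits(trace, "evoked_trace")) {
    ft_abort("`trace` must be an evoked_trace().", "flytube_bad_argument")
  }
  polarity <- match.arg(polarity)
  stim <- attr(trace, "stim_time")
  modality <- attr(trace, "modality")
  if (is.null(response_window_s)) {
    response_window_s <- .default_response_window(modality)
  }
  if (polarity == "auto") polarity <- .modality_polarity(modality)

  if (stim - baseline_s < trace$time_s[1]) {
    ft_abort("Baseline window extends before the start of the record.",
             "flytube_bad_baseline")
  }
  base_sel <- trace$time_s >= stim - baseline_s & trace$time_s < stim
  if (!any(base_sel)) {
    ft_abort("No samples in the baseline window.", "flytube_bad_baseline")
  }
  baseline <- mean(trace$signal[base_sel])

  resp_sel <- trace$time_s >= stim & trace$time_s <= stim + response_window_s
  if (!any(resp_sel)) {
    ft_abort("No samples in the response window.", "flytube_bad_trace")
  }
  dev <- trace$signal[resp_sel] - baseline
  idx <- if (polarity == "down") which.min(dev) else which.max(dev)
  amplitude <- if (polarity == "down") -dev[idx] else dev[idx]
  peak_time <- trace$time_s[resp_sel][idx]

  excluded <- FALSE
  reason <- NA_character_
  if (modality == "eag" && is.finite(exclude_below) && amplitude < exclude_below) {
    excluded <- TRUE
    reason <- sprintf("no_response_below_%g_mV", exclude_below)
  }
  structure(
    tibble::tibble(
      modality = modality, unit = attr(trace, "unit"),
      baseline_mean = baseline, amplitude = amplitude,
      peak_time_s = peak_time, excluded = excluded, reason = reason
    ),
    class = c("peak_response", class(tibble::tibble()))
  )
}

#' Express a test response as percent of its control
#'
#' @param test,control `peak_response` rows (e.g. light vs. dark
#'   recordings). The control must be non-excluded with nonzero amplitude.
#' @return `100 * test$amplitude / control$amplitude`.
#' @examples
#' # a response attenuated to half its dark control
#' # percent_of_control(light, dark) -> 50
#' @export
percent_of_control <- function(test, control) {
  for (p in list(test, control)) {
    if (!inherits(p, "peak_response")) {
      ft_abort("Arguments must be peak_response objects.", "flytube_bad_argument")
    }
  }
  if (isTRUE(control$excluded) || !is.finite(control$amplitude) ||
      control$amplitude == 0) {
    ft_abort("Control response is excluded or has zero amplitude; percent-of-control undefined.",
             "flytube_bad_control")
  }
  100 * test$amplitude / control$amplitude
}

#' Quantify a DCFDA (ROS sensor) fluorescence response
#'
#' Fluorescence is recorded for `baseline_s` seconds before the UV
#' stimulus and then sampled every few seconds for `post_s` seconds. The
#' response is the *steady-state peak* after the stimulus — the maximum of
#' a short moving average (default 3 samples, i.e. 9 s at the standard 3 s
#' cadence), which honors both "steady-state" and "peak" — minus the
#' baseline mean. Both the raw change dF and the normalized dF/F0
#' (relative to the baseline mean) are reported; a decrease gives a
#' negative dF.
#'
#' @param trace An [evoked_trace()] with modality `"dcfda"`.
#' @param baseline_s Baseline duration, seconds (default 30).
#' @param post_s Post-stimulus duration to consider, seconds (default 120).
#' @param smooth_n Moving-average length in samples for the steady-state
#'   peak (default 3).
#' @return A one-row tibble: `baseline_mean`, `delta_f`, `delta_f_over_f0`,
#'   `peak_time_s`.
#' @examples
#' tr <- evoked_trace(seq(0, 150, 3), c(rep(100, 11), rep(140, 40)),
#'                    stim_time = 30, modality = "dcfda")
#' dcfda_response(tr)
#' @export
dcfda_response <- function(trace, baseline_s = 30, post_s = 120, smooth_n = 3) {
  if (!inherits(trace, "evoked_trace") || attr(trace, "modality") != "dcfda") {
    ft_abort("`trace` must be an evoked_trace with modality 'dcfda'.",
             "flytube_bad_argument")
  }
  stim <- attr(trace, "stim_time")
  if (stim - baseline_s < trace$time_s[1]) {
    ft_abort("Baseline window extends before the start of the record.",
             "flytube_bad_baseline")
  }
  base_sel <- trace$time_s >= stim - baseline_s & trace$time_s < stim
  post_sel <- trace$time_s >= stim & trace$time_s <= stim + post_s
  if (sum(post_sel) < smooth_n) {
    ft_abort("Missing or too-short post-stimulus record.", "flytube_bad_trace")
  }
  f0 <- mean(trace$signal[base_sel])
  post <- trace$signal[post_sel]
  post_t <- trace$time_s[post_sel]
  sm <- stats::filter(post, rep(1 / smooth_n, smooth_n), sides = 2)
  sm <- as.numeric(sm)
  idx <- which.max(sm)
  delta_f <- sm[idx] - f0
  tibble::tibble(
    baseline_mean = f0,
    delta_f = delta_f,
    delta_f_over_f0 = delta_f / f0,
    peak_time_s = post_t[idx]
  )
}
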