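#' Motion-artifact detection parameters
#'
#' Sliding-window motion flagging operates on optical density. A window of
#' `t_motion` seconds slides across each channel/wavelength trace; samples in a
#' window are flagged when the within-window amplitude excursion (max - min)
#' strictly exceeds `amp_thresh` OD units, or when the SD of the
#' sample-to-sample differences inside the window strictly exceeds `sd_thresh`
#' times the record-wide SD of those differences. Flagged samples are dilated
#' by `t_mask` seconds on both sides.
#'
#' @param t_motion Window length in seconds.
#' @param t_mask Dilation half-width in seconds applied around flagged samples.
#' @param sd_thresh Multiple of the record-wide difference SD.
#' @param amp_thresh Amplitude excursion threshold in optical-density units.
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(t_motion = 0.5, t_mask = 1.0, sd_thresh = 5,
                          amp_thresh = 0.1) {
  stopifnot(t_motion > 0, t_mask > 0, sd_thresh > 0, amp_thresh > 0)
  structure(list(t_motion = t_motion, t_mask = t_mask,
                 sd_thresh = sd_thresh, amp_thresh = amp_thresh),
            class = "motion_params")
}

#' Band-pass filter parameters
#'
#' Third-order Butterworth band-pass (0.01-0.2 Hz by default), applied
#' forward-backward (zero phase) so that event timing is preserved. The
#' passband retains the hemodynamic response while rejecting cardiac and
#' respiratory oscillations and slow drift.
#'
#' @param order Filter order per band edge.
#' @param low_cut High-pass corner frequency in Hz.
#' @param high_cut Low-pass corner frequency in Hz.
#' @param zero_phase Apply the filter forward and backward.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(order = 3, low_cut = 0.01, high_cut = 0.2,
                          zero_phase = TRUE) {
  stopifnot(order >= 1, low_cut > 0, high_cut > low_cut)
  structure(list(order = as.integer(order), low_cut = low_cut,
                 high_cut = high_cut, zero_phase = isTRUE(zero_phase)),
            class = "filter_params")
}

#' Canonical haemodynamic response parameters
#'
#' Double-gamma kernel: a positive gamma peaking at `peak_delay` seconds minus
#' an undershoot gamma peaking at `undershoot_delay` seconds scaled by
#' `undershoot_ratio`; the kernel is normalised to unit peak so GLM betas keep
#' the units of the signal (micromolar).
#'
#' @param peak_delay Peak delay in seconds.
#' @param undershoot_delay Undershoot delay in seconds.
#' @param undershoot_ratio Relative undershoot amplitude.
#' @param duration Kernel support in seconds.
#' @return An object of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       undershoot_ratio = 1 / 6, duration = 32) {
  stopifnot(peak_delay > 0, undershoot_delay > peak_delay,
            undershoot_ratio >= 0, duration > undershoot_delay)
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 undershoot_ratio = undershoot_ratio, duration = duration),
            class = "hrf_params")
}

#' Extinction coefficients for oxy-/deoxy-haemoglobin
#'
#' Molar extinction coefficients (cm^-1 mM^-1) at the two acquisition
#' wavelengths, from the Gratzer/Cope compilation commonly shipped with fNIRS
#' toolboxes. Rows are wavelengths (760, 850 nm), columns are (HbO, HbR).
#'
#' @return A 2 x 2 numeric matrix with dimnames.
#' @export
extinction_default <- function() {
  matrix(c(0.5864, 1.5485,
           1.0580, 0.6916),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("760", "850"), c("HbO", "HbR")))
}

#' Pipeline configuration
#'
#' Bundles every analysis parameter: motion detection, band-pass, modified
#' Beer-Lambert constants, HRF shape, the prestimulus baseline window for
#' Cohen d, the QC ceiling on the masked fraction, and inference switches.
#' Runs embed the resolved configuration in their outputs.
#'
#' @param motion [motion_params()].
#' @param filter [filter_params()].
#' @param hrf [hrf_params()].
#' @param extinction 2 x 2 extinction matrix as from [extinction_default()].
#' @param pathlength Source-detector separation in cm.
#' @param baseline_window_s Prestimulus baseline length (s) for Cohen d.
#' @param qc_ceiling Maximum tolerated masked fraction before a recording is
#'   declared invalid.
#' @param d_denominator `"pooled"` (baseline + condition samples) or
#'   `"baseline"` (baseline samples only).
#' @param fisher_z Fisher z-transform coactivation values before paired
#'   inference (back-transformed for reporting).
#' @param filter_design Band-pass the GLM condition regressors with the same
#'   filter applied to the data (keeps betas unbiased under zero-phase
#'   filtering).
#' @param seed Base seed recorded with outputs.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(motion = motion_params(),
                            filter = filter_params(),
                            hrf = hrf_params(),
                            extinction = extinction_default(),
                            pathlength = 3.5,
                            baseline_window_s = 10,
                            qc_ceiling = 0.5,
                            d_denominator = c("pooled", "baseline"),
                            fisher_z = TRUE,
                            filter_design = TRUE,
                            seed = 1L) {
  d_denominator <- match.arg(d_denominator)
  stopifnot(inherits(motion, "motion_params"),
            inherits(filter, "filter_params"),
            inherits(hrf, "hrf_params"),
            is.matrix(extinction), all(dim(extinction) == c(2, 2)),
            pathlength > 0, baseline_window_s > 0,
            qc_ceiling > 0, qc_ceiling <= 1)
  structure(list(motion = motion, filter = filter, hrf = hrf,
                 extinction = extinction, pathlength = pathlength,
                 baseline_window_s = baseline_window_s,
                 qc_ceiling = qc_ceiling, d_denominator = d_denominator,
                 fisher_z = isTRUE(fisher_z),
                 filter_design = isTRUE(filter_design),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("fNIRS pipeline configuration\n")
  cat(sprintf("  motion: window %.2g s, mask %.2g s, %.3g SD, amp %.3g OD\n",
              x$motion$t_motion, x$motion$t_mask, x$motion$sd_thresh,
              x$motion$amp_thresh))
  cat(sprintf("  filter: order %d Butterworth %.3g-%.3g Hz%s\n",
              x$filter$order, x$filter$low_cut, x$filter$high_cut,
              if (x$filter$zero_phase) " (zero phase)" else ""))
  cat(sprintf("  MBLL: pathlength %.2f cm, age-adjusted DPF\n", x$pathlength))
  cat(sprintf("  Cohen d: %.0f s prestimulus baseline, %s SD\n",
              x$baseline_window_s, x$d_denominator))
  cat(sprintf("  QC ceiling %.2f; Fisher z for FC: %s\n",
              x$qc_ceiling, x$fisher_z))
  invisible(x)
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `motion`,
#' `filter` and `hrf` are nested maps whose keys mirror [motion_params()],
#' [filter_params()] and [hrf_params()]. Missing keys keep their defaults,
#' so a config file only states what it overrides.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$motion)) args$motion <- do.call(motion_params, y$motion)
  if (!is.null(y$filter)) args$filter <- do.call(filter_params, y$filter)
  if (!is.null(y$hrf)) args$hrf <- do.call(hrf_params, y$hrf)
  if (!is.null(y$extinction))
    args$extinction <- matrix(unlist(y$extinction), 2, 2, byrow = TRUE,
                              dimnames = list(c("760", "850"),
                                              c("HbO", "HbR")))
  for (k in c("pathlength", "baseline_window_s", "qc_ceiling",
              "d_denominator", "fisher_z", "filter_design", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}
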