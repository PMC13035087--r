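#' Raw dual-wavelength recording
#'
#' @param intensity Numeric array `channels x wavelengths x time` (8 x 2 x T),
#'   strictly positive, arbitrary units. Wavelength order is 760 then 850 nm.
#' @param sampling_rate Hz.
#' @param events Data frame `label`, `onset`, `duration` (seconds).
#' @param subject_age Age in years (drives the differential pathlength factor).
#' @param excluded_spans Data frame `start`, `end` (seconds) of pre-marked
#'   manual trims; may have zero rows.
#' @param subject_id,visit Optional identifiers carried through outputs.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(intensity, sampling_rate, events, subject_age,
                          excluded_spans = data.frame(start = numeric(0),
                                                      end = numeric(0)),
                          subject_id = NA_character_, visit = NA_character_) {
  stopifnot(is.array(intensity), length(dim(intensity)) == 3,
            dim(intensity)[2] == 2, sampling_rate > 0,
            is.data.frame(events), subject_age > 0)
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("intensities must be finite and strictly positive", call. = FALSE)
  dur <- dim(intensity)[3] / sampling_rate
  if (nrow(events) && any(events$onset + events$duration > dur + 1e-9))
    stop("event extends past record duration", call. = FALSE)
  structure(list(intensity = intensity, sampling_rate = sampling_rate,
                 events = events, subject_age = subject_age,
                 excluded_spans = excluded_spans,
                 subject_id = subject_id, visit = visit),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "raw_recording: %d channels x %d wavelengths x %d samples (%.0f s @ %g Hz)\n",
    d[1], d[2], d[3], d[3] / x$sampling_rate, x$sampling_rate))
  cat(sprintf("  subject %s / visit %s, age %.1f, %d event(s)\n",
              x$subject_id, x$visit, x$subject_age, nrow(x$events)))
  invisible(x)
}

#' Convert raw intensities to optical density change
#'
#' OD(c, lambda, t) = -ln( I(c, lambda, t) / mean_t I(c, lambda, .) ). The
#' normalisation by the per-channel, per-wavelength time mean makes OD
#' scale-free in the source intensity.
#'
#' @param raw A [raw_recording()].
#' @return An `od_series`: list with `od` (same shape as the intensity array),
#'   `motion_mask` (channels x time, all `FALSE` until
#'   [detect_motion_artifacts()] runs), and acquisition metadata.
#' @export
intensity_to_od <- function(raw) {
  stopifnot(inherits(raw, "raw_recording"))
  I <- raw$intensity
  if (any(I <= 0)) {
    bad <- which(I <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive intensity at channel %d, wavelength %d, sample %d",
                 bad[1], bad[2], bad[3]), call. = FALSE)
  }
  od <- I
  for (ch in seq_len(dim(I)[1]))
    for (wl in 1:2) {
      x <- I[ch, wl, ]
      od[ch, wl, ] <- -log(x / mean(x))
    }
  structure(list(od = od, motion_mask = matrix(FALSE, dim(I)[1], dim(I)[3]),
                 sampling_rate = raw$sampling_rate, events = raw$events,
                 subject_age = raw$subject_age,
                 excluded_spans = raw$excluded_spans,
                 subject_id = raw$subject_id, visit = raw$visit),
            class = "od_series")
}

# Running windowed max-min and SD of first differences, window length w.
# Returns per-window logicals aligned to window start.
window_flags <- function(x, w, amp_thresh, sd_thresh, sd_ref) {
  n <- length(x)
  nw <- n - w + 1
  E <- stats::embed(x, w)            # nw x w, row i = x[i+w-1], ..., x[i]
  rng <- do.call(pmax, as.data.frame(E)) - do.call(pmin, as.data.frame(E))
  d <- diff(x)
  wd <- w - 1                        # diffs inside a window of w samples
  s1 <- c(0, cumsum(d))
  s2 <- c(0, cumsum(d^2))
  i <- seq_len(nw)
  sumd <- s1[i + wd] - s1[i]
  sumd2 <- s2[i + wd] - s2[i]
  v <- (sumd2 - sumd^2 / wd) / (wd - 1)
  v[v < 0] <- 0
  sdw <- sqrt(v)
  rng > amp_thresh | sdw > sd_thresh * sd_ref
}

#' Flag motion artifacts on optical-density traces
#'
#' Sliding window of `t_motion` seconds per channel and wavelength; a window
#' is flagged when its amplitude excursion strictly exceeds `amp_thresh` OD
#' units or when the SD of its sample-to-sample differences strictly exceeds
#' `sd_thresh` times the record-wide SD of differences. Flagged windows are
#' dilated by `t_mask` seconds on both sides, and the per-channel mask is the
#' union over the two wavelengths.
#'
#' @param od An `od_series` from [intensity_to_od()].
#' @param params [motion_params()].
#' @param sampling_rate Hz; defaults to the value stored in `od`.
#' @return Logical matrix channels x time, `TRUE` = contaminated.
#' @export
detect_motion_artifacts <- function(od, params = motion_params(),
                                    sampling_rate = od$sampling_rate) {
  stopifnot(inherits(od, "od_series"), inherits(params, "motion_params"))
  n <- dim(od$od)[3]
  w <- round(params$t_motion * sampling_rate)
  if (w < 2) stop("t_motion window shorter than 2 samples", call. = FALSE)
  if (n <= w) stop("record shorter than the motion window", call. = FALSE)
  m <- round(params$t_mask * sampling_rate)
  nch <- dim(od$od)[1]
  mask <- matrix(FALSE, nch, n)
  for (ch in seq_len(nch)) {
    flagged <- rep(FALSE, n)
    for (wl in 1:2) {
      x <- od$od[ch, wl, ]
      sd_ref <- stats::sd(diff(x))
      if (!is.finite(sd_ref)) sd_ref <- 0
      wf <- window_flags(x, w, params$amp_thresh, params$sd_thresh, sd_ref)
      # a flagged window marks all w samples it covers
      hit <- rep(FALSE, n)
      idx <- which(wf)
      for (i in idx) hit[i:(i + w - 1)] <- TRUE
      flagged <- flagged | hit
    }
    # dilate by +/- t_mask
    idx <- which(flagged)
    if (length(idx)) {
      lo <- pmax(1L, idx - m)
      hi <- pmin(n, idx + m)
      out <- rep(FALSE, n)
      for (k in seq_along(idx)) out[lo[k]:hi[k]] <- TRUE
      mask[ch, ] <- out
    }
  }
  mask
}

# Zero-phase (or single-pass) Butterworth band-pass on one numeric vector.
apply_bandpass <- function(x, params, sampling_rate) {
  nyq <- sampling_rate / 2
  if (params$high_cut >= nyq)
    stop("high_cut must be below the Nyquist frequency", call. = FALSE)
  bf <- signal::butter(params$order,
                       c(params$low_cut, params$high_cut) / nyq,
                       type = "pass")
  if (params$zero_phase) signal::filtfilt(bf, x)
  else as.numeric(signal::filter(bf, x))
}

#' Band-pass filter an optical-density series
#'
#' Applies the configured Butterworth band-pass to every channel/wavelength
#' trace. Output length equals input length; the motion mask is carried
#' through unchanged.
#'
#' @param od An `od_series`.
#' @param params [filter_params()].
#' @param sampling_rate Hz; defaults to the value stored in `od`.
#' @return The filtered `od_series`.
#' @export
bandpass_filter <- function(od, params = filter_params(),
                            sampling_rate = od$sampling_rate) {
  stopifnot(inherits(od, "od_series"), inherits(params, "filter_params"))
  out <- od
  for (ch in seq_len(dim(od$od)[1]))
    for (wl in 1:2)
      out$od[ch, wl, ] <- apply_bandpass(od$od[ch, wl, ], params,
                                         sampling_rate)
  out
}

# General age- and wavelength-dependent DPF (Scholkmann & Wolf form).
.dpf_coef <- c(a = 223.3, b = 0.05624, g = 0.8493,
               d = -5.723e-7, e = 0.001245, z = -0.9025)

#' Differential pathlength factor for a given age and wavelength
#'
#' General age- and wavelength-dependent formula
#' `DPF = a + b * age^g + d * lambda^3 + e * lambda^2 + z * lambda`
#' with lambda in nm; monotonically increasing in age at fixed wavelength.
#'
#' @param age Age in years (18-100).
#' @param wavelength 760 or 850 (nm).
#' @return DPF (dimensionless).
#' @export
dpf_for_age <- function(age, wavelength) {
  if (!all(wavelength %in% c(760, 850)))
    stop("unsupported wavelength; expected 760 or 850 nm", call. = FALSE)
  if (any(age < 18 | age > 100))
    stop("age outside the supported 18-100 range", call. = FALSE)
  k <- .dpf_coef
  k[["a"]] + k[["b"]] * age^k[["g"]] + k[["d"]] * wavelength^3 +
    k[["e"]] * wavelength^2 + k[["z"]] * wavelength
}

#' Convert optical density to haemoglobin concentration changes
#'
#' Modified Beer-Lambert law: per channel and sample solves
#' `dOD(lambda) = (eHbO(lambda) dHbO + eHbR(lambda) dHbR) * L * DPF(lambda)`
#' for (dHbO, dHbR), with L in cm and extinction coefficients in
#' cm^-1 mM^-1; results are scaled to micromolar.
#'
#' @param od An `od_series` (typically band-pass filtered).
#' @param age Age in years; defaults to the age stored in `od`.
#' @param pathlength Source-detector separation in cm.
#' @param extinction 2 x 2 matrix as from [extinction_default()].
#' @return An `hb_series`: `hbo`, `hbr` (channels x time, micromolar),
#'   `valid_mask` (channels x time, `TRUE` = usable, i.e. not
#'   motion-contaminated), `dpf`, `pathlength`, plus acquisition metadata.
#' @export
od_to_hemoglobin <- function(od, age = od$subject_age, pathlength = 3.5,
                             extinction = extinction_default()) {
  stopifnot(inherits(od, "od_series"), pathlength > 0)
  if (abs(det(extinction)) < 1e-12)
    stop("extinction matrix is singular", call. = FALSE)
  dpf <- c(dpf_for_age(age, 760), dpf_for_age(age, 850))
  nch <- dim(od$od)[1]; n <- dim(od$od)[3]
  Einv <- solve(extinction)
  hbo <- matrix(NA_real_, nch, n)
  hbr <- matrix(NA_real_, nch, n)
  for (ch in seq_len(nch)) {
    Y <- rbind(od$od[ch, 1, ] / (pathlength * dpf[1]),
               od$od[ch, 2, ] / (pathlength * dpf[2]))   # mM scale
    C <- Einv %*% Y * 1000                               # -> uM
    hbo[ch, ] <- C[1, ]
    hbr[ch, ] <- C[2, ]
  }
  structure(list(hbo = hbo, hbr = hbr, valid_mask = !od$motion_mask,
                 dpf = stats::setNames(dpf, c("760", "850")),
                 pathlength = pathlength,
                 sampling_rate = od$sampling_rate, events = od$events,
                 subject_age = od$subject_age,
                 subject_id = od$subject_id, visit = od$visit),
            class = "hb_series")
}

#' @export
print.hb_series <- function(x, ...) {
  cat(sprintf("hb_series: %d channels x %d samples @ %g Hz, %.1f%% valid\n",
              nrow(x$hbo), ncol(x$hbo), x$sampling_rate,
              100 * mean(x$valid_mask)))
  invisible(x)
}

#' Run the full preprocessing chain
#'
#' quality check (pre-marked excluded spans merged into the mask) ->
#' optical-density conversion -> motion-artifact flagging -> band-pass
#' filtering -> modified Beer-Lambert conversion. A recording is declared
#' invalid when the overall masked fraction exceeds `config$qc_ceiling`;
#' invalidity is a recorded outcome, not an exception.
#'
#' @param raw A [raw_recording()].
#' @param config A [pipeline_config()].
#' @return List with `hb` (an `hb_series`) and `qc` (list: `masked_fraction`,
#'   per-channel `channel_masked_fraction` and `channel_valid`, and `valid`).
#' @export
run_preprocessing <- function(raw, config = pipeline_config()) {
  stopifnot(inherits(raw, "raw_recording"),
            inherits(config, "pipeline_config"))
  od <- intensity_to_od(raw)
  n <- dim(od$od)[3]
  excl <- rep(FALSE, n)
  if (nrow(raw$excluded_spans))
    for (i in seq_len(nrow(raw$excluded_spans)))
      excl <- excl | samples_in_span(raw$excluded_spans$start[i],
                                     raw$excluded_spans$end[i] -
                                       raw$excluded_spans$start[i],
                                     raw$sampling_rate, n)
  motion <- detect_motion_artifacts(od, config$motion)
  od$motion_mask <- motion | matrix(excl, nrow(motion), n, byrow = TRUE)
  od <- bandpass_filter(od, config$filter)
  hb <- od_to_hemoglobin(od, age = raw$subject_age,
                         pathlength = config$pathlength,
                         extinction = config$extinction)
  ch_frac <- rowMeans(!hb$valid_mask)
  frac <- mean(!hb$valid_mask)
  qc <- list(masked_fraction = frac,
             channel_masked_fraction = ch_frac,
             channel_valid = ch_frac <= config$qc_ceiling,
             valid = frac <= config$qc_ceiling)
  list(hb = hb, qc = qc)
}
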