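#' Planted neural ground truth for the simulator
#'
#' @param beta 8 x n-conditions matrix of planted GLM amplitudes (micromolar);
#'   column names are the condition labels.
#' @param shared_components List of `list(channels = <int vector>, weight =
#'   <numeric>)` entries; each adds a common band-limited signal, scaled by
#'   `weight` (micromolar), to the listed channels, planting coactivation.
#' @param hrf [hrf_params()] used by the forward model.
#' @param beta_sd Between-subject SD of the planted betas (micromolar).
#' @param change_sd Within-subject SD of the pre-to-post beta change
#'   (micromolar).
#' @param hbr_ratio HbR is generated as `-hbr_ratio` times the HbO signal
#'   (the Beer-Lambert-consistent counterpart; no independent HbR effects).
#' @return Object of class `neural_truth`.
#' @export
neural_truth <- function(beta, shared_components = list(),
                         hrf = hrf_params(), beta_sd = 0.05,
                         change_sd = 0.05, hbr_ratio = 0.25) {
  stopifnot(is.matrix(beta), nrow(beta) == 8, !is.null(colnames(beta)),
            all(is.finite(beta)), beta_sd >= 0, change_sd >= 0)
  for (sc in shared_components)
    stopifnot(all(sc$channels %in% 1:8), is.finite(sc$weight))
  structure(list(beta = beta, shared_components = shared_components,
                 hrf = hrf, beta_sd = beta_sd, change_sd = change_sd,
                 hbr_ratio = hbr_ratio),
            class = "neural_truth")
}

#' Default planted truth for a study-like cohort
#'
#' Movement conditions activate all channels moderately; VR conditions
#' activate the medial channels; `post = TRUE` adds the planted pre-to-post
#' increase at channel 4 (right medial PFC) for both VR conditions. The
#' planted increase defaults to 1.5 times the within-subject change SD, a
#' regime where the paired t-test at n = 10 has high theoretical power.
#'
#' @param post Return the post-treatment truth.
#' @param effect_multiple Planted channel-4 increase as a multiple of
#'   `change_sd`.
#' @param ... Passed to [neural_truth()].
#' @return A [neural_truth()].
#' @export
default_truth <- function(post = FALSE, effect_multiple = 1.5, ...) {
  conds <- c("noninjured", "injured", "relaxation", "distraction")
  beta <- matrix(0.2, 8, 4, dimnames = list(NULL, conds))
  beta[, "injured"] <- 0.35
  beta[, c("relaxation", "distraction")] <- 0.15
  beta[3:6, c("relaxation", "distraction")] <- 0.25
  truth <- neural_truth(beta,
                        shared_components = list(
                          list(channels = c(4, 7), weight = 0.3),
                          list(channels = c(3, 8), weight = 0.25)),
                        ...)
  if (post)
    truth$beta[4, c("relaxation", "distraction")] <-
      truth$beta[4, c("relaxation", "distraction")] +
      effect_multiple * truth$change_sd
  truth
}

#' Physiological and instrumental noise specification
#'
#' Oscillatory components are `(frequency Hz, amplitude uM)` pairs: cardiac
#' (~1.1 Hz), respiratory (~0.25 Hz) and Mayer waves (~0.1 Hz), plus linear
#' drift, white measurement noise, and transient motion artifacts injected in
#' optical-density units.
#'
#' @param cardiac,respiratory,mayer Numeric length-2 `(freq, amplitude)`.
#' @param drift_slope Linear drift in uM per second.
#' @param white_sd White-noise SD in uM.
#' @param artifact_rate Motion artifacts per minute.
#' @param artifact_amplitude Artifact amplitude in OD units.
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(cardiac = c(1.1, 0.2), respiratory = c(0.25, 0.1),
                       mayer = c(0.1, 0.1), drift_slope = 0.002,
                       white_sd = 0.05, artifact_rate = 0.5,
                       artifact_amplitude = 0.2) {
  stopifnot(length(cardiac) == 2, length(respiratory) == 2,
            length(mayer) == 2,
            cardiac[2] >= 0, respiratory[2] >= 0, mayer[2] >= 0,
            white_sd >= 0, artifact_rate >= 0, artifact_amplitude >= 0)
  structure(list(cardiac = cardiac, respiratory = respiratory, mayer = mayer,
                 drift_slope = drift_slope, white_sd = white_sd,
                 artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude),
            class = "noise_spec")
}

#' Noise-free specification (all amplitudes zero)
#' @return A [noise_spec()] with every amplitude, drift, and artifact rate 0.
#' @export
noise_free <- function() {
  noise_spec(cardiac = c(1.1, 0), respiratory = c(0.25, 0),
             mayer = c(0.1, 0), drift_slope = 0, white_sd = 0,
             artifact_rate = 0, artifact_amplitude = 0)
}

# Band-limited (0.02-0.1 Hz) unit-SD random signal for shared components.
smooth_signal <- function(n, sampling_rate) {
  x <- stats::rnorm(n)
  bf <- signal::butter(2, c(0.02, 0.1) / (sampling_rate / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  y / stats::sd(y)
}

#' Synthesize one raw dual-wavelength recording
#'
#' Forward model: per-channel HbO is planted-beta times the HRF-convolved
#' condition boxcars, plus shared band-limited components (planted
#' coactivation), physiological oscillations, drift and white noise; HbR is
#' the scaled negative counterpart. The modified Beer-Lambert law (same
#' extinction table, pathlength and age-adjusted DPF the pipeline uses) maps
#' concentrations to optical density; intensities are
#' `baseline * exp(-OD)`, so the pipeline's conversions invert the forward
#' model exactly up to a per-channel constant. Motion artifacts (spikes and
#' baseline steps) are injected in OD units. Deterministic given `seed`.
#'
#' @param design A [task_design()].
#' @param truth A [neural_truth()] with beta columns matching the design's
#'   condition labels.
#' @param noise A [noise_spec()].
#' @param age Subject age in years.
#' @param seed Integer seed.
#' @param pathlength,extinction Forward-model Beer-Lambert constants; must
#'   match the analysis configuration for round-trip recovery.
#' @param baseline_intensity Baseline intensity for exponentiation (arbitrary
#'   units; unobservable downstream because OD is mean-normalised).
#' @param subject_id,visit Identifiers stored on the recording.
#' @return A [raw_recording()].
#' @export
simulate_subject <- function(design, truth, noise = noise_spec(), age = 47,
                             seed = 1L, pathlength = 3.5,
                             extinction = extinction_default(),
                             baseline_intensity = 1.0,
                             subject_id = "sim", visit = "pre") {
  stopifnot(inherits(design, "task_design"), inherits(truth, "neural_truth"),
            inherits(noise, "noise_spec"))
  fs <- design$sampling_rate
  nyq <- fs / 2
  for (osc in list(noise$cardiac, noise$respiratory, noise$mayer))
    if (osc[2] > 0 && osc[1] >= nyq)
      stop("noise oscillation at or above the Nyquist frequency",
           call. = FALSE)
  labels <- condition_labels(design)
  if (!all(labels %in% colnames(truth$beta)))
    stop("truth beta columns do not cover the design's conditions",
         call. = FALSE)
  set.seed(seed)
  n <- round(design$total_duration * fs)
  tt <- (seq_len(n) - 1) / fs
  X <- build_design_matrix(design, hrf = truth$hrf, sampling_rate = fs,
                           nuisance = character(0))
  task <- X$X %*% t(truth$beta[, X$labels, drop = FALSE])   # n x 8

  shared <- matrix(0, n, 8)
  for (sc in truth$shared_components) {
    s <- smooth_signal(n, fs)
    for (ch in sc$channels) shared[, ch] <- shared[, ch] + sc$weight * s
  }

  physio <- matrix(0, n, 8)
  for (osc in list(noise$cardiac, noise$respiratory, noise$mayer)) {
    if (osc[2] == 0) next
    phase <- stats::runif(8, 0, 2 * pi)
    for (ch in 1:8)
      physio[, ch] <- physio[, ch] + osc[2] * sin(2 * pi * osc[1] * tt +
                                                    phase[ch])
  }
  drift <- noise$drift_slope * tt
  white <- matrix(stats::rnorm(n * 8, sd = noise$white_sd), n, 8)

  clean <- task + shared
  hbo <- clean + physio + drift + white
  hbr <- -truth$hbr_ratio * (clean + physio + drift) +
    matrix(stats::rnorm(n * 8, sd = 0.3 * noise$white_sd), n, 8)

  dpf <- c(dpf_for_age(age, 760), dpf_for_age(age, 850))
  intensity <- array(NA_real_, c(8, 2, n))
  od_art <- matrix(0, 8, n)
  n_art <- stats::rpois(1, noise$artifact_rate * design$total_duration / 60)
  if (n_art > 0)
    for (a in seq_len(n_art)) {
      ch <- sample.int(8, 1)
      at <- sample.int(n, 1)
      amp <- noise$artifact_amplitude * stats::runif(1, 0.8, 1.5) *
        sample(c(-1, 1), 1)
      if (stats::runif(1) < 0.7) {         # spike with fast decay
        idx <- at:min(n, at + 3)
        od_art[ch, idx] <- od_art[ch, idx] + amp * exp(-(seq_along(idx) - 1))
      } else {                             # baseline step
        od_art[ch, at:n] <- od_art[ch, at:n] + amp / 2
      }
    }
  for (wl in 1:2) {
    e <- extinction[wl, ]
    for (ch in 1:8) {
      od <- (e[["HbO"]] * hbo[, ch] + e[["HbR"]] * hbr[, ch]) * 1e-3 *
        pathlength * dpf[wl] + od_art[ch, ]
      intensity[ch, wl, ] <- baseline_intensity * exp(-od)
    }
  }
  raw_recording(intensity, sampling_rate = fs, events = design$blocks,
                subject_age = age, subject_id = subject_id, visit = visit)
}

#' Behavioural instrument and brain-behaviour effect specification
#'
#' Instruments mirror the study battery: numerical pain ratings at rest and
#' with activity (0-10), four pain-interference items (0-10), pain
#' catastrophizing (PCS-13, 0-52), pain anxiety (PASS-20, 0-100), pain
#' self-efficacy (PSEQ, 0-60), mindfulness (CAMS-R, 12-48) and coping (MOCS,
#' 0-52). Planted mean changes are the published group mean differences and
#' change SDs are derived from the published paired d values; pre-visit means
#' are plausible mid-scale values consistent with the trial's inclusion
#' thresholds.
#'
#' @param instruments Data frame `name`, `min`, `max`, `pre_mean`, `pre_sd`,
#'   `mean_change`, `change_sd`.
#' @param brain_behavior List `channel`, `condition`, `instrument`, `r`: the
#'   planted correlation between the named channel/condition beta change and
#'   the named instrument's change score.
#' @return Object of class `behavioral_effect_spec`.
#' @export
behavioral_effect_spec <- function(instruments = default_instruments(),
                                   brain_behavior = list(
                                     channel = 4, condition = "distraction",
                                     instrument = "CAMS-R", r = -0.7)) {
  stopifnot(is.data.frame(instruments),
            all(c("name", "min", "max", "pre_mean", "pre_sd", "mean_change",
                  "change_sd") %in% names(instruments)))
  if (abs(brain_behavior$r) > 1)
    stop("|brain_behavior_r| must be <= 1", call. = FALSE)
  if (!brain_behavior$instrument %in% instruments$name)
    stop("brain_behavior instrument not in the instrument table",
         call. = FALSE)
  structure(list(instruments = instruments, brain_behavior = brain_behavior),
            class = "behavioral_effect_spec")
}

#' @rdname behavioral_effect_spec
#' @export
default_instruments <- function() {
  data.frame(
    name = c("NRS-rest", "NRS-activity", "DVPRS-activity", "DVPRS-sleep",
             "DVPRS-mood", "DVPRS-stress", "PCS-13", "PASS-20", "PSEQ",
             "CAMS-R", "MOCS"),
    min = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 12, 0),
    max = c(10, 10, 10, 10, 10, 10, 52, 100, 60, 48, 52),
    pre_mean = c(5.5, 6.5, 6.0, 5.5, 5.0, 5.5, 28, 55, 30, 30, 26),
    pre_sd = c(1.8, 1.8, 2.0, 2.0, 2.0, 2.0, 6, 12, 10, 5, 6),
    mean_change = c(-2.50, -3.40, -3.90, -4.20, -4.50, -4.90, -16.40,
                    -32.70, 15.40, 3.29, 0.59),
    change_sd = c(1.12, 1.72, 2.17, 2.33, 2.50, 2.72, 7.70, 15.28, 10.20,
                  3.50, 0.58),
    stringsAsFactors = FALSE)
}

#' Draw per-subject metric-level scores for a cohort
#'
#' The sampling core of [simulate_cohort()], usable on its own for
#' statistical-calibration studies: per-subject planted beta matrices (pre =
#' population truth + between-subject deviation; post = pre + planted mean
#' change + within-subject change noise) and behavioural pre/post scores.
#' The named neural change score and the named instrument's change score are
#' drawn jointly from a bivariate normal with the planted correlation, then
#' affine-mapped into the instrument range with clipping; the clipping
#' fraction is reported because clipping attenuates the planted correlation.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param pre_truth,post_truth [neural_truth()] objects for the two visits.
#' @param effect_spec A [behavioral_effect_spec()].
#' @param seed Integer seed.
#' @return List: `ages`, `pre_beta`/`post_beta` (lists of 8 x k matrices),
#'   `neural_change` (named metric, per subject), `behavioral` (long data
#'   frame), `behavioral_change` (instruments x subjects matrix, unclipped),
#'   `clip_fraction`.
#' @export
draw_cohort_scores <- function(n_subjects, pre_truth = default_truth(),
                               post_truth = default_truth(post = TRUE),
                               effect_spec = behavioral_effect_spec(),
                               seed = 1L) {
  if (n_subjects < 2)
    stop("n_subjects must be at least 2", call. = FALSE)
  stopifnot(inherits(pre_truth, "neural_truth"),
            inherits(post_truth, "neural_truth"),
            inherits(effect_spec, "behavioral_effect_spec"))
  set.seed(seed)
  ages <- numeric(n_subjects)
  for (s in seq_len(n_subjects)) {
    repeat {
      a <- stats::rnorm(1, 47, 12)
      if (a >= 18 && a <= 80) break
    }
    ages[s] <- a
  }
  k <- ncol(pre_truth$beta)
  delta <- post_truth$beta - pre_truth$beta
  bb <- effect_spec$brain_behavior
  ins <- effect_spec$instruments
  pre_beta <- post_beta <- vector("list", n_subjects)
  neural_change <- numeric(n_subjects)
  beh_rows <- list()
  beh_change <- matrix(NA_real_, nrow(ins), n_subjects,
                       dimnames = list(ins$name, NULL))
  n_clip <- 0; n_scores <- 0
  for (s in seq_len(n_subjects)) {
    Zb <- matrix(stats::rnorm(8 * k), 8, k,
                 dimnames = dimnames(pre_truth$beta))
    Zc <- matrix(stats::rnorm(8 * k), 8, k,
                 dimnames = dimnames(pre_truth$beta))
    pre_b <- pre_truth$beta + pre_truth$beta_sd * Zb
    post_b <- pre_b + delta + pre_truth$change_sd * Zc
    dimnames(pre_b) <- dimnames(post_b) <- dimnames(pre_truth$beta)
    pre_beta[[s]] <- pre_b
    post_beta[[s]] <- post_b
    z1 <- Zc[bb$channel, bb$condition]
    neural_change[s] <- post_b[bb$channel, bb$condition] -
      pre_b[bb$channel, bb$condition]
    for (i in seq_len(nrow(ins))) {
      z <- if (ins$name[i] == bb$instrument)
        bb$r * z1 + sqrt(1 - bb$r^2) * stats::rnorm(1)
      else stats::rnorm(1)
      pre_raw <- ins$pre_mean[i] + ins$pre_sd[i] * stats::rnorm(1)
      change <- ins$mean_change[i] + ins$change_sd[i] * z
      pre_sc <- min(max(pre_raw, ins$min[i]), ins$max[i])
      post_sc <- min(max(pre_sc + change, ins$min[i]), ins$max[i])
      n_scores <- n_scores + 2
      n_clip <- n_clip + (pre_sc != pre_raw) +
        (post_sc != pre_sc + change)
      beh_change[i, s] <- change
      beh_rows[[length(beh_rows) + 1]] <- data.frame(
        subject = sprintf("S%02d", s), visit = c("pre", "post"),
        instrument = ins$name[i], score = c(pre_sc, post_sc),
        stringsAsFactors = FALSE)
    }
  }
  list(ages = ages, pre_beta = pre_beta, post_beta = post_beta,
       neural_change = neural_change,
       behavioral = do.call(rbind, beh_rows),
       behavioral_change = beh_change,
       clip_fraction = n_clip / n_scores)
}

#' Simulate a paired pre/post cohort of raw recordings
#'
#' Draws per-subject planted betas and behavioural scores with
#' [draw_cohort_scores()], then synthesizes a pre and a post raw recording
#' per subject with [simulate_subject()]. Movement-evoked pain manipulation
#' checks (per-hold 0-100 ratings, higher on the injured side) are generated
#' but not consumed by the numeric pipeline. The complete planted ground
#' truth is exported for recovery tests.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param effect_spec A [behavioral_effect_spec()].
#' @param pre_truth,post_truth Population [neural_truth()] per visit.
#' @param noise A [noise_spec()].
#' @param seed Integer seed; all randomness derives from it.
#' @param design A [task_design()]; default [make_protocol()].
#' @return Object of class `cohort_dataset`: `subjects` (list of `id`, `age`,
#'   `pre`, `post` raw recordings), `behavioral`, `pain_ratings`, `truth`
#'   (per-subject planted betas, neural change scores, specs, seed).
#' @export
simulate_cohort <- function(n_subjects = 10,
                            effect_spec = behavioral_effect_spec(),
                            pre_truth = default_truth(),
                            post_truth = default_truth(post = TRUE),
                            noise = noise_spec(), seed = 1L,
                            design = make_protocol()) {
  scores <- draw_cohort_scores(n_subjects, pre_truth, post_truth,
                               effect_spec, seed)
  set.seed(seed + 1L)
  rec_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 2 * n_subjects), n_subjects, 2)
  n_holds <- sum(design$blocks$label == "injured")
  subjects <- vector("list", n_subjects)
  pain_rows <- list()
  for (s in seq_len(n_subjects)) {
    id <- sprintf("S%02d", s)
    tr_pre <- pre_truth; tr_pre$beta <- scores$pre_beta[[s]]
    tr_post <- post_truth; tr_post$beta <- scores$post_beta[[s]]
    subjects[[s]] <- list(
      id = id, age = scores$ages[s],
      pre = simulate_subject(design, tr_pre, noise, scores$ages[s],
                             seed = rec_seeds[s, 1], subject_id = id,
                             visit = "pre"),
      post = simulate_subject(design, tr_post, noise, scores$ages[s],
                              seed = rec_seeds[s, 2], subject_id = id,
                              visit = "post"))
    for (v in c("pre", "post"))
      for (side in c("noninjured", "injured")) {
        mu <- if (side == "injured") 44.11 else 2.74
        sdv <- if (side == "injured") 17.17 else 7.60
        r <- pmin(pmax(stats::rnorm(n_holds, mu, sdv), 0), 100)
        pain_rows[[length(pain_rows) + 1]] <- data.frame(
          subject = id, visit = v, condition = side,
          hold = seq_len(n_holds), rating = r, stringsAsFactors = FALSE)
      }
  }
  set.seed(seed + 2L)
  covariates <- data.frame(
    subject = vapply(subjects, `[[`, "", "id"),
    age = scores$ages,
    time_since_injury_days = pmax(1, round(stats::rnorm(n_subjects,
                                                        38.4, 36.33))),
    injury_type = sample(c("fracture", "rupture"), n_subjects,
                         replace = TRUE, prob = c(0.9, 0.1)),
    stringsAsFactors = FALSE)
  structure(list(subjects = subjects, behavioral = scores$behavioral,
                 pain_ratings = do.call(rbind, pain_rows),
                 covariates = covariates,
                 truth = list(pre_truth = pre_truth, post_truth = post_truth,
                              pre_beta = scores$pre_beta,
                              post_beta = scores$post_beta,
                              neural_change = scores$neural_change,
                              behavioral_change = scores$behavioral_change,
                              clip_fraction = scores$clip_fraction,
                              effect_spec = effect_spec, seed = seed),
                 design = design, seed = seed),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort_dataset: %d subjects x 2 visits, seed %d\n",
              length(x$subjects), x$seed))
  cat(sprintf("  conditions: %s\n",
              paste(condition_labels(x$design), collapse = ", ")))
  cat(sprintf("  behavioural instruments: %d; clipping fraction %.3f\n",
              length(unique(x$behavioral$instrument)),
              x$truth$clip_fraction))
  invisible(x)
}
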