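#' Channel-to-region assignment for the 8-channel prefrontal montage
#'
#' Two channels per region: channels 1-2 right lateral PFC, 3-4 right medial
#' PFC, 5-6 left medial PFC, 7-8 left lateral PFC. This is the unique
#' 2-per-region assignment consistent with the montage's printed channel
#' labels (channel 4 right medial, channel 8 left lateral) and with the
#' region labels of the indexed channel pairs under lexicographic pair
#' enumeration.
#'
#' @return Named character vector of length 8, `channel -> region`.
#' @export
region_map <- function() {
  stats::setNames(rep(c("right-lateral", "right-medial",
                        "left-medial", "left-lateral"), each = 2),
                  as.character(1:8))
}

#' Lexicographic enumeration of unordered channel pairs
#'
#' FC1 = (1,2), ..., FC7 = (1,8), FC8 = (2,3), ..., FC28 = (7,8).
#'
#' @return Data frame with columns `pair` ("FC1".."FC28"), `i`, `j`,
#'   `region_i`, `region_j`.
#' @export
fc_pair_table <- function() {
  ij <- utils::combn(8, 2)
  rm <- region_map()
  data.frame(pair = paste0("FC", seq_len(ncol(ij))),
             i = ij[1, ], j = ij[2, ],
             region_i = unname(rm[as.character(ij[1, ])]),
             region_j = unname(rm[as.character(ij[2, ])]),
             stringsAsFactors = FALSE)
}

#' Prestimulus-baseline effect size per channel
#'
#' Cohen d of a condition against its prestimulus baseline: the difference
#' between the mean HbO over the condition's samples and the mean over the
#' `baseline_window_s` seconds immediately preceding the condition's first
#' block, divided by the pooled SD of the two intervals (or the baseline SD
#' when `denominator = "baseline"`). Increased HbO during the condition gives
#' d > 0. Masked samples are excluded; an empty baseline yields `NA` with a
#' warning.
#'
#' @param hb An `hb_series`.
#' @param design A [task_design()].
#' @param condition Condition label.
#' @param baseline_window_s Baseline window length in seconds (default 10).
#' @param denominator `"pooled"` or `"baseline"`.
#' @return Numeric vector, one d per channel.
#' @export
block_effect_size <- function(hb, design, condition, baseline_window_s = 10,
                              denominator = c("pooled", "baseline")) {
  stopifnot(inherits(hb, "hb_series"), inherits(design, "task_design"))
  denominator <- match.arg(denominator)
  n <- ncol(hb$hbo)
  cond_sel <- condition_samples(design, condition, n)
  first_on <- min(design$blocks$onset[design$blocks$label == condition])
  base_sel <- samples_in_span(max(0, first_on - baseline_window_s),
                              min(baseline_window_s, first_on),
                              hb$sampling_rate, n)
  d <- rep(NA_real_, nrow(hb$hbo))
  for (ch in seq_len(nrow(hb$hbo))) {
    v <- hb$valid_mask[ch, ]
    xb <- hb$hbo[ch, base_sel & v]
    xc <- hb$hbo[ch, cond_sel & v]
    if (length(xb) < 5 || length(xc) < 2) {
      warning(sprintf("channel %d: insufficient baseline/condition samples", ch))
      next
    }
    sdv <- if (denominator == "pooled") {
      sqrt(((length(xb) - 1) * stats::var(xb) +
              (length(xc) - 1) * stats::var(xc)) /
             (length(xb) + length(xc) - 2))
    } else stats::sd(xb)
    d[ch] <- (mean(xc) - mean(xb)) / sdv
  }
  d
}

#' Pairwise channel coactivation within a condition
#'
#' Pearson correlation of HbO between every unordered channel pair, computed
#' over the condition's samples using only jointly valid samples. Returns the
#' full symmetric matrix and its vectorisation in the lexicographic pair
#' order of [fc_pair_table()].
#'
#' @param hb An `hb_series`.
#' @param design A [task_design()].
#' @param condition Condition label.
#' @param min_samples Minimum jointly valid samples per pair (default 10).
#' @return List: `fc` (8 x 8, unit diagonal), `fc_pairs` (named 28-vector).
#' @export
coactivation_matrix <- function(hb, design, condition, min_samples = 10) {
  stopifnot(inherits(hb, "hb_series"), inherits(design, "task_design"))
  n <- ncol(hb$hbo)
  sel <- condition_samples(design, condition, n)
  nch <- nrow(hb$hbo)
  fc <- diag(nch)
  for (i in seq_len(nch - 1))
    for (j in (i + 1):nch) {
      jv <- sel & hb$valid_mask[i, ] & hb$valid_mask[j, ]
      if (sum(jv) < min_samples) {
        fc[i, j] <- fc[j, i] <- NA_real_
        next
      }
      xi <- hb$hbo[i, jv]; xj <- hb$hbo[j, jv]
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
        warning(sprintf("constant channel in pair (%d,%d)", i, j))
        fc[i, j] <- fc[j, i] <- NA_real_
        next
      }
      fc[i, j] <- fc[j, i] <- stats::cor(xi, xj)
    }
  pt <- fc_pair_table()
  fcp <- stats::setNames(fc[cbind(pt$i, pt$j)], pt$pair)
  list(fc = fc, fc_pairs = fcp)
}

#' Region-pair averages of a coactivation matrix
#'
#' For each unordered pair of distinct regions, the mean of the four
#' inter-region channel-pair correlations (2 x 2 channels); for a region with
#' itself, the single intra-region pair correlation. Missing entries
#' propagate, with the count of contributing pairs reported.
#'
#' @param fc 8 x 8 coactivation matrix.
#' @param map Channel-to-region assignment, as from [region_map()].
#' @return Data frame `region_a`, `region_b`, `fc`, `n_pairs`.
#' @export
region_pair_fc <- function(fc, map = region_map()) {
  stopifnot(is.matrix(fc), nrow(fc) == 8, ncol(fc) == 8)
  regs <- unique(unname(map))
  out <- NULL
  for (a in seq_along(regs))
    for (b in a:length(regs)) {
      cha <- as.integer(names(map)[map == regs[a]])
      chb <- as.integer(names(map)[map == regs[b]])
      vals <- if (a == b) fc[cha[1], cha[2]]
              else as.vector(fc[cha, chb])
      out <- rbind(out, data.frame(
        region_a = regs[a], region_b = regs[b],
        fc = mean(vals, na.rm = TRUE),
        n_pairs = sum(!is.na(vals)), stringsAsFactors = FALSE))
    }
  out$fc[out$n_pairs == 0] <- NA_real_
  out
}

#' Compute all subject-level metrics for one preprocessed recording
#'
#' GLM activation betas (HbO regressed on the HRF-convolved condition
#' regressors; when the data were band-pass filtered the condition regressors
#' are filtered identically, so betas are unbiased under zero-phase
#' filtering), prestimulus-baseline Cohen d, and per-condition pairwise
#' coactivation with region averages.
#'
#' @param hb An `hb_series` from [run_preprocessing()].
#' @param design The session's [task_design()].
#' @param config A [pipeline_config()].
#' @return Object of class `subject_metrics`: `beta`, `cohen_d` (channels x
#'   conditions), `fc` (list of 8 x 8 per condition), `fc_pairs` (28 x
#'   conditions), `region_fc` (per-condition data frames), identifiers.
#' @export
compute_subject_metrics <- function(hb, design, config = pipeline_config()) {
  stopifnot(inherits(hb, "hb_series"), inherits(design, "task_design"))
  X <- build_design_matrix(design, hrf = config$hrf,
                           sampling_rate = hb$sampling_rate)
  if (config$filter_design) {
    # Filter regressors exactly as the data were filtered so betas stay
    # unbiased; a filtered-constant column absorbs the transient the
    # zero-phase filter leaves from any per-channel DC offset.
    for (k in X$condition_cols)
      X$X[, k] <- apply_bandpass(X$X[, k], config$filter, hb$sampling_rate)
    if ("drift" %in% colnames(X$X))
      X$X[, "drift"] <- apply_bandpass(X$X[, "drift"], config$filter,
                                       hb$sampling_rate)
    dc <- apply_bandpass(rep(1, nrow(X$X)), config$filter, hb$sampling_rate)
    X$X <- cbind(X$X, dc_transient = dc)
  }
  glm <- fit_glm(hb, X)
  labels <- X$labels
  cohen_d <- sapply(labels, function(cn)
    block_effect_size(hb, design, cn, config$baseline_window_s,
                      config$d_denominator))
  fc <- lapply(labels, function(cn) coactivation_matrix(hb, design, cn))
  names(fc) <- labels
  fcp <- sapply(fc, `[[`, "fc_pairs")
  structure(list(beta = glm$beta, tval = glm$tval,
                 cohen_d = cohen_d,
                 fc = lapply(fc, `[[`, "fc"),
                 fc_pairs = fcp,
                 region_fc = lapply(fc, function(f) region_pair_fc(f$fc)),
                 subject_id = hb$subject_id, visit = hb$visit),
            class = "subject_metrics")
}

#' @export
print.subject_metrics <- function(x, ...) {
  cat(sprintf("subject_metrics: subject %s, visit %s\n", x$subject_id, x$visit))
  cat("  GLM betas (uM):\n")
  print(round(x$beta, 4))
  invisible(x)
}
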