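# Shared fixtures: a shortened session protocol and small builders so most
# tests run on a few thousand samples.

short_protocol <- function(cycles = 2, vr_duration_s = 40) {
  make_protocol(cycles = cycles, vr_duration_s = vr_duration_s,
                lead_in_s = 20, inter_rest_s = 30, inter_vr_s = 20,
                tail_s = 10)
}

quiet_truth <- function(design = short_protocol(), beta_val = 0.3,
                        shared = FALSE) {
  conds <- condition_labels(design)
  beta <- matrix(beta_val, 8, length(conds),
                 dimnames = list(NULL, conds))
  neural_truth(beta,
               shared_components = if (shared)
                 list(list(channels = c(4, 7), weight = 0.3),
                      list(channels = c(3, 8), weight = 0.25))
               else list())
}

# hb_series built directly from a channels x time matrix (bypasses optics)
make_hb <- function(hbo, sampling_rate = 10, hbr = -0.25 * hbo,
                    valid = NULL) {
  structure(list(hbo = hbo, hbr = hbr,
                 valid_mask = if (is.null(valid))
                   matrix(TRUE, nrow(hbo), ncol(hbo)) else valid,
                 dpf = c("760" = 6, "850" = 5.2), pathlength = 3.5,
                 sampling_rate = sampling_rate,
                 events = data.frame(label = character(0),
                                     onset = numeric(0),
                                     duration = numeric(0)),
                 subject_age = 47, subject_id = "T", visit = "pre"),
            class = "hb_series")
}

# Brute-force Benjamini-Hochberg step-up (independent of stats::p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q[q > 1] <- 1
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force sliding-window motion scan on one trace
motion_oracle <- function(x, fs, t_motion = 0.5, t_mask = 1, sd_thresh = 5,
                          amp_thresh = 0.1) {
  n <- length(x)
  w <- round(t_motion * fs)
  m <- round(t_mask * fs)
  d <- diff(x)
  sd_ref <- sd(d)
  flag <- rep(FALSE, n)
  for (i in 1:(n - w + 1)) {
    win <- x[i:(i + w - 1)]
    dw <- d[i:(i + w - 2)]
    if ((max(win) - min(win)) > amp_thresh || sd(dw) > sd_thresh * sd_ref)
      flag[i:(i + w - 1)] <- TRUE
  }
  out <- rep(FALSE, n)
  for (i in which(flag)) out[max(1, i - m):min(n, i + m)] <- TRUE
  out
}

# Minimal raw recording with one trace substituted in
flat_recording <- function(n = 600, fs = 10, age = 47) {
  raw_recording(array(1, c(8, 2, n)), fs,
                data.frame(label = character(0), onset = numeric(0),
                           duration = numeric(0)), age)
}
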