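test_that("optical density conversion matches the -ln(I/mean) definition", {
  rec <- flat_recording(n = 200)
  od <- intensity_to_od(rec)
  expect_true(all(od$od == 0))          # constant intensity -> OD 0

  set.seed(11)
  I <- array(exp(rnorm(8 * 2 * 200, sd = 0.1)), c(8, 2, 200))
  rec <- raw_recording(I, 10, rec$events, 47)
  od <- intensity_to_od(rec)
  for (ch in c(1, 5)) for (wl in 1:2) {
    x <- I[ch, wl, ]
    oracle <- vapply(seq_along(x), function(t) -log(x[t] / mean(x)),
                     numeric(1))
    expect_lt(max(abs(od$od[ch, wl, ] - oracle)), 1e-12)
  }

  # one sample at half the record mean gives OD = ln 2 there
  I2 <- array(1, c(8, 2, 200))
  x <- rep(1, 200); x[50] <- NA
  # choose v so that v = mean(x)/2 with mean including v
  # mean = (199 + v)/200 ; v = mean/2  =>  v = 199/399
  x[50] <- 199 / 399
  I2[1, 1, ] <- x
  od2 <- intensity_to_od(raw_recording(I2, 10, rec$events, 47))
  expect_equal(od2$od[1, 1, 50], log(2), tolerance = 1e-12)
})

test_that("non-positive intensities are rejected with location", {
  I <- array(1, c(8, 2, 50))
  I[3, 2, 7] <- 0
  expect_error(raw_recording(I, 10, data.frame(label = character(0),
                                               onset = numeric(0),
                                               duration = numeric(0)), 47),
               "positive")
})

test_that("motion flagging matches a brute-force window scan incl. the 0.1 boundary", {
  fs <- 10
  n <- 400
  set.seed(21)
  base <- cumsum(rnorm(n, sd = 1e-4))

  for (step in c(0.1, 0.1 + 1e-6, 0.2)) {
    x <- base; x[200:n] <- x[200:n] + step
    rec <- flat_recording(n = n)
    rec$intensity[1, 1, ] <- exp(-x)
    od <- intensity_to_od(rec)
    mask <- detect_motion_artifacts(od, motion_params(sd_thresh = 1e9))
    oracle <- motion_oracle(od$od[1, 1, ], fs, sd_thresh = 1e9)
    expect_identical(mask[1, ], oracle)
  }
  # exactly 0.1 is below the strict-inequality threshold at the jump itself;
  # build the OD series directly so the excursion is exactly representable
  od_step <- function(step) {
    arr <- array(0, c(8, 2, n))
    arr[1, 1, 200:n] <- step
    structure(list(od = arr, motion_mask = matrix(FALSE, 8, n),
                   sampling_rate = fs), class = "od_series")
  }
  mask_eq <- detect_motion_artifacts(od_step(0.1),
                                     motion_params(sd_thresh = 1e9),
                                     sampling_rate = fs)
  expect_false(any(mask_eq[1, ]))
  mask_gt <- detect_motion_artifacts(od_step(0.1 + 1e-6),
                                     motion_params(sd_thresh = 1e9),
                                     sampling_rate = fs)
  expect_true(any(mask_gt[1, ]))
})

test_that("a 0.2 OD step is masked about +/- 1 s and a constant trace is not", {
  fs <- 10; n <- 600
  rec <- flat_recording(n = n)
  x <- rep(0, n); x[300:n] <- 0.2
  rec$intensity[1, 1, ] <- exp(-x)
  od <- intensity_to_od(rec)
  mask <- detect_motion_artifacts(od)
  flagged <- which(mask[1, ])
  expect_true(all(c(290:310) %in% flagged))     # step +/- 1 s covered
  expect_true(min(flagged) >= 300 - 10 - 5)     # window + mask margin
  expect_true(max(flagged) <= 300 + 10 + 5)
  expect_false(any(mask[2, ]))                  # constant channels untouched
})

test_that("motion mask is monotone in both thresholds", {
  fs <- 10; n <- 500
  set.seed(31)
  for (rep in 1:5) {
    rec <- flat_recording(n = n)
    x <- cumsum(rnorm(n, sd = 0.01))
    x[sample(50:450, 1) + 0:2] <- x[200] + 0.15   # one spike
    rec$intensity[1, 1, ] <- exp(-x)
    od <- intensity_to_od(rec)
    loose <- detect_motion_artifacts(od, motion_params(sd_thresh = 8,
                                                       amp_thresh = 0.2))
    tight <- detect_motion_artifacts(od, motion_params(sd_thresh = 3,
                                                       amp_thresh = 0.05))
    expect_true(all(tight[loose]))      # lowering thresholds never shrinks
  }
})

test_that("too-short motion window is rejected", {
  od <- intensity_to_od(flat_recording())
  expect_error(detect_motion_artifacts(od, motion_params(t_motion = 0.1)),
               "2 samples")
})

test_that("band-pass honours the analytic Butterworth magnitude response", {
  fp <- filter_params(); fs <- 10
  t <- seq(0, 3000, by = 1 / fs)
  core <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  # analytic two-pass oracle |H|^2 = 1 / (1 + (f/fc)^6) per pass
  gain2 <- function(f) 1 / (1 + (f / fp$high_cut)^6)

  x1 <- sin(2 * pi * 1.0 * t)
  y1 <- nirspipe:::apply_bandpass(x1, fp, fs)
  att <- sqrt(mean(y1[core]^2) / mean(x1[core]^2))
  expect_lt(att, 1e-3)                        # >= 60 dB two-pass
  expect_lt(att, sqrt(gain2(1.0)) * 10)       # consistent with the oracle

  x2 <- sin(2 * pi * 0.05 * t)
  y2 <- nirspipe:::apply_bandpass(x2, fp, fs)
  g <- sqrt(mean(y2[core]^2) / mean(x2[core]^2))
  expect_equal(g, 1, tolerance = 0.05)        # mid-passband preserved

  ydc <- nirspipe:::apply_bandpass(rep(1, length(t)), fp, fs)
  expect_lt(sqrt(mean(ydc[core]^2)), 1e-2)    # DC > 40 dB down
})

test_that("filter preserves length, carries the mask, and is idempotent in band", {
  fs <- 10
  set.seed(41)
  rec <- flat_recording(n = 4000)
  rec$intensity[1, 1, ] <- exp(-0.01 * sin(2 * pi * 0.05 * (0:3999) / fs))
  od <- intensity_to_od(rec)
  od$motion_mask[1, 5:10] <- TRUE
  f1 <- bandpass_filter(od)
  expect_equal(dim(f1$od), dim(od$od))
  expect_identical(f1$motion_mask, od$motion_mask)
  f2 <- bandpass_filter(f1)
  core <- 800:3200
  rel <- sqrt(mean((f2$od[1, 1, core] - f1$od[1, 1, core])^2) /
                mean(f1$od[1, 1, core]^2))
  expect_lt(rel, 0.01)
})

test_that("high cutoff at or above Nyquist is rejected", {
  od <- intensity_to_od(flat_recording())
  expect_error(bandpass_filter(od, filter_params(high_cut = 5)), "Nyquist")
})

test_that("DPF is monotone and continuous in age, and its cohort range is compact", {
  for (wl in c(760, 850)) {
    expect_gt(dpf_for_age(60, wl), dpf_for_age(30, wl))
    expect_lt(abs(dpf_for_age(47 + 1e-6, wl) - dpf_for_age(47, wl)), 1e-4)
  }
  # cohort ages ~ mean 46.8, SD 11.86 -> take +/- 2 SD clipped to adults
  ages <- seq(23, 71, by = 0.5)
  vals <- c(dpf_for_age(ages, 760), dpf_for_age(ages, 850))
  expect_true(all(vals > 4.5 & vals < 8))
  expect_error(dpf_for_age(47, 800), "wavelength")
  expect_error(dpf_for_age(10, 760), "age")
})

test_that("Beer-Lambert inversion is exact on forward-synthesized OD", {
  set.seed(51)
  n <- 300; L <- 3.5; age <- 52
  E <- extinction_default()
  dpf <- c(dpf_for_age(age, 760), dpf_for_age(age, 850))
  hbo <- matrix(rnorm(8 * n, sd = 0.5), 8, n)
  hbr <- matrix(rnorm(8 * n, sd = 0.2), 8, n)
  od_arr <- array(NA_real_, c(8, 2, n))
  for (wl in 1:2)
    od_arr[, wl, ] <- (E[wl, "HbO"] * hbo + E[wl, "HbR"] * hbr) * 1e-3 *
      L * dpf[wl]
  od <- structure(list(od = od_arr, motion_mask = matrix(FALSE, 8, n),
                       sampling_rate = 10,
                       events = data.frame(), subject_age = age,
                       subject_id = "x", visit = "pre"),
                  class = "od_series")
  hb <- od_to_hemoglobin(od, age = age, pathlength = L, extinction = E)
  expect_lt(max(abs(hb$hbo - hbo)), 1e-9)
  expect_lt(max(abs(hb$hbr - hbr)), 1e-9)

  # zero OD -> zero concentrations
  od$od[] <- 0
  hb0 <- od_to_hemoglobin(od, age = age, pathlength = L, extinction = E)
  expect_true(all(hb0$hbo == 0) && all(hb0$hbr == 0))

  # doubling the pathlength (equivalently DPF product) halves concentrations
  hb2 <- od_to_hemoglobin(structure(modifyList(unclass(od), list(od = od_arr)),
                                    class = "od_series"),
                          age = age, pathlength = 2 * L, extinction = E)
  expect_equal(hb2$hbo, hbo / 2, tolerance = 1e-9)

  expect_error(od_to_hemoglobin(od, extinction = matrix(1, 2, 2)),
               "singular")
})

test_that("preprocessing QC flags heavily trimmed recordings and passes clean ones", {
  d <- short_protocol()
  tr <- quiet_truth(d)
  rec <- simulate_subject(d, tr, noise_free(), age = 47, seed = 5)
  pp <- run_preprocessing(rec)
  expect_true(pp$qc$valid)
  expect_equal(pp$qc$masked_fraction, 0)

  rec$excluded_spans <- data.frame(start = 0, end = 0.6 * d$total_duration)
  pp2 <- run_preprocessing(rec)
  expect_false(pp2$qc$valid)
  expect_gt(pp2$qc$masked_fraction, 0.5)
})
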