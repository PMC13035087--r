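test_that("design-matrix columns equal brute-force boxcar-HRF convolution", {
  d <- task_design(data.frame(label = "a", onset = c(10, 60),
                              duration = 5), 10, 100)
  X <- build_design_matrix(d, nuisance = character(0))
  n <- 1000
  hp <- hrf_params()
  h <- canonical_hrf(seq(0, hp$duration, by = 0.1), hp)
  box <- as.numeric(nirspipe:::condition_samples(d, "a", n))
  oracle <- vapply(seq_len(n), function(t) {
    j <- seq_len(min(t, length(h)))
    sum(h[j] * box[t - j + 1])
  }, numeric(1))
  oracle <- oracle / max(abs(oracle))
  expect_lt(max(abs(X$X[, "a"] - oracle)), 1e-10)
})

test_that("HRF-convolved regressor peaks after onset and is linear in blocks", {
  d1 <- task_design(data.frame(label = "a", onset = 10, duration = 5),
                    10, 200)
  X1 <- build_design_matrix(d1, nuisance = character(0))
  tpk <- (which.max(X1$X[, "a"]) - 1) / 10
  expect_gt(tpk, 10 + 3)      # peak well after onset,
  expect_lt(tpk, 10 + 12)     # roughly an HRF delay later

  d2 <- task_design(data.frame(label = "a", onset = 120, duration = 5),
                    10, 200)
  X2 <- build_design_matrix(d2, nuisance = character(0))
  dd <- task_design(data.frame(label = "a", onset = c(10, 120),
                               duration = 5), 10, 200)
  Xd <- build_design_matrix(dd, nuisance = character(0))
  # far-apart blocks: column is the sum of the shifted single-block columns
  sum12 <- X1$X[, "a"] + X2$X[, "a"]
  expect_lt(max(abs(Xd$X[, "a"] - sum12 / max(abs(sum12)))), 1e-10)

  expect_error(build_design_matrix(
    task_design(data.frame(label = character(0), onset = numeric(0),
                           duration = numeric(0)), 10, 10)), "empty")
})

test_that("GLM recovers exact betas and matches the normal-equation oracle", {
  d <- task_design(data.frame(label = "a", onset = c(10, 40, 70),
                              duration = 5), 10, 100)
  X <- build_design_matrix(d)
  n <- nrow(X$X)

  hbo <- matrix(0, 8, n)
  hbo[1, ] <- 2.0 * X$X[, "a"] + 0.7          # beta 2 + intercept
  hbo[2, ] <- 5 * (seq_len(n) / n - 0.5)      # pure drift
  fit <- fit_glm(make_hb(hbo), X)
  expect_equal(unname(fit$beta[1, "a"]), 2.0, tolerance = 1e-9)
  expect_equal(unname(fit$beta[2, "a"]), 0.0, tolerance = 1e-9)

  set.seed(61)
  hbo <- matrix(rnorm(8 * n), 8, n)
  fit <- fit_glm(make_hb(hbo), X)
  for (ch in 1:8) {
    oracle <- solve(t(X$X) %*% X$X, t(X$X) %*% hbo[ch, ])
    expect_lt(abs(fit$beta[ch, "a"] - oracle[1]), 1e-8)
  }
})

test_that("GLM masking yields NA for starved channels, not errors", {
  d <- task_design(data.frame(label = "a", onset = 10, duration = 5), 10, 60)
  X <- build_design_matrix(d)
  hbo <- matrix(rnorm(8 * 600), 8, 600)
  valid <- matrix(TRUE, 8, 600)
  valid[3, ] <- FALSE; valid[3, 1:4] <- TRUE
  expect_warning(fit <- fit_glm(make_hb(hbo, valid = valid), X),
                 "channel 3")
  expect_true(is.na(fit$beta[3, "a"]))
  expect_false(anyNA(fit$beta[-3, "a"]))
})

test_that("Cohen d matches a hand-computed oracle and its sign convention", {
  fs <- 10
  d <- task_design(data.frame(label = "a", onset = 10, duration = 5),
                   fs, 20)
  n <- 200
  set.seed(71)
  base_i <- which(nirspipe:::samples_in_span(0, 10, fs, n))
  cond_i <- which(nirspipe:::condition_samples(d, "a", n))
  hbo <- matrix(0, 8, n)
  jit <- rnorm(n, sd = 0.01)
  # centre the jitter inside each interval so the two means are exactly equal
  jit0 <- jit
  jit0[base_i] <- jit0[base_i] - mean(jit0[base_i])
  jit0[cond_i] <- jit0[cond_i] - mean(jit0[cond_i])
  hbo[1, ] <- 1 + jit0                  # equal means -> d = 0
  hbo[2, ] <- 1 + jit; hbo[2, cond_i] <- hbo[2, cond_i] + 0.5
  dd <- block_effect_size(make_hb(hbo), d, "a", baseline_window_s = 10)
  expect_equal(dd[1], 0, tolerance = 1e-9)

  xb <- hbo[2, base_i]; xc <- hbo[2, cond_i]
  pooled <- sqrt(((length(xb) - 1) * var(xb) + (length(xc) - 1) * var(xc)) /
                   (length(xb) + length(xc) - 2))
  expect_equal(dd[2], (mean(xc) - mean(xb)) / pooled, tolerance = 1e-9)
  expect_gt(dd[2], 0)                   # HbO increase -> positive d

  db <- block_effect_size(make_hb(hbo), d, "a", denominator = "baseline")
  expect_equal(db[2], (mean(xc) - mean(xb)) / sd(xb), tolerance = 1e-9)
})

test_that("Cohen d and GLM beta agree in sign on noiseless activation", {
  d <- short_protocol()
  tr <- quiet_truth(d, beta_val = 0.4)
  cfg <- pipeline_config()
  rec <- simulate_subject(d, tr, noise_free(), age = 47, seed = 3)
  pp <- run_preprocessing(rec, cfg)
  sm <- compute_subject_metrics(pp$hb, d, cfg)
  expect_true(all(sign(sm$beta) == sign(sm$cohen_d)))
})

test_that("coactivation matrix has exact structure and matches pair indexing", {
  set.seed(81)
  n <- 400
  d <- task_design(data.frame(label = "vr", onset = 0, duration = 40),
                   10, 40)
  hbo <- matrix(rnorm(8 * n), 8, n)
  hbo[2, ] <- hbo[1, ]                   # duplicate channel
  hbo[3, ] <- -hbo[1, ]                  # negation
  fc <- coactivation_matrix(make_hb(hbo), d, "vr")
  expect_equal(fc$fc[1, 2], 1)
  expect_equal(fc$fc[1, 3], -1)
  expect_true(isSymmetric(fc$fc))
  expect_true(all(diag(fc$fc) == 1))
  expect_true(all(abs(fc$fc) <= 1 + 1e-12))
  pt <- fc_pair_table()
  expect_identical(unname(fc$fc_pairs),
                   unname(fc$fc[cbind(pt$i, pt$j)]))

  hbo[4, ] <- 2                          # constant channel
  expect_warning(fc2 <- coactivation_matrix(make_hb(hbo), d, "vr"),
                 "constant")
  expect_true(all(is.na(fc2$fc[4, -4])))
})

test_that("pair enumeration reproduces the montage's printed region labels", {
  pt <- fc_pair_table()
  lab <- function(k) unlist(pt[pt$pair == k, c("region_i", "region_j")],
                            use.names = FALSE)
  expect_equal(unlist(pt[pt$pair == "FC3", c("i", "j")], use.names = FALSE),
               c(1L, 4L))
  expect_setequal(lab("FC3"), c("right-lateral", "right-medial"))
  expect_setequal(lab("FC4"), c("right-lateral", "left-medial"))
  expect_setequal(lab("FC18"), c("right-medial", "left-lateral"))
  expect_setequal(lab("FC21"), c("right-medial", "left-lateral"))
  expect_equal(lab("FC23"), c("left-medial", "left-medial"))
  rm <- region_map()
  expect_equal(unname(rm["4"]), "right-medial")
  expect_equal(unname(rm["8"]), "left-lateral")
  expect_true(all(table(rm) == 2))
})

test_that("region averages equal by-hand means and respect within-region symmetry", {
  m <- diag(8)
  m[upper.tri(m)] <- seq(0.1, 0.1 + 0.01 * 27, by = 0.01)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  rf <- region_pair_fc(m)
  # right-lateral (1,2) x right-medial (3,4): mean of m[1,3], m[1,4], m[2,3], m[2,4]
  got <- rf$fc[rf$region_a == "right-lateral" & rf$region_b == "right-medial"]
  expect_equal(got, mean(c(m[1, 3], m[1, 4], m[2, 3], m[2, 4])))
  within <- rf$fc[rf$region_a == "left-medial" & rf$region_b == "left-medial"]
  expect_equal(within, m[5, 6])

  m2 <- matrix(0.5, 8, 8); diag(m2) <- 1
  expect_true(all(region_pair_fc(m2)$fc == 0.5))

  # permuting the two channels of a region leaves averages unchanged
  perm <- c(2, 1, 3, 4, 5, 6, 8, 7)
  expect_equal(region_pair_fc(m[perm, perm])$fc, rf$fc)
})

test_that("planted shared components produce higher coactivation than unshared pairs", {
  d <- short_protocol(vr_duration_s = 120)
  cfg <- pipeline_config()
  shared_pairs <- c("FC21", "FC18")      # (4,7) and (3,8)
  pt <- fc_pair_table()
  hits <- vapply(1:12, function(s) {
    tr <- quiet_truth(d, beta_val = 0.2, shared = TRUE)
    rec <- simulate_subject(d, tr, noise_spec(artifact_rate = 0),
                            age = 47, seed = 3000 + s)
    pp <- run_preprocessing(rec, cfg)
    fc <- coactivation_matrix(pp$hb, d, "distraction")
    shared <- mean(fc$fc_pairs[shared_pairs])
    unshared <- mean(fc$fc_pairs[setdiff(pt$pair, shared_pairs)])
    shared > unshared
  }, logical(1))
  expect_true(all(hits))
})
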