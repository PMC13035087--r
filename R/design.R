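#' Canonical double-gamma haemodynamic response function
#'
#' Positive gamma density peaking near `peak_delay` minus a scaled undershoot
#' gamma peaking near `undershoot_delay`, sampled at `t`; normalised so the
#' kernel peak is 1.
#'
#' @param t Time grid in seconds (t >= 0).
#' @param params [hrf_params()].
#' @return Numeric vector, the sampled kernel.
#' @export
canonical_hrf <- function(t, params = hrf_params()) {
  stopifnot(inherits(params, "hrf_params"))
  h <- stats::dgamma(t, shape = params$peak_delay, rate = 1) -
    params$undershoot_ratio *
      stats::dgamma(t, shape = params$undershoot_delay, rate = 1)
  h / max(h)
}

# Full discrete convolution of x with kernel h, truncated to length(x).
conv_trunc <- function(x, h) {
  m <- length(h)
  n <- length(x)
  xp <- c(rep(0, m - 1), x)
  y <- stats::filter(xp, h, method = "convolution", sides = 1)
  as.numeric(y[m:(m + n - 1)])
}

#' Build the GLM design matrix for a task design
#'
#' One column per condition label: the condition's boxcar (1 inside
#' `[onset, onset + duration)`) convolved with the canonical double-gamma HRF
#' and peak-normalised so betas keep the signal's units. Nuisance columns are
#' an intercept and a linear drift by default.
#'
#' @param design A [task_design()].
#' @param hrf [hrf_params()].
#' @param sampling_rate Hz; defaults to the design's rate.
#' @param nuisance Character subset of `c("intercept", "drift")`.
#' @return List of class `design_matrix`: `X` (time x k), `condition_cols`
#'   (indices of condition columns), `labels`.
#' @export
build_design_matrix <- function(design, hrf = hrf_params(),
                                sampling_rate = design$sampling_rate,
                                nuisance = c("intercept", "drift")) {
  stopifnot(inherits(design, "task_design"))
  if (!nrow(design$blocks)) stop("empty task design", call. = FALSE)
  n <- round(design$total_duration * sampling_rate)
  tk <- seq(0, hrf$duration, by = 1 / sampling_rate)
  h <- canonical_hrf(tk, hrf)
  labels <- condition_labels(design)
  Xc <- sapply(labels, function(cn) {
    box <- as.numeric(condition_samples(design, cn, n))
    col <- conv_trunc(box, h)
    m <- max(abs(col))
    if (m > 0) col / m else col
  })
  Xn <- NULL
  nn <- character(0)
  if ("intercept" %in% nuisance) {
    Xn <- cbind(Xn, rep(1, n))
    nn <- c(nn, "intercept")
  }
  if ("drift" %in% nuisance) {
    Xn <- cbind(Xn, seq_len(n) / n - 0.5)
    nn <- c(nn, "drift")
  }
  X <- cbind(Xc, Xn)
  colnames(X) <- c(labels, nn)
  structure(list(X = X, condition_cols = seq_along(labels), labels = labels,
                 sampling_rate = sampling_rate),
            class = "design_matrix")
}

#' Fit the per-channel GLM
#'
#' Ordinary least squares of each channel's HbO trace on the design matrix,
#' restricted to samples where the channel's validity mask is `TRUE`.
#' Channels with too few valid samples, or a rank-deficient design after
#' masking, yield `NA` betas with a warning rather than an error.
#'
#' @param hb An `hb_series`.
#' @param X A `design_matrix` from [build_design_matrix()].
#' @return List: `beta` (channels x conditions, micromolar), `tval`
#'   (descriptive per-regressor t), `sigma2` (residual variance per channel).
#' @export
fit_glm <- function(hb, X) {
  stopifnot(inherits(hb, "hb_series"), inherits(X, "design_matrix"))
  nch <- nrow(hb$hbo)
  k <- ncol(X$X)
  beta <- matrix(NA_real_, nch, length(X$condition_cols),
                 dimnames = list(NULL, X$labels))
  tval <- matrix(NA_real_, nch, length(X$condition_cols),
                 dimnames = list(NULL, X$labels))
  sigma2 <- rep(NA_real_, nch)
  for (ch in seq_len(nch)) {
    v <- hb$valid_mask[ch, ]
    if (sum(v) < k + 2) {
      warning(sprintf("channel %d: too few valid samples for GLM", ch))
      next
    }
    Xv <- X$X[v, , drop = FALSE]
    qrX <- qr(Xv)
    if (qrX$rank < k) {
      warning(sprintf("channel %d: rank-deficient design after masking", ch))
      next
    }
    y <- hb$hbo[ch, v]
    fit <- stats::lm.fit(Xv, y)
    co <- fit$coefficients
    df <- sum(v) - k
    s2 <- sum(fit$residuals^2) / df
    XtXinv <- chol2inv(qr.R(qrX))
    se <- sqrt(s2 * diag(XtXinv))
    beta[ch, ] <- co[X$condition_cols]
    tval[ch, ] <- (co / se)[X$condition_cols]
    sigma2[ch] <- s2
  }
  list(beta = beta, tval = tval, sigma2 = sigma2)
}
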