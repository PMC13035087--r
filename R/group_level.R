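#' Paired pre/post change test
#'
#' Paired t-test on post - pre differences with pairwise deletion of
#' incomplete subjects. Reports the mean difference (MD), t, two-sided p
#' (df = n - 1), the paired effect size d = MD / SD(diff), and n.
#'
#' @param pre,post Numeric vectors aligned by subject.
#' @return List `MD`, `t`, `p`, `d`, `n` (all `NA` when fewer than 2 complete
#'   pairs, with a warning).
#' @export
paired_change_test <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  ok <- is.finite(pre) & is.finite(post)
  d <- post[ok] - pre[ok]
  n <- length(d)
  if (n < 2) {
    warning("fewer than 2 complete pairs; paired test not computed")
    return(list(MD = NA_real_, t = NA_real_, p = NA_real_, d = NA_real_,
                n = n))
  }
  MD <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    tt <- if (MD == 0) 0 else Inf * sign(MD)
    p <- if (MD == 0) 1 else 0
  } else {
    tt <- MD / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(tt), df = n - 1)
  }
  list(MD = MD, t = tt, p = p,
       d = if (sdd == 0) ifelse(MD == 0, 0, Inf * sign(MD)) else MD / sdd,
       n = n)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity, computed within one
#' correction family (channels, coactivation pairs and behavioural
#' instruments are corrected separately).
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed, passed
#'   through).
#' @param family Optional family label, recorded as an attribute.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
fdr_adjust <- function(p, family = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  if (!is.null(family)) attr(q, "family") <- family
  q
}

#' Brain-behaviour correlation on change scores
#'
#' Pearson correlation between per-subject neural change and behavioural
#' change, with the two-sided p from `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param neural_change,behavioral_change Numeric vectors aligned by subject.
#' @return List `r`, `p`, `n`.
#' @export
brain_behavior_correlation <- function(neural_change, behavioral_change) {
  stopifnot(length(neural_change) == length(behavioral_change))
  ok <- is.finite(neural_change) & is.finite(behavioral_change)
  x <- neural_change[ok]; y <- behavioral_change[ok]
  n <- length(x)
  if (n < 3) {
    warning("fewer than 3 complete pairs; correlation not computed")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
fisher_z_inv <- function(z) tanh(z)

#' Group-level pre/post analysis of a cohort's subject metrics
#'
#' For every channel x condition the paired change in GLM beta and in Cohen
#' d, and for every coactivation pair x condition the paired change in
#' correlation (Fisher z-transformed before the t-test when configured,
#' back-transformed MD reported on the r scale). Benjamini-Hochberg
#' correction is applied within each family: the 8 channels of one condition
#' and metric form a family, as do the 28 pairs of one condition.
#'
#' @param metrics List per subject, each with elements `pre` and `post`
#'   (objects from [compute_subject_metrics()]); a missing visit is `NULL`.
#' @param config A [pipeline_config()].
#' @return A data frame of class `group_result`: `metric` ("beta",
#'   "cohen_d", "fc"), `condition`, `id` (channel number or pair label),
#'   `MD`, `t`, `p`, `q`, `d`, `n`.
#' @export
group_change_analysis <- function(metrics, config = pipeline_config()) {
  some <- Filter(Negate(is.null), lapply(metrics, `[[`, "pre"))
  if (!length(some)) stop("no pre-visit metrics in cohort", call. = FALSE)
  conditions <- colnames(some[[1]]$beta)
  pull <- function(visit, field, cond, idx) {
    vapply(metrics, function(m) {
      sm <- m[[visit]]
      if (is.null(sm)) return(NA_real_)
      sm[[field]][idx, cond]
    }, numeric(1))
  }
  rows <- list()
  for (cond in conditions) {
    for (field in c("beta", "cohen_d")) {
      res <- lapply(1:8, function(ch)
        paired_change_test(pull("pre", field, cond, ch),
                           pull("post", field, cond, ch)))
      q <- fdr_adjust(vapply(res, `[[`, 1, "p"),
                      family = paste(field, cond, sep = ":"))
      for (ch in 1:8)
        rows[[length(rows) + 1]] <- data.frame(
          metric = field, condition = cond, id = as.character(ch),
          MD = res[[ch]]$MD, t = res[[ch]]$t, p = res[[ch]]$p, q = q[ch],
          d = res[[ch]]$d, n = res[[ch]]$n, stringsAsFactors = FALSE)
    }
    pt <- fc_pair_table()
    res <- lapply(seq_len(nrow(pt)), function(k) {
      pre <- pull("pre", "fc_pairs", cond, k)
      post <- pull("post", "fc_pairs", cond, k)
      if (config$fisher_z) {
        out <- paired_change_test(fisher_z(pre), fisher_z(post))
        # report the mean difference on the correlation scale
        ok <- is.finite(pre) & is.finite(post)
        out$MD <- mean(post[ok]) - mean(pre[ok])
        out
      } else paired_change_test(pre, post)
    })
    q <- fdr_adjust(vapply(res, `[[`, 1, "p"),
                    family = paste("fc", cond, sep = ":"))
    for (k in seq_len(nrow(pt)))
      rows[[length(rows) + 1]] <- data.frame(
        metric = "fc", condition = cond, id = pt$pair[k],
        MD = res[[k]]$MD, t = res[[k]]$t, p = res[[k]]$p, q = q[k],
        d = res[[k]]$d, n = res[[k]]$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("group_result", "data.frame")
  out
}

#' Pre/post analysis of the behavioural table
#'
#' Paired change test per instrument, corrected as one family.
#'
#' @param behavioral Data frame `subject`, `visit` ("pre"/"post"),
#'   `instrument`, `score`.
#' @return A `group_result` data frame with `metric = "behavioral"`.
#' @export
behavioral_change_analysis <- function(behavioral) {
  stopifnot(all(c("subject", "visit", "instrument", "score") %in%
                  names(behavioral)))
  instruments <- unique(behavioral$instrument)
  subjects <- unique(behavioral$subject)
  res <- lapply(instruments, function(ins) {
    b <- behavioral[behavioral$instrument == ins, ]
    pre <- b$score[match(paste(subjects, "pre"), paste(b$subject, b$visit))]
    post <- b$score[match(paste(subjects, "post"), paste(b$subject, b$visit))]
    paired_change_test(pre, post)
  })
  q <- fdr_adjust(vapply(res, `[[`, 1, "p"), family = "behavioral")
  out <- do.call(rbind, lapply(seq_along(instruments), function(i)
    data.frame(metric = "behavioral", condition = NA_character_,
               id = instruments[i], MD = res[[i]]$MD, t = res[[i]]$t,
               p = res[[i]]$p, q = q[i], d = res[[i]]$d, n = res[[i]]$n,
               stringsAsFactors = FALSE)))
  class(out) <- c("group_result", "data.frame")
  out
}

#' @export
print.group_result <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$report <- sprintf("(MD=%+.2f, P=%.3g, d=%.2f)", df$MD, df$p, df$d)
  print.data.frame(df[, c("metric", "condition", "id", "report", "q", "n")],
                   digits = digits, row.names = FALSE)
  invisible(x)
}

#' Sensitivity analyses for cohort heterogeneity
#'
#' (a) Spearman rank correlations between time since injury and each metric's
#' baseline value and change score, Benjamini-Hochberg corrected as one
#' family; (b) leave-one-out re-estimation of the paired change test per
#' metric, reporting the range of t across folds; (c) ANCOVA: OLS of the post
#' value on the baseline value, time since injury, and injury type
#' (categorical, collapsed), reporting covariate coefficients and p-values.
#' Constant covariates are dropped with a warning.
#'
#' @param pre,post Named list of numeric per-subject vectors (one element per
#'   metric), aligned by subject.
#' @param time_since_injury Numeric per-subject covariate (days).
#' @param injury_type Factor-like per-subject covariate.
#' @return List of class `sensitivity_report` with elements `spearman`,
#'   `leave_one_out`, `ancova` (data frames).
#' @export
sensitivity_suite <- function(pre, post, time_since_injury, injury_type) {
  stopifnot(is.list(pre), is.list(post),
            identical(names(pre), names(post)))
  metrics <- names(pre)
  sp <- do.call(rbind, lapply(metrics, function(m) {
    base <- pre[[m]]; chg <- post[[m]] - pre[[m]]
    r1 <- stats::cor.test(time_since_injury, base, method = "spearman",
                          exact = FALSE)
    r2 <- stats::cor.test(time_since_injury, chg, method = "spearman",
                          exact = FALSE)
    data.frame(metric = m, target = c("baseline", "change"),
               rho = c(unname(r1$estimate), unname(r2$estimate)),
               p = c(r1$p.value, r2$p.value), stringsAsFactors = FALSE)
  }))
  sp$q <- fdr_adjust(sp$p, family = "sensitivity-spearman")
  loo <- do.call(rbind, lapply(metrics, function(m) {
    n <- length(pre[[m]])
    ts <- vapply(seq_len(n), function(i)
      paired_change_test(pre[[m]][-i], post[[m]][-i])$t, numeric(1))
    if (!any(is.finite(ts)))
      data.frame(metric = m, t_min = NA_real_, t_max = NA_real_,
                 fold_min = NA_integer_, fold_max = NA_integer_,
                 stringsAsFactors = FALSE)
    else
      data.frame(metric = m, t_min = min(ts, na.rm = TRUE),
                 t_max = max(ts, na.rm = TRUE),
                 fold_min = which.min(ts), fold_max = which.max(ts),
                 stringsAsFactors = FALSE)
  }))
  anc <- do.call(rbind, lapply(metrics, function(m) {
    dat <- data.frame(post = post[[m]], baseline = pre[[m]],
                      tsi = time_since_injury,
                      type = factor(injury_type))
    drop_type <- nlevels(droplevels(dat$type)) < 2
    drop_tsi <- stats::sd(dat$tsi) == 0
    if (drop_type) warning("injury_type constant; dropped from ANCOVA")
    if (drop_tsi) warning("time_since_injury constant; dropped from ANCOVA")
    form <- stats::as.formula(paste(
      "post ~ baseline",
      if (!drop_tsi) "+ tsi" else "",
      if (!drop_type) "+ type" else ""))
    fit <- stats::lm(form, data = dat)
    cf <- summary(fit)$coefficients
    data.frame(metric = m, term = rownames(cf), estimate = cf[, 1],
               p = cf[, 4], row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(spearman = sp, leave_one_out = loo, ancova = anc),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity analyses\n Spearman (time since injury):\n")
  print(x$spearman, row.names = FALSE, digits = 3)
  cat(" Leave-one-out t ranges:\n")
  print(x$leave_one_out, row.names = FALSE, digits = 3)
  cat(" ANCOVA covariates:\n")
  print(x$ancova, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Feasibility accounting of scheduled recordings
#'
#' @param status Character vector with one entry per scheduled recording,
#'   each `"valid"`, `"missing"` or `"invalid"`; names (if any) must be
#'   unique recording ids.
#' @return Object of class `qc_ledger`: `possible`, `missing`, `invalid`,
#'   `valid`, `valid_pct` (percent, rounded half-up to integer).
#' @export
feasibility_report <- function(status) {
  if (!is.null(names(status)) && anyDuplicated(names(status)))
    stop("duplicate recording ids", call. = FALSE)
  if (!all(status %in% c("valid", "missing", "invalid")))
    stop("status must be 'valid', 'missing' or 'invalid'", call. = FALSE)
  possible <- length(status)
  missing <- sum(status == "missing")
  invalid <- sum(status == "invalid")
  valid <- possible - missing - invalid
  structure(list(possible = possible, missing = missing, invalid = invalid,
                 valid = valid,
                 valid_pct = floor(100 * valid / possible + 0.5)),
            class = "qc_ledger")
}

#' @export
print.qc_ledger <- function(x, ...) {
  cat(sprintf("Of %d possible recordings, %d (%d%%) valid (%d missing, %d invalid)\n",
              x$possible, x$valid, x$valid_pct, x$missing, x$invalid))
  invisible(x)
}
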