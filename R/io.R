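#' Write a raw recording as a plain-text bundle
#'
#' Three files in `dir`: `signals.tsv` (`time_s`, `channel`,
#' `wavelength_nm`, `intensity`; 15 significant digits), `events.tsv`
#' (`label`, `onset_s`, `duration_s`) and `metadata.yaml` (subject id, visit,
#' age, sampling rate, excluded spans).
#'
#' @param rec A [raw_recording()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "raw_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(rec$intensity)[3]
  t_s <- (seq_len(n) - 1) / rec$sampling_rate
  wl <- c(760, 850)
  sig <- do.call(rbind, lapply(1:dim(rec$intensity)[1], function(ch)
    do.call(rbind, lapply(1:2, function(w)
      data.frame(time_s = t_s, channel = ch, wavelength_nm = wl[w],
                 intensity = rec$intensity[ch, w, ])))))
  sig$time_s <- sprintf("%.6f", sig$time_s)
  sig$intensity <- sprintf("%.15g", sig$intensity)
  utils::write.table(sig, file.path(dir, "signals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ev <- data.frame(label = rec$events$label, onset_s = rec$events$onset,
                   duration_s = rec$events$duration)
  utils::write.table(ev, file.path(dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(subject_id = rec$subject_id, visit = rec$visit,
               age = rec$subject_age, sampling_rate_hz = rec$sampling_rate,
               excluded_spans = if (nrow(rec$excluded_spans))
                 lapply(seq_len(nrow(rec$excluded_spans)), function(i)
                   list(start = rec$excluded_spans$start[i],
                        end = rec$excluded_spans$end[i]))
               else list())
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

read_tsv_checked <- function(path, cols) {
  if (!file.exists(path))
    stop("missing file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", basename(path),
                 paste(miss, collapse = ", ")), call. = FALSE)
  df
}

#' Read a raw recording from a plain-text bundle
#'
#' Validates the schema written by [write_recording()]: channels 1-8,
#' wavelengths 760/850, time strictly increasing per trace, events inside
#' the record.
#'
#' @param dir Bundle directory.
#' @return A [raw_recording()].
#' @export
read_recording <- function(dir) {
  sig <- read_tsv_checked(file.path(dir, "signals.tsv"),
                          c("time_s", "channel", "wavelength_nm",
                            "intensity"))
  ev <- read_tsv_checked(file.path(dir, "events.tsv"),
                         c("label", "onset_s", "duration_s"))
  meta <- yaml::read_yaml(file.path(dir, "metadata.yaml"))
  if (!all(sig$channel %in% 1:8))
    stop("signals.tsv: channel outside 1..8", call. = FALSE)
  if (!all(sig$wavelength_nm %in% c(760, 850)))
    stop("signals.tsv: wavelength must be 760 or 850", call. = FALSE)
  fs <- meta$sampling_rate_hz
  n <- length(unique(sig$time_s))
  chs <- sort(unique(sig$channel))
  intensity <- array(NA_real_, c(length(chs), 2, n))
  for (ci in seq_along(chs))
    for (w in 1:2) {
      tr <- sig[sig$channel == chs[ci] &
                  sig$wavelength_nm == c(760, 850)[w], ]
      if (nrow(tr) != n)
        stop(sprintf("signals.tsv: channel %d wavelength %d has %d samples, expected %d",
                     chs[ci], c(760, 850)[w], nrow(tr), n), call. = FALSE)
      if (any(diff(tr$time_s) <= 0))
        stop("signals.tsv: time not strictly increasing", call. = FALSE)
      intensity[ci, w, ] <- tr$intensity
    }
  spans <- meta$excluded_spans
  excluded <- if (length(spans))
    data.frame(start = vapply(spans, `[[`, 0, "start"),
               end = vapply(spans, `[[`, 0, "end"))
  else data.frame(start = numeric(0), end = numeric(0))
  raw_recording(intensity, sampling_rate = fs,
                events = data.frame(label = ev$label, onset = ev$onset_s,
                                    duration = ev$duration_s),
                subject_age = meta$age, excluded_spans = excluded,
                subject_id = meta$subject_id %||% NA_character_,
                visit = meta$visit %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write subject metrics as a tidy long table
#'
#' Columns: `subject`, `visit`, `metric` ("beta", "cohen_d", "fc"),
#' `condition`, `id` (channel or pair label), `value`.
#'
#' @param sm A `subject_metrics` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_subject_metrics <- function(sm, path) {
  stopifnot(inherits(sm, "subject_metrics"))
  df <- subject_metrics_table(sm)
  df$value <- sprintf("%.15g", df$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subject_metrics
#' @export
subject_metrics_table <- function(sm) {
  conds <- colnames(sm$beta)
  rows <- list()
  for (cond in conds) {
    for (ch in 1:8) {
      rows[[length(rows) + 1]] <- data.frame(
        subject = sm$subject_id, visit = sm$visit, metric = "beta",
        condition = cond, id = as.character(ch),
        value = sm$beta[ch, cond], stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        subject = sm$subject_id, visit = sm$visit, metric = "cohen_d",
        condition = cond, id = as.character(ch),
        value = sm$cohen_d[ch, cond], stringsAsFactors = FALSE)
    }
    for (k in seq_len(nrow(fc_pair_table())))
      rows[[length(rows) + 1]] <- data.frame(
        subject = sm$subject_id, visit = sm$visit, metric = "fc",
        condition = cond, id = fc_pair_table()$pair[k],
        value = sm$fc_pairs[k, cond], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Read subject metrics written by [write_subject_metrics()]
#'
#' @param path TSV path.
#' @return A `subject_metrics` object (beta, cohen_d, fc_pairs and the fc
#'   matrices reconstructed from the pair vector).
#' @export
read_subject_metrics <- function(path) {
  df <- read_tsv_checked(path, c("subject", "visit", "metric", "condition",
                                 "id", "value"))
  conds <- unique(df$condition)
  get <- function(metric, cond, ids) {
    sub <- df[df$metric == metric & df$condition == cond, ]
    sub$value[match(ids, sub$id)]
  }
  beta <- sapply(conds, function(cn) get("beta", cn, as.character(1:8)))
  cohen_d <- sapply(conds, function(cn) get("cohen_d", cn,
                                            as.character(1:8)))
  pt <- fc_pair_table()
  fcp <- sapply(conds, function(cn) get("fc", cn, pt$pair))
  rownames(fcp) <- pt$pair
  fc <- lapply(conds, function(cn) {
    m <- diag(8)
    m[cbind(pt$i, pt$j)] <- fcp[, cn]
    m[cbind(pt$j, pt$i)] <- fcp[, cn]
    m
  })
  names(fc) <- conds
  structure(list(beta = beta, cohen_d = cohen_d, fc = fc, fc_pairs = fcp,
                 region_fc = lapply(fc, region_pair_fc),
                 subject_id = df$subject[1], visit = df$visit[1]),
            class = "subject_metrics")
}

#' Write a synthetic cohort to disk
#'
#' One bundle directory per subject-visit (`<id>_<visit>/`), the behavioural
#' table, covariates, and a ground-truth sidecar (`truth.json`) holding the
#' planted betas, neural change scores, effect spec and seed.
#'
#' @param cohort A `cohort_dataset` from [simulate_cohort()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    write_recording(s$pre, file.path(dir, paste0(s$id, "_pre")))
    write_recording(s$post, file.path(dir, paste0(s$id, "_post")))
  }
  utils::write.table(cohort$behavioral, file.path(dir, "behavioral.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$covariates))
    utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  sidecar <- list(
    seed = truth$seed,
    pre_beta = lapply(truth$pre_beta, function(m) as.data.frame(m)),
    post_beta = lapply(truth$post_beta, function(m) as.data.frame(m)),
    neural_change = truth$neural_change,
    clip_fraction = truth$clip_fraction,
    brain_behavior = truth$effect_spec$brain_behavior,
    instruments = truth$effect_spec$instruments,
    shared_components = truth$pre_truth$shared_components)
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
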