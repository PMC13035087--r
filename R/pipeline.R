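# Polynomial rolling hash over the serialised configuration; fingerprints a
# resolved parameter set in run logs.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Analyse a paired pre/post cohort end to end
#'
#' Runs preprocessing on every recording, computes subject-level metrics for
#' the valid ones, then group-level paired inference on neural metrics and
#' behavioural instruments, brain-behaviour correlations between the
#' neural changes reaching p < .05 and every instrument's change score,
#' sensitivity analyses (when covariates are present), and the feasibility
#' ledger (one scheduled recording per subject x visit x condition). Invalid
#' recordings are excluded and counted, never silently dropped.
#'
#' @param cohort A `cohort_dataset` (from [simulate_cohort()] or assembled
#'   from [read_recording()] outputs).
#' @param config A [pipeline_config()].
#' @param verbose Log stage transitions.
#' @return Object of class `cohort_analysis`: `qc` ([feasibility_report()]
#'   ledger), `recording_status`, `metrics`, `group_neural`,
#'   `group_behavioral`, `brain_behavior`, `sensitivity`, `config`,
#'   `config_hash`, `seed`.
#' @export
analyze_cohort <- function(cohort, config = pipeline_config(),
                           verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort_dataset"),
            inherits(config, "pipeline_config"))
  design <- cohort$design
  conds <- condition_labels(design)
  say <- function(...) if (verbose) message(sprintf(...))
  metrics <- list()
  status <- character(0)
  for (s in cohort$subjects) {
    m <- list(pre = NULL, post = NULL)
    for (v in c("pre", "post")) {
      rec <- s[[v]]
      rid <- paste(s$id, v, sep = "_")
      if (is.null(rec)) {
        status[paste(rid, conds, sep = "_")] <- "missing"
        next
      }
      say("preprocessing %s", rid)
      pp <- run_preprocessing(rec, config)
      if (!pp$qc$valid) {
        warning(sprintf("%s: masked fraction %.2f exceeds QC ceiling; excluded",
                        rid, pp$qc$masked_fraction))
        status[paste(rid, conds, sep = "_")] <- "invalid"
        next
      }
      status[paste(rid, conds, sep = "_")] <- "valid"
      m[[v]] <- compute_subject_metrics(pp$hb, design, config)
    }
    metrics[[s$id]] <- m
  }
  qc <- feasibility_report(status)
  if (qc$valid == 0)
    stop("no valid recordings after QC", call. = FALSE)

  say("group-level inference")
  usable <- Filter(function(m) !is.null(m$pre) && !is.null(m$post), metrics)
  group_neural <- group_change_analysis(usable, config)
  group_behavioral <- behavioral_change_analysis(cohort$behavioral)

  say("brain-behaviour correlations")
  bb <- brain_behavior_table(usable, cohort$behavioral, group_neural)

  sens <- NULL
  if (!is.null(cohort$covariates)) {
    say("sensitivity analyses")
    subj <- names(usable)
    ins <- unique(cohort$behavioral$instrument)
    beh <- cohort$behavioral
    pre <- lapply(ins, function(i)
      beh$score[match(paste(subj, "pre", i),
                      paste(beh$subject, beh$visit, beh$instrument))])
    post <- lapply(ins, function(i)
      beh$score[match(paste(subj, "post", i),
                      paste(beh$subject, beh$visit, beh$instrument))])
    names(pre) <- names(post) <- ins
    cv <- cohort$covariates[match(subj, cohort$covariates$subject), ]
    sens <- sensitivity_suite(pre, post, cv$time_since_injury_days,
                              cv$injury_type)
  }
  structure(list(qc = qc, recording_status = status, metrics = metrics,
                 group_neural = group_neural,
                 group_behavioral = group_behavioral,
                 brain_behavior = bb, sensitivity = sens,
                 config = config, config_hash = config_hash(config),
                 seed = config$seed),
            class = "cohort_analysis")
}

#' Brain-behaviour correlation table
#'
#' For every neural change (beta or Cohen d row of the group result) with
#' p < `alpha`, the Pearson correlation between its per-subject change score
#' and each behavioural instrument's change score.
#'
#' @param metrics Named list per subject with `pre`/`post` subject metrics.
#' @param behavioral Long behavioural table.
#' @param group_neural A `group_result` from [group_change_analysis()].
#' @param alpha Selection threshold on the uncorrected p (default .05).
#' @return Data frame `metric`, `condition`, `id`, `instrument`, `r`, `p`,
#'   `n`.
#' @export
brain_behavior_table <- function(metrics, behavioral, group_neural,
                                 alpha = 0.05) {
  sel <- group_neural[group_neural$metric %in% c("beta", "cohen_d") &
                        is.finite(group_neural$p) &
                        group_neural$p < alpha, , drop = FALSE]
  if (!nrow(sel)) return(NULL)
  subj <- names(metrics)
  ins <- unique(behavioral$instrument)
  beh_change <- sapply(ins, function(i) {
    pre <- behavioral$score[match(paste(subj, "pre", i),
                                  paste(behavioral$subject,
                                        behavioral$visit,
                                        behavioral$instrument))]
    post <- behavioral$score[match(paste(subj, "post", i),
                                   paste(behavioral$subject,
                                         behavioral$visit,
                                         behavioral$instrument))]
    post - pre
  })
  rows <- list()
  for (k in seq_len(nrow(sel))) {
    ch <- as.integer(sel$id[k])
    nc <- vapply(metrics, function(m)
      m$post[[sel$metric[k]]][ch, sel$condition[k]] -
        m$pre[[sel$metric[k]]][ch, sel$condition[k]], numeric(1))
    for (i in ins) {
      r <- brain_behavior_correlation(nc, beh_change[, i])
      rows[[length(rows) + 1]] <- data.frame(
        metric = sel$metric[k], condition = sel$condition[k],
        id = sel$id[k], instrument = i, r = r$r, p = r$p, n = r$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("Cohort analysis (config ", x$config_hash, ", seed ", x$seed, ")\n",
      sep = "")
  print(x$qc)
  sig <- x$group_neural[is.finite(x$group_neural$p) &
                          x$group_neural$p < 0.05, ]
  cat(sprintf("Neural changes with p < .05: %d of %d\n", nrow(sig),
              nrow(x$group_neural)))
  if (nrow(sig))
    for (k in seq_len(nrow(sig)))
      cat(sprintf("  %s %s %s (MD=%+.3f, t=%.3f, P=%.3f, q=%.3f, d=%.2f)\n",
                  sig$metric[k], sig$condition[k], sig$id[k], sig$MD[k],
                  sig$t[k], sig$p[k], sig$q[k], sig$d[k]))
  cat("Behavioural changes:\n")
  gb <- x$group_behavioral
  for (k in seq_len(nrow(gb)))
    cat(sprintf("  %-15s (MD=%+.2f, P=%s, d=%.2f)\n", gb$id[k], gb$MD[k],
                format.pval(gb$p[k], digits = 2), gb$d[k]))
  invisible(x)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param design The session [task_design()]; default [make_protocol()].
#' @return A `cohort_dataset` (without ground truth unless `truth.json`
#'   exists).
#' @export
read_cohort <- function(dir, design = make_protocol()) {
  bundles <- list.dirs(dir, recursive = FALSE)
  ids <- unique(sub("_(pre|post)$", "", basename(bundles)))
  subjects <- lapply(ids, function(id) {
    pre_d <- file.path(dir, paste0(id, "_pre"))
    post_d <- file.path(dir, paste0(id, "_post"))
    pre <- if (dir.exists(pre_d)) read_recording(pre_d) else NULL
    post <- if (dir.exists(post_d)) read_recording(post_d) else NULL
    list(id = id, age = (pre %||% post)$subject_age, pre = pre, post = post)
  })
  behavioral <- read_tsv_checked(file.path(dir, "behavioral.tsv"),
                                 c("subject", "visit", "instrument",
                                   "score"))
  cov_path <- file.path(dir, "covariates.tsv")
  covariates <- if (file.exists(cov_path))
    read_tsv_checked(cov_path, c("subject", "time_since_injury_days",
                                 "injury_type"))
  else NULL
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path)
  else NULL
  structure(list(subjects = subjects, behavioral = behavioral,
                 covariates = covariates, truth = truth, design = design,
                 seed = NA_integer_),
            class = "cohort_dataset")
}

#' Run the file-based pipeline
#'
#' Reads a cohort directory (as written by [write_cohort()]), analyses it,
#' and writes tidy result tables plus a run log holding the resolved
#' configuration, its hash, and the seed. Reruns with the same configuration
#' and inputs produce identical outputs.
#'
#' @param input_dir Cohort directory.
#' @param output_dir Results directory (created).
#' @param config A [pipeline_config()].
#' @param design The session [task_design()].
#' @return The `cohort_analysis`, invisibly.
#' @export
run_pipeline <- function(input_dir, output_dir,
                         config = pipeline_config(),
                         design = make_protocol()) {
  cohort <- read_cohort(input_dir, design)
  res <- analyze_cohort(cohort, config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(res$metrics))
    for (v in c("pre", "post"))
      if (!is.null(res$metrics[[s]][[v]]))
        write_subject_metrics(res$metrics[[s]][[v]],
                              file.path(output_dir,
                                        sprintf("metrics_%s_%s.tsv", s, v)))
  utils::write.table(as.data.frame(res$group_neural),
                     file.path(output_dir, "group_neural.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(res$group_behavioral),
                     file.path(output_dir, "group_behavioral.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$brain_behavior))
    utils::write.table(res$brain_behavior,
                       file.path(output_dir, "brain_behavior.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$sensitivity)) {
    utils::write.table(res$sensitivity$spearman,
                       file.path(output_dir, "sensitivity_spearman.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$sensitivity$leave_one_out,
                       file.path(output_dir, "sensitivity_loo.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$sensitivity$ancova,
                       file.path(output_dir, "sensitivity_ancova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(config = unclass_deep(res$config), config_hash = res$config_hash,
         seed = res$seed, qc = unclass(res$qc),
         recording_status = as.list(res$recording_status)),
    file.path(output_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}
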