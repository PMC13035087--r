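#' Task design container
#'
#' @param blocks Data frame with columns `label`, `onset`, `duration`
#'   (seconds). Blocks must be ordered by onset and non-overlapping.
#' @param sampling_rate Sampling rate in Hz.
#' @param total_duration Record length in seconds.
#' @return An object of class `task_design`.
#' @export
task_design <- function(blocks, sampling_rate, total_duration) {
  stopifnot(is.data.frame(blocks),
            all(c("label", "onset", "duration") %in% names(blocks)),
            sampling_rate > 0, total_duration > 0)
  blocks <- blocks[order(blocks$onset), , drop = FALSE]
  rownames(blocks) <- NULL
  if (nrow(blocks)) {
    if (any(blocks$duration <= 0))
      stop("block durations must be positive", call. = FALSE)
    ends <- blocks$onset + blocks$duration
    if (any(ends > total_duration + 1e-9))
      stop("block extends past total_duration", call. = FALSE)
    if (nrow(blocks) > 1 &&
        any(blocks$onset[-1] < ends[-nrow(blocks)] - 1e-9))
      stop("blocks overlap", call. = FALSE)
  }
  structure(list(blocks = blocks, sampling_rate = sampling_rate,
                 total_duration = total_duration),
            class = "task_design")
}

#' Build the session protocol
#'
#' Assembles the within-session block design: a movement-evoked pain paradigm
#' on the noninjured side first, then the injured side, followed by the two
#' 6-minute immersive VR blocks (relaxation, then distraction — fixed order).
#' Each movement side consists of `cycles` hold-move-hold cycles: move to first
#' pain threshold (`move_s`), hold (`hold_s`), move ~5 degrees further
#' (`move_s`), hold again (`hold_s`), relax (`relax_s`). Only the hold
#' sub-blocks carry the condition label (2 holds per cycle), so the default 10
#' cycles yield 20 labelled 5-s holds per side. Rest periods separate the
#' paradigms and provide the prestimulus baselines.
#'
#' @param move_s Seconds to move into position (default 2.5).
#' @param hold_s Hold duration in seconds (default 5).
#' @param relax_s Relax duration between cycles in seconds (default 3).
#' @param cycles Number of hold-move-hold cycles per side (default 10).
#' @param vr_duration_s Duration of each VR block in seconds (default 360).
#' @param sampling_rate Sampling rate in Hz (default 10).
#' @param lead_in_s Rest before the first movement block (default 30 s).
#' @param inter_rest_s Rest between paradigms (default 120 s).
#' @param inter_vr_s Rest between the two VR blocks (default 60 s).
#' @param tail_s Rest after the final block (default 30 s).
#' @return A [task_design()] whose labelled blocks are, in order, the
#'   `"noninjured"` holds, the `"injured"` holds, one `"relaxation"` block and
#'   one `"distraction"` block.
#' @export
make_protocol <- function(move_s = 2.5, hold_s = 5, relax_s = 3, cycles = 10,
                          vr_duration_s = 360, sampling_rate = 10,
                          lead_in_s = 30, inter_rest_s = 120,
                          inter_vr_s = 60, tail_s = 30) {
  if (any(c(move_s, hold_s, relax_s, vr_duration_s) <= 0) || cycles < 1)
    stop("durations must be positive and cycles >= 1", call. = FALSE)
  if (sampling_rate <= 0)
    stop("sampling_rate must be positive", call. = FALSE)

  side_blocks <- function(label, start) {
    onsets <- numeric(0)
    t <- start
    for (k in seq_len(cycles)) {
      t <- t + move_s            # move to threshold
      onsets <- c(onsets, t); t <- t + hold_s
      t <- t + move_s            # ~5 degrees further
      onsets <- c(onsets, t); t <- t + hold_s
      t <- t + relax_s
    }
    list(blocks = data.frame(label = label, onset = onsets,
                             duration = hold_s),
         end = t)
  }

  t <- lead_in_s
  non <- side_blocks("noninjured", t)
  t <- non$end + inter_rest_s
  inj <- side_blocks("injured", t)
  t <- inj$end + inter_rest_s
  relax <- data.frame(label = "relaxation", onset = t,
                      duration = vr_duration_s)
  t <- t + vr_duration_s + inter_vr_s
  distract <- data.frame(label = "distraction", onset = t,
                         duration = vr_duration_s)
  t <- t + vr_duration_s + tail_s

  task_design(rbind(non$blocks, inj$blocks, relax, distract),
              sampling_rate = sampling_rate, total_duration = t)
}

#' @export
print.task_design <- function(x, ...) {
  conds <- unique(x$blocks$label)
  cat(sprintf("task_design: %d blocks, %d condition(s), %.0f s @ %g Hz\n",
              nrow(x$blocks), length(conds), x$total_duration,
              x$sampling_rate))
  for (cn in conds) {
    b <- x$blocks[x$blocks$label == cn, ]
    cat(sprintf("  %-12s %3d block(s), %.0f s total\n", cn, nrow(b),
                sum(b$duration)))
  }
  invisible(x)
}

#' Condition labels of a task design
#' @param design A [task_design()].
#' @return Character vector of unique condition labels, in onset order.
#' @export
condition_labels <- function(design) {
  unique(design$blocks$label)
}

# Logical selector for samples inside [onset, onset + duration), 0-based time.
samples_in_span <- function(onset, duration, sampling_rate, n) {
  t <- (seq_len(n) - 1) / sampling_rate
  t >= onset & t < onset + duration
}

# Union of a condition's block spans as a logical sample selector.
condition_samples <- function(design, condition, n) {
  b <- design$blocks[design$blocks$label == condition, , drop = FALSE]
  if (!nrow(b)) stop("unknown condition: ", condition, call. = FALSE)
  sel <- rep(FALSE, n)
  for (i in seq_len(nrow(b)))
    sel <- sel | samples_in_span(b$onset[i], b$duration[i],
                                 design$sampling_rate, n)
  sel
}
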