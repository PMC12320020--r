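# Spatiotemporal template-matching decoders: six-way block-design localizer
# identification and N-way movie-segment identification.

#' Interleave blocks into training and testing splits
#'
#' Odd-indexed blocks (1-based) become training data and even-indexed blocks
#' testing data, preserving order within each split.
#'
#' @param blocks ordered vector or list of block identifiers.
#' @param drop_last with an odd number of blocks, drop the last one with a
#'   warning (default TRUE); otherwise error.
#' @return list with `train` and `test`.
#' @export
split_blocks_interleaved <- function(blocks, drop_last = TRUE) {
  n <- length(blocks)
  if (n < 2) stop("at least 2 blocks are required")
  if (n %% 2 == 1) {
    if (!drop_last) stop("odd block count")
    warning("odd block count: dropping the last block")
    blocks <- blocks[seq_len(n - 1)]
    n <- n - 1
  }
  idx <- seq_len(n)
  list(train = blocks[idx %% 2 == 1], test = blocks[idx %% 2 == 0])
}

#' Extract a masked voxel x time block window
#'
#' Cuts the response window of one stimulus block out of a reconstructed
#' series: the first `trim_s` seconds after onset are discarded (transient
#' onset response) and the next `window_s` seconds are kept.
#'
#' @param series voxels x frames matrix (or `voxel_image`) at rate `fs`.
#' @param onset_s block onset in seconds.
#' @param trim_s seconds removed from the start of the block (default 4).
#' @param window_s window length in seconds (default 16).
#' @param mask integer or logical voxel mask (default all voxels).
#' @param fs frame rate, Hz (default 1).
#' @return masked voxels x frames matrix with `floor(window_s * fs)` columns.
#' @export
extract_block_window <- function(series, onset_s, trim_s = 4, window_s = 16,
                                 mask = NULL, fs = 1) {
  m <- if (inherits(series, "voxel_image")) series$values else as.matrix(series)
  if (!is.null(mask)) m <- m[mask, , drop = FALSE]
  i0 <- floor((onset_s + trim_s) * fs) + 1
  n <- floor(window_s * fs)
  if (i0 + n - 1 > ncol(m))
    stop("truncation error: window extends beyond the run")
  m[, i0:(i0 + n - 1), drop = FALSE]
}

#' Score a trial against spatiotemporal templates
#'
#' For each template, the spatial Pearson correlation between trial and
#' template is computed at each time point and aggregated over time:
#' `score = "mean"` averages the per-time-point correlations (default),
#' `"max"` takes their maximum, and `"flat"` correlates the flattened
#' voxel x time arrays. The template with the highest score wins; exact ties
#' are broken by template order and flagged.
#'
#' @param trial voxels x time matrix.
#' @param templates named list of voxels x time matrices with the same shape.
#' @param score aggregation rule.
#' @return list with `label`, `scores` (named), `tie` (logical).
#' @export
classify_trial <- function(trial, templates, score = c("mean", "max", "flat")) {
  score <- match.arg(score)
  stopifnot(length(templates) >= 1)
  trial <- as.matrix(trial)
  scores <- vapply(templates, function(tem) {
    tem <- as.matrix(tem)
    if (!all(dim(tem) == dim(trial)))
      stop("template and trial shapes differ")
    if (score == "flat") {
      return(stats::cor(as.vector(trial), as.vector(tem)))
    }
    r <- vapply(seq_len(ncol(trial)), function(k) {
      a <- trial[, k]; b <- tem[, k]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      stats::cor(a, b)
    }, numeric(1))
    r <- r[!is.na(r)]
    if (length(r) == 0) return(NA_real_)
    if (score == "mean") mean(r) else max(r)
  }, numeric(1))
  if (all(is.na(scores))) stop("undecodable trial: all time points degenerate")
  best <- max(scores, na.rm = TRUE)
  winners <- which(scores == best)
  list(label = names(templates)[winners[1]], scores = scores,
       tie = length(winners) > 1)
}

#' Confusion matrix and accuracy from decoded labels
#'
#' @param truth,decoded character vectors of true and decoded labels.
#' @param levels label set (default: sorted unique truth).
#' @return object of class `confusion_matrix`: K x K count matrix with
#'   attributes `accuracy` and `chance` (1/K).
#' @export
confusion_matrix <- function(truth, decoded, levels = sort(unique(truth))) {
  cm <- table(factor(truth, levels = levels),
              factor(decoded, levels = levels))
  cm <- unclass(as.matrix(cm))
  structure(cm, class = c("confusion_matrix", class(cm)),
            accuracy = sum(diag(cm)) / sum(cm),
            chance = 1 / length(levels))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d-way, accuracy %.1f%% (chance %.1f%%)\n",
              nrow(x), 100 * attr(x, "accuracy"), 100 * attr(x, "chance")))
  print(unclass(x))
  invisible(x)
}

#' Six-way localizer decoding for one subject session
#'
#' For each task, blocks are interleaved into train/test; training blocks are
#' averaged into one spatiotemporal template per task, and every test block
#' is scored against all templates. Each block window drops the first
#' `trim_s` seconds and keeps `window_s` seconds.
#'
#' @param runs named list (one entry per task label) of voxels x frames
#'   matrices at `fs`.
#' @param designs named list of [stimulus_design()]s matching `runs`; for
#'   tasks with more than `max_blocks` blocks only the first `max_blocks` are
#'   used (protocol parity for the longer lateralized runs).
#' @param mask voxel mask applied to every run.
#' @param fs frame rate (default 1 Hz).
#' @param trim_s,window_s block window parameters (defaults 4 and 16 s).
#' @param max_blocks blocks used per task (default 6).
#' @param score aggregation rule for [classify_trial()].
#' @return list with `confusion` (a [confusion_matrix()]), `trials`
#'   (data.frame of truth/decoded/tie), `templates`.
#' @export
decode_localizer_session <- function(runs, designs, mask = NULL, fs = 1,
                                     trim_s = 4, window_s = 16,
                                     max_blocks = 6,
                                     score = c("mean", "max", "flat")) {
  score <- match.arg(score)
  tasks <- names(runs)
  if (length(tasks) < 2) stop("at least two tasks are required")
  templates <- list()
  test_blocks <- list()
  for (tk in tasks) {
    des <- designs[[tk]]
    onsets <- des$onset[seq_len(min(nrow(des), max_blocks))]
    wins <- lapply(onsets, function(on)
      extract_block_window(runs[[tk]], on, trim_s, window_s, mask, fs))
    sp <- split_blocks_interleaved(wins)
    templates[[tk]] <- Reduce(`+`, sp$train) / length(sp$train)
    test_blocks[[tk]] <- sp$test
  }
  truth <- character(); decoded <- character(); tie <- logical()
  for (tk in tasks) {
    for (w in test_blocks[[tk]]) {
      res <- classify_trial(w, templates, score = score)
      truth <- c(truth, tk)
      decoded <- c(decoded, res$label)
      tie <- c(tie, res$tie)
    }
  }
  cm <- confusion_matrix(truth, decoded, levels = tasks)
  list(confusion = cm,
       trials = data.frame(truth = truth, decoded = decoded, tie = tie),
       templates = templates)
}

#' Aggregate subject confusion matrices
#'
#' @param cms list of [confusion_matrix()]s with identical labels.
#' @return a [confusion_matrix()] of summed counts.
#' @export
aggregate_confusions <- function(cms) {
  total <- Reduce(`+`, lapply(cms, unclass))
  structure(total, class = c("confusion_matrix", class(total)),
            accuracy = sum(diag(total)) / sum(total),
            chance = 1 / nrow(total))
}

#' Movie segmentation windows
#'
#' Divides a run of `total_s` seconds into `n_clips` equal contiguous
#' segments; the first `guard_s` seconds of each segment are excluded from
#' scoring to avoid transient boundary responses.
#'
#' @param total_s run duration, s.
#' @param n_clips number of segments.
#' @param guard_s guard interval, s (default 6).
#' @return data.frame with `clip`, `start_s`, `end_s` (nominal division) and
#'   `scored_start_s` (start + guard); nominal duration total_s/n_clips.
#' @export
movie_segments <- function(total_s, n_clips, guard_s = 6) {
  dur <- total_s / n_clips
  if (guard_s >= dur)
    stop("invalid segmentation: guard interval is not shorter than a segment")
  start <- (seq_len(n_clips) - 1) * dur
  data.frame(clip = seq_len(n_clips), start_s = start, end_s = start + dur,
             scored_start_s = start + guard_s)
}

#' N-way movie-segment decoding between two viewings
#'
#' Segments of the first viewing act as templates and the time-aligned
#' segments of the second viewing as trials, scored with [classify_trial()];
#' chance is 1/n_clips.
#'
#' @param run1,run2 voxels x frames matrices (template and test viewing),
#'   equal shape, at `fs`.
#' @param n_clips number of segments.
#' @param mask voxel mask.
#' @param fs frame rate (default 1 Hz).
#' @param guard_s per-segment guard interval, s (default 6).
#' @param score aggregation rule.
#' @return list with `confusion`, `trials`, `segments`.
#' @export
decode_movie <- function(run1, run2, n_clips, mask = NULL, fs = 1,
                         guard_s = 6, score = c("mean", "max", "flat")) {
  score <- match.arg(score)
  m1 <- if (inherits(run1, "voxel_image")) run1$values else as.matrix(run1)
  m2 <- if (inherits(run2, "voxel_image")) run2$values else as.matrix(run2)
  if (!all(dim(m1) == dim(m2)))
    stop("alignment error: the two viewings differ in shape")
  total_s <- ncol(m1) / fs
  seg <- movie_segments(total_s, n_clips, guard_s)
  scored_len_s <- floor(total_s / n_clips - guard_s)
  cut_seg <- function(m, k)
    extract_block_window(m, seg$start_s[k], trim_s = guard_s,
                         window_s = scored_len_s, mask = mask, fs = fs)
  templates <- lapply(seq_len(n_clips), function(k) cut_seg(m1, k))
  names(templates) <- as.character(seg$clip)
  truth <- character(); decoded <- character(); tie <- logical()
  for (k in seq_len(n_clips)) {
    res <- classify_trial(cut_seg(m2, k), templates, score = score)
    truth <- c(truth, as.character(k))
    decoded <- c(decoded, res$label)
    tie <- c(tie, res$tie)
  }
  cm <- confusion_matrix(truth, decoded, levels = as.character(seg$clip))
  list(confusion = cm,
       trials = data.frame(truth = truth, decoded = decoded, tie = tie),
       segments = seg)
}
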