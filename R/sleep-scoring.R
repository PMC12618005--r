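#' Sleep-scoring configuration
#'
#' Sleep is scored as consolidated immobility: a frame is immobile when its
#' velocity is strictly below `velocity_threshold` (ties at the cut-off count
#' as active swimming), and a maximal immobile run lasting at least
#' `min_bout_s` is a sleep bout. `max_gap_s > 0` optionally tolerates brief
#' mobile interruptions inside a bout; the default 0 reads "consolidated"
#' as uninterrupted.
#'
#' @param velocity_threshold Mobility cut-off, mm/s (default 6).
#' @param min_bout_s Minimum bout duration, seconds (default 60).
#' @param max_gap_s Longest mobile interruption absorbed into a bout,
#'   seconds (default 0 = none).
#' @param nan_policy How missing frames are treated: `"break"` (missing
#'   frames are mobile, so they break bouts; conservative default) or
#'   `"fill_short"` (runs of missing frames up to 1 s inherit the previous
#'   frame's flag; longer runs break).
#' @param epoch_s Epoch length for transition-probability estimation,
#'   seconds (default 1, the resolution of the sleep definition).
#' @return An object of class `scoring_config`.
#' @export
scoring_config <- function(velocity_threshold = 6, min_bout_s = 60,
                           max_gap_s = 0, nan_policy = c("break", "fill_short"),
                           epoch_s = 1) {
  stop_if_not_positive(velocity_threshold, "velocity_threshold")
  stop_if_not_positive(min_bout_s, "min_bout_s")
  stop_if_not_positive(epoch_s, "epoch_s")
  if (!is.numeric(max_gap_s) || length(max_gap_s) != 1L || max_gap_s < 0) {
    stop("`max_gap_s` must be a single number >= 0", call. = FALSE)
  }
  nan_policy <- match.arg(nan_policy)
  structure(list(velocity_threshold = velocity_threshold,
                 min_bout_s = min_bout_s, max_gap_s = max_gap_s,
                 nan_policy = nan_policy, epoch_s = epoch_s),
            class = "scoring_config")
}

#' Per-frame immobility flags from a velocity trace
#'
#' @param trace A [velocity_trace()].
#' @param cfg A [scoring_config()].
#' @return Logical vector, one flag per frame; `TRUE` = immobile
#'   (velocity strictly below the cut-off).
#' @export
binarize_mobility <- function(trace, cfg = scoring_config()) {
  stopifnot(inherits(trace, "velocity_trace"), inherits(cfg, "scoring_config"))
  v <- trace$velocity
  if (length(v) == 0L) stop("empty trace", call. = FALSE)
  imm <- v < cfg$velocity_threshold
  if (anyNA(imm)) {
    if (cfg$nan_policy == "break") {
      imm[is.na(imm)] <- FALSE
    } else {
      max_fill <- max(1L, as.integer(round(trace$frame_rate)))  # <= 1 s
      r <- rle(is.na(imm))
      pos <- cumsum(c(1L, r$lengths))
      for (j in seq_along(r$lengths)) {
        if (!r$values[j]) next
        i0 <- pos[j]
        idx <- i0:(i0 + r$lengths[j] - 1L)
        if (r$lengths[j] <= max_fill && i0 > 1L) {
          imm[idx] <- imm[i0 - 1L]
        } else {
          imm[idx] <- FALSE
        }
      }
    }
  }
  imm
}

# Maximal immobile runs as frame indices, merging gaps of <= gap_frames
# mobile frames. Boundary-difference method (no rle), so the brute-force
# run-length oracle used in tests stays independent.
immobile_runs <- function(flags, gap_frames = 0L) {
  x <- as.integer(flags)
  d <- diff(c(0L, x, 0L))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  if (length(starts) == 0L) {
    return(data.frame(start_frame = integer(0), end_frame = integer(0)))
  }
  if (gap_frames > 0L && length(starts) > 1L) {
    gap <- starts[-1L] - ends[-length(ends)] - 1L
    newrun <- c(TRUE, gap > gap_frames)
    grp <- cumsum(newrun)
    starts <- tapply(starts, grp, min)
    ends <- tapply(ends, grp, max)
  }
  data.frame(start_frame = as.integer(starts), end_frame = as.integer(ends))
}

#' Detect sleep bouts from immobility flags
#'
#' A sleep bout is a maximal run of immobility (optionally absorbing mobile
#' gaps up to `max_gap_s`) lasting at least `min_bout_s`. Durations are
#' whole frames times the frame period, so at 1 Hz a run of exactly 60
#' immobile frames is a 60 s bout and qualifies (the rule is ">= 60 s"),
#' while 59 frames do not.
#'
#' @param flags Logical immobility flags from [binarize_mobility()].
#' @param frame_rate Hz.
#' @param cfg A [scoring_config()].
#' @param t_start Time (s) of the first frame (default 0).
#' @return A `sleep_bouts` data frame with columns `start`, `end`,
#'   `duration` (seconds); bouts are disjoint and ordered.
#' @export
detect_sleep_bouts <- function(flags, frame_rate, cfg = scoring_config(),
                               t_start = 0) {
  stopifnot(is.logical(flags), inherits(cfg, "scoring_config"))
  stop_if_not_positive(frame_rate, "frame_rate")
  if (length(flags) == 0L) stop("empty flag vector", call. = FALSE)
  flags[is.na(flags)] <- FALSE
  gap_frames <- as.integer(floor(cfg$max_gap_s * frame_rate))
  runs <- immobile_runs(flags, gap_frames)
  nfr <- runs$end_frame - runs$start_frame + 1L
  keep <- nfr / frame_rate >= cfg$min_bout_s
  runs <- runs[keep, , drop = FALSE]
  nfr <- nfr[keep]
  out <- data.frame(
    start = t_start + (runs$start_frame - 1L) / frame_rate,
    duration = nfr / frame_rate)
  out$end <- out$start + out$duration
  out <- out[, c("start", "end", "duration")]
  class(out) <- c("sleep_bouts", "data.frame")
  attr(out, "frame_rate") <- frame_rate
  out
}

#' Score sleep directly from a velocity trace
#'
#' Convenience wrapper: [binarize_mobility()] then [detect_sleep_bouts()].
#'
#' @inheritParams binarize_mobility
#' @return A `sleep_bouts` data frame.
#' @export
score_sleep <- function(trace, cfg = scoring_config()) {
  flags <- binarize_mobility(trace, cfg)
  detect_sleep_bouts(flags, trace$frame_rate, cfg, t_start = trace$time[1L])
}

#' Windowed sleep metrics
#'
#' Totals use bout/window overlap (time is conserved across window edges);
#' bout counts and mean bout length use bouts whose *onset* falls in the
#' window, each contributing its full duration to the mean.
#'
#' @param bouts A `sleep_bouts` data frame.
#' @param window Numeric length-2, window start and end in trace seconds.
#' @return A one-row data frame: `total_sleep_min`, `bout_number`,
#'   `mean_bout_length_s` (`NA` when no bout onsets fall in the window).
#' @examples
#' b <- data.frame(start = 100, end = 400, duration = 300)
#' compute_sleep_metrics(b, c(0, 10800))  # 5 min, 1 bout, 300 s
#' @export
compute_sleep_metrics <- function(bouts, window) {
  stopifnot(is.data.frame(bouts), length(window) == 2L)
  w1 <- window[1L]; w2 <- window[2L]
  if (!(w2 > w1)) stop("window must have positive length", call. = FALSE)
  if (nrow(bouts) == 0L) {
    return(data.frame(total_sleep_min = 0, bout_number = 0L,
                      mean_bout_length_s = NA_real_))
  }
  overlap <- pmax(0, pmin(bouts$end, w2) - pmax(bouts$start, w1))
  onset_in <- bouts$start >= w1 & bouts$start < w2
  data.frame(
    total_sleep_min = sum(overlap) / 60,
    bout_number = sum(onset_in),
    mean_bout_length_s = if (any(onset_in)) mean(bouts$duration[onset_in])
                         else NA_real_)
}

#' Binned sleep profile on the Zeitgeber-time axis
#'
#' Apportions scored sleep to consecutive `bin_min`-minute bins tiling the
#' recording by exact overlap, so the bins sum to the windowed total. Bin
#' start times are reported in Zeitgeber hours (`ZT = (t - zt0_offset)/3600
#' mod 24`); under the 14:10 schedule day is ZT0-14 and night ZT14-24.
#'
#' @param bouts A `sleep_bouts` data frame.
#' @param t_start,t_end Recording extent, seconds.
#' @param zt0_offset Clock time (s) of lights-on.
#' @param bin_min Bin width in minutes; must divide 60.
#' @return A data frame `bin_start_s`, `bin_end_s`, `zt_start_h`,
#'   `sleep_min`.
#' @export
compute_sleep_profile <- function(bouts, t_start, t_end, zt0_offset = 0,
                                  bin_min = 10) {
  stopifnot(is.data.frame(bouts))
  if (60 %% bin_min != 0) stop("`bin_min` must divide 60", call. = FALSE)
  bin_s <- bin_min * 60
  if (t_end - t_start < bin_s) {
    stop("trace shorter than one bin", call. = FALSE)
  }
  edges <- seq(t_start, t_end, by = bin_s)
  if (edges[length(edges)] < t_end) edges <- c(edges, t_end)  # partial last bin
  lo <- edges[-length(edges)]
  hi <- edges[-1L]
  sleep_s <- vapply(seq_along(lo), function(i) {
    if (nrow(bouts) == 0L) return(0)
    sum(pmax(0, pmin(bouts$end, hi[i]) - pmax(bouts$start, lo[i])))
  }, numeric(1))
  data.frame(bin_start_s = lo, bin_end_s = hi,
             zt_start_h = ((lo - zt0_offset) / 3600) %% 24,
             sleep_min = sleep_s / 60)
}

#' Per-epoch sleep/wake transition probabilities
#'
#' Estimates the sleep-pressure proxy P(doze) (wake -> sleep per epoch) and
#' its converse P(wake) (sleep -> wake). The window is tiled with
#' `epoch_s`-second epochs; an epoch is labelled *sleep* either by scored
#' bout membership (epoch start inside a bout; pass `bouts`) or, when only
#' `flags` are given, by full-epoch immobility. Bout labelling reflects the
#' scored behavioural state (what sleep-probability figures report); flag
#' labelling estimates the underlying mobility-state chain and is the one
#' that recovers the generator's per-epoch probabilities, since bout
#' scoring censors quiescent dwells shorter than the 60 s rule.
#'
#' `p_doze` = (# wake epochs whose successor is sleep) / (# wake epochs with
#' a successor); `p_wake` symmetrically. A probability with no source-state
#' epochs is `NA`, not zero.
#'
#' @param window Numeric length-2, seconds; must contain >= 2 epochs.
#' @param epoch_s Epoch length, seconds.
#' @param bouts Optional `sleep_bouts` data frame (bout labelling).
#' @param flags,frame_rate,t_start Optional immobility flags (from
#'   [binarize_mobility()]), their frame rate and first-frame time
#'   (flag labelling; missing flags count as mobile).
#' @return A list of class `transition_probs`: `p_doze`, `p_wake`,
#'   `n_epochs`, `n_wake_epochs`, `n_sleep_epochs`.
#' @export
transition_probabilities <- function(window, epoch_s = 1, bouts = NULL,
                                     flags = NULL, frame_rate = NULL,
                                     t_start = 0) {
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  n_ep <- as.integer(floor((window[2L] - window[1L]) / epoch_s))
  if (n_ep < 2L) stop("window must contain at least 2 epochs", call. = FALSE)
  starts <- window[1L] + (seq_len(n_ep) - 1L) * epoch_s
  if (!is.null(bouts)) {
    sleep <- rep(FALSE, n_ep)
    if (nrow(bouts) > 0L) {
      ord <- order(bouts$start)
      bs <- bouts$start[ord]; be <- bouts$end[ord]
      idx <- findInterval(starts, bs)
      sleep <- idx > 0L & starts < be[pmax(idx, 1L)]
    }
  } else {
    if (is.null(flags) || is.null(frame_rate)) {
      stop("supply either `bouts` or `flags` + `frame_rate`", call. = FALSE)
    }
    flags[is.na(flags)] <- FALSE
    tm <- t_start + (seq_along(flags) - 1L) / frame_rate
    inwin <- tm >= window[1L] & tm < window[1L] + n_ep * epoch_s
    e <- floor((tm[inwin] - window[1L]) / epoch_s) + 1L
    n_frames <- tabulate(e, nbins = n_ep)
    n_imm <- tabulate(e[flags[inwin]], nbins = n_ep)
    sleep <- n_frames > 0L & n_imm == n_frames
  }
  from <- sleep[-n_ep]
  to <- sleep[-1L]
  n_wake <- sum(!from)
  n_sleep <- sum(from)
  structure(list(
    p_doze = if (n_wake > 0L) sum(!from & to) / n_wake else NA_real_,
    p_wake = if (n_sleep > 0L) sum(from & !to) / n_sleep else NA_real_,
    n_epochs = n_ep, n_wake_epochs = n_wake, n_sleep_epochs = n_sleep),
    class = "transition_probs")
}

#' Per-subject sleep metrics for a cohort
#'
#' @param cohort A `locomotor_cohort`.
#' @param window Metric window, seconds (length 2).
#' @param cfg A [scoring_config()].
#' @return Data frame with one row per subject: labels plus the
#'   [compute_sleep_metrics()] columns.
#' @export
cohort_sleep_metrics <- function(cohort, window, cfg = scoring_config()) {
  stopifnot(inherits(cohort, "locomotor_cohort"))
  rows <- lapply(cohort, function(tr) {
    m <- compute_sleep_metrics(score_sleep(tr, cfg), window)
    cbind(data.frame(subject_id = tr$subject_id,
                     group = as.character(tr$group)), m)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
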