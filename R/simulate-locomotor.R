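#' Parameters for the two-state locomotor simulator
#'
#' The generator models larval activity as a hidden two-state Markov chain on
#' 1-second epochs: an *active* (swimming) state and a *quiescent* (drifting)
#' state. Each epoch, an active fish becomes quiescent with probability
#' `p_doze` and a quiescent fish becomes active with probability `p_wake`.
#' The hidden state is expanded to frames at `frame_rate` and each frame's
#' velocity is drawn from the state's emission distribution, a normal
#' truncated at zero. Defining the dynamics on 1-s epochs keeps the
#' transition probabilities independent of the camera frame rate and matches
#' the 1-s resolution at which sleep (>= 60 s immobility) is defined.
#'
#' Default emissions (active 25 +/- 4 mm/s, quiescent 0.5 +/- 1 mm/s) put
#' essentially no probability mass on the wrong side of the conventional
#' 6 mm/s mobility cut-off, so scored immobility tracks the hidden state.
#'
#' @param p_doze Per-epoch probability of the active -> quiescent transition.
#' @param p_wake Per-epoch probability of the quiescent -> active transition.
#' @param frame_rate Sampling rate of the velocity trace, Hz.
#' @param duration Trace duration, seconds.
#' @param v_active_mean,v_active_sd Velocity emission (mm/s) when active.
#' @param v_quiescent_mean,v_quiescent_sd Velocity emission (mm/s) when
#'   quiescent.
#' @param initial_state State of the first epoch, `"active"` or `"quiescent"`.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   traces.
#' @return An object of class `locomotor_params`.
#' @seealso [simulate_locomotor_trace()], [simulate_cohort()]
#' @export
locomotor_params <- function(p_doze, p_wake,
                             frame_rate = 1, duration = 86400,
                             v_active_mean = 25, v_active_sd = 4,
                             v_quiescent_mean = 0.5, v_quiescent_sd = 1,
                             initial_state = c("active", "quiescent"),
                             seed = 1L) {
  stop_if_not_scalar_prob(p_doze, "p_doze")
  stop_if_not_scalar_prob(p_wake, "p_wake")
  stop_if_not_positive(frame_rate, "frame_rate")
  stop_if_not_positive(duration, "duration")
  if (v_active_sd < 0 || v_quiescent_sd < 0) {
    stop("emission standard deviations must be >= 0", call. = FALSE)
  }
  initial_state <- match.arg(initial_state)
  if (v_quiescent_mean >= 6 || v_active_mean <= 6) {
    warning("emission means straddle the conventional 6 mm/s cut-off poorly; ",
            "scored immobility may not track the hidden state", call. = FALSE)
  }
  structure(
    list(p_doze = p_doze, p_wake = p_wake,
         frame_rate = frame_rate, duration = duration,
         v_active_mean = v_active_mean, v_active_sd = v_active_sd,
         v_quiescent_mean = v_quiescent_mean, v_quiescent_sd = v_quiescent_sd,
         initial_state = initial_state, seed = as.integer(seed)),
    class = "locomotor_params")
}

# Hidden state per 1-s epoch (0 = active, 1 = quiescent), sampled as
# alternating geometric dwells -- distributionally identical to the
# per-epoch Bernoulli chain.
sim_epoch_states <- function(n_epochs, p_doze, p_wake, initial_state) {
  lens <- integer(0)
  vals <- integer(0)
  state <- if (initial_state == "active") 0L else 1L
  filled <- 0L
  while (filled < n_epochs) {
    p_leave <- if (state == 0L) p_doze else p_wake
    if (p_leave <= 0) {
      len <- n_epochs - filled
    } else {
      len <- rgeom(1L, p_leave) + 1L
      if (is.na(len) || len > n_epochs - filled) len <- n_epochs - filled
    }
    lens <- c(lens, len)
    vals <- c(vals, state)
    filled <- filled + len
    state <- 1L - state
  }
  inverse.rle(structure(list(lengths = lens, values = vals), class = "rle"))
}

#' Simulate a velocity trace from the two-state locomotor model
#'
#' @param params A [locomotor_params()] object.
#' @param subject_id Identifier stored on the trace.
#' @param zt0_offset Clock time (s) of lights-on; used when binning profiles
#'   on the Zeitgeber-time axis.
#' @return A `velocity_trace`: a list with `time` (s), `velocity` (mm/s),
#'   `frame_rate`, `zt0_offset`, `light_schedule` (14 h light : 10 h dark),
#'   label fields, and the ground-truth per-frame `state` factor
#'   (`active`/`quiescent`), which downstream code never modifies.
#' @examples
#' p <- locomotor_params(p_doze = 0.01, p_wake = 0.05, duration = 3600, seed = 7)
#' tr <- simulate_locomotor_trace(p)
#' mean(tr$state == "quiescent")
#' @export
simulate_locomotor_trace <- function(params, subject_id = "subject_1",
                                     zt0_offset = 0) {
  stopifnot(inherits(params, "locomotor_params"))
  n_epochs <- as.integer(ceiling(params$duration))
  n_frames <- as.integer(round(params$duration * params$frame_rate))
  if (n_frames < 1L) stop("duration x frame_rate must be >= 1 frame", call. = FALSE)
  with_seed(params$seed, {
    st <- sim_epoch_states(n_epochs, params$p_doze, params$p_wake,
                           params$initial_state)
    tm <- (seq_len(n_frames) - 1L) / params$frame_rate
    epoch_of_frame <- pmin(floor(tm) + 1L, n_epochs)
    frame_state <- st[epoch_of_frame]
    v <- numeric(n_frames)
    act <- frame_state == 0L
    v[act] <- rtnorm0(sum(act), params$v_active_mean, params$v_active_sd)
    v[!act] <- rtnorm0(sum(!act), params$v_quiescent_mean, params$v_quiescent_sd)
    velocity_trace(subject_id = subject_id, time = tm, velocity = v,
                   frame_rate = params$frame_rate, zt0_offset = zt0_offset,
                   state = factor(ifelse(act, "active", "quiescent"),
                                  levels = c("active", "quiescent")))
  })
}

#' Construct a velocity trace
#'
#' Container for a uniformly sampled per-frame velocity time series with
#' light-schedule metadata, the unit of input for sleep scoring.
#'
#' @param subject_id Subject identifier.
#' @param time Frame times, seconds, a uniform strictly increasing grid.
#' @param velocity Per-frame velocity, mm/s; `NA` marks missing frames.
#' @param frame_rate Hz; must agree with the time grid.
#' @param zt0_offset Clock time (s) of lights-on (ZT0).
#' @param light_schedule Hours of light and dark, default `c(light_h = 14, dark_h = 10)`.
#' @param population,treatment,group Optional label strings.
#' @param state Optional ground-truth per-frame state factor (simulations).
#' @return An object of class `velocity_trace`.
#' @export
velocity_trace <- function(subject_id, time, velocity, frame_rate,
                           zt0_offset = 0,
                           light_schedule = c(light_h = 14, dark_h = 10),
                           population = NA_character_,
                           treatment = NA_character_,
                           group = NA_character_,
                           state = NULL) {
  n <- length(time)
  if (n < 1L || length(velocity) != n) {
    stop("`time` and `velocity` must be non-empty and of equal length",
         call. = FALSE)
  }
  stop_if_not_positive(frame_rate, "frame_rate")
  if (n > 1L) {
    dt <- diff(time)
    if (any(dt <= 0) || max(abs(dt - 1 / frame_rate)) > 1e-6) {
      stop("`time` must be a uniform strictly increasing grid at `frame_rate`",
           call. = FALSE)
    }
  }
  if (any(velocity < 0, na.rm = TRUE)) {
    stop("velocities must be >= 0 (or NA for missing frames)", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, time = as.numeric(time),
         velocity = as.numeric(velocity), frame_rate = frame_rate,
         zt0_offset = zt0_offset, light_schedule = light_schedule,
         population = population, treatment = treatment, group = group,
         state = state),
    class = "velocity_trace")
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf("<velocity_trace> %s: %d frames @ %g Hz (%.1f h)%s\n",
              x$subject_id, length(x$time), x$frame_rate,
              diff(range(x$time)) / 3600,
              if (!is.na(x$group)) paste0(", group ", x$group) else ""))
  invisible(x)
}

#' Simulate a cohort of traces across labelled groups
#'
#' Per-subject seeds are derived deterministically from the master seed and
#' the subject's position, so the same call always reproduces the same
#' cohort while subjects get independent streams.
#'
#' @param group_specs A list; each element a list with `label` (string),
#'   `params` (a [locomotor_params()]) and `n_subjects`.
#' @param seed Master integer seed.
#' @param zt0_offset Passed to every trace.
#' @return A `locomotor_cohort`: a named list of `velocity_trace` objects
#'   (names are subject ids); see [cohort_manifest()].
#' @examples
#' specs <- list(
#'   list(label = "ctrl", params = locomotor_params(0.01, 0.05, duration = 600), n_subjects = 3),
#'   list(label = "uv",   params = locomotor_params(0.03, 0.05, duration = 600), n_subjects = 3))
#' cohort <- simulate_cohort(specs, seed = 1)
#' cohort_manifest(cohort)
#' @export
simulate_cohort <- function(group_specs, seed = 1L, zt0_offset = 0) {
  labels <- vapply(group_specs, function(g) as.character(g$label), character(1))
  ns <- vapply(group_specs, function(g) as.integer(g$n_subjects), integer(1))
  if (any(ns < 1L)) stop("each group needs n_subjects >= 1", call. = FALSE)
  ids <- unlist(mapply(function(lab, n) sprintf("%s_%02d", lab, seq_len(n)),
                       labels, ns, SIMPLIFY = FALSE))
  if (anyDuplicated(ids)) stop("duplicate subject identifiers", call. = FALSE)
  traces <- vector("list", length(ids))
  k <- 0L
  for (gi in seq_along(group_specs)) {
    g <- group_specs[[gi]]
    for (si in seq_len(ns[gi])) {
      k <- k + 1L
      p <- g$params
      p$seed <- derive_seed(seed, k)
      tr <- simulate_locomotor_trace(p, subject_id = ids[k],
                                     zt0_offset = zt0_offset)
      tr$group <- labels[gi]
      traces[[k]] <- tr
    }
  }
  names(traces) <- ids
  structure(traces, class = "locomotor_cohort")
}

#' Tabulate a cohort's subjects and labels
#'
#' @param cohort A `locomotor_cohort` from [simulate_cohort()].
#' @return A data frame with columns `subject_id`, `group`, `population`,
#'   `treatment`.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "locomotor_cohort"))
  data.frame(
    subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
    group = vapply(cohort, function(x) as.character(x$group), character(1)),
    population = vapply(cohort, function(x) as.character(x$population), character(1)),
    treatment = vapply(cohort, function(x) as.character(x$treatment), character(1)),
    row.names = NULL)
}
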