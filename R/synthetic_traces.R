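# Seeded synthetic fluorescence traces with known ground truth. These
# emulate the tabular per-ROI traces produced upstream by a computer-vision
# extraction stage: Li-Rinzel dynamics mapped through the saturating
# indicator function with additive mean-zero Gaussian noise, 180 frames at
# 1 Hz by default (3 min of acquisition).

#' Construct a trace object
#'
#' @param times Strictly increasing, uniformly spaced time stamps, s.
#' @param fluorescence Fluorescence values, arbitrary units; same length.
#' @param roi_id ROI identifier.
#' @return List of class \code{"ca_trace"} with fields \code{roi_id},
#'   \code{times}, \code{fluorescence}, \code{frame_dt}.
#' @export
make_trace <- function(times, fluorescence, roi_id = "roi1") {
  if (length(times) != length(fluorescence))
    stop("times and fluorescence lengths differ")
  if (length(times) < 2L) stop("a trace needs at least 2 frames")
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("times must be uniformly spaced")
  structure(list(roi_id = as.character(roi_id), times = as.numeric(times),
                 fluorescence = as.numeric(fluorescence),
                 frame_dt = mean(dt)),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("Trace %s: %d frames at %.3g s (%.3g s total)\n", x$roi_id,
              length(x$times), x$frame_dt, max(x$times)))
  invisible(x)
}

#' Generate one synthetic fluorescence trace
#'
#' Forward-simulates the kinetic model on the acquisition grid
#' (micro-stepped), optionally injects per-frame Gaussian state noise
#' (safeguarded into the physical state domain), maps the calcium path
#' through the observation function, and adds i.i.d. Gaussian observation
#' noise. Frames are at \code{t = 0, frame_dt, ...}; the number of frames
#' is \code{round(duration / frame_dt)}.
#'
#' @param params A [kinetic_params()] object (ground truth).
#' @param obs An [observation_params()] object.
#' @param state0 Initial [kinetic_state()].
#' @param obs_noise_sd Observation noise standard deviation, fluorescence
#'   units (>= 0).
#' @param state_noise_sd Per-component state noise standard deviation
#'   applied at frame resolution (scalar or length 3; default 0: the
#'   dynamics themselves are deterministic).
#' @param duration Acquisition duration, s.
#' @param frame_dt Frame interval, s.
#' @param micro_dt Integration sub-step, s.
#' @param seed Integer seed; the trace is reproducible for a fixed seed.
#' @param roi_id ROI identifier.
#' @return A \code{ca_trace} with attribute \code{"truth"} (list with the
#'   generating parameters, initial state, and noise levels).
#' @examples
#' tr <- generate_trace(obs_noise_sd = 0.02, duration = 60, seed = 1)
#' range(tr$fluorescence)
#' @export
generate_trace <- function(params = kinetic_params(),
                           obs = observation_params(kappa_f = 10, d_f = 2),
                           state0 = kinetic_state(0.1, 0.5, 0.5),
                           obs_noise_sd = 0, state_noise_sd = 0,
                           duration = 180, frame_dt = 1, micro_dt = 0.1,
                           seed = 1L, roi_id = "roi1") {
  if (any(obs_noise_sd < 0) || any(state_noise_sd < 0))
    stop("noise standard deviations must be non-negative")
  n_frames <- as.integer(round(duration / frame_dt))
  if (n_frames < 2L) stop("duration must cover at least 2 frames")
  .check_grid(frame_dt, micro_dt)
  if (length(state_noise_sd) == 1L) state_noise_sd <- rep(state_noise_sd, 3)

  old <- .Random.seed_exists()
  set.seed(seed)
  pflat <- .lr_flat(params)
  if (all(state_noise_sd == 0)) {
    st <- lr_simulate_cpp(.as_state(state0), pflat, n_frames,
                          frame_dt, micro_dt)$states
  } else {
    st <- matrix(NA_real_, n_frames, 3)
    s <- .as_state(state0)
    st[1, ] <- s
    cmax <- params[["C0"]] * (1 + params[["c1"]]) - 1e-9
    for (t in 2:n_frames) {
      s <- lr_evolve_cpp(s, pflat, frame_dt, micro_dt)$state
      s <- s + stats::rnorm(3, 0, state_noise_sd)
      s[1] <- min(max(s[1], 1e-9), cmax)
      s[2] <- min(max(s[2], 0), 1)
      s[3] <- max(s[3], 1e-9)
      st[t, ] <- s
    }
  }
  y <- predict_trace(st[, 1], obs)
  if (obs_noise_sd > 0) y <- y + stats::rnorm(n_frames, 0, obs_noise_sd)
  .restore_seed(old)

  tr <- make_trace(times = (seq_len(n_frames) - 1) * frame_dt,
                   fluorescence = y, roi_id = roi_id)
  attr(tr, "truth") <- list(params = params, obs = obs, state0 = state0,
                            obs_noise_sd = obs_noise_sd,
                            state_noise_sd = state_noise_sd, seed = seed)
  tr
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a cohort of synthetic traces with group structure
#'
#' Emulates a two-group (or multi-group) experiment: each group's free
#' kinetic parameters are the base values times the group's multiplicative
#' shift, with per-trace log-normal jitter. Each trace gets a sub-seed
#' derived deterministically from the master seed, so a cohort regenerates
#' bitwise-identically.
#'
#' @param n_per_group Traces per group (>= 1).
#' @param group_effects Named list, one entry per group; each entry a named
#'   numeric vector of multiplicative shifts on free kinetic parameters
#'   (strictly positive; parameters not named are unshifted). Example:
#'   \code{list(wt = c(), del = c(vs = 0.85, v2 = 0.85))}.
#' @param base_params Base [kinetic_params()].
#' @param obs An [observation_params()] used for every trace.
#' @param state0 Initial state for every trace.
#' @param obs_noise_frac Observation noise as a fraction of each noiseless
#'   trace's range (default 0.02, i.e. 2 percent of range).
#' @param state_noise_sd Per-frame state noise (default 0).
#' @param jitter_sd Standard deviation of the per-trace log-normal jitter
#'   on the free parameters (on the log scale).
#' @param duration,frame_dt,micro_dt Trace geometry, s.
#' @param seed Master seed.
#' @return A list of class \code{"ca_cohort"}: \code{traces} (list of
#'   \code{ca_trace}), \code{truth} (data frame: one row per trace with
#'   roi_id, group, true free-parameter values, noise sd, sub-seed).
#' @examples
#' coh <- generate_cohort(3, list(wt = c(), del = c(vs = 0.85)), seed = 11)
#' coh$truth[, c("roi_id", "group", "vs")]
#' @export
generate_cohort <- function(n_per_group,
                            group_effects = list(A = c(), B = c()),
                            base_params = kinetic_params(),
                            obs = observation_params(kappa_f = 10, d_f = 2),
                            state0 = kinetic_state(0.1, 0.5, 0.5),
                            obs_noise_frac = 0.02, state_noise_sd = 0,
                            jitter_sd = 0.1, duration = 180, frame_dt = 1,
                            micro_dt = 0.1, seed = 1L) {
  stopifnot(n_per_group >= 1, length(group_effects) >= 1)
  free_names <- attr(base_params, "free")
  for (g in names(group_effects)) {
    ef <- group_effects[[g]]
    if (length(ef)) {
      if (is.null(names(ef)) || !all(names(ef) %in% free_names))
        stop("group effects must be named after free kinetic parameters")
      if (any(ef <= 0)) stop("group effect shifts must be strictly positive")
    }
  }
  n_total <- n_per_group * length(group_effects)

  old <- .Random.seed_exists()
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_total)
  jitter_seeds <- sub_seeds[seq_len(n_total)]
  trace_seeds <- sub_seeds[n_total + seq_len(n_total)]
  .restore_seed(old)

  traces <- vector("list", n_total)
  truth <- vector("list", n_total)
  i <- 0L
  for (g in names(group_effects)) {
    shifts <- stats::setNames(rep(1, length(free_names)), free_names)
    ef <- group_effects[[g]]
    if (length(ef)) shifts[names(ef)] <- ef
    for (k in seq_len(n_per_group)) {
      i <- i + 1L
      roi <- sprintf("%s_%02d", g, k)
      oldj <- .Random.seed_exists()
      set.seed(jitter_seeds[i])
      mult <- exp(stats::rnorm(length(free_names), 0, jitter_sd))
      .restore_seed(oldj)
      pv <- unclass(base_params)
      pv[free_names] <- pv[free_names] * shifts * mult
      params_i <- do.call(kinetic_params, as.list(pv))
      # noiseless pass to scale the observation noise to the trace range
      clean <- generate_trace(params_i, obs, state0, obs_noise_sd = 0,
                              state_noise_sd = state_noise_sd,
                              duration = duration, frame_dt = frame_dt,
                              micro_dt = micro_dt, seed = trace_seeds[i],
                              roi_id = roi)
      sd_i <- obs_noise_frac * diff(range(clean$fluorescence))
      traces[[i]] <- generate_trace(params_i, obs, state0,
                                    obs_noise_sd = sd_i,
                                    state_noise_sd = state_noise_sd,
                                    duration = duration, frame_dt = frame_dt,
                                    micro_dt = micro_dt,
                                    seed = trace_seeds[i], roi_id = roi)
      truth[[i]] <- data.frame(roi_id = roi, group = g,
                               as.list(pv[free_names]),
                               obs_noise_sd = sd_i, seed = trace_seeds[i],
                               stringsAsFactors = FALSE)
    }
  }
  structure(list(traces = traces, truth = do.call(rbind, truth)),
            class = "ca_cohort")
}

#' @export
print.ca_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d traces, groups: %s\n", length(x$traces),
              paste(unique(x$truth$group), collapse = ", ")))
  invisible(x)
}
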