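#' Dense-time waveform oracle
#'
#' Independent reference simulator used to verify the epoch-quantized
#' event engine. Every PRE gate pulse and POST feedback spike is laid out
#' explicitly as a rectangular waveform on a fine time grid (default
#' 0.1 ms); pulse overlaps are then measured directly on the grid and the
#' same switching rules applied in chronological event order: an overlap
#' of an open gate with a positive feedback pulse longer than the
#' \code{eps_overlap} guard sets the synapse, overlap with a negative
#' pulse resets it. The negative pulse of a fire at time \code{t} starts at
#' \code{t + delay_neg} and is cancelled when the same POST fires again in
#' \code{(t, t + delay_neg]} (the feedback driver holds one pending pulse).
#'
#' Variability is disabled (binary target levels) and stimuli are binary:
#' the oracle checks waveform timing, not device statistics.
#'
#' @param pre_onsets list of length \code{n_pre}; element n holds the
#'   absolute onset times (ms) of the gate pulses of PRE n.
#' @param fire_times list of length \code{n_post}; element p holds the
#'   absolute fire times (ms) of POST p.
#' @param initial_r \code{n_post x n_pre} matrix of initial resistances.
#' @param params a \code{\link{device_params}} (sigmas forced to 0).
#' @param timing a \code{\link{pulse_timing}}.
#' @param grid_dt time grid resolution, ms.
#' @return the final \code{n_post x n_pre} resistance matrix.
#' @examples
#' dp <- device_params()
#' # single PRE at t = 0, POST fire at t = 3 ms: potentiation to LRS
#' dense_time_oracle(list(0), list(3),
#'                   matrix(dp$r_hrs_target, 1, 1), dp, pulse_timing())
#' @export
dense_time_oracle <- function(pre_onsets, fire_times, initial_r,
                              params = device_params(),
                              timing = pulse_timing(), grid_dt = 0.1) {
  stopifnot(is.list(pre_onsets), is.list(fire_times), is.matrix(initial_r),
            inherits(params, "device_params"), inherits(timing, "pulse_timing"))
  n_pre <- length(pre_onsets)
  n_post <- length(fire_times)
  if (nrow(initial_r) != n_post || ncol(initial_r) != n_pre)
    stop("initial_r must be n_post x n_pre", call. = FALSE)
  p0 <- params
  p0$sigma_lrs <- 0
  p0$sigma_hrs <- 0

  # surviving negative-pulse onsets per POST (replacement rule)
  neg_onsets <- lapply(fire_times, function(ft) {
    ft <- sort(ft)
    keep <- vapply(seq_along(ft), function(i) {
      later <- ft[ft > ft[i] & ft <= ft[i] + timing$delay_neg]
      length(later) == 0L
    }, logical(1))
    ft[keep] + timing$delay_neg
  })

  all_t <- c(unlist(pre_onsets), unlist(fire_times), unlist(neg_onsets))
  if (length(all_t) == 0L) return(initial_r)
  t0 <- min(all_t) - grid_dt
  t1 <- max(all_t) + timing$t_gate + timing$delay_neg + timing$t_fb_pulse
  grid <- seq(t0, t1, by = grid_dt)
  nt <- length(grid)

  # half-open [onset, onset + width) occupancy on the grid
  occupancy <- function(onsets, width) {
    on <- logical(nt)
    for (s in onsets) {
      i0 <- which(grid >= s - grid_dt / 2)[1]
      i1 <- max(which(grid < s + width - grid_dt / 2), 0L)
      if (!is.na(i0) && i1 >= i0) on[i0:i1] <- TRUE
    }
    on
  }

  gate <- lapply(pre_onsets, occupancy, width = timing$t_gate)
  pos <- lapply(fire_times, occupancy, width = timing$t_fb_pulse)
  neg <- lapply(neg_onsets, occupancy, width = timing$t_fb_pulse)

  # contiguous TRUE runs longer than the overlap guard -> events at the
  # run start time
  run_events <- function(active) {
    if (!any(active)) return(numeric(0))
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & (r$lengths * grid_dt > timing$eps_overlap)
    grid[starts[keep]]
  }

  ev_time <- numeric(0)
  ev_post <- integer(0)
  ev_pre <- integer(0)
  ev_kind <- integer(0)  # +1 set, -1 reset
  for (p in seq_len(n_post)) {
    for (n in seq_len(n_pre)) {
      ts <- run_events(gate[[n]] & pos[[p]])
      tr <- run_events(gate[[n]] & neg[[p]])
      ev_time <- c(ev_time, ts, tr)
      ev_post <- c(ev_post, rep.int(p, length(ts) + length(tr)))
      ev_pre <- c(ev_pre, rep.int(n, length(ts) + length(tr)))
      ev_kind <- c(ev_kind, rep.int(1L, length(ts)), rep.int(-1L, length(tr)))
    }
  }
  R <- initial_r
  if (length(ev_time)) {
    ord <- order(ev_time, ev_kind)  # reset before set on exact ties
    for (i in ord) {
      R[ev_post[i], ev_pre[i]] <-
        if (ev_kind[i] > 0) p0$r_lrs_target else p0$r_hrs_target
    }
  }
  R
}

#' Replay an engine run through the dense-time oracle
#'
#' Converts an epoch schedule plus the fire log of an engine run into the
#' explicit pulse-onset scenario of \code{\link{dense_time_oracle}}: PRE
#' gates open at \code{epoch * t_epoch} for every active pixel, and a POST
#' that fired in epoch i emitted its feedback spike at
#' \code{i * t_epoch + t_gate - t_fb_pulse} (the end of the gate window
#' that completed the integration).
#'
#' @param schedule an \code{\link{epoch_schedule}} (binary stimuli).
#' @param fire_epochs list per POST of 0-based epoch indices of fires.
#' @param initial_r initial resistance matrix.
#' @param config a \code{\link{network_config}}.
#' @return the final resistance matrix according to the oracle.
#' @export
oracle_replay <- function(schedule, fire_epochs, initial_r, config) {
  stopifnot(inherits(config, "network_config"))
  tm <- config$timing
  n_pre <- config$n_pre
  masks <- vapply(schedule$images, function(im) as_pre_vector(im) > 0,
                  logical(n_pre))
  masks <- matrix(masks, nrow = n_pre)
  pre_onsets <- lapply(seq_len(n_pre), function(n) {
    (which(masks[n, ]) - 1L) * config$t_epoch
  })
  fire_times <- lapply(fire_epochs, function(ep) {
    ep * config$t_epoch + tm$t_gate - tm$t_fb_pulse
  })
  dense_time_oracle(pre_onsets, fire_times, initial_r,
                    config$device, tm)
}
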