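#' Network configuration
#'
#' Geometry, timing, and neuron parameters of the perceptron network: a
#' first layer of \code{n_pre} retina neurons fully connected to
#' \code{n_post} integrate-and-fire output neurons through one 1T1R synapse
#' each.
#'
#' Internal potentials are kept in "LRS units": one epoch of a single
#' active full-LRS synapse contributes exactly 1 unit, so the training
#' threshold calibrated to fire on 2 simultaneous full-LRS PRE spikes is
#' 2.0 units. A cosmetic volts-per-unit constant (default 0.36 V/unit, so
#' the training threshold displays as 0.72 V) is carried for reporting
#' only and never enters the dynamics.
#'
#' @param n_pre number of PREs (16 for 4x4 images, 9 for 3x3).
#' @param n_post number of POSTs (1 or 2).
#' @param device a \code{\link{device_params}}.
#' @param timing a \code{\link{pulse_timing}}; validated against the device.
#' @param t_epoch epoch (stimulus slot) duration, ms; default equals
#'   \code{t_gate}.
#' @param n_fire_threshold training fire threshold in LRS units (default
#'   2.0: fire on two full-LRS PRE spikes).
#' @param inhibition_fraction fraction by which a fire reduces the internal
#'   potential of every other POST (winner-take-all lateral inhibition);
#'   default 0.4.
#' @param stdp_enabled when \code{FALSE} fires discharge the neuron but
#'   cause no synaptic switching (recognition mode).
#' @param decay multiplicative per-epoch decay of the internal potential;
#'   default 1 (no leak: the neuron integrates digitally until fire or
#'   explicit discharge).
#' @param volts_per_unit cosmetic LRS-unit to volt conversion for display.
#' @return an object of class \code{"network_config"}.
#' @examples
#' network_config()                    # 16 PREs, 1 POST, defaults
#' network_config(n_pre = 9, n_post = 2)
#' @export
network_config <- function(n_pre = 16L, n_post = 1L,
                           device = device_params(),
                           timing = pulse_timing(),
                           t_epoch = timing$t_gate,
                           n_fire_threshold = 2.0,
                           inhibition_fraction = 0.4,
                           stdp_enabled = TRUE,
                           decay = 1.0,
                           volts_per_unit = 0.36) {
  stopifnot(n_pre >= 1, n_post >= 1, t_epoch > 0,
            n_fire_threshold > 0, decay > 0, decay <= 1)
  if (inhibition_fraction < 0 || inhibition_fraction > 1)
    stop("inhibition_fraction must lie in [0, 1]", call. = FALSE)
  validate_timing(timing, device)
  structure(list(n_pre = as.integer(n_pre), n_post = as.integer(n_post),
                 device = device, timing = timing, t_epoch = t_epoch,
                 n_fire_threshold = n_fire_threshold,
                 inhibition_fraction = inhibition_fraction,
                 stdp_enabled = isTRUE(stdp_enabled), decay = decay,
                 volts_per_unit = volts_per_unit),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("memstdp network: %d PREs -> %d POST(s)\n", x$n_pre, x$n_post))
  cat(sprintf("  epoch %.4g ms, threshold %.3g LRS units (%.2f V), %s\n",
              x$t_epoch, x$n_fire_threshold,
              x$n_fire_threshold * x$volts_per_unit,
              if (x$stdp_enabled) "STDP on" else "STDP off"))
  if (x$n_post > 1L)
    cat(sprintf("  lateral inhibition: %.0f%%\n", 100 * x$inhibition_fraction))
  invisible(x)
}

# Vectorized level sampling for array updates. `grade` is the pixel value
# in (0, 1]: graded gates limit the compliance current and raise the LRS
# level (see gray_lrs_map); the optional log-normal spread multiplies the
# sampled level, clipped at the HRS ceiling.
sample_lrs_vec <- function(params, grade = 1) {
  base <- params$r_lrs_target / grade
  if (params$sigma_lrs > 0)
    base <- base * exp(stats::rnorm(length(base), 0, params$sigma_lrs))
  pmin(base, params$r_hrs_target)
}

sample_hrs_vec <- function(params, n) {
  if (params$sigma_hrs == 0) rep.int(params$r_hrs_target, n)
  else params$r_hrs_target * exp(stats::rnorm(n, 0, params$sigma_hrs))
}

#' Create a network state
#'
#' Builds the synapse array and discharged neurons for a configuration.
#' The synapse array is an \code{n_post x n_pre} matrix of resistances in
#' ohms (row = POST, column = PRE; the weight of a synapse is its
#' conductance 1/R).
#'
#' @param config a \code{\link{network_config}}.
#' @param init \code{"hrs"}, \code{"lrs"}, \code{"random"} (each device
#'   independently LRS or HRS with probability 1/2), or an explicit
#'   \code{n_post x n_pre} resistance matrix.
#' @return an object of class \code{"memstdp_network"}: a list with the
#'   configuration, the resistance matrix \code{R}, internal potentials
#'   \code{v_int} (LRS units), per-POST pending negative-pulse flags, and
#'   the epoch counter.
#' @examples
#' net <- new_network(network_config(), init = "hrs")
#' net
#' @export
new_network <- function(config, init = "hrs") {
  stopifnot(inherits(config, "network_config"))
  d <- config$device
  n <- config$n_post * config$n_pre
  R <- if (is.matrix(init)) {
    if (nrow(init) != config$n_post || ncol(init) != config$n_pre)
      stop("init matrix must be n_post x n_pre", call. = FALSE)
    if (any(init <= 0)) stop("resistances must be positive", call. = FALSE)
    init
  } else {
    switch(match.arg(init, c("hrs", "lrs", "random")),
           hrs = matrix(sample_hrs_vec(d, n), config$n_post, config$n_pre),
           lrs = matrix(sample_lrs_vec(d, rep(1, n)), config$n_post, config$n_pre),
           random = matrix(ifelse(stats::runif(n) < 0.5,
                                  sample_lrs_vec(d, rep(1, n)),
                                  sample_hrs_vec(d, n)),
                           config$n_post, config$n_pre))
  }
  structure(list(config = config, R = R,
                 v_int = numeric(config$n_post),
                 pending = logical(config$n_post),
                 epoch = 0L),
            class = "memstdp_network")
}

#' @export
print.memstdp_network <- function(x, ...) {
  print(x$config)
  cat(sprintf("  epoch %d; v_int = %s LRS units\n", x$epoch,
              paste(signif(x$v_int, 4), collapse = ", ")))
  cat(sprintf("  synapses in LRS: %d / %d\n",
              sum(x$R <= 2 * x$config$device$r_lrs_target), length(x$R)))
  invisible(x)
}

# Stimulus -> PRE activation vector, validated against the configuration.
stimulus_vector <- function(stimulus, config) {
  a <- if (is.matrix(stimulus)) as_pre_vector(stimulus) else as.numeric(stimulus)
  if (length(a) != config$n_pre)
    stop(sprintf("stimulus has %d pixels but the network has %d PREs",
                 length(a), config$n_pre), call. = FALSE)
  if (any(a < 0 | a > 1))
    stop("stimulus values must lie in [0, 1]", call. = FALSE)
  a
}

#' Integrate one epoch of PRE current into a POST
#'
#' During an epoch the total current into a POST is the read bias times
#' the sum of the conductances of its gated synapses (only PREs active in
#' the stimulus conduct). In LRS units the potential increment is
#' \code{sum(a_n * (1/R_n) / (1/r_lrs_target))} over active PREs, so one
#' full-LRS synapse driven at full amplitude contributes exactly 1 unit.
#' Graded (gray) pixels contribute proportionally to their level.
#'
#' @param net a \code{\link{new_network}} state.
#' @param post_index which POST to integrate (1-based).
#' @param active activation vector over PREs (logical or numeric in [0,1]),
#'   or an \code{\link{image_grid}}.
#' @return the updated network state (only \code{v_int[post_index]}
#'   changes).
#' @examples
#' net <- new_network(network_config(), init = "lrs")
#' net <- integrate_epoch(net, 1, c(rep(1, 2), rep(0, 14)))
#' net$v_int   # 2 LRS units: crosses the training threshold
#' @export
integrate_epoch <- function(net, post_index, active) {
  stopifnot(inherits(net, "memstdp_network"))
  cfg <- net$config
  if (!(post_index >= 1 && post_index <= cfg$n_post))
    stop("post_index out of range", call. = FALSE)
  a <- stimulus_vector(active, cfg)
  act <- which(a > 0)
  if (length(act)) {
    g <- a[act] / net$R[post_index, act]
    net$v_int[post_index] <- net$v_int[post_index] +
      sum(g) * cfg$device$r_lrs_target
  }
  net
}

#' Has a POST crossed its fire threshold?
#'
#' Pure predicate: \code{TRUE} iff the internal potential is at or above
#' the threshold (fire-at-threshold convention); never mutates state.
#'
#' @inheritParams integrate_epoch
#' @return logical.
#' @export
check_fire <- function(net, post_index = 1L) {
  stopifnot(inherits(net, "memstdp_network"))
  net$v_int[post_index] >= net$config$n_fire_threshold
}

# Core fire transition, shared by fire_event() and step_epoch(); no
# contract checks here. Returns the updated state.
.fire <- function(net, post_index, a) {
  cfg <- net$config
  if (cfg$stdp_enabled) {
    act <- which(a > 0)
    if (length(act))
      net$R[post_index, act] <- sample_lrs_vec(cfg$device, a[act])
    net$pending[post_index] <- TRUE  # replaces any unlanded negative pulse
  }
  net$v_int[post_index] <- 0
  if (cfg$stdp_enabled && cfg$n_post > 1L) {
    others <- setdiff(seq_len(cfg$n_post), post_index)
    net$v_int[others] <- net$v_int[others] * (1 - cfg$inhibition_fraction)
  }
  net
}

#' Fire a POST neuron
#'
#' The fire transition of a POST whose internal potential has crossed the
#' threshold: (a) every synapse of that POST whose gate is open in the
#' current stimulus undergoes a set transition (positive spike delay:
#' selective potentiation); (b) a negative feedback pulse is scheduled at
#' fire time + \code{delay_neg}, landing in the next epoch, where it will
#' reset every synapse of this POST whose gate is open then - unless a new
#' fire replaces it first (the feedback driver holds at most one pending
#' pulse); (c) the internal potential discharges to 0; (d) every other
#' POST is inhibited by the winner-take-all fraction; (e) the event is
#' reported. With STDP disabled only the discharge happens (recognition
#' mode).
#'
#' @inheritParams integrate_epoch
#' @param active the stimulus active during this epoch.
#' @return the updated network state.
#' @export
fire_event <- function(net, post_index, active) {
  stopifnot(inherits(net, "memstdp_network"))
  if (!(post_index >= 1 && post_index <= net$config$n_post))
    stop("post_index out of range", call. = FALSE)
  if (!check_fire(net, post_index))
    stop("fire_event called below the fire threshold", call. = FALSE)
  a <- stimulus_vector(active, net$config)
  .fire(net, post_index, a)
}

#' Advance the network by one stimulus epoch
#'
#' One step of the epoch-quantized event engine. Within an epoch the PRE
#' gates are open for the whole gate window while any feedback pulse only
#' acts at the end of the window, so the order of operations is: (1)
#' apply the per-epoch potential decay; (2) integrate the gated synaptic
#' current into every POST with the pre-update resistances; (3) evaluate
#' fires in a randomized tie-break order, applying lateral inhibition
#' immediately (a POST inhibited below threshold in the same epoch does
#' not fire); (4) land the pending negative pulses of POSTs that fired in
#' the previous epoch onto this epoch's open gates (depression) - except
#' for POSTs that fired again this epoch, whose new feedback spike
#' replaces the pending pulse.
#'
#' @inheritParams integrate_epoch
#' @param stimulus the image presented this epoch (\code{\link{image_grid}}
#'   or activation vector).
#' @return a list with \code{net} (updated state) and \code{events}: epoch
#'   index, active pixel count, per-POST peak potential \code{v_peak} (after
#'   integration, before discharge), per-POST fire flags, and the number of
#'   set/reset switching events.
#' @examples
#' net <- new_network(network_config(), init = "lrs")
#' out <- step_epoch(net, builtin_pattern("diag4"))
#' out$events
#' @export
step_epoch <- function(net, stimulus) {
  stopifnot(inherits(net, "memstdp_network"))
  cfg <- net$config
  a <- stimulus_vector(stimulus, cfg)
  prev_pending <- net$pending
  if (cfg$decay < 1) net$v_int <- net$v_int * cfg$decay
  act <- which(a > 0)
  n_set <- 0L
  n_reset <- 0L
  if (length(act)) {
    g <- net$R[, act, drop = FALSE]
    net$v_int <- net$v_int +
      as.numeric(g^-1 %*% a[act]) * cfg$device$r_lrs_target
  }
  v_peak <- net$v_int
  fired <- logical(cfg$n_post)
  order <- if (cfg$n_post > 1L) sample.int(cfg$n_post) else 1L
  for (p in order) {
    if (net$v_int[p] >= cfg$n_fire_threshold) {
      if (cfg$stdp_enabled && length(act))
        n_set <- n_set + sum(net$R[p, act] > 2 * cfg$device$r_lrs_target)
      net <- .fire(net, p, a)
      fired[p] <- TRUE
    }
  }
  if (cfg$stdp_enabled) {
    land <- which(prev_pending & !fired)
    for (p in land) {
      if (length(act)) {
        n_reset <- n_reset + sum(net$R[p, act] < cfg$device$r_hrs_target / 2)
        net$R[p, act] <- sample_hrs_vec(cfg$device, length(act))
      }
      net$pending[p] <- FALSE
    }
  }
  net$epoch <- net$epoch + 1L
  list(net = net,
       events = list(epoch = net$epoch - 1L,
                     n_active = length(act),
                     v_peak = v_peak,
                     fired = fired,
                     n_set = n_set, n_reset = n_reset))
}

#' Explicitly discharge the internal potentials
#'
#' Used between recognition tests: resets every (or one) POST potential to
#' zero without any synaptic side effect.
#'
#' @inheritParams integrate_epoch
#' @param post_index POST to discharge, or \code{NULL} for all.
#' @return the updated network state.
#' @export
discharge <- function(net, post_index = NULL) {
  stopifnot(inherits(net, "memstdp_network"))
  if (is.null(post_index)) net$v_int[] <- 0
  else net$v_int[post_index] <- 0
  net
}
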