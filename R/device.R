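#' Device parameters for a 1T1R RRAM synapse
#'
#' Collects the behavioral parameters of a one-transistor/one-resistor
#' (1T1R) HfO2 RRAM synapse: the two binary resistance levels and the
#' voltage thresholds of the abrupt set (HRS to LRS, positive voltage) and
#' reset (LRS to HRS, negative voltage) transitions. The low-resistance
#' state (LRS) reached on set is dictated by the transistor compliance
#' current, itself fixed by the gate amplitude; the high-resistance state
#' (HRS) reached on reset is dictated by the top-electrode amplitude.
#'
#' @param r_lrs_target LRS resistance level in ohms (default 1e4). The two
#'   levels are configurable because the device window depends on the
#'   programming conditions; a ~100x window keeps the recognition levels of
#'   a learned network well separated.
#' @param r_hrs_target HRS resistance level in ohms (default 1e6).
#' @param v_set_threshold top-electrode voltage (V, positive) above which a
#'   gated device sets to LRS; default +1.0 V.
#' @param v_reset_threshold top-electrode voltage (V, negative) below which
#'   a gated device resets to HRS; default -1.5 V.
#' @param sigma_lrs,sigma_hrs log-scale spreads of the sampled LRS/HRS
#'   levels (log-normal, independent per switching event); default 0, i.e.
#'   deterministic binary levels.
#' @return an object of class \code{"device_params"}.
#' @examples
#' dp <- device_params()
#' dp
#' @export
device_params <- function(r_lrs_target = 1e4, r_hrs_target = 1e6,
                          v_set_threshold = 1.0, v_reset_threshold = -1.5,
                          sigma_lrs = 0, sigma_hrs = 0) {
  stopifnot(is.numeric(r_lrs_target), length(r_lrs_target) == 1L,
            is.numeric(r_hrs_target), length(r_hrs_target) == 1L)
  if (!(r_lrs_target > 0 && r_hrs_target > 0))
    stop("resistance targets must be positive", call. = FALSE)
  if (!(r_lrs_target < r_hrs_target))
    stop("r_lrs_target must be smaller than r_hrs_target", call. = FALSE)
  if (!(v_set_threshold > 0))
    stop("v_set_threshold must be positive", call. = FALSE)
  if (!(v_reset_threshold < 0))
    stop("v_reset_threshold must be negative", call. = FALSE)
  if (sigma_lrs < 0 || sigma_hrs < 0)
    stop("sigma_lrs and sigma_hrs must be non-negative", call. = FALSE)
  structure(list(r_lrs_target = r_lrs_target,
                 r_hrs_target = r_hrs_target,
                 v_set_threshold = v_set_threshold,
                 v_reset_threshold = v_reset_threshold,
                 sigma_lrs = sigma_lrs, sigma_hrs = sigma_hrs),
            class = "device_params")
}

#' @export
print.device_params <- function(x, ...) {
  cat("1T1R RRAM device parameters\n")
  cat(sprintf("  LRS target: %.3g ohm (sigma %.3g)\n", x$r_lrs_target, x$sigma_lrs))
  cat(sprintf("  HRS target: %.3g ohm (sigma %.3g)\n", x$r_hrs_target, x$sigma_hrs))
  cat(sprintf("  set threshold:   %+.2f V\n", x$v_set_threshold))
  cat(sprintf("  reset threshold: %+.2f V\n", x$v_reset_threshold))
  invisible(x)
}

#' Pulse timing and amplitudes of PRE and POST spikes
#'
#' The waveform geometry of the plasticity protocol. A PRE spike is a
#' rectangular gate pulse of width \code{t_gate} that enables the
#' transistor; a POST fire produces a bipolar feedback spike on the top
#' electrode: a positive pulse (onset at the fire time) that sets any gated
#' synapse, followed after \code{delay_neg} by a negative pulse that resets
#' any synapse whose gate is open at that later time. Outside feedback
#' pulses the top electrode sits at a small standing read bias.
#'
#' \code{delay_neg} defaults to \code{t_gate}, so the negative pulse cannot
#' reach back into the gate window that caused the fire but does overlap a
#' PRE gate opened in the following epoch; this is what turns noise frames
#' presented right after a fire into unselective depression.
#'
#' @param t_gate PRE gate pulse width, ms (default 10).
#' @param v_g_on full-scale gate amplitude, V (default 1.0); gray pixels use
#'   a graded fraction of it.
#' @param t_fb_pulse width of each POST feedback pulse, ms (default 1).
#' @param v_te_plus positive feedback amplitude, V (default +2.0, above the
#'   +1.0 V set threshold with margin for set-voltage fluctuations).
#' @param v_te_minus negative feedback amplitude, V (default -1.6).
#' @param delay_neg onset of the negative pulse after the fire, ms (default
#'   \code{t_gate}).
#' @param v_bias standing read bias on the top electrode, V (default -0.2);
#'   must be non-destructive.
#' @param eps_overlap minimum pulse overlap (ms) counted as a switching
#'   event; guards floating-point edge cases (default 0.01).
#' @return an object of class \code{"pulse_timing"}.
#' @examples
#' pulse_timing()                 # biological 10 ms timescale
#' timing_preset("accelerated")   # 100 us gate / 10 us feedback preset
#' @export
pulse_timing <- function(t_gate = 10, v_g_on = 1.0, t_fb_pulse = 1,
                         v_te_plus = 2.0, v_te_minus = -1.6,
                         delay_neg = t_gate, v_bias = -0.2,
                         eps_overlap = 0.01) {
  if (!(t_gate > 0)) stop("t_gate must be positive", call. = FALSE)
  if (!(t_fb_pulse > 0)) stop("t_fb_pulse must be positive", call. = FALSE)
  if (t_fb_pulse > t_gate)
    stop("t_fb_pulse must not exceed t_gate", call. = FALSE)
  if (!(delay_neg > 0)) stop("delay_neg must be positive", call. = FALSE)
  if (!(v_te_plus > 0)) stop("v_te_plus must be positive", call. = FALSE)
  if (!(v_te_minus < 0)) stop("v_te_minus must be negative", call. = FALSE)
  if (!(eps_overlap >= 0)) stop("eps_overlap must be non-negative", call. = FALSE)
  structure(list(t_gate = t_gate, v_g_on = v_g_on, t_fb_pulse = t_fb_pulse,
                 v_te_plus = v_te_plus, v_te_minus = v_te_minus,
                 delay_neg = delay_neg, v_bias = v_bias,
                 eps_overlap = eps_overlap),
            class = "pulse_timing")
}

#' @export
print.pulse_timing <- function(x, ...) {
  cat("PRE/POST pulse timing\n")
  cat(sprintf("  PRE gate: %.4g ms at V_G = %.2f V\n", x$t_gate, x$v_g_on))
  cat(sprintf("  POST feedback: %.4g ms pulses, %+.2f V then %+.2f V after %.4g ms\n",
              x$t_fb_pulse, x$v_te_plus, x$v_te_minus, x$delay_neg))
  cat(sprintf("  read bias: %+.2f V\n", x$v_bias))
  invisible(x)
}

#' Named timing presets
#'
#' \code{"default"} is the 10 ms biological timescale. \code{"accelerated"}
#' is the same protocol run 100x faster (100 us gate, 10 us feedback
#' pulses) with a raised positive feedback amplitude of 3.3 V that enables
#' the set transition at the 10 us timescale.
#'
#' @param name one of \code{"default"}, \code{"accelerated"}.
#' @return a \code{\link{pulse_timing}} object.
#' @export
timing_preset <- function(name = c("default", "accelerated")) {
  name <- match.arg(name)
  switch(name,
         default = pulse_timing(),
         accelerated = pulse_timing(t_gate = 0.1, t_fb_pulse = 0.01,
                                    v_te_plus = 3.3, delay_neg = 0.1,
                                    eps_overlap = 1e-4))
}

#' Check the joint validity of timing and device parameters
#'
#' The feedback amplitudes must exceed the switching thresholds and the
#' standing read bias must remain non-destructive.
#'
#' @param timing a \code{\link{pulse_timing}} object.
#' @param params a \code{\link{device_params}} object.
#' @return invisibly \code{TRUE}; signals an error otherwise.
#' @export
validate_timing <- function(timing, params) {
  stopifnot(inherits(timing, "pulse_timing"), inherits(params, "device_params"))
  if (abs(timing$v_te_plus) < params$v_set_threshold)
    stop("v_te_plus does not reach the set threshold", call. = FALSE)
  if (abs(timing$v_te_minus) < abs(params$v_reset_threshold))
    stop("v_te_minus does not reach the reset threshold", call. = FALSE)
  if (abs(timing$v_bias) >= min(params$v_set_threshold,
                                abs(params$v_reset_threshold)))
    stop("v_bias must be non-destructive (below both switching thresholds)",
         call. = FALSE)
  invisible(TRUE)
}

# Sample a fresh LRS / HRS level. With sigma = 0 the sample equals the
# target exactly (deterministic binary plasticity).
sample_lrs <- function(params) {
  if (params$sigma_lrs == 0) params$r_lrs_target
  else params$r_lrs_target * exp(stats::rnorm(1L, 0, params$sigma_lrs))
}

sample_hrs <- function(params) {
  if (params$sigma_hrs == 0) params$r_hrs_target
  else params$r_hrs_target * exp(stats::rnorm(1L, 0, params$sigma_hrs))
}

#' Create a single 1T1R synapse device
#'
#' @param params a \code{\link{device_params}} object.
#' @param state initial state, \code{"hrs"} or \code{"lrs"}, or a positive
#'   numeric resistance in ohms.
#' @return an object of class \code{"synapse_device"} with fields
#'   \code{params} and \code{resistance} (ohms; the synaptic weight is the
#'   conductance 1/resistance, siemens).
#' @examples
#' syn <- synapse_device(device_params(), "hrs")
#' syn <- program_pulse(syn, voltage = 1.0, width = 1)  # set to LRS
#' syn$resistance
#' @export
synapse_device <- function(params = device_params(), state = "hrs") {
  stopifnot(inherits(params, "device_params"))
  resistance <-
    if (is.numeric(state)) state
    else switch(match.arg(state, c("hrs", "lrs")),
                hrs = sample_hrs(params), lrs = sample_lrs(params))
  if (!(resistance > 0)) stop("resistance must be positive", call. = FALSE)
  structure(list(params = params, resistance = resistance),
            class = "synapse_device")
}

#' @export
print.synapse_device <- function(x, ...) {
  cat(sprintf("1T1R synapse: R = %.4g ohm (weight %.4g S)\n",
              x$resistance, 1 / x$resistance))
  invisible(x)
}

#' Apply a single programming pulse to a synapse
#'
#' Models the abrupt set/reset response measured with 1 ms pulses of
#' increasing amplitude: a gated device completes the transition to LRS for
#' voltages at or above the set threshold (+1 V by default) and to HRS at
#' or below the reset threshold (-1.5 V by default); intermediate voltages
#' leave the state unchanged. Switching is instantaneous and complete, so
#' repeating an identical pulse is idempotent when the variability spreads
#' are zero.
#'
#' @param device a \code{\link{synapse_device}}.
#' @param voltage top-electrode pulse amplitude, V.
#' @param width pulse width, ms; must be positive (the behavioral model is
#'   width-independent above threshold, but a non-positive width is a
#'   contract violation).
#' @param gate_on is the transistor gate enabled during the pulse? Both
#'   transitions require a conducting channel in the 1T1R stack.
#' @return the updated \code{synapse_device}.
#' @export
program_pulse <- function(device, voltage, width, gate_on = TRUE) {
  stopifnot(inherits(device, "synapse_device"))
  if (!is.numeric(width) || length(width) != 1L || !(width > 0))
    stop("pulse width must be a positive number", call. = FALSE)
  if (!gate_on) return(device)
  p <- device$params
  if (voltage >= p$v_set_threshold) {
    device$resistance <- sample_lrs(p)
  } else if (voltage <= p$v_reset_threshold) {
    device$resistance <- sample_hrs(p)
  }
  device
}

# Overlap length of two closed intervals [a1,a2], [b1,b2].
interval_overlap <- function(a1, a2, b1, b2) {
  max(0, min(a2, b2) - max(a1, b1))
}

#' Pulse-overlap STDP: apply one PRE/POST spike pair
#'
#' Computes the conductance change of one synapse caused by a PRE gate
#' pulse and a POST bipolar feedback spike separated by a delay
#' \code{delta_t = t_POST - t_PRE}. The PRE gate is open on
#' \code{[0, t_gate]} (PRE time origin); the POST positive pulse starts at
#' \code{delta_t} and the negative pulse at \code{delta_t + delay_neg}.
#' Any overlap of the open gate with the positive pulse (beyond the
#' \code{eps_overlap} guard) triggers a full set transition; overlap with
#' the negative pulse triggers a full reset. When both would occur the
#' pulses act in chronological order, so the later one determines the final
#' state. For \code{|delta_t| >= t_gate} the device characterization shows
#' no conductance change and the operation is the identity.
#'
#' The returned plasticity ratio \code{eta = R_before / R_after} is > 1 for
#' potentiation, < 1 for depression, and 1 for no change; a device already
#' at the destination level yields \code{eta} of 1 (state-dependent,
#' multiplicative plasticity).
#'
#' @param device a \code{\link{synapse_device}}.
#' @param delta_t spike delay t_POST - t_PRE, ms; must be finite.
#' @param timing a \code{\link{pulse_timing}} object.
#' @return a list with elements \code{device} (updated) and \code{eta}.
#' @examples
#' dp <- device_params()
#' tm <- pulse_timing()
#' apply_spike_pair(synapse_device(dp, "hrs"), 3, tm)$eta    # potentiation
#' apply_spike_pair(synapse_device(dp, "lrs"), -7, tm)$eta   # depression
#' apply_spike_pair(synapse_device(dp, "lrs"), 15, tm)$eta   # no overlap
#' @export
apply_spike_pair <- function(device, delta_t, timing = pulse_timing()) {
  stopifnot(inherits(device, "synapse_device"),
            inherits(timing, "pulse_timing"))
  if (!is.numeric(delta_t) || length(delta_t) != 1L || !is.finite(delta_t))
    stop("delta_t must be a finite number", call. = FALSE)
  r_before <- device$resistance
  if (abs(delta_t) < timing$t_gate) {
    tg <- timing$t_gate
    tf <- timing$t_fb_pulse
    eps <- timing$eps_overlap
    pos_on <- delta_t
    neg_on <- delta_t + timing$delay_neg
    ov_pos <- interval_overlap(0, tg, pos_on, pos_on + tf)
    ov_neg <- interval_overlap(0, tg, neg_on, neg_on + tf)
    events <- list()
    if (ov_pos > eps) events[[length(events) + 1L]] <- c(pos_on, +1)
    if (ov_neg > eps) events[[length(events) + 1L]] <- c(neg_on, -1)
    if (length(events) > 1L)
      events <- events[order(vapply(events, `[`, numeric(1), 1L))]
    for (ev in events) {
      device$resistance <-
        if (ev[2] > 0) sample_lrs(device$params) else sample_hrs(device$params)
    }
  }
  list(device = device, eta = r_before / device$resistance)
}

#' Deterministic STDP characteristic surface
#'
#' Evaluates the plasticity ratio \code{eta = R0 / R} over a grid of spike
#' delays for a set of initial resistances, with variability disabled
#' (sigma = 0), reproducing the measured STDP characteristic: potentiation
#' (\code{eta > 1}) only for \code{0 < delta_t < t_gate} starting above the
#' LRS level, depression (\code{eta < 1}) only for
#' \code{-t_gate < delta_t < 0} starting below the HRS level.
#'
#' @param r0_values initial resistances R0, ohms.
#' @param delta_t_grid spike delays, ms; must be non-empty.
#' @param timing a \code{\link{pulse_timing}}.
#' @param params a \code{\link{device_params}}; its sigmas are forced to 0.
#' @return a data frame with columns \code{delta_t_ms}, \code{r0_ohm},
#'   \code{eta}.
#' @examples
#' head(stdp_curve(c(1e6, 1e4), seq(-12, 12, 1)))
#' @export
stdp_curve <- function(r0_values, delta_t_grid, timing = pulse_timing(),
                       params = device_params()) {
  if (length(delta_t_grid) == 0L)
    stop("delta_t_grid must be non-empty", call. = FALSE)
  stopifnot(all(r0_values > 0))
  p0 <- params
  p0$sigma_lrs <- 0
  p0$sigma_hrs <- 0
  grid <- expand.grid(delta_t_ms = delta_t_grid, r0_ohm = r0_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$eta <- mapply(function(dt, r0) {
    apply_spike_pair(synapse_device(p0, r0), dt, timing)$eta
  }, grid$delta_t_ms, grid$r0_ohm)
  grid
}

#' Gray-level to LRS resistance mapping
#'
#' A graded gate amplitude limits the compliance current during set and
#' therefore the LRS conductance. The mapping is conductance-linear in the
#' gate amplitude, \code{1/R = (v_g / v_g_full) / r_lrs_target}, clipped
#' below at the HRS conductance, which is the simplest monotone choice: at
#' full scale it returns the LRS target exactly and it is non-increasing in
#' resistance as \code{v_g} grows.
#'
#' @param v_g graded gate amplitude, V; must satisfy
#'   \code{0 < v_g <= v_g_full}.
#' @param params a \code{\link{device_params}}.
#' @param v_g_full full-scale gate amplitude, V.
#' @return LRS resistance target in ohms for that gate amplitude.
#' @examples
#' gray_lrs_map(1.0, device_params(), 1.0)   # full scale: 1e4
#' gray_lrs_map(0.5, device_params(), 1.0)   # half scale: 2e4
#' @export
gray_lrs_map <- function(v_g, params = device_params(), v_g_full = 1.0) {
  stopifnot(inherits(params, "device_params"), v_g_full > 0)
  if (!is.numeric(v_g) || any(v_g <= 0) || any(v_g > v_g_full))
    stop("v_g must satisfy 0 < v_g <= v_g_full", call. = FALSE)
  g <- (v_g / v_g_full) / params$r_lrs_target
  pmin(1 / pmax(g, 1 / params$r_hrs_target), params$r_hrs_target)
}
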