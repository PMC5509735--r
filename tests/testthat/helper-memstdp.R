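# Shared fixtures for the memstdp test-suite. Everything is generated in
# code; no binary fixtures.

default_params <- function(...) device_params(...)
default_timing <- function(...) pulse_timing(...)

R_LRS <- 1e4
R_HRS <- 1e6

# Ideal post-training weights for a 1-POST 4x4 network: pattern pixels in
# LRS, background in HRS.
ideal_weights <- function(pattern, params = device_params()) {
  mask <- as_pre_vector(pattern) > 0
  matrix(ifelse(mask, params$r_lrs_target, params$r_hrs_target), 1L)
}

# One-phase schedule under the study defaults.
static_schedule <- function(pattern, n_epochs, p_pattern = 0.5,
                            noise_density = 0.03) {
  build_schedule(list(training_phase(pattern, n_epochs)),
                 p_pattern = p_pattern, noise_density = noise_density)
}

# Extract per-POST 0-based fire epochs from a training log.
fire_epochs_of <- function(log) {
  lapply(seq_len(log$config$n_post), function(p)
    log$events$epoch[log$events[[paste0("fired_", p)]]])
}

# Is POST p's row locked to exactly image `which` of a disjoint pair
# (pattern pixels LRS, other image's pixels HRS)?
locked_to <- function(r_row, img_own, img_other, cut = 2 * R_LRS) {
  own <- as_pre_vector(img_own) > 0
  oth <- as_pre_vector(img_other) > 0
  all(r_row[own] <= cut) && !any(r_row[oth] <= cut)
}
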