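#' Describe one training phase
#'
#' @param image an \code{\link{image_grid}}, or a list of image grids
#'   presented alternately (drawn uniformly on each pattern epoch, as in
#'   the two-neuron experiment).
#' @param n_epochs number of epochs in the phase; must be positive.
#' @return a phase descriptor for \code{\link{build_schedule}}.
#' @export
training_phase <- function(image, n_epochs) {
  if (!(n_epochs >= 1)) stop("n_epochs must be positive", call. = FALSE)
  imgs <- if (is.list(image)) image else list(image)
  lapply(imgs, function(im) stopifnot(is.matrix(im)))
  list(images = imgs, n_epochs = as.integer(n_epochs))
}

#' Build a stochastic stimulus schedule
#'
#' Materializes the epoch-by-epoch stimulus sequence of the stochastic
#' training protocol: in every 10 ms epoch either the phase's pattern or a
#' sparse random noise frame is presented, drawn independently with
#' pattern probability \code{p_pattern} (noise and pattern epochs are
#' mutually exclusive). Noise frames have each pixel active independently
#' with probability \code{noise_density}. The schedule is fully
#' reproducible given \code{seed}.
#'
#' @param phases list of \code{\link{training_phase}} descriptors; must be
#'   non-empty, all images on the same grid.
#' @param p_pattern probability of a pattern epoch (default 0.5).
#' @param noise_density noise pixel activation probability (default 0.03).
#' @param seed optional integer seed for the schedule draws.
#' @return an object of class \code{"epoch_schedule"}: epoch-indexed
#'   stimulus kinds, materialized images, and phase labels.
#' @examples
#' sch <- build_schedule(list(training_phase(builtin_pattern("diag4"), 300)),
#'                       seed = 1)
#' table(sch$kind)
#' @export
build_schedule <- function(phases, p_pattern = 0.5, noise_density = 0.03,
                           seed = NULL) {
  if (!is.list(phases) || length(phases) == 0L)
    stop("phases must be a non-empty list", call. = FALSE)
  if (p_pattern < 0 || p_pattern > 1)
    stop("p_pattern must lie in [0, 1]", call. = FALSE)
  if (noise_density < 0 || noise_density > 1)
    stop("noise_density must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dims <- dim(phases[[1]]$images[[1]])
  kind <- character(0)
  phase <- integer(0)
  images <- list()
  for (k in seq_along(phases)) {
    ph <- phases[[k]]
    for (im in ph$images)
      if (!all(dim(im) == dims))
        stop("all phase images must share one grid size", call. = FALSE)
    is_pat <- stats::runif(ph$n_epochs) < p_pattern
    pick <- sample.int(length(ph$images), ph$n_epochs, replace = TRUE)
    for (e in seq_len(ph$n_epochs)) {
      images[[length(images) + 1L]] <-
        if (is_pat[e]) ph$images[[pick[e]]]
        else make_noise(dims[1], dims[2], noise_density)
    }
    kind <- c(kind, ifelse(is_pat, "pattern", "noise"))
    phase <- c(phase, rep.int(k, ph$n_epochs))
  }
  structure(list(kind = kind, images = images, phase = phase,
                 phase_images = lapply(phases, `[[`, "images"),
                 n_pre = prod(dims), dims = dims,
                 p_pattern = p_pattern, noise_density = noise_density,
                 seed = seed),
            class = "epoch_schedule")
}

#' @export
print.epoch_schedule <- function(x, ...) {
  cat(sprintf("epoch schedule: %d epochs, %d phase(s), %d x %d grid\n",
              length(x$kind), max(x$phase), x$dims[1], x$dims[2]))
  cat(sprintf("  pattern epochs: %d (p = %.2f), noise density %.3f\n",
              sum(x$kind == "pattern"), x$p_pattern, x$noise_density))
  invisible(x)
}

#' Does a synapse row adhere to a pattern?
#'
#' A POST adheres to an image when every pattern synapse is in (or near)
#' the LRS and every background synapse is in (or near) the HRS:
#' \code{R <= lrs_factor * r_lrs_target} for pattern pixels and
#' \code{R >= hrs_factor * r_hrs_target} for background pixels.
#'
#' @param r_row numeric vector of synapse resistances over PREs, or an
#'   \code{n_post x n_pre} matrix (then a vector over POSTs is returned).
#' @param pattern an \code{\link{image_grid}} or activation vector.
#' @param params a \code{\link{device_params}}.
#' @param lrs_factor,hrs_factor adherence band factors (defaults 2 and
#'   0.5).
#' @return logical (one value per POST row).
#' @export
adheres_to <- function(r_row, pattern, params = device_params(),
                       lrs_factor = 2, hrs_factor = 0.5) {
  mask <- (if (is.matrix(pattern)) as_pre_vector(pattern) else pattern) > 0
  R <- if (is.matrix(r_row)) r_row else matrix(r_row, nrow = 1L)
  stopifnot(ncol(R) == length(mask))
  lo <- lrs_factor * params$r_lrs_target
  hi <- hrs_factor * params$r_hrs_target
  apply(R, 1L, function(r) all(r[mask] <= lo) && all(r[!mask] >= hi))
}

#' Run stochastic unsupervised training
#'
#' Steps a network through an epoch schedule with STDP enabled, recording
#' the weight trajectory, internal potential traces, and fire events.
#' Pattern synapses are selectively potentiated (fires coincide with
#' pattern presentations) while noise frames presented right after a fire
#' depress whatever they touch, driving the background to HRS; the final
#' state is independent of the initial weight configuration.
#'
#' @param config a \code{\link{network_config}} (with
#'   \code{stdp_enabled = TRUE}).
#' @param init initial weights: \code{"hrs"}, \code{"lrs"},
#'   \code{"random"}, or an explicit resistance matrix (see
#'   \code{\link{new_network}}).
#' @param schedule an \code{\link{epoch_schedule}} whose grid matches
#'   \code{config$n_pre}.
#' @param seed optional integer seed covering every stochastic element of
#'   the run (initial random weights, device variability, fire tie-breaks).
#' @param record_weights record the full per-epoch resistance trajectory
#'   (default \code{TRUE}).
#' @return an object of class \code{"experiment_log"} with elements:
#'   \code{events} (data frame: epoch, phase, kind, n_active, per-POST
#'   peak potential and fire flag columns, switching counts),
#'   \code{weights} (epoch x POST x PRE resistance array, if recorded),
#'   \code{snapshots} (resistance matrices at epoch 0 and every phase
#'   end), \code{net} (final state), plus the configuration, schedule
#'   metadata, seed, and a config hash.
#' @examples
#' cfg <- network_config()
#' sch <- build_schedule(list(training_phase(builtin_pattern("diag4"), 100)),
#'                       seed = 7)
#' log <- run_training(cfg, "hrs", sch, seed = 7)
#' summary(log)
#' @export
run_training <- function(config, init = "hrs", schedule, seed = NULL,
                         record_weights = TRUE) {
  stopifnot(inherits(config, "network_config"),
            inherits(schedule, "epoch_schedule"))
  if (schedule$n_pre != config$n_pre)
    stop(sprintf("schedule grid (%d pixels) does not match n_pre (%d)",
                 schedule$n_pre, config$n_pre), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  net <- new_network(config, init)
  n_ep <- length(schedule$kind)
  np <- config$n_post
  v_peak <- matrix(NA_real_, n_ep, np)
  fired <- matrix(FALSE, n_ep, np)
  n_active <- integer(n_ep)
  n_set <- integer(n_ep)
  n_reset <- integer(n_ep)
  weights <- if (record_weights)
    array(NA_real_, c(n_ep, np, config$n_pre)) else NULL
  snapshots <- list(`0` = net$R)
  phase_ends <- cumsum(tabulate(schedule$phase))
  for (e in seq_len(n_ep)) {
    out <- step_epoch(net, schedule$images[[e]])
    net <- out$net
    v_peak[e, ] <- out$events$v_peak
    fired[e, ] <- out$events$fired
    n_active[e] <- out$events$n_active
    n_set[e] <- out$events$n_set
    n_reset[e] <- out$events$n_reset
    if (record_weights) weights[e, , ] <- net$R
    if (e %in% phase_ends) snapshots[[as.character(e)]] <- net$R
  }
  events <- data.frame(epoch = seq_len(n_ep) - 1L,
                       phase = schedule$phase,
                       kind = schedule$kind,
                       n_active = n_active,
                       n_set = n_set, n_reset = n_reset)
  colnames(v_peak) <- paste0("v_peak_", seq_len(np))
  colnames(fired) <- paste0("fired_", seq_len(np))
  events <- cbind(events, as.data.frame(v_peak), as.data.frame(fired))
  structure(list(config = config,
                 schedule = schedule[c("kind", "phase", "phase_images",
                                       "p_pattern", "noise_density", "dims")],
                 events = events, weights = weights, snapshots = snapshots,
                 net = net, seed = seed,
                 config_hash = config_hash(config)),
            class = "experiment_log")
}

#' First epoch of full pattern adherence
#'
#' Scans a recorded weight trajectory for the first epoch at which a POST
#' adheres to a pattern (see \code{\link{adheres_to}}).
#'
#' @param log an \code{\link{run_training}} log with recorded weights.
#' @param pattern target pattern.
#' @param post POST index.
#' @param from 0-based epoch at which to start scanning.
#' @return the 0-based epoch index, or \code{NA} if adherence is never
#'   reached.
#' @export
first_adherence_epoch <- function(log, pattern, post = 1L, from = 0L) {
  stopifnot(inherits(log, "experiment_log"), !is.null(log$weights))
  mask <- as_pre_vector(pattern) > 0
  p <- log$config$device
  lo <- 2 * p$r_lrs_target
  hi <- p$r_hrs_target / 2
  W <- log$weights[, post, , drop = FALSE]
  n_ep <- dim(W)[1]
  for (e in seq_len(n_ep)) {
    if (e - 1L < from) next
    r <- W[e, 1L, ]
    if (all(r[mask] <= lo) && all(r[!mask] >= hi)) return(e - 1L)
  }
  NA_integer_
}

#' Enumerate all k-active test patterns
#'
#' All binary images with exactly \code{n_active} of \code{n_pixels}
#' pixels active, ordered lexicographically by the tuple of active pixel
#' indices (row-major pixel order). The 4x4 recognition sweep enumerates
#' choose(16, 4) = 1820 patterns.
#'
#' @param n_pixels total pixel count.
#' @param n_active number of active pixels; must satisfy
#'   \code{0 <= n_active <= n_pixels}.
#' @return a logical matrix with one pattern per row.
#' @examples
#' nrow(enumerate_test_patterns(16, 4))  # 1820
#' @export
enumerate_test_patterns <- function(n_pixels, n_active) {
  stopifnot(n_pixels >= 0, n_active >= 0)
  if (n_active > n_pixels)
    stop("n_active must not exceed n_pixels", call. = FALSE)
  if (n_active == 0L)
    return(matrix(FALSE, 1L, n_pixels))
  combos <- utils::combn(n_pixels, n_active)
  out <- matrix(FALSE, ncol(combos), n_pixels)
  for (i in seq_len(ncol(combos))) out[i, combos[, i]] <- TRUE
  out
}

#' Recognition sweep over enumerated test patterns
#'
#' Presents every test pattern to a trained network with STDP disabled:
#' one integration epoch per pattern, record the internal potential and
#' whether it crossed the recognition threshold, then discharge for the
#' next test. For ideally learned weights the potential depends only on
#' the overlap with the training pattern, so the sweep collapses to one
#' sub-distribution per overlap count, and a threshold placed between the
#' top two levels fires for the training pattern alone (no false
#' positives). The default threshold of 3.5 LRS units sits midway between
#' the ideal overlap-3 and overlap-4 levels.
#'
#' @param trained a trained \code{\link{new_network}} state or an
#'   \code{n_post x n_pre} resistance matrix.
#' @param training_pattern the pattern used during training (for overlap
#'   bookkeeping).
#' @param threshold recognition fire threshold, LRS units; must be
#'   positive.
#' @param config a \code{\link{network_config}} (used when \code{trained}
#'   is a bare matrix); STDP is forced off either way.
#' @param test_patterns optional pattern matrix from
#'   \code{\link{enumerate_test_patterns}}; defaults to all patterns with
#'   the training pattern's active count.
#' @param post POST index to monitor.
#' @return an object of class \code{"recognition_result"}: a data frame
#'   with columns \code{pattern_id}, \code{overlap}, \code{v_int},
#'   \code{fired}, with the threshold as an attribute.
#' @export
run_recognition <- function(trained, training_pattern, threshold = 3.5,
                            config = NULL, test_patterns = NULL,
                            post = 1L) {
  if (inherits(trained, "memstdp_network")) {
    config <- trained$config
    R <- trained$R
  } else {
    stopifnot(is.matrix(trained), inherits(config, "network_config"))
    R <- trained
  }
  if (!(threshold > 0)) stop("threshold must be positive", call. = FALSE)
  config$stdp_enabled <- FALSE
  pat <- stimulus_vector(training_pattern, config)
  if (is.null(test_patterns))
    test_patterns <- enumerate_test_patterns(config$n_pre, sum(pat > 0))
  net <- structure(list(config = config, R = R,
                        v_int = numeric(config$n_post),
                        pending = logical(config$n_post), epoch = 0L),
                   class = "memstdp_network")
  n <- nrow(test_patterns)
  v <- numeric(n)
  fired <- logical(n)
  for (i in seq_len(n)) {
    net <- integrate_epoch(net, post, as.numeric(test_patterns[i, ]))
    v[i] <- net$v_int[post]
    fired[i] <- v[i] >= threshold
    net <- discharge(net, post)
  }
  overlap <- as.integer(test_patterns %*% (pat > 0))
  structure(data.frame(pattern_id = seq_len(n), overlap = overlap,
                       v_int = v, fired = fired),
            threshold = threshold,
            class = c("recognition_result", "data.frame"))
}

#' @export
summary.recognition_result <- function(object, ...) {
  by_overlap <- split(object$v_int, object$overlap)
  tab <- data.frame(overlap = as.integer(names(by_overlap)),
                    n_patterns = lengths(by_overlap),
                    v_min = vapply(by_overlap, min, numeric(1)),
                    v_max = vapply(by_overlap, max, numeric(1)),
                    n_fired = vapply(split(object$fired, object$overlap),
                                     sum, numeric(1)))
  rownames(tab) <- NULL
  structure(list(by_overlap = tab,
                 threshold = attr(object, "threshold"),
                 n_distinct_levels = length(unique(signif(object$v_int, 10))),
                 n_fired = sum(object$fired)),
            class = "summary.recognition_result")
}

#' @export
print.summary.recognition_result <- function(x, ...) {
  cat(sprintf("recognition sweep: %d patterns, threshold %.3g LRS units\n",
              sum(x$by_overlap$n_patterns), x$threshold))
  cat(sprintf("  distinct potential levels: %d; fires: %d\n",
              x$n_distinct_levels, x$n_fired))
  print(x$by_overlap)
  invisible(x)
}

#' @export
plot.recognition_result <- function(x, ...) {
  graphics::plot(stats::ecdf(x$v_int),
                 main = "Recognition sweep: internal potential",
                 xlab = "V_int (LRS units)", ylab = "cumulative fraction",
                 ...)
  graphics::abline(v = attr(x, "threshold"), lty = 2)
  invisible(x)
}

#' Two-neuron tracking of perimeter-shifted patterns
#'
#' The dynamic tracking experiment: a 3x3 retina drives two POSTs with
#' winner-take-all inhibition. Phase 1 trains the two disjoint starting
#' images (presented alternately with noise) until each POST specializes
#' to one of them; each following phase shifts both images one step
#' counter-clockwise along the border cycle and retrains, so a POST locked
#' to an image only needs to potentiate the pixel entering the image and
#' depress the pixel leaving it - two switched synapses per POST per
#' shift.
#'
#' @param config a 2-POST \code{\link{network_config}}.
#' @param patterns list of two disjoint 3x3 \code{\link{image_grid}}s.
#' @param n_shift_steps number of one-cell perimeter shifts after the
#'   static phase (default 4).
#' @param epochs_per_phase epochs per training phase (default 1000).
#' @param p_pattern,noise_density stochastic schedule parameters.
#' @param init initial weights; defaults to \code{"lrs"}: the two-neuron
#'   competition requires both POSTs to be fire-capable from the start
#'   (from an all-HRS preparation the first neuron to specialize
#'   permanently starves the other through lateral inhibition, because a
#'   neuron with no low-resistance synapse can never accumulate to
#'   threshold between inhibition events).
#' @param seed optional integer seed.
#' @return an object of class \code{"tracking_log"}: the underlying
#'   \code{\link{run_training}} log, per-phase-end resistance snapshots,
#'   the POST-to-image assignment at the end of each phase, and the
#'   per-POST count of synapses that changed binary state between
#'   consecutive phase ends.
#' @export
run_tracking <- function(config, patterns, n_shift_steps = 4L,
                         epochs_per_phase = 1000L, p_pattern = 0.5,
                         noise_density = 0.03, init = "lrs", seed = NULL) {
  stopifnot(inherits(config, "network_config"), is.list(patterns),
            length(patterns) == 2L)
  if (config$n_post != 2L)
    stop("run_tracking requires a 2-POST configuration", call. = FALSE)
  m1 <- as_pre_vector(patterns[[1]]) > 0
  m2 <- as_pre_vector(patterns[[2]]) > 0
  if (any(m1 & m2))
    stop("the two starting patterns must be disjoint", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  phases <- lapply(0:n_shift_steps, function(k) {
    training_phase(lapply(patterns, shift_perimeter, steps = k),
                   epochs_per_phase)
  })
  schedule <- build_schedule(phases, p_pattern, noise_density)
  log <- run_training(config, init, schedule, record_weights = FALSE)
  cut <- sqrt(config$device$r_lrs_target * config$device$r_hrs_target)
  snaps <- log$snapshots[-1L]  # phase-end snapshots
  n_phase <- length(snaps)
  changed <- matrix(NA_integer_, config$n_post, max(n_phase - 1L, 0L))
  if (n_phase > 1L) {
    for (k in 2:n_phase) {
      prev <- snaps[[k - 1L]] <= cut
      now <- snaps[[k]] <= cut
      changed[, k - 1L] <- rowSums(prev != now)
    }
  }
  adh <- array(NA, c(config$n_post, 2L, n_phase))
  for (k in seq_len(n_phase)) {
    for (im in 1:2) {
      pat_k <- shift_perimeter(patterns[[im]], k - 1L)
      adh[, im, k] <- adheres_to(snaps[[k]], pat_k, config$device)
    }
  }
  structure(list(log = log, phase_end_R = snaps, changed = changed,
                 adherence = adh, binary_cutoff = cut,
                 patterns = patterns, n_shift_steps = n_shift_steps,
                 seed = seed),
            class = "tracking_log")
}

#' @export
print.tracking_log <- function(x, ...) {
  n_phase <- dim(x$adherence)[3]
  cat(sprintf("2-POST tracking: %d phases (%d shifts)\n",
              n_phase, x$n_shift_steps))
  for (k in seq_len(n_phase)) {
    a <- x$adherence[, , k]
    lab <- apply(a, 1L, function(row) {
      w <- which(row)
      if (length(w) == 1L) sprintf("image %d", w)
      else if (length(w) == 0L) "none" else "both"
    })
    cat(sprintf("  phase %d: POST1 -> %s, POST2 -> %s\n", k, lab[1], lab[2]))
  }
  if (ncol(x$changed) > 0) {
    cat("  synapses changing binary state per shift phase:\n")
    print(x$changed)
  }
  invisible(x)
}
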