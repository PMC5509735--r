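#' Hash a configuration object
#'
#' MD5 of the serialized configuration, recorded in every experiment log
#' so that outputs can be traced back to the exact parameter set.
#'
#' @param config any serializable configuration object.
#' @return a hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' @export
print.experiment_log <- function(x, ...) {
  n_ep <- nrow(x$events)
  fired_cols <- grep("^fired_", names(x$events))
  cat(sprintf("experiment log: %d epochs, %d phase(s), %d fire event(s)\n",
              n_ep, max(x$events$phase), sum(as.matrix(x$events[fired_cols]))))
  cat(sprintf("  config hash %s; seed %s\n", x$config_hash,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Summarize a training log
#'
#' Per-phase report: epochs, fire and switching-event counts, adherence
#' verdicts of every POST against each of the phase's training images at
#' phase end, and the number of synapses changing binary state between
#' consecutive phase-end snapshots.
#'
#' @param object an \code{\link{run_training}} log.
#' @param ... unused.
#' @return an object of class \code{"summary.experiment_log"} (a per-phase
#'   data frame plus metadata).
#' @export
summary.experiment_log <- function(object, ...) {
  ev <- object$events
  if (nrow(ev) == 0L) stop("empty experiment log", call. = FALSE)
  cfg <- object$config
  fired_cols <- grep("^fired_", names(ev))
  n_phase <- max(ev$phase)
  phase_ends <- cumsum(tabulate(ev$phase, n_phase))
  cut <- sqrt(cfg$device$r_lrs_target * cfg$device$r_hrs_target)
  rows <- lapply(seq_len(n_phase), function(k) {
    in_k <- ev$phase == k
    snap <- object$snapshots[[as.character(phase_ends[k])]]
    imgs <- object$schedule$phase_images[[k]]
    adh <- vapply(imgs, function(im) adheres_to(snap, im, cfg$device),
                  logical(cfg$n_post))
    adh <- matrix(adh, nrow = cfg$n_post)
    verdict <- apply(adh, 1L, function(row) {
      w <- which(row)
      if (length(w)) paste0("image", w, collapse = "+") else "none"
    })
    prev <- if (k == 1L) object$snapshots[["0"]]
            else object$snapshots[[as.character(phase_ends[k - 1L])]]
    data.frame(phase = k,
               epochs = sum(in_k),
               fires = sum(as.matrix(ev[in_k, fired_cols, drop = FALSE])),
               n_set = sum(ev$n_set[in_k]),
               n_reset = sum(ev$n_reset[in_k]),
               adherent = paste(verdict, collapse = " / "),
               changed_synapses = sum((prev <= cut) != (snap <= cut)))
  })
  structure(list(phases = do.call(rbind, rows),
                 n_post = cfg$n_post,
                 config_hash = object$config_hash),
            class = "summary.experiment_log")
}

#' @export
print.summary.experiment_log <- function(x, ...) {
  cat(sprintf("training summary (%d POST%s)\n", x$n_post,
              if (x$n_post > 1) "s" else ""))
  print(x$phases, row.names = FALSE)
  invisible(x)
}

#' @rdname summary.experiment_log
#' @param log an \code{\link{run_training}} log.
#' @export
summarize <- function(log) summary(log)

#' @export
plot.experiment_log <- function(x, post = 1L, ...) {
  if (is.null(x$weights))
    stop("log was recorded without weights; nothing to plot", call. = FALSE)
  W <- 1 / x$weights[, post, ]  # conductances, siemens
  graphics::matplot(x$events$epoch, W, type = "l", lty = 1,
                    xlab = "epoch", ylab = "synaptic weight 1/R (S)",
                    main = sprintf("Synaptic weights, POST %d", post), ...)
  pe <- cumsum(tabulate(x$events$phase))
  graphics::abline(v = pe[-length(pe)], lty = 3)
  invisible(x)
}

#' Write an experiment log as JSON lines
#'
#' One JSON record per epoch: epoch index, phase, stimulus kind, active
#' pixel count, per-POST peak potential and fire flag, and switching-event
#' counts; a header record carries the seed and config hash. The format is
#' line-diffable, which the test-suite relies on for determinism checks.
#'
#' @param log an \code{\link{run_training}} log.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_log_jsonl <- function(log, path) {
  ev <- log$events
  con <- file(path, "w")
  on.exit(close(con))
  header <- list(type = "header", n_epochs = nrow(ev),
                 n_post = log$config$n_post, n_pre = log$config$n_pre,
                 seed = log$seed, config_hash = log$config_hash)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, null = "null"), con)
  vp <- as.matrix(ev[grep("^v_peak_", names(ev))])
  fi <- as.matrix(ev[grep("^fired_", names(ev))])
  for (i in seq_len(nrow(ev))) {
    rec <- list(epoch = ev$epoch[i], phase = ev$phase[i], kind = ev$kind[i],
                n_active = ev$n_active[i],
                v_peak = round(unname(vp[i, ]), 6),
                fired = unname(fi[i, ]),
                n_set = ev$n_set[i], n_reset = ev$n_reset[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Write weight snapshots as CSV grids
#'
#' Each phase-boundary snapshot is written twice: resistances in ohms and
#' weights 1/R in siemens, one file per snapshot and POST, pixels laid out
#' on the image grid.
#'
#' @param log an \code{\link{run_training}} log.
#' @param dir output directory (created if missing).
#' @return the written file paths, invisibly.
#' @export
write_weights_csv <- function(log, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dims <- log$schedule$dims
  paths <- character(0)
  for (nm in names(log$snapshots)) {
    snap <- log$snapshots[[nm]]
    for (p in seq_len(nrow(snap))) {
      grid_r <- matrix(snap[p, ], dims[1], dims[2], byrow = TRUE)
      f1 <- file.path(dir, sprintf("weights_epoch%s_post%d_ohm.csv", nm, p))
      f2 <- file.path(dir, sprintf("weights_epoch%s_post%d_siemens.csv", nm, p))
      utils::write.table(grid_r, f1, sep = ",", row.names = FALSE,
                         col.names = FALSE)
      utils::write.table(1 / grid_r, f2, sep = ",", row.names = FALSE,
                         col.names = FALSE)
      paths <- c(paths, f1, f2)
    }
  }
  invisible(paths)
}

# ---- configuration files ----------------------------------------------

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("unknown configuration key%s in %s: %s",
                 if (length(extra) > 1) "s" else "", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
}

build_section <- function(section, constructor, where, extra_args = list()) {
  section <- if (is.null(section)) list() else section
  check_keys(section, names(formals(constructor)), where)
  do.call(constructor, utils::modifyList(extra_args, section))
}

resolve_pattern <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) {
    if (file.exists(spec)) read_pattern(spec) else builtin_pattern(spec)
  } else if (is.list(spec)) {
    image_grid(do.call(rbind, lapply(spec, as.numeric)))
  } else stop("pattern must be a name, a file path, or a row list",
              call. = FALSE)
}

#' Load and validate a run configuration
#'
#' Reads a flat YAML document describing a full experiment: optional
#' \code{preset} (\code{"accelerated"} swaps in the 100x faster timing),
#' \code{device}, \code{timing} and \code{network} sections overriding
#' individual defaults, a \code{protocol} section (pattern name/file or a
#' phase list, schedule probabilities, initial weights, recognition
#' threshold, tracking geometry), the mandatory \code{seed}, and an
#' \code{output} directory. Unknown keys anywhere are rejected with the
#' offending key named; cross-parameter invariants (pulse widths,
#' switching margins, read bias) are validated on load.
#'
#' @param path path to a YAML configuration file.
#' @return an object of class \code{"run_config"}: validated
#'   \code{device}, \code{timing}, \code{network} objects plus the
#'   protocol parameter list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  check_keys(raw, c("preset", "seed", "device", "timing", "network",
                    "protocol", "output"), "top level")
  device <- build_section(raw$device, device_params, "device")
  timing_defaults <- if (identical(raw$preset, "accelerated"))
    timing_preset("accelerated") else timing_preset("default")
  timing_section <- if (is.null(raw$timing)) list() else raw$timing
  check_keys(timing_section, names(formals(pulse_timing)), "timing")
  timing <- do.call(pulse_timing,
                    utils::modifyList(unclass(timing_defaults),
                                      timing_section))
  net_section <- if (is.null(raw$network)) list() else raw$network
  check_keys(net_section,
             setdiff(names(formals(network_config)), c("device", "timing")),
             "network")
  network <- do.call(network_config,
                     c(list(device = device, timing = timing), net_section))
  proto <- if (is.null(raw$protocol)) list() else raw$protocol
  check_keys(proto, c("pattern", "patterns", "phases", "n_epochs",
                      "p_pattern", "noise_density", "init",
                      "recognition_threshold", "n_shift_steps",
                      "epochs_per_phase"), "protocol")
  proto_defaults <- list(n_epochs = 300L, p_pattern = 0.5,
                         noise_density = 0.03, init = "hrs",
                         recognition_threshold = 3.5, n_shift_steps = 4L,
                         epochs_per_phase = 1000L)
  proto <- utils::modifyList(proto_defaults, proto)
  if (!is.null(proto$pattern)) proto$pattern <- resolve_pattern(proto$pattern)
  if (!is.null(proto$patterns))
    proto$patterns <- lapply(proto$patterns, resolve_pattern)
  if (!is.null(proto$phases)) {
    proto$phases <- lapply(proto$phases, function(ph) {
      check_keys(ph, c("pattern", "n_epochs"), "protocol$phases")
      training_phase(resolve_pattern(ph$pattern), ph$n_epochs)
    })
  }
  structure(list(device = device, timing = timing, network = network,
                 protocol = proto, seed = raw$seed,
                 output = if (is.null(raw$output)) "." else raw$output),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("memstdp run configuration\n")
  print(x$network)
  cat(sprintf("  seed: %s; output: %s\n",
              if (is.null(x$seed)) "unset" else x$seed, x$output))
  invisible(x)
}
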