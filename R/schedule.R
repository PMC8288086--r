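#' Stimulation conditions and slice-locked session schedules
#'
#' The two experiments interleave TMS pulse trains with fMRI acquisition so
#' that every pulse lands in a known slice. Experiment 1 (TR 1000 ms, 25
#' descending slices of 40 ms) compares low-intensity 1 Hz trains,
#' high-intensity 1 Hz trains and high-intensity bursts (4 pulses 80 ms
#' apart, bursts every 2 s). Experiment 2 (TR 1240 ms, 31 descending slices
#' of 40 ms) delivers 30 pulses per trial every 1, 2, 3 or 5 slices, giving
#' 25, 12.5, 8.33 and 5 Hz.
#'
#' @name schedule
NULL

#' Define a stimulation condition
#'
#' @param name condition label
#' @param intensity percent of resting motor threshold (50 or 100)
#' @param pulse_offsets seconds of each pulse from trial onset, strictly
#'   increasing
#' @param trial_duration seconds from trial onset to the end of the
#'   stimulation window
#' @return an object of class `stim_condition`
#' @export
stim_condition <- function(name, intensity, pulse_offsets, trial_duration) {
  stopifnot(intensity %in% c(50, 100),
            all(diff(pulse_offsets) > 0),
            all(pulse_offsets < trial_duration + 1e-9))
  structure(list(name = name, intensity = intensity,
                 pulse_offsets = pulse_offsets,
                 trial_duration = trial_duration),
            class = "stim_condition")
}

#' Slice spacing to stimulation frequency
#'
#' Pulses delivered every `k` slices of `slice_ms` ms each arrive at
#' 1000 / (k * slice_ms) Hz; with 40-ms slices, spacings 1, 2, 3, 5 give
#' 25, 12.5, 8.33 and 5 Hz.
#'
#' @param k number of slices between consecutive pulses (>= 1)
#' @param slice_ms per-slice acquisition time in ms (> 0)
#' @return frequency in Hz (exact; round to 2 decimals for display)
#' @export
frequency_from_slice_spacing <- function(k, slice_ms) {
  if (any(k < 1) || any(slice_ms <= 0))
    stop("k must be >= 1 and slice_ms > 0")
  1000 / (k * slice_ms)
}

#' Map a slice-locked pulse train to (volume, slice) targets
#'
#' The train starts at slice 1 of `start_volume` and hits every k-th slice
#' thereafter, wrapping into subsequent volumes (n_slices slices each). With
#' k coprime-free wrapping, e.g. k = 2 over 31 slices, the first volume gets
#' slices 1, 3, ..., 31 and the second slices 2, 4, ..., 28, so no slice
#' repeats in consecutive volumes.
#'
#' @param condition a `stim_condition` (label recorded on each target)
#' @param start_volume 0-based volume index of the first pulse
#' @param k slice spacing
#' @param n_pulses number of pulses
#' @param n_slices slices per volume
#' @param tr_ms,slice_ms timing metadata used to stamp each target's time
#' @return data.frame with columns time (s), volume (0-based),
#'   slice (1-based acquisition order), condition
#' @export
pulses_to_slices <- function(condition, start_volume, k, n_pulses, n_slices,
                             tr_ms = 1240, slice_ms = 40) {
  gidx <- 1 + k * (seq_len(n_pulses) - 1)     # global slice index from train start
  vol <- start_volume + (gidx - 1) %/% n_slices
  slice <- (gidx - 1) %% n_slices + 1
  data.frame(time = vol * tr_ms / 1000 + (slice - 1) * slice_ms / 1000,
             volume = as.integer(vol), slice = as.integer(slice),
             condition = condition$name, stringsAsFactors = FALSE)
}

exp1_conditions <- function() {
  list(
    low1Hz  = stim_condition("low1Hz", 50, 0:9, 10),
    high1Hz = stim_condition("high1Hz", 100, 0:9, 10),
    # five bursts of four pulses 80 ms apart (12.5 Hz within burst),
    # consecutive bursts 2 s apart
    burst   = stim_condition("burst", 100,
                             as.vector(outer(c(0, 0.08, 0.16, 0.24),
                                             seq(0, 8, by = 2), "+")), 10)
  )
}

exp2_conditions <- function(slice_ms = 40) {
  ks <- c(hz5 = 5, hz8.33 = 3, hz12.5 = 2, hz25 = 1)
  out <- lapply(names(ks), function(nm) {
    k <- ks[[nm]]
    offs <- (seq_len(30) - 1) * k * slice_ms / 1000
    stim_condition(nm, 100, offs, 30 * k * slice_ms / 1000)
  })
  names(out) <- names(ks)
  out
}

#' Frequencies (Hz) of the Experiment-2 condition labels
#' @return named numeric vector
#' @export
exp2_frequencies <- function() c(hz5 = 5, hz8.33 = 25 / 3, hz12.5 = 12.5, hz25 = 25)

new_session_schedule <- function(experiment, tr_ms, n_slices, slice_ms,
                                 n_volumes_per_run, conditions, events, pulses) {
  stopifnot(n_slices * slice_ms <= tr_ms)
  structure(list(experiment = experiment, tr_ms = tr_ms, n_slices = n_slices,
                 slice_ms = slice_ms, n_volumes_per_run = n_volumes_per_run,
                 conditions = conditions, events = events, pulses = pulses),
            class = "session_schedule")
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("session_schedule (Experiment %d): %d runs x %d volumes, TR %g ms, %d slices\n",
              x$experiment, length(unique(x$events$run)), x$n_volumes_per_run,
              x$tr_ms, x$n_slices))
  cat(sprintf("  %d trials, %d pulses\n", nrow(x$events), nrow(x$pulses)))
  invisible(x)
}

#' Build an Experiment-1 session schedule
#'
#' Three 615-s runs (10-s lead-in, ten 60-s blocks, 5-s trailing scan) of 10
#' blocks each; a block holds one 10-s trial per condition in seed-randomized
#' order, each followed by a 10-s break. 1-Hz pulses land on slice 25 (the
#' deepest slice of the descending sequence); burst pulses land on slices 19,
#' 21, 23 and 25 of one volume. 400 pulses per run, 1,200 per session.
#'
#' @param seed integer seed controlling within-block condition order
#' @return a `session_schedule`
#' @export
build_exp1_session <- function(seed = 0L) {
  tr_ms <- 1000; n_slices <- 25L; slice_ms <- 40
  conds <- exp1_conditions()
  rng <- local({ set.seed(seed); lapply(1:30, function(i) sample(names(conds))) })
  events <- list(); pulses <- list()
  for (run in 1:3) {
    for (block in 1:10) {
      order_cb <- rng[[(run - 1) * 10 + block]]
      block_start <- 10 + (block - 1) * 60          # 10-s lead-in
      for (j in 1:3) {
        cond <- conds[[order_cb[j]]]
        onset <- block_start + (j - 1) * 20         # trial + 10-s break = 20 s
        events[[length(events) + 1L]] <-
          data.frame(onset = onset, duration = cond$trial_duration,
                     trial_type = cond$name, run = run, block = block)
        # slice-locked delivery: 1-Hz pulses during slice 25 of the volume
        # starting at each nominal pulse second; burst pulses during slices
        # 19, 21, 23, 25 of the volume starting at each burst onset
        if (cond$name %in% c("low1Hz", "high1Hz")) {
          vols <- onset + 0:9                        # TR = 1 s, volume index = start second
          pl <- data.frame(volume = as.integer(vols), slice = 25L)
        } else {
          burst_vols <- onset + seq(0, 8, by = 2)
          pl <- data.frame(volume = as.integer(rep(burst_vols, each = 4)),
                           slice = rep(c(19L, 21L, 23L, 25L), times = 5))
        }
        pl$time <- pl$volume * tr_ms / 1000 + (pl$slice - 1) * slice_ms / 1000
        pl$condition <- cond$name; pl$run <- run
        pulses[[length(pulses) + 1L]] <- pl[, c("time", "volume", "slice", "condition", "run")]
      }
    }
  }
  new_session_schedule(1L, tr_ms, n_slices, slice_ms, 615L, conds,
                       do.call(rbind, events), do.call(rbind, pulses))
}

#' Build an Experiment-2 session schedule
#'
#' Three 682-s runs (550 volumes at TR 1240 ms) of 5 blocks x 4 trials (one
#' per frequency, seed-randomized within block); consecutive trial onsets are
#' exactly 31 s (25 volumes) apart and aligned to volume boundaries. Each
#' trial delivers 30 pulses starting at slice 1 of its onset volume, every
#' 1, 2, 3 or 5 slices for the 25, 12.5, 8.33 and 5 Hz conditions. 1,800
#' pulses per session.
#'
#' @param seed integer seed controlling within-block condition order
#' @param lead_in_volumes volumes of rest before the first trial (default 10)
#' @return a `session_schedule`
#' @export
build_exp2_session <- function(seed = 0L, lead_in_volumes = 10L) {
  tr_ms <- 1240; n_slices <- 31L; slice_ms <- 40
  conds <- exp2_conditions(slice_ms)
  ks <- c(hz5 = 5L, hz8.33 = 3L, hz12.5 = 2L, hz25 = 1L)
  rng <- local({ set.seed(seed); lapply(1:15, function(i) sample(names(conds))) })
  events <- list(); pulses <- list()
  for (run in 1:3) {
    for (block in 1:5) {
      order_cb <- rng[[(run - 1) * 5 + block]]
      for (j in 1:4) {
        trial_idx <- (block - 1) * 4 + (j - 1)       # 0-based within run
        onset_vol <- lead_in_volumes + trial_idx * 25L
        cond <- conds[[order_cb[j]]]
        events[[length(events) + 1L]] <-
          data.frame(onset = onset_vol * tr_ms / 1000,
                     duration = cond$trial_duration,
                     trial_type = cond$name, run = run, block = block)
        pl <- pulses_to_slices(cond, onset_vol, ks[[cond$name]], 30L, n_slices,
                               tr_ms, slice_ms)
        pl$run <- run
        pulses[[length(pulses) + 1L]] <- pl
      }
    }
  }
  new_session_schedule(2L, tr_ms, n_slices, slice_ms, 550L, conds,
                       do.call(rbind, events), do.call(rbind, pulses))
}

#' Write a schedule to BIDS-style TSV files
#'
#' Writes one `events_run-XX.tsv` per run (onset, duration, trial_type,
#' block; onsets/durations in 6-decimal fixed point) plus a single
#' `pulses.tsv` (time, volume, slice, condition, run) and a JSON dump of the
#' timing metadata. The TSVs round-trip losslessly via [read_events()].
#'
#' @param schedule a `session_schedule`
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_events <- function(schedule, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  runs <- sort(unique(schedule$events$run))
  if (!length(runs)) runs <- integer()
  fmt <- function(x) sprintf("%.6f", x)
  for (r in runs) {
    ev <- schedule$events[schedule$events$run == r, , drop = FALSE]
    out <- data.frame(onset = fmt(ev$onset), duration = fmt(ev$duration),
                      trial_type = ev$trial_type, block = ev$block)
    p <- file.path(dir, sprintf("events_run-%02d.tsv", r))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!nrow(schedule$events)) {
    p <- file.path(dir, "events_run-01.tsv")
    utils::write.table(schedule$events[, c("onset", "duration", "trial_type", "block")],
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  pp <- file.path(dir, "pulses.tsv")
  pu <- schedule$pulses
  if (nrow(pu)) pu$time <- fmt(pu$time)
  utils::write.table(pu, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(schema_version = "1.0", experiment = schedule$experiment,
               tr_ms = schedule$tr_ms, n_slices = schedule$n_slices,
               slice_ms = schedule$slice_ms,
               n_volumes_per_run = schedule$n_volumes_per_run)
  jp <- file.path(dir, "schedule.json")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, pp, jp))
}

#' Read events TSVs written by write_events
#' @param dir directory containing events_run-XX.tsv files
#' @return data.frame with onset, duration, trial_type, block, run
#' @export
read_events <- function(dir) {
  files <- sort(list.files(dir, pattern = "^events_run-[0-9]+\\.tsv$",
                           full.names = TRUE))
  out <- lapply(files, function(f) {
    ev <- utils::read.delim(f, stringsAsFactors = FALSE)
    if (nrow(ev))
      ev$run <- as.integer(sub("^.*events_run-([0-9]+)\\.tsv$", "\\1", f))
    ev
  })
  do.call(rbind, out)
}
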