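#' Phase-encoded stimulation protocol
#'
#' Timing constants of the traveling-wave design: each cycle stimulates the
#' four fingertips (d2, d3, d4, d5) for `s_per_finger` seconds each, followed
#' by `rest_s` seconds of rest; `cycles_per_run` cycles are delivered in each
#' of `n_runs` functional runs sampled at `tr_s`. The defaults encode 6 s per
#' finger, 6 s rest, 12 cycles/run, 4 runs, TR = 2 s and 183 volumes of which
#' the first 3 are dummies, giving a stimulus frequency of 1/30 Hz and a
#' 360 s analysed run.
#'
#' The hemodynamic response enters the analysis only as a constant phase
#' offset `2*pi*hemodynamic_delay_s/cycle_s`, used when converting phase to
#' finger preference.
#'
#' @param tr_s repetition time, s.
#' @param volumes_per_run volumes acquired per run.
#' @param dummy_volumes initial volumes discarded from analysis.
#' @param n_runs number of functional runs.
#' @param s_per_finger stimulation time per fingertip, s.
#' @param n_fingers number of fingers stimulated per cycle.
#' @param rest_s rest after each cycle, s.
#' @param cycles_per_run stimulation cycles per run.
#' @param hemodynamic_delay_s assumed BOLD delay, s (affects finger
#'   labelling only, no test statistic).
#' @return object of class `stim_protocol`; derived elements: `cycle_s`
#'   (cycle duration), `stim_freq_hz`, `n_kept` (analysed volumes/run),
#'   `stim_bin` (DFT bin of the stimulus frequency), `stim_fraction`
#'   (stimulated fraction of the cycle), `delay_offset_rad`.
#' @export
stim_protocol <- function(tr_s = 2, volumes_per_run = 183, dummy_volumes = 3,
                          n_runs = 4, s_per_finger = 6, n_fingers = 4,
                          rest_s = 6, cycles_per_run = 12,
                          hemodynamic_delay_s = 5) {
  cycle_s <- n_fingers * s_per_finger + rest_s
  n_kept <- volumes_per_run - dummy_volumes
  if (abs(cycles_per_run * cycle_s - n_kept * tr_s) > 1e-9) {
    stop("inconsistent protocol: cycles_per_run * cycle length (",
         cycles_per_run * cycle_s, " s) must equal the analysed run duration (",
         n_kept * tr_s, " s)")
  }
  structure(list(
    tr_s = tr_s, volumes_per_run = volumes_per_run,
    dummy_volumes = dummy_volumes, n_runs = n_runs,
    s_per_finger = s_per_finger, n_fingers = n_fingers, rest_s = rest_s,
    cycles_per_run = cycles_per_run, hemodynamic_delay_s = hemodynamic_delay_s,
    cycle_s = cycle_s, stim_freq_hz = 1 / cycle_s, n_kept = n_kept,
    stim_bin = cycles_per_run,
    stim_fraction = n_fingers * s_per_finger / cycle_s,
    delay_offset_rad = 2 * pi * hemodynamic_delay_s / cycle_s),
    class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(paste0("<stim_protocol: %d fingers x %g s + %g s rest, ",
                     "%d cycles/run, %d runs, TR=%g s, f_stim=%.4g Hz>\n"),
              x$n_fingers, x$s_per_finger, x$rest_s, x$cycles_per_run,
              x$n_runs, x$tr_s, x$stim_freq_hz))
  invisible(x)
}
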